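# Brute-force oracles, independent of the package's implementations.

adjacency_from_net <- function(net) {
  nodes <- net$nodes$canonical_key
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_data_frame(net$graph, what = "edges")
  for (i in seq_len(nrow(el))) {
    A[el$from[i], el$to[i]] <- A[el$from[i], el$to[i]] + el$weight[i]
    A[el$to[i], el$from[i]] <- A[el$to[i], el$from[i]] + el$weight[i]
  }
  A
}

# all-simple-paths betweenness with distances = 1/weight
oracle_betweenness <- function(net, weighted = TRUE) {
  A <- adjacency_from_net(net)
  n <- nrow(A)
  D <- ifelse(A > 0, if (weighted) 1 / A else 1, Inf)
  bc <- stats::setNames(numeric(n), rownames(A))
  if (n < 3) return(bc)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      rec <- function(v, visited, len) {
        if (v == t) {
          paths[[length(paths) + 1]] <<- list(nodes = visited, len = len)
          return(invisible())
        }
        for (u in which(is.finite(D[v, ]))) {
          if (!(u %in% visited)) rec(u, c(visited, u), len + D[v, u])
        }
      }
      rec(s, s, 0)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(p) p$len, numeric(1))
      best <- min(lens)
      sel <- which(lens <= best + best * 1e-9 + 1e-12)
      inc <- numeric(n)
      for (i in sel) {
        interior <- setdiff(paths[[i]]$nodes, c(s, t))
        inc[interior] <- inc[interior] + 1
      }
      bc <- bc + inc / length(sel)
    }
  }
  bc
}

# power-iteration PageRank on the weighted undirected graph
oracle_pagerank <- function(net, damping = 0.85, tol = 1e-14) {
  A <- adjacency_from_net(net)
  n <- nrow(A)
  strength <- rowSums(A)
  x <- rep(1 / n, n)
  for (iter in 1:100000) {
    inflow <- numeric(n)
    dangling <- 0
    for (i in 1:n) {
      if (strength[i] > 0) {
        inflow <- inflow + x[i] * A[i, ] / strength[i]
      } else {
        dangling <- dangling + x[i]
      }
    }
    x_new <- (1 - damping) / n + damping * (inflow + dangling / n)
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  stats::setNames(x, rownames(A))
}

# direct evaluation of weighted Newman modularity
oracle_modularity <- function(net, membership) {
  A <- adjacency_from_net(net)
  two_m <- sum(A)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in 1:n) {
    for (j in 1:n) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - k[i] * k[j] / two_m
      }
    }
  }
  unname(q / two_m)
}

# weighted categorical assortativity from the mixing matrix
oracle_assortativity <- function(net, cats) {
  A <- adjacency_from_net(net)
  levels <- sort(unique(cats))
  k <- length(levels)
  e <- matrix(0, k, k, dimnames = list(levels, levels))
  n <- nrow(A)
  for (i in 1:n) {
    for (j in 1:n) {
      e[cats[i], cats[j]] <- e[cats[i], cats[j]] + A[i, j]
    }
  }
  e <- e / sum(e)
  a <- rowSums(e)
  (sum(diag(e)) - sum(a^2)) / (1 - sum(a^2))
}

# exhaustive-permutation two-sided Wilcoxon rank-sum p-value via bitmasks
oracle_wilcoxon_p <- function(a, b) {
  n <- length(a)
  N <- n + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  masks <- 0:(2^N - 1)
  bits <- matrix(as.integer(intToBits(masks)), nrow = 32)[seq_len(N), ,
                                                          drop = FALSE]
  keep <- colSums(bits) == n
  ws <- as.numeric(crossprod(bits[, keep, drop = FALSE], r))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
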