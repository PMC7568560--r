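#' Pairwise co-authorship weight
#'
#' The weight of one co-authorship link from one manuscript is the product
#' of the two authors' manuscript-specific impact scores divided by the
#' total number of authors on the manuscript. Dividing by team size damps
#' any single link on a large multi-institutional paper while letting the
#' total weight of the paper's neighborhood grow linearly with team size.
#'
#' @param score_i,score_j Manuscript-specific impact scores of the two
#'   authors.
#' @param n_authors Total number of authors on the manuscript (>= 2).
#'
#' @return Non-negative numeric weight(s).
#' @export
#'
#' @examples
#' coauthorship_weight(0.2, 0.2, 10)
coauthorship_weight <- function(score_i, score_j, n_authors) {
  if (any(n_authors < 2)) {
    abort("a co-authorship pair requires at least 2 authors",
          class = "trialnet_network_error")
  }
  score_i * score_j / n_authors
}

#' Build the cumulative co-authorship network at a given year
#'
#' Collects every record with `year <= up_to_year` into a weighted
#' co-authorship multigraph: one edge per unordered author pair per
#' manuscript, weighted by [coauthorship_weight()]. Node attributes carry
#' each author's cumulative impact at the cutoff plus (optionally) gender
#' and primary subspecialty. A weight-summed simple-graph view is kept
#' alongside the multigraph; all network metrics run on the simple view
#' while the multigraph retains edge-level provenance.
#'
#' @param ledger An [impact_ledger()] for the corpus (already
#'   canonicalized via its `mapping` argument).
#' @param up_to_year Inclusive year cutoff.
#' @param node_attrs Optional tibble `canonical_key`, `gender`,
#'   `subspecialty` attaching attributes to nodes; unknown keys are
#'   ignored, missing ones get `NA`.
#'
#' @return An object of class `yearly_network`: a list with `year`,
#'   `nodes` (tibble `canonical_key`, `impact`, `gender`, `subspecialty`),
#'   `edges` (multigraph tibble `record_id`, `from`, `to`, `weight`) and
#'   `graph` (weighted simple [igraph::graph]).
#' @export
build_network <- function(ledger, up_to_year, node_attrs = NULL) {
  led <- as_tibble(ledger)[, c("record_id", "year", "canonical_key", "score")]
  led <- led[led$year <= up_to_year, , drop = FALSE]
  per_rec <- distinct(led, .data$record_id, .data$canonical_key,
                      .keep_all = TRUE)
  per_rec <- per_rec[order(per_rec$record_id, per_rec$canonical_key), ]

  edge_rows <- purrr::map(split(per_rec, per_rec$record_id), function(rec) {
    k <- nrow(rec)
    if (k < 2) return(NULL)
    pairs <- combn(k, 2)
    tibble(
      record_id = rec$record_id[[1]],
      from = rec$canonical_key[pairs[1, ]],
      to = rec$canonical_key[pairs[2, ]],
      weight = coauthorship_weight(rec$score[pairs[1, ]],
                                   rec$score[pairs[2, ]], k)
    )
  })
  edges <- bind_rows(edge_rows)
  if (nrow(edges) == 0) {
    edges <- tibble(record_id = character(), from = character(),
                    to = character(), weight = numeric())
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$record_id, edges$from, edges$to), ]

  nodes <- cumulative_impact(ledger, up_to_year = up_to_year)
  nodes$gender <- NA_character_
  nodes$subspecialty <- NA_character_
  if (!is.null(node_attrs)) {
    m <- match(nodes$canonical_key, node_attrs$canonical_key)
    if ("gender" %in% names(node_attrs)) {
      nodes$gender <- as.character(node_attrs$gender)[m]
    }
    if ("subspecialty" %in% names(node_attrs)) {
      nodes$subspecialty <- as.character(node_attrs$subspecialty)[m]
    }
  }

  simple <- edges %>%
    group_by(.data$from, .data$to) %>%
    summarise(weight = sum(.data$weight), .groups = "drop") %>%
    arrange(.data$from, .data$to)
  g <- igraph::graph_from_data_frame(
    simple,
    directed = FALSE,
    vertices = data.frame(name = nodes$canonical_key,
                          stringsAsFactors = FALSE)
  )
  structure(
    list(year = up_to_year, nodes = nodes, edges = edges, graph = g),
    class = "yearly_network"
  )
}

#' @export
print.yearly_network <- function(x, ...) {
  cat(sprintf(
    "<yearly_network %s: %d authors, %d links (%d co-authorship edges)>\n",
    x$year, nrow(x$nodes), igraph::ecount(x$graph), nrow(x$edges)))
  invisible(x)
}

#' Network density from link and author counts
#'
#' Fraction of realized distinct co-author pairs among all `n(n-1)/2`
#' possible pairs.
#'
#' @param n_links Number of distinct co-author pairs.
#' @param n_authors Number of authors (>= 2).
#'
#' @return Density as a fraction in \[0, 1\].
#' @export
#'
#' @examples
#' link_density(30, 12)      # 0.4545...
#' link_density(697084, 29197)
link_density <- function(n_links, n_authors) {
  if (any(n_authors < 2)) {
    abort("density requires at least 2 authors",
          class = "trialnet_network_error")
  }
  n_links / (n_authors * (n_authors - 1) / 2)
}

#' Density of a yearly network
#'
#' Multi-edges collapse to one distinct pair.
#'
#' @param net A [build_network()] result.
#' @return Density as a fraction.
#' @export
net_density <- function(net) {
  link_density(igraph::ecount(net$graph), nrow(net$nodes))
}

node_categories <- function(net, by, none_label = "None") {
  cats <- net$nodes[[by]]
  if (is.null(cats)) {
    abort(sprintf("unknown node attribute '%s'", by),
          class = "trialnet_network_error")
  }
  if (by == "subspecialty") cats[is.na(cats)] <- none_label
  cats
}

#' Weighted modularity of the subspecialty (or any categorical) partition
#'
#' Newman modularity of the weight-summed simple-graph view under the
#' partition given by a node attribute: the fraction of edge weight falling
#' within communities minus the fraction expected if edges were placed at
#' random with the same weighted degrees. Authors without a subspecialty
#' (`NA`) are grouped into a single `"None"` community.
#'
#' @param net A [build_network()] result.
#' @param by Node attribute defining the partition (default
#'   `"subspecialty"`).
#'
#' @return Modularity in \[-0.5, 1\].
#' @export
net_modularity <- function(net, by = "subspecialty") {
  if (igraph::ecount(net$graph) == 0) {
    abort("modularity undefined on a network with no links",
          class = "trialnet_network_error")
  }
  cats <- node_categories(net, by)
  membership <- as.integer(factor(cats))
  igraph::modularity(net$graph, membership,
                     weights = igraph::E(net$graph)$weight)
}

#' Weighted categorical assortativity
#'
#' The assortativity coefficient for a discrete node attribute, computed on
#' the weight-summed simple-graph view: with `e[k, l]` the fraction of
#' total edge weight joining categories `k` and `l` (each undirected edge
#' counted in both directions) and `a[k] = sum_l e[k, l]`,
#' `r = (sum_k e[k, k] - sum_k a[k]^2) / (1 - sum_k a[k]^2)`. Positive when
#' like connects to like, -1 for perfect disassortativity. Edges incident
#' to a node with an undefined attribute are excluded.
#'
#' @param net A [build_network()] result.
#' @param by Node attribute (default `"subspecialty"`).
#'
#' @return Assortativity in \[-1, 1\].
#' @export
net_assortativity <- function(net, by = "subspecialty") {
  cats <- node_categories(net, by)
  names(cats) <- net$nodes$canonical_key
  el <- igraph::as_data_frame(net$graph, what = "edges")
  c1 <- cats[el$from]
  c2 <- cats[el$to]
  keep <- !is.na(c1) & !is.na(c2)
  el <- el[keep, , drop = FALSE]
  c1 <- c1[keep]
  c2 <- c2[keep]
  if (nrow(el) == 0) {
    abort("assortativity undefined: no links between labelled nodes",
          class = "trialnet_network_error")
  }
  levels <- sort(unique(c(c1, c2)))
  if (length(levels) < 2) {
    abort("assortativity undefined with a single category",
          class = "trialnet_network_error")
  }
  k <- length(levels)
  e <- matrix(0, k, k, dimnames = list(levels, levels))
  for (i in seq_len(nrow(el))) {
    a <- c1[[i]]; b <- c2[[i]]; w <- el$weight[[i]]
    e[a, b] <- e[a, b] + w
    e[b, a] <- e[b, a] + w
  }
  e <- e / sum(e)
  ai <- rowSums(e)
  denom <- 1 - sum(ai^2)
  if (denom <= 0) {
    abort("assortativity undefined: degenerate mixing matrix",
          class = "trialnet_network_error")
  }
  (sum(diag(e)) - sum(ai^2)) / denom
}

effective_weights <- function(w) {
  # zero-weight links (both endpoint scores zero) get a negligible positive
  # floor so reciprocal-weight distances stay finite
  if (any(w <= 0)) {
    pos <- w[w > 0]
    floor_w <- if (length(pos) == 0) 1 else min(pos) * 1e-9
    w[w <= 0] <- floor_w
  }
  w
}

#' Betweenness centrality
#'
#' Weighted shortest-path betweenness on the simple-graph view, with
#' distance the reciprocal of the summed link weight (stronger
#' collaboration = shorter path). Pairs in different components contribute
#' nothing. The normalized variant divides by the maximum score.
#'
#' @param net A [build_network()] result.
#' @param weighted Use reciprocal-weight distances (default `TRUE`);
#'   otherwise hop counts.
#'
#' @return A tibble `canonical_key`, `betweenness`, `betweenness_norm`.
#' @export
net_betweenness <- function(net, weighted = TRUE) {
  g <- net$graph
  w <- if (weighted && igraph::ecount(g) > 0) {
    1 / effective_weights(igraph::E(g)$weight)
  } else {
    NA
  }
  b <- igraph::betweenness(g, directed = FALSE, weights = w)
  mx <- max(b, 0)
  tibble(
    canonical_key = igraph::V(g)$name,
    betweenness = unname(b),
    betweenness_norm = if (mx > 0) unname(b) / mx else rep(0, length(b))
  ) %>% arrange(.data$canonical_key)
}

#' PageRank centrality
#'
#' Weighted PageRank on the simple-graph view (undirected links walked in
#' both directions, link weights as transition propensities). The scores
#' form a probability vector summing to one.
#'
#' @param net A [build_network()] result.
#' @param damping Damping factor (default 0.85).
#' @param weighted Use link weights (default `TRUE`).
#'
#' @return A tibble `canonical_key`, `pagerank`.
#' @export
net_pagerank <- function(net, damping = 0.85, weighted = TRUE) {
  g <- net$graph
  w <- if (weighted && igraph::ecount(g) > 0) {
    effective_weights(igraph::E(g)$weight)
  } else {
    NA
  }
  pr <- igraph::page_rank(g, damping = damping, weights = w)$vector
  tibble(canonical_key = igraph::V(g)$name, pagerank = unname(pr)) %>%
    arrange(.data$canonical_key)
}

#' Per-author homophily
#'
#' The proportion of an author's co-authors sharing their attribute value.
#' Mode `"neighbors"` counts distinct co-authors; mode `"outlinks"` weights
#' each co-author by the summed link weight, giving the weight share of
#' incident links whose far end matches. Authors without a defined
#' attribute value (subspecialty `"None"`/`NA`; gender other than
#' woman/man) are excluded both as egos and from their co-authors'
#' denominators, and authors with no remaining co-author are dropped
#' (homophily is not calculable for them).
#'
#' @param net A [build_network()] result.
#' @param attribute `"subspecialty"` or `"gender"`.
#' @param mode `"neighbors"` or `"outlinks"`.
#'
#' @return A tibble `canonical_key`, `value`, `homophily`, `n_coauthors`.
#' @export
net_homophily <- function(net, attribute = c("subspecialty", "gender"),
                          mode = c("neighbors", "outlinks")) {
  attribute <- match.arg(attribute)
  mode <- match.arg(mode)
  cats <- net$nodes[[attribute]]
  names(cats) <- net$nodes$canonical_key
  defined <- if (attribute == "gender") {
    !is.na(cats) & cats %in% c("woman", "man")
  } else {
    !is.na(cats) & cats != "None"
  }
  el <- igraph::as_data_frame(net$graph, what = "edges")
  keep <- defined[el$from] & defined[el$to]
  el <- el[keep, , drop = FALSE]
  if (nrow(el) == 0) {
    return(tibble(canonical_key = character(), value = character(),
                  homophily = numeric(), n_coauthors = integer()))
  }
  half <- bind_rows(
    tibble(ego = el$from, alter = el$to, weight = el$weight),
    tibble(ego = el$to, alter = el$from, weight = el$weight)
  )
  half$match <- cats[half$ego] == cats[half$alter]
  out <- half %>%
    group_by(.data$ego) %>%
    summarise(
      homophily = if (.env$mode == "neighbors") {
        mean(.data$match)
      } else {
        if (sum(.data$weight) > 0) {
          sum(.data$weight[.data$match]) / sum(.data$weight)
        } else {
          mean(.data$match)
        }
      },
      n_coauthors = dplyr::n(),
      .groups = "drop"
    ) %>%
    rename(canonical_key = "ego")
  out$value <- unname(cats[out$canonical_key])
  out %>%
    select("canonical_key", "value", "homophily", "n_coauthors") %>%
    arrange(.data$canonical_key)
}

#' Concentration of links and impact among top-impact authors
#'
#' Ranks authors by cumulative impact (ties broken by key), takes the top
#' `ceiling(top_fraction * n)`, and reports their share of multigraph edge
#' endpoints and of total impact.
#'
#' @param net A [build_network()] result.
#' @param top_fraction Fraction of authors to take, in (0, 1).
#'
#' @return A one-row tibble `top_fraction`, `n_top`, `share_links`,
#'   `share_impact`.
#' @export
concentration <- function(net, top_fraction = 0.1) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("top_fraction must be in (0, 1)", class = "trialnet_network_error")
  }
  nodes <- net$nodes
  if (nrow(nodes) == 0) {
    abort("empty network", class = "trialnet_network_error")
  }
  ord <- order(-nodes$impact, nodes$canonical_key)
  k <- ceiling(top_fraction * nrow(nodes))
  top <- nodes$canonical_key[ord[seq_len(k)]]
  endpoints <- c(net$edges$from, net$edges$to)
  share_links <- if (length(endpoints) > 0) {
    mean(endpoints %in% top)
  } else {
    NA_real_
  }
  total <- sum(nodes$impact)
  share_impact <- if (total > 0) {
    sum(nodes$impact[ord[seq_len(k)]]) / total
  } else {
    NA_real_
  }
  tibble(top_fraction = top_fraction, n_top = k,
         share_links = share_links, share_impact = share_impact)
}

#' Share of authors in the largest connected component
#'
#' @param net A [build_network()] result.
#' @return Fraction in (0, 1\].
#' @export
largest_component_share <- function(net) {
  if (nrow(net$nodes) == 0) {
    abort("empty network", class = "trialnet_network_error")
  }
  comp <- igraph::components(net$graph)
  max(comp$csize) / nrow(net$nodes)
}

#' Export a yearly network
#'
#' GraphML export carries node attributes (impact, gender, subspecialty)
#' and summed link weights on the simple-graph view; the edge-list export
#' is a tab-separated `from`, `to`, `weight` table.
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"`.
#'
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net$graph
    m <- match(igraph::V(g)$name, net$nodes$canonical_key)
    g <- igraph::set_vertex_attr(g, "impact", value = net$nodes$impact[m])
    g <- igraph::set_vertex_attr(
      g, "gender", value = ifelse(is.na(net$nodes$gender[m]), "",
                                  net$nodes$gender[m]))
    g <- igraph::set_vertex_attr(
      g, "subspecialty", value = ifelse(is.na(net$nodes$subspecialty[m]), "",
                                        net$nodes$subspecialty[m]))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(net$graph, what = "edges")
    readr::write_tsv(as_tibble(el), path, progress = FALSE)
  }
  invisible(path)
}

#' Per-year cumulative network metric series
#'
#' Builds the cumulative network at each requested year and tabulates its
#' summary metrics. Degenerate years (fewer than 2 authors, no links, or a
#' single subspecialty) report `NA` for the undefined metrics.
#'
#' @param ledger An [impact_ledger()].
#' @param years Years at which to discretize; default every calendar year
#'   from the first to the last publication.
#' @param node_attrs_by_year Optional tibble `canonical_key`, `year`,
#'   `subspecialty` (and optionally `gender`) giving each author's
#'   attribute state per assignment year; the latest state at or before
#'   each network year is used.
#' @param damping PageRank damping factor.
#' @param weighted Use link weights in centrality metrics.
#'
#' @return A tibble with one row per year: `year`, `n_authors`, `n_links`,
#'   `n_edges`, `density`, `modularity`, `assortativity`,
#'   `median_pagerank`, `lcc_share`.
#' @export
yearly_metrics <- function(ledger, years = NULL, node_attrs_by_year = NULL,
                           damping = 0.85, weighted = TRUE) {
  if (nrow(ledger) == 0) {
    abort("empty ledger", class = "trialnet_network_error")
  }
  if (is.null(years)) {
    years <- seq(min(ledger$year), max(ledger$year))
  }
  rows <- purrr::map(years, function(y) {
    attrs <- NULL
    if (!is.null(node_attrs_by_year)) {
      attrs <- node_attrs_by_year %>%
        filter(.data$year <= y) %>%
        group_by(.data$canonical_key) %>%
        slice(which.max(.data$year)) %>%
        ungroup()
    }
    net <- build_network(ledger, up_to_year = y, node_attrs = attrs)
    n <- nrow(net$nodes)
    tibble(
      year = y,
      n_authors = n,
      n_links = igraph::ecount(net$graph),
      n_edges = nrow(net$edges),
      density = if (n >= 2) net_density(net) else NA_real_,
      modularity = tryCatch(net_modularity(net), error = function(e) NA_real_),
      assortativity = tryCatch(net_assortativity(net),
                               error = function(e) NA_real_),
      median_pagerank = if (n >= 1) {
        median(net_pagerank(net, damping = damping,
                            weighted = weighted)$pagerank)
      } else {
        NA_real_
      },
      lcc_share = if (n >= 1) largest_component_share(net) else NA_real_
    )
  })
  bind_rows(rows)
}
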