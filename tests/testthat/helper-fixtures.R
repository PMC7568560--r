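# Small corpora built in code for unit tests.

make_record <- function(record_id, year, authors, citations = 100L,
                        randomized = TRUE, update_index = 0L,
                        pooled = NULL, weights = c(breast = 1),
                        journal_tier = 1L, equal_contrib = NULL) {
  n <- length(authors)
  if (is.null(equal_contrib)) equal_contrib <- rep(FALSE, n)
  tibble::tibble(
    record_id = record_id, year = as.integer(year),
    journal_tier = as.integer(journal_tier), randomized = randomized,
    update_index = as.integer(update_index),
    pooled_update_indices = list(pooled),
    citations = as.integer(citations), positive_trial = NA,
    subspecialty_weights = list(weights),
    authors = list(tibble::tibble(
      raw_name = authors, position = seq_len(n),
      equal_contrib = equal_contrib
    ))
  )
}

toy_corpus <- function() {
  trial_corpus(dplyr::bind_rows(
    make_record("r1", 1995, c("Alpha_Anna", "Beta_Bob", "Gamma_Grace"),
                citations = 200L, randomized = TRUE),
    make_record("r2", 1998, c("Alpha_Anna", "Delta_Dan"),
                citations = 50L, randomized = FALSE,
                weights = c(breast = 0.5, lymphoma = 0.5)),
    make_record("r3", 2001, c("Beta_Bob", "Epsilon_Eve", "Zeta_Zoe"),
                citations = 100L, update_index = 1L,
                weights = c(lymphoma = 1))
  ))
}

# a network object assembled directly from an edge table, mirroring the
# shape build_network() produces, for metric-oracle tests
make_network <- function(edges, impacts = NULL, gender = NULL,
                         subspecialty = NULL, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!"record_id" %in% names(edges)) {
    edges$record_id <- sprintf("e%03d", seq_len(nrow(edges)))
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  node_tbl <- tibble::tibble(
    canonical_key = nodes,
    impact = if (is.null(impacts)) rep(1, length(nodes)) else impacts,
    gender = if (is.null(gender)) NA_character_ else gender,
    subspecialty = if (is.null(subspecialty)) NA_character_ else subspecialty
  )
  simple <- edges |>
    dplyr::group_by(from, to) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop") |>
    dplyr::arrange(from, to)
  g <- igraph::graph_from_data_frame(
    simple, directed = FALSE,
    vertices = data.frame(name = node_tbl$canonical_key))
  structure(list(year = 0L, nodes = node_tbl, edges = edges, graph = g),
            class = "yearly_network")
}

# random connected-ish weighted graph on n nodes; resamples until no
# isolated vertex
random_graph_edges <- function(n, p = 0.45, weight_fun = stats::runif) {
  repeat {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep)) next
    sel <- pairs[, keep, drop = FALSE]
    if (all(seq_len(n) %in% c(sel[1, ], sel[2, ]))) {
      labels <- sprintf("v%02d", seq_len(n))
      return(tibble::tibble(
        from = labels[sel[1, ]], to = labels[sel[2, ]],
        weight = weight_fun(ncol(sel))
      ))
    }
  }
}
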