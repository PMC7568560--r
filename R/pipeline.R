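#' Simulate a corpus and write it to disk
#'
#' Writes the corpus in the requested dialect, the ground truth as JSON,
#' the name lookup tables as TSV, and a run manifest recording the
#' configuration and file checksums. Re-running with the same
#' configuration produces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param dialect Corpus dialect, `"jsonl"` or `"table"`.
#'
#' @return Invisibly, a named list of the files written.
#' @export
run_simulation <- function(config = sim_config(), out_dir,
                           dialect = "jsonl") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_corpus(config)
  corpus_path <- file.path(out_dir, paste0(
    "corpus.", if (dialect == "jsonl") "jsonl" else "tsv"))
  write_corpus(sim$corpus, corpus_path, dialect = dialect)
  truth_path <- file.path(out_dir, "ground_truth.json")
  truth <- list(
    config = unclass(sim$ground_truth$config),
    authors = sim$ground_truth$authors
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  freq_path <- file.path(out_dir, "name_frequency.tsv")
  dict_path <- file.path(out_dir, "name_dictionary.tsv")
  readr::write_tsv(sim$tables$freq_table, freq_path, progress = FALSE)
  readr::write_tsv(sim$tables$dictionary_table, dict_path, progress = FALSE)
  files <- c(corpus = corpus_path, ground_truth = truth_path,
             freq_table = freq_path, dictionary_table = dict_path)
  write_manifest(out_dir, files, config = list(seed = config$seed,
                                               dialect = dialect))
  invisible(as.list(files))
}

write_manifest <- function(out_dir, files, config) {
  manifest <- list(
    package = "trialnet",
    config = config,
    files = purrr::map(unname(files), function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end analysis and write the report bundle
#'
#' Chains identity resolution, impact scoring, per-year career assignment,
#' the yearly network metric series, homophily, the gender comparisons and
#' the gender trend, and writes: the per-year metrics table, the career
#' table, the comparison tables, the final-network GraphML export and a
#' run manifest. All outputs are deterministic functions of the inputs.
#'
#' @param corpus A [trial_corpus()] (or a corpus file path).
#' @param out_dir Output directory.
#' @param config An [impact_config()].
#' @param alias_table,freq_table,dictionary_table,override_table Identity
#'   lookup tables (see [author_identities()]).
#' @param dialect Dialect used when `corpus` is a path.
#' @param damping,weighted Network metric options.
#' @param parity_window Trailing window of the parity extrapolation.
#'
#' @return Invisibly, a list with the in-memory results (`identities`,
#'   `ledger`, `metrics`, `careers`, `network`, `comparisons`, `trend`)
#'   and the files written.
#' @export
run_analysis <- function(corpus, out_dir, config = impact_config(),
                         alias_table = NULL, freq_table = NULL,
                         dictionary_table = NULL, override_table = NULL,
                         dialect = "jsonl", damping = 0.85, weighted = TRUE,
                         parity_window = 30L) {
  if (is.character(corpus)) {
    corpus <- read_corpus(corpus, dialect = dialect)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- author_identities(corpus, alias_table = alias_table,
                           freq_table = freq_table,
                           dictionary_table = dictionary_table,
                           override_table = override_table)
  ledger <- impact_ledger(corpus, mapping = ids$mapping, config = config)
  hist <- career_history(ledger)
  horizon <- max(corpus$year)
  cars <- careers(ledger, identities = ids$identities, horizon = horizon)

  attrs_by_year <- history_node_attrs(hist)
  metrics <- yearly_metrics(ledger, node_attrs_by_year = attrs_by_year,
                            damping = damping, weighted = weighted)

  final_attrs <- attrs_by_year %>%
    group_by(.data$canonical_key) %>%
    slice(which.max(.data$year)) %>%
    ungroup() %>%
    left_join(ids$identities[, c("canonical_key", "gender")],
              by = "canonical_key")
  net <- build_network(ledger, up_to_year = horizon,
                       node_attrs = final_attrs)

  comparisons <- gender_comparisons(cars)
  trend <- new_author_trend(ledger, ids$identities,
                            parity_window = parity_window)

  metrics_path <- file.path(out_dir, "yearly_metrics.tsv")
  readr::write_tsv(metrics, metrics_path, progress = FALSE)
  careers_path <- file.path(out_dir, "careers.tsv")
  readr::write_tsv(cars, careers_path, progress = FALSE)
  comp_path <- file.path(out_dir, "comparisons.tsv")
  readr::write_tsv(comparisons, comp_path, progress = FALSE)
  trend_path <- file.path(out_dir, "gender_trend.tsv")
  trend_tbl <- if (is.null(trend)) {
    tibble(year = integer(), n_women = integer(), n_total = integer(),
           proportion = numeric(), smoothed = numeric())
  } else {
    tidy(trend)
  }
  readr::write_tsv(trend_tbl, trend_path, progress = FALSE)
  graph_path <- file.path(out_dir, "final_network.graphml")
  export_network(net, graph_path, format = "graphml")

  files <- c(metrics = metrics_path, careers = careers_path,
             comparisons = comp_path, trend = trend_path,
             graph = graph_path)
  write_manifest(out_dir, files,
                 config = list(damping = damping, weighted = weighted,
                               parity_window = parity_window))
  invisible(list(identities = ids, ledger = ledger, metrics = metrics,
                 careers = cars, network = net, comparisons = comparisons,
                 trend = trend, files = as.list(files)))
}

#' Gender comparison tables for a career table
#'
#' Wilcoxon comparisons of cumulative impact and longevity between women
#' and men, and of impact/longevity between authors who changed primary
#' subspecialty (longevity >= 1 year) and those who did not.
#'
#' @param cars A [careers()] table with `gender`.
#'
#' @return A tibble with one row per (comparison, group): `comparison`,
#'   `group`, `n`, `median`, `q1`, `q3`, `p_value`.
#' @export
gender_comparisons <- function(cars) {
  rows <- list()
  add <- function(comparison, a, b, labels) {
    if (length(a) == 0 || length(b) == 0) return()
    cmp <- compare_groups(a, b, labels = labels)
    tab <- cmp$summary
    tab$comparison <- comparison
    tab$p_value <- cmp$p_value
    rows[[length(rows) + 1]] <<- tab
  }
  women <- cars[!is.na(cars$gender) & cars$gender == "woman", ]
  men <- cars[!is.na(cars$gender) & cars$gender == "man", ]
  add("impact_by_gender", men$impact, women$impact, c("man", "woman"))
  add("longevity_by_gender", men$longevity, women$longevity,
      c("man", "woman"))
  durable <- cars[cars$longevity >= 1, ]
  changed <- durable[durable$changed_subspecialty, ]
  stayed <- durable[!durable$changed_subspecialty, ]
  add("impact_by_subspecialty_change", changed$impact, stayed$impact,
      c("changed", "stayed"))
  add("longevity_by_subspecialty_change", changed$longevity,
      stayed$longevity, c("changed", "stayed"))
  if (length(rows) == 0) {
    return(tibble(comparison = character(), group = character(),
                  n = integer(), median = numeric(), q1 = numeric(),
                  q3 = numeric(), p_value = numeric()))
  }
  bind_rows(rows) %>%
    select("comparison", "group", "n", "median", "q1", "q3", "p_value")
}

#' Yearly new-author gender proportions and trend
#'
#' Tabulates, per first-publication year, the share of new authors with an
#' assigned gender who are women, and fits [gender_trend()] to the series.
#'
#' @param ledger An [impact_ledger()].
#' @param identities The identity tibble from [author_identities()].
#' @param parity_window Trailing OLS window (default 30 years).
#'
#' @return A `gender_trend` object (or `NULL` with a warning if fewer than
#'   5 usable years).
#' @export
new_author_trend <- function(ledger, identities, parity_window = 30L) {
  first_years <- as_tibble(ledger) %>%
    group_by(.data$canonical_key) %>%
    summarise(year = min(.data$year), .groups = "drop") %>%
    left_join(identities[, c("canonical_key", "gender")],
              by = "canonical_key") %>%
    filter(.data$gender %in% c("woman", "man"))
  series <- first_years %>%
    group_by(.data$year) %>%
    summarise(n_women = sum(.data$gender == "woman"),
              n_total = dplyr::n(), .groups = "drop")
  if (nrow(series) < 5) {
    warn("fewer than 5 usable years; no gender trend fitted")
    return(NULL)
  }
  gender_trend(series, parity_window = parity_window)
}

#' Run the coefficient sensitivity analysis and write its tables
#'
#' @param corpus A [trial_corpus()] (or a corpus file path).
#' @param out_dir Output directory.
#' @param config Baseline [impact_config()].
#' @param dialect Dialect used when `corpus` is a path.
#' @inheritParams sensitivity_analysis
#'
#' @return Invisibly, the [sensitivity_analysis()] result.
#' @export
run_sensitivity <- function(corpus, out_dir, config = impact_config(),
                            role_delta = 0.67, trial_delta = 0.5,
                            dialect = "jsonl", mapping = NULL) {
  if (is.character(corpus)) {
    corpus <- read_corpus(corpus, dialect = dialect)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- sensitivity_analysis(corpus, mapping = mapping, config = config,
                              role_delta = role_delta,
                              trial_delta = trial_delta)
  cor_path <- file.path(out_dir, "sensitivity_correlations.tsv")
  readr::write_tsv(tidy(res), cor_path, progress = FALSE)
  write_manifest(out_dir, c(correlations = cor_path),
                 config = list(role_delta = role_delta,
                               trial_delta = trial_delta))
  invisible(res)
}
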