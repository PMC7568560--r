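#' Impact-score configuration
#'
#' All coefficients of the multiplicative author impact score, exposed so
#' the sensitivity analysis can rescale them. The score of one author on one
#' manuscript is
#' `role x trial x citation x update`, where the role coefficient rewards
#' first/last (or equal-contribution) authorship, the trial coefficient
#' rewards randomized designs, the citation score is the citation count
#' normalized to the corpus-wide maximum (with a blended tier-median
#' phase-in for recent years still accruing citations), and the update
#' coefficient halves the score per update generation.
#'
#' @param role_first_last Coefficient for first/last/equal-contribution
#'   authors (default 3).
#' @param role_middle Coefficient for middle authors (default 1).
#' @param trial_randomized Coefficient for manuscripts reporting at least
#'   one randomized trial (default 2).
#' @param trial_other Coefficient for non-randomized manuscripts (default 1).
#' @param update_half_life Per-generation decay of updates (default 0.5).
#' @param blend_window Calendar years over which the tier-median blend is
#'   phased in (default `c(2009, 2018)`); publications before the window use
#'   the raw citation count.
#' @param tier_median_table Data frame `tier`, `median_citations` giving the
#'   pre-window median citation count per journal tier; required whenever
#'   any record falls in the blend window.
#'
#' @return A list of class `impact_config`.
#' @export
impact_config <- function(role_first_last = 3, role_middle = 1,
                          trial_randomized = 2, trial_other = 1,
                          update_half_life = 0.5,
                          blend_window = c(2009L, 2018L),
                          tier_median_table = NULL) {
  stopifnot(role_first_last > 0, role_middle > 0, trial_randomized > 0,
            trial_other > 0, update_half_life > 0, update_half_life <= 1)
  structure(
    list(
      role_first_last = role_first_last, role_middle = role_middle,
      trial_randomized = trial_randomized, trial_other = trial_other,
      update_half_life = update_half_life,
      blend_window = as.integer(blend_window),
      tier_median_table = tier_median_table
    ),
    class = "impact_config"
  )
}

#' Author-role coefficient
#'
#' First and last authors score `role_first_last` (default 3), as does any
#' author flagged as an equal contributor; middle authors score
#' `role_middle` (default 1). Vectorized over positions.
#'
#' @param position 1-based author position(s).
#' @param n_authors Number of authors on the manuscript.
#' @param equal_contrib Logical, equal-contribution flag(s).
#' @param config An [impact_config()].
#'
#' @return Numeric coefficient(s).
#' @export
#'
#' @examples
#' role_coefficient(c(1, 5, 10), 10, c(FALSE, FALSE, FALSE))
role_coefficient <- function(position, n_authors, equal_contrib,
                             config = impact_config()) {
  if (any(position < 1 | position > n_authors)) {
    abort("author position out of range", class = "trialnet_impact_error")
  }
  if_else(position == 1 | position == n_authors | equal_contrib,
          config$role_first_last, config$role_middle)
}

#' Trial-design coefficient
#'
#' A manuscript reporting on at least one randomized trial scores
#' `trial_randomized` (default 2); otherwise `trial_other` (default 1).
#' Mixed designs therefore use the randomized coefficient.
#'
#' @param randomized_flags Non-empty logical vector of per-trial
#'   randomization flags for the manuscript.
#' @param config An [impact_config()].
#'
#' @return A single numeric coefficient.
#' @export
trial_coefficient <- function(randomized_flags, config = impact_config()) {
  if (length(randomized_flags) == 0 || any(is.na(randomized_flags))) {
    abort("randomized_flags must be a non-empty logical vector",
          class = "trialnet_impact_error")
  }
  if (any(randomized_flags)) config$trial_randomized else config$trial_other
}

#' Update half-life decay coefficient
#'
#' A primary publication (update index 0) has coefficient 1; each update
#' generation halves it, so the first update scores 50%, the second 25%,
#' and so forth. A pooled update of several trials uses the index that
#' yields the maximum coefficient, i.e. the smallest pooled index.
#'
#' @param update_index Non-negative update generation(s); 0 is the primary
#'   publication.
#' @param pooled_indices Optional list (or single vector) of pooled update
#'   indices; when present for an element, it overrides `update_index`.
#' @param half_life Decay factor per generation (default 0.5).
#'
#' @return Numeric coefficient(s) in (0, 1].
#' @export
#'
#' @examples
#' update_coefficient(0:3)
#' update_coefficient(2, pooled_indices = c(1, 3))
update_coefficient <- function(update_index, pooled_indices = NULL,
                               half_life = 0.5) {
  if (any(update_index < 0)) {
    abort("update index must be non-negative",
          class = "trialnet_impact_error")
  }
  idx <- as.numeric(update_index)
  if (!is.null(pooled_indices)) {
    if (!is.list(pooled_indices)) pooled_indices <- list(pooled_indices)
    stopifnot(length(pooled_indices) == length(idx))
    for (i in seq_along(idx)) {
      p <- pooled_indices[[i]]
      if (!is.null(p) && length(p) > 0) {
        if (any(p < 0)) {
          abort("pooled update indices must be non-negative",
                class = "trialnet_impact_error")
        }
        idx[i] <- min(p)
      }
    }
  }
  half_life^idx
}

#' Normalized (optionally blended) citation score
#'
#' Citation counts are normalized to the manuscript with the corpus-wide
#' maximum number of citations, so the maximum citation score is one.
#' Because recent publications are still accruing citations, years inside
#' the blend window receive a blended score: the journal tier's historical
#' median citation count is phased in linearly, with weight
#' `w(year) = (year - (start - 1)) / (end - start + 1)` rising from
#' `1/width` at the window start to 1 at the window end:
#' `(citations + w * tier_median) / max_citations`. Blended scores may
#' exceed 1.
#'
#' @param citations Citation count(s).
#' @param max_citations Corpus-wide maximum raw citation count (> 0).
#' @param year Publication year(s).
#' @param journal_tier Journal tier(s), matched against the tier table.
#' @param config An [impact_config()]; supplies the blend window and the
#'   tier median table.
#'
#' @return Numeric score(s), 0 or greater.
#' @export
citation_score <- function(citations, max_citations, year, journal_tier,
                           config = impact_config()) {
  if (is.na(max_citations) || max_citations <= 0) {
    abort("max_citations must be positive", class = "trialnet_impact_error")
  }
  bw <- config$blend_window
  w <- (year - (bw[1] - 1)) / (bw[2] - bw[1] + 1)
  w <- pmin(pmax(w, 0), 1)
  in_window <- year >= bw[1] & year <= bw[2]
  med <- rep(0, length(citations))
  if (any(in_window)) {
    tab <- config$tier_median_table
    if (is.null(tab)) {
      abort("tier_median_table required for records in the blend window",
            class = "trialnet_impact_error")
    }
    m <- match(journal_tier[in_window], tab$tier)
    if (any(is.na(m))) {
      abort(sprintf(
        "no tier median for journal tier(s): %s",
        paste(unique(journal_tier[in_window][is.na(m)]), collapse = ", ")),
        class = "trialnet_impact_error")
    }
    med[in_window] <- as.numeric(tab$median_citations)[m]
  }
  (citations + ifelse(in_window, w, 0) * med) / max_citations
}

#' Per-manuscript, per-author impact contributions
#'
#' Computes every author's manuscript-specific impact score
#' (`role x trial x citation x update`) for every record in the corpus and
#' splits it across subspecialties by the record's subspecialty weights.
#' The result is the impact ledger: one row per
#' (record, author, subspecialty) with the contribution, plus the
#' undivided per-record score and a first/last-role flag used by the
#' career-assignment rules.
#'
#' @param corpus A [trial_corpus()].
#' @param mapping Optional tibble `raw_name`, `canonical_key` (from
#'   [canonicalize_authors()] or [author_identities()]); defaults to the
#'   identity mapping.
#' @param config An [impact_config()].
#'
#' @return A tibble of class `impact_ledger` with columns `canonical_key`,
#'   `record_id`, `year`, `subspecialty`, `contribution`, `score`,
#'   `first_last`. Attributes `max_citations` and `config` record the
#'   normalization constant and coefficients used.
#' @export
impact_ledger <- function(corpus, mapping = NULL, config = impact_config()) {
  if (nrow(corpus) == 0) {
    out <- tibble(canonical_key = character(), record_id = character(),
                  year = integer(), subspecialty = character(),
                  contribution = numeric(), score = numeric(),
                  first_last = logical())
    return(structure(out, max_citations = NA_real_, config = config,
                     class = c("impact_ledger", class(out))))
  }
  max_cit <- max(corpus$citations)
  if (max_cit <= 0) {
    abort("corpus has no cited manuscript; normalization undefined",
          class = "trialnet_impact_error")
  }
  key_of <- NULL
  if (!is.null(mapping)) {
    key_of <- setNames(mapping$canonical_key, mapping$raw_name)
  }
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    r <- corpus[i, ]
    a <- r$authors[[1]]
    n <- nrow(a)
    keys <- if (is.null(key_of)) a$raw_name else unname(key_of[a$raw_name])
    if (anyNA(keys)) {
      abort(sprintf("record %s has author name(s) missing from the mapping",
                    r$record_id), class = "trialnet_impact_error")
    }
    role <- role_coefficient(a$position, n, a$equal_contrib, config)
    fl <- a$position == 1 | a$position == n | a$equal_contrib
    trial <- trial_coefficient(r$randomized, config)
    cs <- citation_score(r$citations, max_cit, r$year, r$journal_tier, config)
    upd <- update_coefficient(r$update_index,
                              pooled_indices = r$pooled_update_indices,
                              half_life = config$update_half_life)
    score <- role * trial * cs * upd
    w <- r$subspecialty_weights[[1]]
    tibble(
      canonical_key = rep(keys, each = length(w)),
      record_id = r$record_id,
      year = r$year,
      subspecialty = rep(names(w), times = n),
      contribution = rep(score, each = length(w)) * rep(unname(w), times = n),
      score = rep(score, each = length(w)),
      first_last = rep(fl, each = length(w))
    )
  })
  out <- bind_rows(rows)
  structure(out, max_citations = max_cit, config = config,
            class = c("impact_ledger", class(tibble())))
}

#' Cumulative per-author impact
#'
#' Sums ledger contributions over all records published up to and including
#' `up_to_year`.
#'
#' @param ledger An [impact_ledger()].
#' @param up_to_year Inclusive year cutoff (default: all years).
#' @param by_subspecialty If `TRUE`, return one row per
#'   (author, subspecialty); otherwise per-author totals.
#'
#' @return A tibble `canonical_key` (, `subspecialty`), `impact`, sorted by
#'   key.
#' @export
cumulative_impact <- function(ledger, up_to_year = Inf,
                              by_subspecialty = FALSE) {
  led <- ledger[ledger$year <= up_to_year, , drop = FALSE]
  led <- as_tibble(led)
  if (by_subspecialty) {
    led %>%
      group_by(.data$canonical_key, .data$subspecialty) %>%
      summarise(impact = sum(.data$contribution), .groups = "drop") %>%
      arrange(.data$canonical_key, .data$subspecialty)
  } else {
    led %>%
      group_by(.data$canonical_key) %>%
      summarise(impact = sum(.data$contribution), .groups = "drop") %>%
      arrange(.data$canonical_key)
  }
}
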