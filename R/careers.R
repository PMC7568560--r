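#' Per-year primary-subspecialty assignment history
#'
#' Recomputes each author's primary subspecialty in every year in which
#' they publish. An author is eligible for a subspecialty if they were
#' ever a first/last (or equal-contribution) author there, or if their
#' cumulative impact there is positive and at least `mean - 1 SD` of the
#' cumulative impact of all authors with positive impact in that
#' subspecialty that year (population SD; the floor makes the criterion an
#' inclusion threshold). Among eligible subspecialties the primary is the
#' one holding the maximum of the author's impact; exact ties are assigned
#' equally to the tied set; an author eligible nowhere is `"None"`.
#' Once assigned, the primary only changes when another eligible
#' subspecialty's impact strictly exceeds the incumbent's (ties involving
#' the incumbent expand to the tied set).
#'
#' @param ledger An [impact_ledger()].
#'
#' @return A tibble `canonical_key`, `year`, `primary` (labels joined with
#'   `"|"` for equal splits, or `"None"`), `primary_set` (list-column of
#'   label vectors), one row per author per publishing year.
#' @export
career_history <- function(ledger) {
  led <- as_tibble(ledger)
  if (nrow(led) == 0) {
    return(tibble(canonical_key = character(), year = integer(),
                  primary = character(), primary_set = list()))
  }
  authors <- sort(unique(led$canonical_key))
  subs <- sort(unique(led$subspecialty))
  M <- matrix(0, length(authors), length(subs),
              dimnames = list(authors, subs))
  FL <- matrix(FALSE, length(authors), length(subs),
               dimnames = list(authors, subs))
  current <- setNames(vector("list", length(authors)), authors)
  years <- sort(unique(led$year))
  eps <- 1e-12
  out <- list()

  for (y in years) {
    yr <- led[led$year == y, , drop = FALSE]
    add <- aggregate(contribution ~ canonical_key + subspecialty, data = yr,
                     FUN = sum)
    M[cbind(add$canonical_key, add$subspecialty)] <-
      M[cbind(add$canonical_key, add$subspecialty)] + add$contribution
    fl <- yr[yr$first_last, c("canonical_key", "subspecialty")]
    if (nrow(fl) > 0) {
      FL[cbind(fl$canonical_key, fl$subspecialty)] <- TRUE
    }
    thr <- vapply(subs, function(s) {
      x <- M[, s]
      x <- x[x > 0]
      if (length(x) == 0) return(Inf)
      mean(x) - pop_sd(x)
    }, numeric(1))

    pub_authors <- sort(unique(yr$canonical_key))
    for (a in pub_authors) {
      imp <- M[a, ]
      elig <- FL[a, ] | (imp > 0 & imp >= thr - eps)
      cur <- current[[a]]
      if (!any(elig)) {
        if (is.null(cur)) current[[a]] <- "None"
      } else {
        m <- max(imp[elig])
        cand <- sort(subs[elig & imp >= m - eps * max(m, 1)])
        if (is.null(cur) || identical(cur, "None")) {
          current[[a]] <- cand
        } else {
          m_cur <- max(imp[cur])
          if (m > m_cur + eps * max(m, 1)) {
            current[[a]] <- cand
          } else if (any(cur %in% cand) &&
                     abs(m - m_cur) <= eps * max(m, 1)) {
            current[[a]] <- cand
          }
        }
      }
      out[[length(out) + 1]] <- tibble(
        canonical_key = a, year = as.integer(y),
        primary = paste(current[[a]], collapse = "|"),
        primary_set = list(current[[a]])
      )
    }
  }
  bind_rows(out) %>% arrange(.data$canonical_key, .data$year)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-year node attributes from a career history
#'
#' Converts a [career_history()] into the `(canonical_key, year,
#' subspecialty)` shape expected by [yearly_metrics()]: single-label
#' assignments carry their label, equal splits and `"None"` carry `NA`
#' (excluded from subspecialty partitions and homophily).
#'
#' @param history A [career_history()] tibble.
#' @return A tibble `canonical_key`, `year`, `subspecialty`.
#' @export
history_node_attrs <- function(history) {
  history %>%
    mutate(subspecialty = ifelse(
      lengths(.data$primary_set) == 1 & .data$primary != "None",
      .data$primary, NA_character_)) %>%
    select("canonical_key", "year", "subspecialty")
}

#' Primary-subspecialty assignment at a given year
#'
#' Runs the per-year assignment rules of [career_history()] and returns
#' each author's state as of `year`.
#'
#' @param ledger An [impact_ledger()].
#' @param year Assignment year.
#'
#' @return A tibble `canonical_key`, `primary`, `primary_set`.
#' @export
assign_primary_subspecialty <- function(ledger, year) {
  hist <- career_history(ledger[ledger$year <= year, , drop = FALSE])
  hist %>%
    group_by(.data$canonical_key) %>%
    slice(which.max(.data$year)) %>%
    ungroup() %>%
    select("canonical_key", "primary", "primary_set")
}

#' Author longevity
#'
#' The interval in years between an author's first and final publication.
#' Because publishing trial results takes substantial time, an author whose
#' first publication predates `adjust_from` and whose final publication
#' falls in `[adjust_from, horizon)` has the final year adjusted to
#' `horizon`.
#'
#' @param years Vector of an author's publication years (>= 1 value).
#' @param horizon Final database year (default 2018).
#' @param adjust_from First year of the truncation-adjustment window
#'   (default 2016).
#'
#' @return Longevity in whole years.
#' @export
#'
#' @examples
#' longevity(c(1950, 1970))  # 20
#' longevity(c(2010, 2016))  # 8: endpoint adjusted to 2018
#' longevity(2005)           # 0
longevity <- function(years, horizon = 2018L, adjust_from = 2016L) {
  if (length(years) == 0) {
    abort("at least one publication year required",
          class = "trialnet_career_error")
  }
  first <- min(years)
  last <- max(years)
  if (first < adjust_from && last >= adjust_from && last < horizon) {
    last <- horizon
  }
  as.integer(last - first)
}

#' Whether a career changed primary subspecialty
#'
#' `TRUE` if the per-year primary label, restricted to single-label years
#' and excluding `"None"`, takes at least two distinct values. Transitions
#' into or out of equal-split states do not count unless the dominant
#' single label changes.
#'
#' @param history The rows of [career_history()] for one author.
#'
#' @return Logical flag.
#' @export
subspecialty_change_flag <- function(history) {
  single <- purrr::map_lgl(history$primary_set, ~ length(.x) == 1)
  labels <- history$primary[single]
  labels <- labels[labels != "None"]
  length(unique(labels)) >= 2
}

#' Career summary table
#'
#' One row per author: first and (adjusted) last publication years,
#' longevity, final primary subspecialty, and the subspecialty-change flag.
#'
#' @param ledger An [impact_ledger()].
#' @param identities Optional identity tibble (from [author_identities()])
#'   used to attach gender.
#' @param horizon,adjust_from See [longevity()].
#'
#' @return A tibble `canonical_key`, `first_year`, `last_year_raw`,
#'   `last_year_adjusted`, `longevity`, `primary_subspecialty`,
#'   `changed_subspecialty`, `impact`, `gender`.
#' @export
careers <- function(ledger, identities = NULL, horizon = 2018L,
                    adjust_from = 2016L) {
  hist <- career_history(ledger)
  totals <- cumulative_impact(ledger)
  out <- hist %>%
    group_by(.data$canonical_key) %>%
    summarise(
      first_year = min(.data$year),
      last_year_raw = max(.data$year),
      primary_subspecialty = .data$primary[which.max(.data$year)],
      changed_subspecialty = {
        single_labels <- .data$primary[lengths(.data$primary_set) == 1]
        length(unique(single_labels[single_labels != "None"])) >= 2
      },
      .groups = "drop"
    )
  out$last_year_adjusted <- ifelse(
    out$first_year < adjust_from &
      out$last_year_raw >= adjust_from & out$last_year_raw < horizon,
    horizon, out$last_year_raw)
  out$last_year_adjusted <- as.integer(out$last_year_adjusted)
  out$longevity <- out$last_year_adjusted - out$first_year
  out <- left_join(out, totals, by = "canonical_key")
  if (!is.null(identities)) {
    out <- left_join(out,
                     identities[, c("canonical_key", "gender")],
                     by = "canonical_key")
  } else {
    out$gender <- NA_character_
  }
  out %>%
    select("canonical_key", "first_year", "last_year_raw",
           "last_year_adjusted", "longevity", "primary_subspecialty",
           "changed_subspecialty", "impact", "gender") %>%
    arrange(.data$canonical_key)
}
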