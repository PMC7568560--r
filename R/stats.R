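#' Two-group comparison by Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test with midranks. For groups of at most
#' `exact_max` observations each, the p-value is exact: every assignment of
#' the pooled values to the two groups is enumerated and the p-value is the
#' fraction of assignments whose rank sum is at least as far from its
#' expectation as the observed one (this handles ties exactly). Larger
#' groups use the tie-corrected normal approximation without continuity
#' correction. Medians and quartiles use the linear-interpolation
#' convention (R quantile type 7).
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param labels Group labels, length 2.
#' @param exact_max Largest per-group size for exact enumeration
#'   (default 10).
#'
#' @return An object of class `group_comparison` with a per-group summary
#'   table, the rank-sum statistic of the first group, and the two-sided
#'   p-value. Use [tidy()]/[glance()] to extract tables.
#' @export
#'
#' @examples
#' cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
#' glance(cmp)
compare_groups <- function(values_a, values_b, labels = c("a", "b"),
                           exact_max = 10L) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both groups must be non-empty", class = "trialnet_stats_error")
  }
  n <- length(values_a)
  m <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2

  if (n <= exact_max && m <= exact_max) {
    sets <- combn(n + m, n)
    ws <- colSums(matrix(r[sets], nrow = n))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w_obs - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }

  summary_tbl <- tibble(
    group = labels,
    n = c(n, m),
    median = c(median(values_a), median(values_b)),
    q1 = c(quantile(values_a, 0.25, names = FALSE),
           quantile(values_b, 0.25, names = FALSE)),
    q3 = c(quantile(values_a, 0.75, names = FALSE),
           quantile(values_b, 0.75, names = FALSE))
  )
  structure(
    list(summary = summary_tbl, statistic = w_obs, p_value = min(p, 1),
         method = method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Two-sided Wilcoxon rank-sum test (", x$method, ")\n", sep = "")
  print(x$summary)
  cat(sprintf("rank sum W = %g, p = %s\n", x$statistic,
              format_pvalue(x$p_value)))
  invisible(x)
}

format_pvalue <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("%.4g", p)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method)
}

#' Smoothed gender trend and parity extrapolation
#'
#' Fits a LOESS curve (degree 2, span 0.75 by default) to the yearly
#' proportion of women, and extrapolates the parity year by ordinary least
#' squares on the most recent `parity_window` years of the series: the
#' parity year is the first calendar year, starting from the beginning of
#' the series, at which the fitted straight line reaches 0.5.
#'
#' @param data A data frame with columns `year` and either `proportion` or
#'   the pair `n_women`, `n_total`.
#' @param span,degree LOESS smoothing parameters (defaults 0.75 and 2).
#' @param parity_window Number of trailing years used for the linear
#'   extrapolation (default 30).
#'
#' @return An object of class `gender_trend`: the input series with a
#'   `smoothed` column, the linear fit, and `parity_year` (`NA` with a
#'   warning if the line never reaches 0.5 going forward).
#' @export
gender_trend <- function(data, span = 0.75, degree = 2,
                         parity_window = 30L) {
  data <- as_tibble(data)
  if (!"proportion" %in% names(data)) {
    if (!all(c("n_women", "n_total") %in% names(data))) {
      abort("data needs 'proportion' or 'n_women' + 'n_total' columns",
            class = "trialnet_stats_error")
    }
    if (all(data$n_total == 0)) {
      abort("all yearly denominators are zero",
            class = "trialnet_stats_error")
    }
    data <- data[data$n_total > 0, , drop = FALSE]
    data$proportion <- data$n_women / data$n_total
  }
  data <- data[order(data$year), ]
  if (nrow(data) < 5) {
    abort("at least 5 yearly points required", class = "trialnet_stats_error")
  }
  lo <- loess(proportion ~ year, data = data, span = span, degree = degree)
  data$smoothed <- unname(predict(lo, newdata = data))

  recent <- tail(data, parity_window)
  fit <- lm(proportion ~ year, data = recent)
  a <- coef(fit)[[1]]
  b <- coef(fit)[[2]]
  eps <- 1e-9
  first_year <- min(data$year)
  parity_year <- NA_integer_
  if (a + b * first_year >= 0.5 - eps && b >= 0) {
    parity_year <- as.integer(first_year)
  } else if (abs(b) < eps) {
    if (a >= 0.5 - eps) parity_year <- as.integer(first_year)
  } else {
    cross <- (0.5 - a) / b
    if (b > 0) {
      parity_year <- as.integer(ceiling(cross - eps))
      if (parity_year < first_year) parity_year <- as.integer(first_year)
    }
  }
  if (is.na(parity_year)) {
    warn("trend never reaches parity going forward; parity_year is NA")
  }
  structure(
    list(series = data, loess = lo, linear_fit = fit,
         parity_window = parity_window, parity_year = parity_year),
    class = "gender_trend"
  )
}

#' @export
print.gender_trend <- function(x, ...) {
  cat(sprintf(
    "<gender_trend: %d years, LOESS span %.2f, parity year %s (OLS window %d)>\n",
    nrow(x$series), x$loess$pars$span,
    ifelse(is.na(x$parity_year), "not reached", x$parity_year),
    x$parity_window))
  invisible(x)
}

#' @method tidy gender_trend
#' @export
tidy.gender_trend <- function(x, ...) x$series

#' @method glance gender_trend
#' @export
glance.gender_trend <- function(x, ...) {
  tibble(
    parity_year = x$parity_year,
    slope = coef(x$linear_fit)[[2]],
    intercept = coef(x$linear_fit)[[1]],
    parity_window = x$parity_window,
    span = x$loess$pars$span
  )
}

#' Coefficient sensitivity analysis
#'
#' Rescales the author-role and trial-design coefficients one at a time
#' (role by `1 +/- role_delta`, default +/-67%; trial by
#' `1 +/- trial_delta`, default +/-50%), recomputes the impact ledger, the
#' yearly assortativity and modularity series and the final normalized
#' score distribution under each variant, and correlates each variant's
#' series with the baseline by Pearson's r.
#'
#' @param corpus A [trial_corpus()].
#' @param mapping Optional raw-name-to-key mapping (see [impact_ledger()]).
#' @param config Baseline [impact_config()].
#' @param role_delta,trial_delta Relative perturbations of the first/last
#'   role coefficient and the randomized-trial coefficient.
#' @param years Years for the metric series (default: every publication
#'   year).
#'
#' @return An object of class `sensitivity_result`: a tibble of variants
#'   with their coefficient factors, Pearson correlations
#'   (`r_assortativity`, `r_modularity`), and list-columns holding the
#'   yearly series and the normalized final score distribution. Series of
#'   fewer than 3 usable points yield `NA` correlations with a warning
#'   (degenerate). Use [tidy()] to extract the correlation table.
#' @export
sensitivity_analysis <- function(corpus, mapping = NULL,
                                 config = impact_config(),
                                 role_delta = 0.67, trial_delta = 0.5,
                                 years = NULL) {
  variants <- tibble(
    variant = c("baseline", "role_low", "role_high", "trial_low",
                "trial_high"),
    role_factor = c(1, 1 - role_delta, 1 + role_delta, 1, 1),
    trial_factor = c(1, 1, 1, 1 - trial_delta, 1 + trial_delta)
  )
  run_variant <- function(role_factor, trial_factor) {
    cfg <- config
    cfg$role_first_last <- config$role_first_last * role_factor
    cfg$trial_randomized <- config$trial_randomized * trial_factor
    ledger <- impact_ledger(corpus, mapping = mapping, config = cfg)
    metrics <- yearly_metrics(
      ledger, years = years,
      node_attrs_by_year = history_node_attrs(career_history(ledger)))
    totals <- cumulative_impact(ledger)
    max_imp <- max(totals$impact)
    totals$normalized <- if (max_imp > 0) totals$impact / max_imp else 0
    list(metrics = metrics, scores = totals)
  }
  runs <- purrr::map2(variants$role_factor, variants$trial_factor,
                      run_variant)
  base <- runs[[1]]
  series_cor <- function(x, y) {
    ok <- complete.cases(x, y)
    if (sum(ok) < 3) {
      warn("fewer than 3 usable points; correlation degenerate")
      return(NA_real_)
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  variants$r_assortativity <- purrr::map_dbl(runs, function(r) {
    series_cor(base$metrics$assortativity, r$metrics$assortativity)
  })
  variants$r_modularity <- purrr::map_dbl(runs, function(r) {
    series_cor(base$metrics$modularity, r$metrics$modularity)
  })
  variants$metrics <- purrr::map(runs, "metrics")
  variants$scores <- purrr::map(runs, "scores")
  structure(list(variants = variants, role_delta = role_delta,
                 trial_delta = trial_delta),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_result: role +/-%.0f%%, trial +/-%.0f%%>\n",
    100 * x$role_delta, 100 * x$trial_delta))
  print(tidy(x))
  invisible(x)
}

#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) {
  x$variants %>%
    select("variant", "role_factor", "trial_factor", "r_assortativity",
           "r_modularity")
}

#' @method glance sensitivity_result
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble(
    n_variants = nrow(x$variants),
    min_r_assortativity = min(x$variants$r_assortativity, na.rm = TRUE),
    min_r_modularity = min(x$variants$r_modularity, na.rm = TRUE)
  )
}
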