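#' Simulation configuration
#'
#' Parameters of the synthetic publication-record generator. The defaults
#' emulate, at roughly 1/50 scale, the corpus structure the analysis
#' assumes: log-linear growth in yearly output between 1946 and 2018
#' (about 112 papers in total), team sizes whose median rises from 6 to 20
#' (with an end-of-period IQR near 16--25), 13 disease subspecialties with
#' a within-subspecialty co-author preference of 0.88, repeat-collaboration
#' preferential attachment, a gender entry schedule holding at 15% women
#' before 1980 and rising linearly to 40% by 2018, heavy-tailed lognormal
#' citation counts scaled by journal tier, update chains with half-life
#' lineage, and a randomized-design fraction of 0.78.
#'
#' @param seed Integer RNG seed; a fixed seed yields an identical corpus.
#' @param years Calendar-year range of the simulation.
#' @param target_papers Approximate total number of papers.
#' @param growth_rate Exponential rate of the papers-per-year schedule.
#' @param team_median_start,team_median_end Median authors per paper at the
#'   start and end of the period (log-linear interpolation in between).
#' @param team_sdlog Lognormal sd (log scale) of team sizes; 0.33 puts the
#'   end-of-period IQR near 16--25.
#' @param n_subspecialties Number of disease subspecialties.
#' @param within_pref Probability that a returning co-author is drawn from
#'   the paper's own subspecialty.
#' @param attachment_strength Exponent on accumulated collaboration weight
#'   in the veteran-selection probability (0 = uniform; larger values give
#'   heavier-tailed degree distributions).
#' @param new_author_prob Probability that an author slot is filled by a
#'   new entrant rather than a returning author.
#' @param gender_start,gender_end,gender_rise_start Woman proportion among
#'   new entrants: constant `gender_start` before `gender_rise_start`, then
#'   linear to `gender_end` at the final year.
#' @param firstlast_gender_bias Multiplicative odds factor favouring men
#'   for first/last slots (1 = no bias, so gender affects entry proportion
#'   only and disparity metrics are testable under the null).
#' @param initials_prob Probability an author always appears with initials
#'   only.
#' @param mixed_form_prob Probability an author alternates between full and
#'   initials forms (exercising automatic name merging).
#' @param ambiguous_name_prob Probability a new entrant carries a
#'   gender-ambiguous given name.
#' @param multi_sub_prob Probability a paper is split evenly across two
#'   subspecialties.
#' @param update_prob Probability a paper is an update of an earlier
#'   primary publication.
#' @param pooled_prob Probability an update pools two earlier trials.
#' @param randomized_prob Probability a paper reports a randomized trial.
#' @param tier_probs Journal-tier assignment probabilities (tiers 1..k).
#' @param tier_medians Median citation counts per journal tier, also used
#'   as the analysis-side tier-median table.
#' @param citation_sdlog Lognormal sd of citation counts.
#' @param senior_last_prob Probability the last-author slot goes to the
#'   strongest team member.
#' @param equal_contrib_prob Probability a middle author is flagged as an
#'   equal contributor.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       years = 1946:2018,
                       target_papers = 112L,
                       growth_rate = 0.064,
                       team_median_start = 6,
                       team_median_end = 20,
                       team_sdlog = 0.33,
                       n_subspecialties = 13L,
                       within_pref = 0.88,
                       attachment_strength = 1,
                       new_author_prob = 0.4,
                       gender_start = 0.15,
                       gender_end = 0.40,
                       gender_rise_start = 1980L,
                       firstlast_gender_bias = 1,
                       initials_prob = 0.12,
                       mixed_form_prob = 0.08,
                       ambiguous_name_prob = 0.05,
                       multi_sub_prob = 0.04,
                       update_prob = 0.22,
                       pooled_prob = 0.03,
                       randomized_prob = 0.78,
                       tier_probs = c(0.25, 0.3, 0.25, 0.2),
                       tier_medians = c(300, 120, 50, 20),
                       citation_sdlog = 1.3,
                       senior_last_prob = 0.7,
                       equal_contrib_prob = 0.02) {
  cfg <- as.list(environment())
  probs <- c(within_pref, new_author_prob, gender_start, gender_end,
             initials_prob, mixed_form_prob, ambiguous_name_prob,
             multi_sub_prob, update_prob, pooled_prob, randomized_prob,
             senior_last_prob, equal_contrib_prob)
  stopifnot(all(probs >= 0 & probs <= 1), length(tier_probs) ==
              length(tier_medians), target_papers >= 1)
  structure(cfg, class = "sim_config")
}

gender_schedule <- function(year, config) {
  y0 <- config$gender_rise_start
  y1 <- max(config$years)
  ifelse(year < y0, config$gender_start,
         config$gender_start +
           (config$gender_end - config$gender_start) *
           pmin(1, (year - y0) / (y1 - y0)))
}

synthetic_given_names <- function() {
  list(
    woman = c("Mary", "Susan", "Linda", "Karen", "Patricia", "Barbara",
              "Nancy", "Laura", "Sarah", "Emily", "Rebecca", "Rachel",
              "Catherine", "Margaret", "Teresa", "Monica", "Angela",
              "Helen", "Julia", "Diane", "Louise", "Irene", "Clara",
              "Alice", "Ruth"),
    man = c("James", "John", "Robert", "Michael", "William", "David",
            "Richard", "Thomas", "Charles", "Joseph", "Daniel", "Paul",
            "Mark", "George", "Kenneth", "Steven", "Edward", "Brian",
            "Ronald", "Anthony", "Kevin", "Jason", "Matthew", "Gary",
            "Eric"),
    ambiguous = c("Jordan", "Casey", "Robin", "Alex", "Jamie", "Taylor"),
    dict_woman = c("Aoife", "Sinead", "Marit"),
    dict_man = c("Bjorn", "Tariq", "Wenceslao")
  )
}

#' Synthetic name lookup tables
#'
#' Gender lookup tables matching the generator's given-name vocabulary: a
#' frequency table (gendered names at a 95:5 ratio, ambiguous names at
#' 50:50), a dictionary table covering names absent from the frequency
#' table, and an empty override table.
#'
#' @return A list `freq_table`, `dictionary_table`, `override_table`.
#' @export
synthetic_name_tables <- function() {
  v <- synthetic_given_names()
  freq <- bind_rows(
    tibble(name = v$woman, n_woman = 95, n_man = 5),
    tibble(name = v$man, n_woman = 5, n_man = 95),
    tibble(name = v$ambiguous, n_woman = 50, n_man = 50)
  )
  dict <- bind_rows(
    tibble(name = v$dict_woman, gender = "woman"),
    tibble(name = v$dict_man, gender = "man")
  )
  list(freq_table = freq, dictionary_table = dict,
       override_table = tibble(name = character(), gender = character()))
}

papers_per_year <- function(config) {
  years <- config$years
  w <- exp(config$growth_rate * (years - min(years)))
  n <- round(config$target_papers * w / sum(w))
  if (sum(n) == 0) n[length(n)] <- 1L
  as.integer(n)
}

#' Simulate a synthetic publication corpus
#'
#' Generates a corpus of publication records with the statistical structure
#' described in [sim_config()], together with the latent ground truth
#' needed for recovery tests. Per year, papers draw a subspecialty, a team
#' mixing new entrants (gender by the entry schedule) and returning
#' authors (selected preferentially by accumulated collaboration weight,
#' from the paper's subspecialty with probability `within_pref`), a
#' journal tier, a heavy-tailed citation count (damped in recent years
#' still accruing citations), a randomized-design flag, and possibly an
#' update lineage pointing at an earlier primary record.
#'
#' @param config A [sim_config()].
#'
#' @return A list with `corpus` (a [trial_corpus()]), `ground_truth` (a
#'   list: `authors` tibble with true key, gender, subspecialty and
#'   name-form behaviour; `config`), and `tables` (the
#'   [synthetic_name_tables()]).
#' @export
simulate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vocab <- synthetic_given_names()
  subs <- sprintf("sub%02d", seq_len(config$n_subspecialties))
  n_tiers <- length(config$tier_probs)
  y_end <- max(config$years)
  y_span <- y_end - min(config$years)

  reg <- new.env(parent = emptyenv())
  reg$id <- 0L
  reg$key <- character()
  reg$surname <- character()
  reg$given <- character()
  reg$gender <- character()
  reg$sub <- character()
  reg$strength <- numeric()
  reg$form <- character()   # "full", "initials", "mixed"
  reg$first_year <- integer()

  new_author <- function(year, sub) {
    reg$id <- reg$id + 1L
    i <- reg$id
    gender <- if (runif(1) < gender_schedule(year, config)) "woman" else "man"
    surname <- sprintf("Name%05d", i)
    u <- runif(1)
    given <- if (u < config$ambiguous_name_prob) {
      sample(vocab$ambiguous, 1)
    } else if (u < config$ambiguous_name_prob + 0.03) {
      if (gender == "woman") sample(vocab$dict_woman, 1) else
        sample(vocab$dict_man, 1)
    } else {
      if (gender == "woman") sample(vocab$woman, 1) else
        sample(vocab$man, 1)
    }
    uf <- runif(1)
    form <- if (uf < config$initials_prob) "initials" else
      if (uf < config$initials_prob + config$mixed_form_prob) "mixed" else
        "full"
    reg$key[i] <- paste0(surname, "_", given)
    reg$surname[i] <- surname
    reg$given[i] <- given
    reg$gender[i] <- gender
    reg$sub[i] <- sub
    reg$strength[i] <- 0
    reg$form[i] <- form
    reg$first_year[i] <- year
    i
  }

  raw_form <- function(i) {
    f <- reg$form[i]
    use_initials <- f == "initials" || (f == "mixed" && runif(1) < 0.5)
    if (use_initials) {
      paste0(reg$surname[i], "_", toupper(substr(reg$given[i], 1, 1)))
    } else {
      reg$key[i]
    }
  }

  pick_veterans <- function(n_vet, paper_sub, exclude) {
    chosen <- integer(0)
    for (j in seq_len(n_vet)) {
      avail <- setdiff(seq_len(reg$id), c(exclude, chosen))
      if (length(avail) == 0) break
      same <- avail[reg$sub[avail] == paper_sub]
      pool <- if (length(same) > 0 && runif(1) < config$within_pref) {
        same
      } else {
        avail
      }
      w <- reg$strength[pool]^config$attachment_strength + 1
      chosen <- c(chosen, pool[sample.int(length(pool), 1, prob = w)])
    }
    chosen
  }

  npy <- papers_per_year(config)
  records <- list()
  paper_no <- 0L
  # update bookkeeping: per primary record, how many updates exist so far
  primaries <- character()
  primary_sub <- character()
  update_count <- integer()

  for (yi in seq_along(config$years)) {
    year <- config$years[yi]
    for (p in seq_len(npy[yi])) {
      paper_no <- paper_no + 1L
      rid <- sprintf("P%05d", paper_no)

      if (runif(1) < config$multi_sub_prob &&
          config$n_subspecialties >= 2) {
        two <- sample(subs, 2)
        weights <- setNames(c(0.5, 0.5), two)
      } else {
        weights <- setNames(1, sample(subs, 1))
      }
      paper_sub <- names(weights)[[1]]

      med <- config$team_median_start *
        (config$team_median_end / config$team_median_start)^
        ((year - min(config$years)) / y_span)
      k <- max(2L, as.integer(round(rlnorm(1, log(med), config$team_sdlog))))

      n_new <- rbinom(1, k, config$new_author_prob)
      n_vet <- min(k - n_new, reg$id)
      n_new <- k - n_vet
      vets <- pick_veterans(n_vet, paper_sub, exclude = integer(0))
      n_new <- k - length(vets)
      news <- vapply(seq_len(n_new), function(j) new_author(year, paper_sub),
                     integer(1))
      team <- c(vets, news)
      k <- length(team)

      # order the team; the strongest member tends to take the last slot
      ord <- sample(team)
      if (k >= 2 && runif(1) < config$senior_last_prob) {
        strongest <- team[which.max(reg$strength[team])]
        ord <- c(setdiff(ord, strongest), strongest)
      }
      if (config$firstlast_gender_bias != 1 && k >= 3) {
        # push women out of the first slot with the configured odds factor
        if (reg$gender[ord[1]] == "woman" &&
            runif(1) < 1 - 1 / config$firstlast_gender_bias) {
          men_mid <- ord[-c(1, k)][reg$gender[ord[-c(1, k)]] == "man"]
          if (length(men_mid) > 0) {
            swap_with <- men_mid[[1]]
            i1 <- which(ord == swap_with)
            ord[i1] <- ord[1]
            ord[1] <- swap_with
          }
        }
      }
      equal_contrib <- rep(FALSE, k)
      if (k > 2) {
        mid <- 2:(k - 1)
        equal_contrib[mid] <- runif(length(mid)) < config$equal_contrib_prob
      }
      authors <- tibble(
        raw_name = vapply(ord, raw_form, character(1)),
        position = seq_len(k),
        equal_contrib = equal_contrib
      )

      update_index <- 0L
      pooled <- NULL
      if (length(primaries) > 0 && runif(1) < config$update_prob) {
        cand <- which(primary_sub == paper_sub)
        if (length(cand) == 0) cand <- seq_along(primaries)
        if (runif(1) < config$pooled_prob && length(cand) >= 2) {
          par <- sample(cand, 2)
          update_count[par] <- update_count[par] + 1L
          pooled <- sort(update_count[par])
          update_index <- min(pooled)
        } else {
          par <- if (length(cand) == 1) cand else sample(cand, 1)
          update_count[par] <- update_count[par] + 1L
          update_index <- update_count[par]
        }
      } else {
        primaries <- c(primaries, rid)
        primary_sub <- c(primary_sub, paper_sub)
        update_count <- c(update_count, 0L)
      }

      tier <- sample.int(n_tiers, 1, prob = config$tier_probs)
      cit <- rlnorm(1, log(config$tier_medians[tier]), config$citation_sdlog)
      if (year >= 2009) cit <- cit * (y_end + 1 - year) / 10
      citations <- max(0L, as.integer(round(cit)))

      records[[paper_no]] <- list(
        record_id = rid, year = year, journal_tier = tier,
        randomized = runif(1) < config$randomized_prob,
        update_index = update_index, pooled_update_indices = pooled,
        citations = citations,
        positive_trial = runif(1) < 0.5,
        subspecialty_weights = weights,
        authors = authors
      )
      reg$strength[team] <- reg$strength[team] + (k - 1)
    }
  }

  corpus <- corpus_from_record_list(records,
                                    year_range = range(config$years))
  authors_truth <- tibble(
    canonical_key = reg$key[seq_len(reg$id)],
    surname = reg$surname[seq_len(reg$id)],
    given = reg$given[seq_len(reg$id)],
    gender = reg$gender[seq_len(reg$id)],
    subspecialty = reg$sub[seq_len(reg$id)],
    name_form = reg$form[seq_len(reg$id)],
    first_year = reg$first_year[seq_len(reg$id)]
  )
  list(
    corpus = corpus,
    ground_truth = list(authors = authors_truth, config = config),
    tables = synthetic_name_tables()
  )
}

#' Analysis-side impact configuration matching a simulation
#'
#' @param config A [sim_config()].
#' @return An [impact_config()] whose tier-median table matches the
#'   generator's journal tiers.
#' @export
sim_impact_config <- function(config = sim_config()) {
  impact_config(tier_median_table = tibble(
    tier = seq_along(config$tier_medians),
    median_citations = config$tier_medians
  ))
}

#' Gini coefficient
#'
#' @param x Non-negative numeric vector.
#' @return Gini coefficient in \[0, 1\].
#' @export
gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0 || sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Parameter-recovery report for a synthetic corpus
#'
#' Runs the full pipeline (identity, impact, careers, final network) on a
#' simulated corpus and compares the realized structure to the generator's
#' configured parameters: median within-subspecialty neighbor homophily
#' versus the configured preference, realized gender proportions among new
#' entrants by era versus the entry schedule (with binomial standard
#' errors), median team size in the final five years versus the target,
#' median career longevity, and the Gini coefficient of final degree (a
#' summary of preferential-attachment tail heaviness).
#'
#' @param sim The result of [simulate_corpus()].
#'
#' @return A list: `homophily_median`, `gender_by_era` (tibble `era`, `n`,
#'   `realized`, `expected`, `se`, `z`), `team_median_end`,
#'   `median_longevity`, `degree_gini`.
#' @export
recovery_report <- function(sim) {
  config <- sim$ground_truth$config
  ids <- author_identities(
    sim$corpus,
    freq_table = sim$tables$freq_table,
    dictionary_table = sim$tables$dictionary_table
  )
  icfg <- sim_impact_config(config)
  ledger <- impact_ledger(sim$corpus, mapping = ids$mapping, config = icfg)
  y_end <- max(sim$corpus$year)
  assign <- assign_primary_subspecialty(ledger, y_end)
  node_attrs <- tibble(
    canonical_key = assign$canonical_key,
    subspecialty = ifelse(
      purrr::map_int(assign$primary_set, length) == 1 &
        assign$primary != "None",
      assign$primary, NA_character_),
    gender = ids$identities$gender[
      match(assign$canonical_key, ids$identities$canonical_key)]
  )
  net <- build_network(ledger, up_to_year = y_end, node_attrs = node_attrs)
  hom <- net_homophily(net, "subspecialty", "neighbors")

  truth <- sim$ground_truth$authors
  rise <- config$gender_rise_start
  truth$era <- ifelse(truth$first_year < rise,
                      sprintf("pre-%d", rise), sprintf("%d-on", rise))
  gender_by_era <- truth %>%
    group_by(.data$era) %>%
    summarise(
      n = dplyr::n(),
      realized = mean(.data$gender == "woman"),
      expected = mean(gender_schedule(.data$first_year, config)),
      .groups = "drop"
    ) %>%
    mutate(
      se = sqrt(.data$expected * (1 - .data$expected) / .data$n),
      z = (.data$realized - .data$expected) / .data$se
    )

  recent <- sim$corpus[sim$corpus$year > y_end - 5, ]
  team_sizes <- purrr::map_int(recent$authors, nrow)
  cars <- careers(ledger, horizon = y_end)
  deg <- igraph::degree(net$graph)

  list(
    homophily_median = median(hom$homophily),
    gender_by_era = gender_by_era,
    team_median_end = median(team_sizes),
    median_longevity = median(cars$longevity),
    degree_gini = gini(deg)
  )
}
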