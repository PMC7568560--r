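test_that("role coefficient rewards first, last and equal contributors", {
  expect_equal(role_coefficient(1, 10, FALSE), 3)
  expect_equal(role_coefficient(10, 10, FALSE), 3)
  expect_equal(role_coefficient(5, 10, TRUE), 3)
  expect_equal(role_coefficient(5, 10, FALSE), 1)
  expect_error(role_coefficient(11, 10, FALSE),
               class = "trialnet_impact_error")
})

test_that("trial coefficient uses the randomized value for mixed designs", {
  expect_equal(trial_coefficient(TRUE), 2)
  expect_equal(trial_coefficient(FALSE), 1)
  expect_equal(trial_coefficient(c(FALSE, TRUE)), 2)
  expect_error(trial_coefficient(logical(0)),
               class = "trialnet_impact_error")
})

test_that("update decay halves per generation; pooled updates take the best index", {
  expect_equal(update_coefficient(0), 1.0)
  expect_equal(update_coefficient(1), 0.5)
  expect_equal(update_coefficient(2), 0.25)
  # pooled: the coefficient that yields the maximum score over the indices
  pooled <- c(1L, 3L)
  expect_equal(update_coefficient(0, pooled_indices = pooled),
               max(0.5^pooled))
  expect_equal(update_coefficient(0, pooled_indices = pooled), 0.5)
  expect_error(update_coefficient(-1), class = "trialnet_impact_error")
})

test_that("citation scores normalize to the corpus maximum and blend recent years", {
  cfg <- impact_config(tier_median_table = data.frame(
    tier = 1L, median_citations = 200))
  expect_equal(citation_score(13341, 13341, 2005, 1L, cfg), 1.0)
  expect_equal(citation_score(0, 13341, 1990, 1L, cfg), 0.0)
  # final blend year: full weight on the tier median
  expect_equal(citation_score(100, 1000, 2018, 1L, cfg), 0.3)
  # window start: one tenth of the median phased in
  expect_equal(citation_score(100, 1000, 2009, 1L, cfg),
               (100 + 0.1 * 200) / 1000)
  expect_error(citation_score(10, 1000, 2018, 2L, cfg),
               class = "trialnet_impact_error")
  expect_error(citation_score(10, 1000, 2018, 1L, impact_config()),
               class = "trialnet_impact_error")
})

test_that("manuscript impact is the coefficient product split by subspecialty", {
  corp <- trial_corpus(dplyr::bind_rows(
    # first author, randomized, primary: citation score 100/200 = 0.5
    make_record("a", 2000, c("First_Fay", "Mid_Moe", "Last_Lou"),
                citations = 100L, randomized = TRUE),
    make_record("max", 2001, c("Solo_Sam", "Other_Oz"), citations = 200L,
                randomized = FALSE),
    # middle author, non-randomized, first update, citation score 1:
    # 1 x 1 x 1 x 0.5 split over two subspecialties
    make_record("b", 2002, c("X_Xa", "Mid_Moe", "Y_Yo"), citations = 200L,
                randomized = FALSE, update_index = 1L,
                weights = c(A = 0.5, B = 0.5)),
    make_record("zero", 2003, c("Nil_Ned", "Nil_Nan"), citations = 0L,
                randomized = TRUE)
  ))
  led <- impact_ledger(corp)
  a_first <- led[led$record_id == "a" & led$canonical_key == "First_Fay", ]
  expect_equal(a_first$score, 3 * 2 * 0.5 * 1)
  expect_equal(a_first$contribution, 3.0)

  b_mid <- led[led$record_id == "b" & led$canonical_key == "Mid_Moe", ]
  expect_equal(sort(b_mid$subspecialty), c("A", "B"))
  expect_equal(b_mid$contribution, c(0.25, 0.25))
  expect_equal(sum(b_mid$contribution), unique(b_mid$score))

  zero <- led[led$record_id == "zero", ]
  expect_true(all(zero$contribution == 0))
})

test_that("cumulative impact is monotone in the cutoff year", {
  sim <- simulate_corpus(sim_config(seed = 9))
  led <- impact_ledger(sim$corpus,
                       config = sim_impact_config(sim$ground_truth$config))
  years <- sort(unique(led$year))
  probe <- years[round(seq(1, length(years), length.out = 5))]
  prev <- NULL
  for (y in probe) {
    cum <- cumulative_impact(led, up_to_year = y)
    if (!is.null(prev)) {
      joined <- dplyr::left_join(prev, cum, by = "canonical_key",
                                 suffix = c("_old", "_new"))
      expect_true(all(joined$impact_new >= joined$impact_old - 1e-12))
    }
    prev <- cum
  }
  # a cutoff before the first record yields an empty ledger
  expect_equal(nrow(cumulative_impact(led, up_to_year = min(years) - 1)), 0L)
})

test_that("one-record ledgers equal that record's contributions", {
  corp <- trial_corpus(make_record("only", 2000, c("A_Al", "B_Bo"),
                                   citations = 10L))
  led <- impact_ledger(corp)
  cum <- cumulative_impact(led)
  expect_equal(cum$impact, c(3 * 2 * 1 * 1, 3 * 2 * 1 * 1))
})

test_that("citation scaling cancels out of normalized scores before the blend window", {
  base <- trial_corpus(dplyr::bind_rows(
    make_record("r1", 1990, c("A_Al", "B_Bo"), citations = 40L),
    make_record("r2", 1995, c("B_Bo", "C_Cy", "D_Dee"), citations = 160L)
  ))
  scaled <- base
  scaled$citations <- scaled$citations * 5L
  scaled <- trial_corpus(scaled)
  expect_equal(cumulative_impact(impact_ledger(base)),
               cumulative_impact(impact_ledger(scaled)))
})
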