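# a corpus where 'Mid_Moe' is a middle author on one big paper with tiny
# impact and the subspecialty has several strong authors, so the
# mean - 1 SD floor excludes them
none_corpus <- function() {
  trial_corpus(dplyr::bind_rows(
    make_record("s1", 2000, c("A_Al", "B_Bo"), citations = 1000L),
    make_record("s2", 2000, c("C_Cy", "D_Dee"), citations = 1000L),
    make_record("s3", 2000, c("E_Ed", "F_Flo"), citations = 1000L),
    make_record("m1", 2001, c("G_Gil", "Mid_Moe", "H_Hal"), citations = 1L,
                randomized = FALSE)
  ))
}

test_that("first/last authorship confers a primary subspecialty", {
  corp <- trial_corpus(make_record("r", 2000, c("A_Anna", "B_Bob"),
                                   weights = c(breast = 1)))
  hist <- career_history(impact_ledger(corp))
  expect_equal(hist$primary, c("breast", "breast"))
})

test_that("low-impact middle authors fall below the eligibility floor", {
  led <- impact_ledger(none_corpus())
  hist <- career_history(led)
  moe <- hist[hist$canonical_key == "Mid_Moe", ]
  expect_equal(moe$primary, "None")
  # the flanking first/last authors of the same weak paper are eligible
  gil <- hist[hist$canonical_key == "G_Gil", ]
  expect_equal(gil$primary, "breast")
})

test_that("exact impact ties split the assignment equally", {
  corp <- trial_corpus(make_record(
    "t", 2000, c("A_Anna", "B_Bob"), weights = c(breast = 0.5,
                                                 lymphoma = 0.5)))
  assign <- assign_primary_subspecialty(impact_ledger(corp), 2000)
  expect_equal(assign$primary, rep("breast|lymphoma", 2))
  expect_equal(assign$primary_set[[1]], c("breast", "lymphoma"))
})

test_that("reassignment needs strictly higher impact in the new subspecialty", {
  corp <- trial_corpus(dplyr::bind_rows(
    make_record("b1", 2000, c("A_Anna", "B_Bob"), citations = 100L,
                weights = c(breast = 1)),
    make_record("l1", 2005, c("A_Anna", "C_Cy"), citations = 400L,
                weights = c(lymphoma = 1)),
    make_record("max", 2006, c("X_Xi", "Y_Yo"), citations = 400L)
  ))
  led <- impact_ledger(corp)
  hist <- career_history(led)
  anna <- hist[hist$canonical_key == "A_Anna", ]
  expect_equal(anna$primary[anna$year == 2000], "breast")
  expect_equal(anna$primary[anna$year == 2005], "lymphoma")

  # smaller later paper does not displace the incumbent
  corp2 <- trial_corpus(dplyr::bind_rows(
    make_record("b1", 2000, c("A_Anna", "B_Bob"), citations = 400L,
                weights = c(breast = 1)),
    make_record("l1", 2005, c("A_Anna", "C_Cy"), citations = 100L,
                weights = c(lymphoma = 1))
  ))
  hist2 <- career_history(impact_ledger(corp2))
  anna2 <- hist2[hist2$canonical_key == "A_Anna", ]
  expect_equal(anna2$primary[anna2$year == 2005], "breast")
})

test_that("eligibility is monotone once first/last authorship is earned", {
  sim <- simulate_corpus(sim_config(seed = 21))
  led <- impact_ledger(sim$corpus,
                       config = sim_impact_config(sim$ground_truth$config))
  hist <- career_history(led)
  led_tbl <- tibble::as_tibble(led)
  fl <- led_tbl[led_tbl$first_last, c("canonical_key", "year")]
  first_fl <- stats::aggregate(year ~ canonical_key, data = fl, FUN = min)
  names(first_fl)[2] <- "fl_year"
  joined <- dplyr::inner_join(hist, first_fl, by = "canonical_key")
  after <- joined[joined$year >= joined$fl_year, ]
  expect_true(all(after$primary != "None"))
})

test_that("longevity measures first-to-last interval with endpoint adjustment", {
  expect_equal(longevity(c(1950, 1970)), 20L)
  expect_equal(longevity(c(2010, 2016)), 8L)
  expect_equal(longevity(c(2010, 2017)), 8L)
  expect_equal(longevity(2005), 0L)
  # no adjustment when the career starts inside the window
  expect_equal(longevity(c(2016, 2017)), 1L)
  expect_equal(longevity(c(2010, 2018)), 8L)
  expect_error(longevity(integer(0)), class = "trialnet_career_error")
})

test_that("subspecialty changes are flagged from single-label years only", {
  stay <- tibble::tibble(primary = c("breast", "breast"),
                         primary_set = list("breast", "breast"))
  expect_false(subspecialty_change_flag(stay))
  move <- tibble::tibble(primary = c("breast", "lymphoma"),
                         primary_set = list("breast", "lymphoma"))
  expect_true(subspecialty_change_flag(move))
  none <- tibble::tibble(primary = c("None", "None"),
                         primary_set = list("None", "None"))
  expect_false(subspecialty_change_flag(none))
  # equal-split transitions are ignored unless the single label changes
  split <- tibble::tibble(
    primary = c("breast", "breast|lymphoma", "breast"),
    primary_set = list("breast", c("breast", "lymphoma"), "breast"))
  expect_false(subspecialty_change_flag(split))
})

test_that("career tables summarise the synthetic corpus coherently", {
  sim <- simulate_corpus(sim_config(seed = 23))
  ids <- author_identities(sim$corpus,
                           freq_table = sim$tables$freq_table)
  led <- impact_ledger(sim$corpus, mapping = ids$mapping,
                       config = sim_impact_config(sim$ground_truth$config))
  cars <- careers(led, identities = ids$identities)
  expect_equal(nrow(cars), length(unique(led$canonical_key)))
  expect_true(all(cars$first_year <= cars$last_year_raw))
  expect_true(all(cars$last_year_raw <= cars$last_year_adjusted))
  expect_true(all(cars$longevity ==
                    cars$last_year_adjusted - cars$first_year))
  expect_true(all(cars$impact > 0))
})
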