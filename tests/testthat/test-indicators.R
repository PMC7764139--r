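test_that("polypharmacy counts residents at or above 9 active ingredients", {
  rec <- make_residents(3, n_active_ingredients = c(8L, 9L, 15L))
  ex <- extract_indicator(rec, "polypharmacy")
  expect_true(all(ex$eligible))
  expect_equal(ex$outcome, c(0L, 1L, 1L))
})

test_that("pain predicate follows the frequency/intensity rules", {
  rec <- make_residents(
    6,
    pain_self_freq = c("daily", "daily", "nondaily", "nondaily", "none",
                       "daily"),
    pain_self_intensity = c("mild", "moderate", "very_strong_unbearable",
                            "strong", "none", "very_strong_unbearable"))
  ex <- extract_indicator(rec, "pain_self")
  expect_equal(ex$outcome, c(0L, 1L, 1L, 0L, 0L, 1L))

  # invalid answers are excluded from the denominator
  rec2 <- make_residents(3, pain_self_freq = c("invalid", "daily", "daily"),
                         pain_self_intensity = c("moderate", "invalid",
                                                 "strong"))
  ex2 <- extract_indicator(rec2, "pain_self")
  expect_equal(ex2$eligible, c(FALSE, FALSE, TRUE))
  expect_equal(ex2$exclusion_reason[1:2], rep("invalid_answer", 2))
  # observed pain has no invalid level and no exclusions
  ex3 <- extract_indicator(make_residents(1, pain_obs_freq = "daily",
                                          pain_obs_intensity = "moderate"),
                           "pain_observed")
  expect_true(ex3$eligible)
  expect_equal(ex3$outcome, 1L)
})

test_that("consented restraint use is excluded, unclarified context kept", {
  rec <- make_residents(
    4,
    trunk_restraint_daily = c(TRUE, TRUE, TRUE, FALSE),
    trunk_restraint_context = c("capable_agreed", "incapable",
                                "not_clarified", "none"))
  ex <- extract_indicator(rec, "restraint_trunk")
  expect_equal(ex$eligible, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(ex$exclusion_reason[1], "consented")
  expect_equal(ex$outcome[-1], c(1L, 1L, 0L))

  # optional stricter denominator also drops unclarified contexts
  ex2 <- extract_indicator(rec, "restraint_trunk",
                           exclude_unclarified_context = TRUE)
  expect_equal(ex2$eligible, c(FALSE, TRUE, FALSE, TRUE))
  # relaxing an exclusion can never decrease eligibility
  expect_true(sum(ex$eligible) >= sum(ex2$eligible))
})

test_that("weight loss exclusions: short life expectancy and admission", {
  rec <- make_residents(
    4,
    weight_loss_10pct_180d = c(TRUE, TRUE, TRUE, FALSE),
    life_expectancy_lt6mo = c("no", "yes", "not_collected", "no"),
    is_admission_assessment = c(TRUE, FALSE, FALSE, FALSE))
  ex <- extract_indicator(rec, "weight_loss")
  expect_equal(ex$eligible, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ex$exclusion_reason[1:2],
               c("admission_assessment", "life_expectancy"))
  expect_equal(ex$outcome[3:4], c(1L, 0L))
  # either weight-loss flag triggers the outcome
  ex5 <- extract_indicator(make_residents(1, weight_loss_5pct_30d = TRUE),
                           "weight_loss")
  expect_equal(ex5$outcome, 1L)
})

test_that("missing required items are deleted listwise", {
  rec <- make_residents(3,
                        bedrails_daily_all_sides = c(NA, TRUE, FALSE),
                        bedrail_context = c("none", "incapable", "none"))
  ex <- extract_indicator(rec, "restraint_bedrails")
  expect_equal(ex$eligible, c(FALSE, TRUE, TRUE))
  expect_equal(ex$exclusion_reason[1], "missing_item")
  expect_true(is.na(ex$outcome[1]))
})

test_that("partition and polypharmacy-denominator invariants hold on a bundle", {
  rec <- simulate_items(sim_config(n_facilities = 30,
                                   residents_per_facility = 50, seed = 9))
  for (id in indicator_ids()) {
    ex <- extract_indicator(rec, id)
    expect_equal(sum(ex$eligible) + sum(ex$exclusion_reason != "none"),
                 nrow(rec), label = id)
    expect_identical(is.na(ex$outcome), !ex$eligible, label = id)
  }
  expect_equal(sum(extract_indicator(rec, "polypharmacy")$eligible),
               nrow(rec))
})

test_that("facility rates aggregate eligible residents", {
  rec <- make_residents(4, n_active_ingredients = c(9L, 3L, 2L, 1L))
  fr <- facility_rates(extract_indicator(rec, "polypharmacy"))
  expect_equal(fr$by_facility$rate, 0.25)
  expect_equal(fr$by_facility$n_events, 1L)

  # all facilities zero events -> zero prevalence
  rec0 <- make_residents(6, facility_id = rep(c("A", "B"), each = 3))
  fr0 <- facility_rates(extract_indicator(rec0, "polypharmacy"))
  expect_equal(fr0$prevalence_mean, 0)

  # a facility with no eligible residents is flagged, not silently dropped
  rec2 <- rbind(
    make_residents(2, facility_id = "A", n_active_ingredients = 9L),
    make_residents(2, facility_id = "B",
                   pain_self_freq = "invalid"))
  fr2 <- facility_rates(extract_indicator(rec2, "pain_self"))
  expect_true(fr2$by_facility$undefined[fr2$by_facility$facility_id == "B"])
  expect_true(is.na(fr2$by_facility$rate[2]))
  expect_error(facility_rates(extract_indicator(rec2, "pain_self")[0, ]),
               "empty")
})

test_that("schema violations are reported with row and field", {
  rec <- make_residents(2, cps = c(2L, 9L))
  expect_error(extract_indicator(rec, "polypharmacy"),
               "field 'cps' at row 2")
  expect_error(extract_indicator(make_residents(1), "not_an_indicator"))
  audit <- exclusion_audit(extract_indicator(
    make_residents(2, pain_self_freq = c("invalid", "daily")), "pain_self"))
  expect_equal(audit[[1]]$invalid_answer, 1)
})
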