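test_that("generation is deterministic under a seed, including on disk", {
  a <- generate_cohort(cohort_spec(), seed = 123)
  b <- generate_cohort(cohort_spec(), seed = 123)
  expect_equal(plain(a), plain(b))
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, pa); write_cohort(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  expect_false(identical(plain(a), plain(generate_cohort(cohort_spec(), seed = 124))))
})

test_that("every generated record passes strict validation", {
  for (seed in c(1, 2, 3)) {
    cohort <- generate_cohort(cohort_spec(), seed = seed)
    expect_silent(validate_cohort(cohort, strict = TRUE))
    expect_equal(nrow(cohort), 78)
  }
})

test_that("class split follows the benign fraction, exactly when stratified", {
  strat <- generate_cohort(cohort_spec(stratified = TRUE), seed = 4)
  expect_equal(sum(strat$tumor_class == "benign"), 18)
  counts <- vapply(1:20, function(s) {
    sum(generate_cohort(cohort_spec(), seed = 200 + s)$tumor_class == "benign")
  }, numeric(1))
  expect_gt(mean(counts), 18 - 3 * sd(counts) / sqrt(20))
  expect_lt(mean(counts), 18 + 3 * sd(counts) / sqrt(20))
})

test_that("benign tumors are never painful", {
  for (seed in c(5, 6)) {
    cohort <- generate_cohort(cohort_spec(), seed = seed)
    benign <- cohort$signs[cohort$tumor_class == "benign"]
    expect_false(any(vapply(benign, function(s) "pain" %in% s, logical(1))))
  }
})

test_that("numeric fields hit their calibration targets", {
  # observed intervals: truncated log-normal with mean 9.14 on [1, 85]
  withr::with_seed(30, x <- draw_intervals(5e4))
  expect_lt(abs(mean(x) - 9.14), 3 * sd(x) / sqrt(length(x)))
  expect_true(all(x >= 1 & x <= 85))
  # the gamma alternative is calibrated to the same mean
  withr::with_seed(31, g <- draw_intervals(5e4, list(family = "gamma", mean = 9.14,
                                                     shape = 1.2, bounds = c(1, 85))))
  expect_lt(abs(mean(g) - 9.14), 0.1)

  big <- generate_cohort(cohort_spec(n_total = 4000), seed = 32)
  # age: median 60.5 years within bounds 21-92
  expect_lt(abs(median(big$age_years) - 60.5),
            3 * 1.2533 * sd(big$age_years) / sqrt(4000) + 0.5) # +0.5 for rounding
  expect_true(all(big$age_years >= 21 & big$age_years <= 92))
  # distance: median 69 km
  expect_lt(abs(median(big$distance_km) - 69),
            3 * 1.2533 * sd(big$distance_km) / sqrt(4000))
  # clinical size medians per class (advice-conditioning barely touches them)
  nb <- big[big$tumor_class == "nonbenign", ]
  expect_lt(abs(median(nb$size_clinical_mm, na.rm = TRUE) - 90), 8)
  expect_true(median(nb$size_radiological_mm, na.rm = TRUE) >= 90)
})

test_that("an infeasible spec is refused with a calibration error", {
  bad <- cohort_spec(interval = list(family = "lognormal", mean = 200,
                                     sdlog = 1, bounds = c(1, 85)))
  expect_error(generate_cohort(bad, seed = 1), "infeasible")
  expect_error(cohort_spec(nonbenign = list(advice = c(refer_expert = 1))),
               "sum to 1")
})

test_that("the 60-record fixture matches the published structure", {
  fx <- make_fixture_cohort()
  expect_equal(nrow(fx), 60)
  expect_true(all(fx$tumor_class == "nonbenign"))
  tr <- triage(fx)
  expect_equal(as.vector(table(tr$outcome)[c("refer_expert", "complementary_imaging",
                                             "local_management")]),
               c(46L, 13L, 1L))
  expect_equal(sum(fx$real_management == "surgery_nonexpert"), 13)
  expect_equal(as.vector(table(fx$real_management)[c(
    "followup_no_imaging", "followup_imaging", "biopsy_nonexpert",
    "surgery_nonexpert", "referral_expert")]), c(5L, 6L, 9L, 13L, 27L))
  # the single local case is the superficial sub-centimeter dermatofibrosarcoma
  local <- fx[tr$outcome == "local_management", ]
  expect_equal(local$histology, "dermatofibrosarcoma")
  expect_equal(local$depth, "superficial")
  expect_lt(size_mm(local$size_radiological_mm, local$size_clinical_mm), 10)
  expect_equal(local$observed_interval_months, 12)
})
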