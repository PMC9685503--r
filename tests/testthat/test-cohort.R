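test_that("CSV round-trip is the identity on valid cohorts", {
  for (seed in 1:4) {
    cohort <- random_cohort(20, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(cohort, path)
    back <- read_cohort(path)
    expect_equal(plain(back), plain(cohort))
  }
})

test_that("missing numeric cells survive a round trip as NA, never zero", {
  cohort <- hand_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  raw <- readLines(path)
  expect_false(any(grepl(",0,", raw[4]))) # H3's missing radiological size
  back <- read_cohort(path)
  expect_true(is.na(back$size_radiological_mm[3]))
  expect_true(is.na(back$size_clinical_mm[4]))
})

test_that("validation names the offending row and column", {
  bad <- hand_cohort()
  bad$observed_interval_months[2] <- -2
  expect_error(validate_cohort(bad), "observed_interval_months.*row 2")

  dup <- hand_cohort()
  dup$patient_id[2] <- "H1"
  expect_error(validate_cohort(dup), "duplicate id.*H1")

  tok <- hand_cohort()
  tok$depth[1] <- "sideways"
  expect_error(validate_cohort(tok), "depth.*unknown token")

  inconsistent <- hand_cohort()
  inconsistent$imaging_performed[1] <- FALSE
  expect_error(validate_cohort(inconsistent), "imaging_pattern")

  expect_error(validate_cohort(hand_cohort()[0, ]), "at least one record")
})

test_that("follow-up-without-imaging on an imaged record is warn-level only", {
  soft <- hand_cohort()
  soft$real_management[1] <- "followup_no_imaging"
  expect_warning(out <- validate_cohort(soft, strict = TRUE), "followup_no_imaging")
  expect_equal(nrow(out), 4)
  expect_message(out2 <- validate_cohort(soft, strict = FALSE), "followup_no_imaging")
  expect_equal(nrow(out2), 4)
})

test_that("the narrative two-case fixture loads as described", {
  cohort <- narrative_cohort()
  expect_equal(nrow(cohort), 2)
  expect_equal(cohort$size_radiological_mm, c(9, 120))
  expect_equal(cohort$signs[[1]], character(0))
  expect_setequal(cohort$signs[[2]], c("growth", "pain"))
})

test_that("summaries match hand arithmetic and degenerate SD is zero", {
  s <- summarize_cohort(hand_cohort())
  age <- dplyr::filter(s$numeric, stratum == "overall", field == "age_years")
  expect_equal(age$median, 55)
  expect_equal(age$mean, 55)
  dist_nb <- dplyr::filter(s$numeric, stratum == "nonbenign", field == "distance_km")
  expect_equal(dist_nb$median, 20)
  expect_equal(dist_nb$n, 3)
  size <- dplyr::filter(s$numeric, stratum == "overall", field == "size_clinical_mm")
  expect_equal(size$n_missing, 1)
  expect_equal(size$median, 60)

  same <- hand_cohort()[rep(1, 5), ]
  same$patient_id <- paste0("R", 1:5)
  s2 <- summarize_cohort(same)
  expect_true(all(s2$numeric$sd[s2$numeric$n > 0] == 0))
})

test_that("summary proportions sum to one on non-missing denominators", {
  s <- summarize_cohort(random_cohort(60, seed = 9))
  sums <- s$categorical |>
    dplyr::filter(field != "sign") |>
    dplyr::group_by(stratum, field) |>
    dplyr::summarise(total = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$total - 1) < 1e-12))
})
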