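test_that("paired_t matches the hand formula on a worked example", {
  obs <- c(2, 4, 6, 8, 10)
  est <- c(1, 2, 3, 4, 5) # differences 1..5
  cmp <- paired_t(obs, est)
  # hand oracle: mean 3, se sqrt(2.5/5), CI 3 +/- t_{.975,4} * se
  se <- sqrt(2.5 / 5)
  expect_equal(cmp$mean_difference_months, 3)
  expect_equal(cmp$t_statistic, 3 / se)
  expect_equal(cmp$degrees_freedom, 4)
  expect_equal(cmp$ci_low, 3 - 2.7764451 * se, tolerance = 1e-6)
  expect_equal(cmp$ci_high, 3 + 2.7764451 * se, tolerance = 1e-6)
  expect_equal(cmp$p_value, 2 * pt(-3 / se, 4))
  expect_equal(tidy(cmp)$n, 5)
})

test_that("paired_t equals the one-sample t on differences over random inputs", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      obs <- rlnorm(n, 2, 0.8)
      est <- sample(c(1, 2), n, replace = TRUE)
      cmp <- paired_t(obs, est)
      oracle <- t.test(obs - est)
      expect_equal(cmp$t_statistic, unname(oracle$statistic))
      expect_equal(cmp$p_value, oracle$p.value)
      expect_equal(c(cmp$ci_low, cmp$ci_high), as.numeric(oracle$conf.int))
      expect_true(cmp$ci_low <= cmp$mean_difference_months &&
                    cmp$mean_difference_months <= cmp$ci_high)
    }
  })
})

test_that("degenerate difference vectors are handled both ways", {
  expect_error(paired_t(c(5, 5, 5), c(2, 2, 2)), "degenerate variance.*3")
  cmp <- paired_t(c(4, 7, 9), c(4, 7, 9))
  expect_equal(cmp$mean_difference_months, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(c(cmp$ci_low, cmp$ci_high), c(0, 0))
})

test_that("outlier rules flag the planted values and only those", {
  tk <- exclude_outliers(c(1, 1, 1, 1, 100), rule = "tukey_1_5_iqr")
  expect_equal(tk$excluded_idx, 5)
  expect_equal(tk$kept, rep(1, 4))

  same <- rep(7, 10)
  expect_length(exclude_outliers(same, "sd_2_5")$excluded_idx, 0)
  expect_length(exclude_outliers(same, "tukey_1_5_iqr")$excluded_idx, 0)

  withr::with_seed(10, {
    x <- runif(76, 1, 10)
    x <- c(x, 500, 800) # two planted extremes
    flagged <- exclude_outliers(x, "sd_2_5")
    # brute-force check of the flag condition
    expect_equal(flagged$excluded_idx, which(x > mean(x) + 2.5 * sd(x)))
    expect_equal(sort(flagged$excluded_idx), c(77, 78))
    expect_equal(length(flagged$kept) + length(flagged$excluded_idx), length(x))
    # masking: re-running on the kept values may flag more, never errors
    again <- exclude_outliers(flagged$kept, "sd_2_5")
    expect_true(length(again$excluded_idx) >= 0)
  })

  # symmetric variant also flags the lower tail
  y <- c(rep(10, 40), -500)
  expect_length(exclude_outliers(y, "sd_2_5")$excluded_idx, 0)
  expect_equal(exclude_outliers(y, "sd_2_5", symmetric = TRUE)$excluded_idx, 41)
})

test_that("paired power is exact noncentral-t power", {
  expect_equal(paired_power(30, 0, 5), 0.05)
  # cross-check against the standard implementation
  for (n in c(20, 60)) {
    for (delta in c(2, 8)) {
      expect_equal(
        paired_power(n, delta, 14.81),
        power.t.test(n = n, delta = delta, sd = 14.81, type = "paired",
                     strict = TRUE)$power,
        tolerance = 1e-9
      )
    }
  }
  # Monte-Carlo oracle at the design point used for the sample-size claim
  sd_bd <- sd_from_ci(4.3677, 11.046, 78)
  expect_equal(sd_bd, 14.81, tolerance = 1e-3)
  p_analytic <- paired_power(60, 8, sd_bd)
  withr::with_seed(99, {
    reps <- 1e5
    x <- matrix(rnorm(60 * reps, mean = 8, sd = sd_bd), nrow = 60)
    m <- colMeans(x)
    s2 <- (colSums(x^2) - 60 * m^2) / 59
    tstat <- m / sqrt(s2 / 60)
    p_mc <- mean(abs(tstat) > qt(0.975, 59))
  })
  mc_se <- sqrt(p_mc * (1 - p_mc) / reps)
  expect_lt(abs(p_analytic - p_mc), 3 * mc_se)
})

test_that("determinant screen recovers hand correlations and flags degeneracy", {
  cohort <- random_cohort(5, seed = 21)
  cohort$distance_km <- c(1, 2, 3, 4, 5)
  response <- c(2, 1, 4, 3, 5)
  out <- determinant_screen(cohort, response = response, covariates = "distance_km")
  expect_equal(out$pearson_r, 0.8) # hand: sum of products 8 / sqrt(10*10)
  expect_equal(out$n_used, 5)

  self <- determinant_screen(cohort, response = cohort$distance_km,
                             covariates = "distance_km")
  expect_equal(self$pearson_r, 1)

  cohort$age_years <- rep(50, 5)
  flagged <- determinant_screen(cohort, response = response, covariates = "age_years")
  expect_true(is.na(flagged$pearson_r))
  expect_match(flagged$note, "zero variance")
})

test_that("determinant screen uses pairwise-complete cases and binary coding", {
  cohort <- random_cohort(60, seed = 13)
  out <- determinant_screen(cohort)
  expect_setequal(out$covariate, c("distance_km", "age_years", "n_signs",
                                   "size_mm", "depth_deep", "imaging_performed"))
  n_depth_known <- sum(cohort$depth != "unknown")
  expect_equal(out$n_used[out$covariate == "depth_deep"], n_depth_known)
  expect_true(all(abs(out$pearson_r[!is.na(out$pearson_r)]) <= 1))
})

test_that("the Pearson screen rejects at the nominal rate under independence", {
  withr::with_seed(31, {
    reps <- 300
    hits <- matrix(NA, reps, 2, dimnames = list(NULL, c("distance_km", "age_years")))
    for (i in seq_len(reps)) {
      cohort <- generate_cohort(cohort_spec(n_total = 40), seed = 40000 + i)
      out <- determinant_screen(cohort, covariates = c("distance_km", "age_years"))
      hits[i, ] <- out$p_value < 0.05
    }
  })
  for (cv in colnames(hits)) {
    rate <- mean(hits[, cv])
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 1e-9)
  }
})
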