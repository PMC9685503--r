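# Paired inference, outlier rules, power, and the determinant screen.

#' Paired t comparison of observed vs estimated intervals
#'
#' Classical paired Student t test: a one-sample t on the per-patient
#' differences `observed - estimated`, with a two-sided p value and the
#' `(1 - alpha)` confidence interval `mean(d) +/- t * sd(d)/sqrt(n)`.
#'
#' When every difference equals the same nonzero constant the test is
#' degenerate and an error reports the constant; when every difference is
#' exactly zero the comparison is returned with t = 0, p = 1 and a zero
#' confidence interval (the two series are identical).
#'
#' @param observed,estimated Numeric vectors of equal length (months).
#' @param alpha Two-sided significance level (default 0.05).
#' @param excluded_ids Optional identifiers of pairs removed beforehand by
#'   an outlier rule, carried along for audit.
#' @return An object of class `paired_comparison` with fields `n`,
#'   `mean_difference_months`, `ci_low`, `ci_high`, `t_statistic`,
#'   `degrees_freedom`, `p_value`, `alpha`, `excluded_ids`.
#' @export
paired_t <- function(observed, estimated, alpha = 0.05, excluded_ids = character()) {
  stopifnot(is.numeric(observed), is.numeric(estimated), alpha > 0, alpha < 1)
  if (length(observed) != length(estimated)) {
    abort("observed and estimated must have equal length")
  }
  if (length(observed) < 2) abort("need at least 2 pairs")
  if (anyNA(observed) || anyNA(estimated)) abort("missing values in the paired series")
  d <- observed - estimated
  n <- length(d)
  if (sd(d) == 0) {
    if (d[1] != 0) {
      abort(sprintf(
        "degenerate variance: every difference equals %g months; the paired t statistic is undefined",
        d[1]
      ))
    }
    return(new_paired_comparison(n, 0, 0, 0, 0, n - 1, 1, alpha, excluded_ids))
  }
  tt <- t.test(d, conf.level = 1 - alpha)
  new_paired_comparison(
    n, mean(d), tt$conf.int[1], tt$conf.int[2],
    unname(tt$statistic), n - 1, tt$p.value, alpha, excluded_ids
  )
}

new_paired_comparison <- function(n, mean_diff, ci_low, ci_high, t_stat, df, p, alpha, excluded_ids) {
  structure(
    list(
      n = n, mean_difference_months = mean_diff,
      ci_low = ci_low, ci_high = ci_high,
      t_statistic = t_stat, degrees_freedom = df, p_value = p,
      alpha = alpha, excluded_ids = excluded_ids
    ),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired comparison (n = %d%s)\n  mean difference %.4f months, %d%% CI [%.4f, %.4f]\n  t = %.3f on %d df, p = %.4g\n",
    x$n,
    if (length(x$excluded_ids)) paste0(", ", length(x$excluded_ids), " excluded") else "",
    x$mean_difference_months, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
    x$t_statistic, x$degrees_freedom, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    mean_difference_months = x$mean_difference_months,
    ci_low = x$ci_low, ci_high = x$ci_high,
    t_statistic = x$t_statistic,
    degrees_freedom = x$degrees_freedom,
    p_value = x$p_value,
    n_excluded = length(x$excluded_ids)
  )
}

#' @export
glance.paired_comparison <- function(x, ...) tidy(x)

#' Flag extreme interval values
#'
#' Two rules used in the evaluation: `sd_2_5` flags values greater than
#' `mean + 2.5 * SD` (upper tail only — delays are strictly positive and
#' right-skewed, and only implausibly long times are suspect); set
#' `symmetric = TRUE` for the two-sided reading. `tukey_1_5_iqr` flags
#' values outside the Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with
#' quartiles by linear interpolation between order statistics
#' (`quantile(type = 7)`). When the spread is zero nothing is flagged under
#' the SD rule, and identical vectors are never flagged under either rule.
#' Re-running the SD rule on the kept values can flag further points
#' (masking); idempotence is not guaranteed.
#'
#' @param values Numeric vector, length at least 3.
#' @param rule `"sd_2_5"` or `"tukey_1_5_iqr"`.
#' @param symmetric For `sd_2_5`, also flag values below `mean - 2.5 * SD`.
#' @return A list with `kept` (the retained values), `excluded_idx`
#'   (positions flagged in the input), and `rule`.
#' @export
exclude_outliers <- function(values, rule = c("sd_2_5", "tukey_1_5_iqr"),
                             symmetric = FALSE) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(values))
  if (length(values) < 3) abort("need at least 3 values")
  if (anyNA(values)) abort("missing values not allowed")
  if (rule == "sd_2_5") {
    s <- sd(values)
    m <- mean(values)
    flagged <- if (s == 0) rep(FALSE, length(values)) else {
      if (symmetric) values > m + 2.5 * s | values < m - 2.5 * s else values > m + 2.5 * s
    }
  } else {
    q <- quantile(values, c(.25, .75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flagged <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  }
  idx <- which(flagged)
  list(kept = values[!flagged], excluded_idx = idx, rule = rule)
}

#' Power of the paired t test
#'
#' Exact power of the two-sided one-sample t test on paired differences,
#' from the noncentral t distribution: with `ncp = delta / (sd / sqrt(n))`
#' and critical value `t* = qt(1 - alpha/2, n - 1)`, power is
#' `P(T > t*) + P(T < -t*)` for `T ~ t(n - 1, ncp)`.
#'
#' @param n_pairs Number of pairs (>= 2).
#' @param delta True mean difference (months).
#' @param sd Standard deviation of the differences (months, > 0).
#' @param alpha Two-sided level.
#' @return Power in `[0, 1]`; equals `alpha` when `delta = 0`.
#' @export
paired_power <- function(n_pairs, delta, sd, alpha = 0.05) {
  stopifnot(n_pairs >= 2, sd > 0, alpha > 0, alpha < 1)
  df <- n_pairs - 1
  ncp <- delta / (sd / sqrt(n_pairs))
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Back-derive the difference SD from a reported confidence interval
#'
#' Given a two-sided `conf` confidence interval for a paired mean
#' difference at sample size `n`, recovers the standard deviation of the
#' differences: `SD = half_width / t_{1-(1-conf)/2, n-1} * sqrt(n)`. Used
#' when a study reports the CI but not the SD behind its power
#' calculation; the result is labelled back-derived.
#'
#' @param ci_low,ci_high Reported interval bounds.
#' @param n Number of pairs the interval was computed on.
#' @param conf Confidence level of the reported interval.
#' @return The implied SD of the paired differences.
#' @export
sd_from_ci <- function(ci_low, ci_high, n, conf = 0.95) {
  stopifnot(ci_high > ci_low, n >= 2)
  half <- (ci_high - ci_low) / 2
  half / qt(1 - (1 - conf) / 2, n - 1) * sqrt(n)
}

#' Pearson screen of putative interval determinants
#'
#' Correlates a response (by default the observed referral interval) with
#' the six putative determinants: distance to the nearest expert center,
#' age, number of clinical signs, tumor size (radiological precedence),
#' depth (deep coded 1, superficial 0, unknown missing) and prior imaging
#' (coded 0/1, giving the point-biserial correlation as a Pearson r). Each
#' test uses pairwise-complete cases and reports the n actually used. A
#' zero-variance covariate yields an undefined r with an explanatory note,
#' never a silent drop. No multiplicity correction is applied by default;
#' `adjust = "holm"` is available.
#'
#' @param cohort A valid cohort tibble.
#' @param response Numeric response vector aligned with `cohort` rows.
#' @param covariates Subset of the six determinant names.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble with `covariate`, `pearson_r`, `p_value`, `n_used`,
#'   `note`.
#' @export
determinant_screen <- function(cohort,
                               response = cohort$observed_interval_months,
                               covariates = c("distance_km", "age_years", "n_signs",
                                              "size_mm", "depth_deep", "imaging_performed"),
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  cohort <- validate_cohort(cohort, strict = FALSE)
  stopifnot(length(response) == nrow(cohort))
  pool <- tibble::tibble(
    distance_km = cohort$distance_km,
    age_years = cohort$age_years,
    n_signs = as.numeric(n_signs(cohort$signs)),
    size_mm = size_mm(cohort$size_radiological_mm, cohort$size_clinical_mm),
    depth_deep = dplyr::case_when(
      cohort$depth == "deep_or_mixed" ~ 1,
      cohort$depth == "superficial" ~ 0,
      TRUE ~ NA_real_
    ),
    imaging_performed = as.numeric(cohort$imaging_performed)
  )
  unknown <- setdiff(covariates, names(pool))
  if (length(unknown) > 0) {
    abort(paste0("unknown determinant(s): ", paste(unknown, collapse = ", ")))
  }
  out <- purrr::map_dfr(covariates, function(cv) {
    x <- pool[[cv]]
    ok <- !is.na(x) & !is.na(response)
    n_used <- sum(ok)
    if (n_used < 3) {
      return(tibble::tibble(covariate = cv, pearson_r = NA_real_, p_value = NA_real_,
                            n_used = n_used, note = "fewer than 3 complete pairs"))
    }
    if (var(x[ok]) == 0 || var(response[ok]) == 0) {
      return(tibble::tibble(covariate = cv, pearson_r = NA_real_, p_value = NA_real_,
                            n_used = n_used, note = "zero variance"))
    }
    ct <- cor.test(x[ok], response[ok], method = "pearson")
    tibble::tibble(covariate = cv, pearson_r = unname(ct$estimate),
                   p_value = ct$p.value, n_used = n_used, note = NA_character_)
  })
  if (adjust == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}
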