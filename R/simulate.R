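# Simulation harnesses: type-I-error calibration of the paired comparison
# and replicate-level recovery of the pipeline's mean difference.

#' Empirical type-I error of the paired comparison
#'
#' Generates `n_rep` null cohorts of `n_pairs` paired interval values —
#' observed and estimated series drawn independently from the generator's
#' observed-interval distribution, so their true means are equal — runs the
#' paired t test on each at level `alpha`, and returns the fraction
#' rejected. Under the null this should equal `alpha` up to Monte-Carlo
#' error.
#'
#' @param n_rep Number of simulated cohorts.
#' @param n_pairs Pairs per cohort.
#' @param alpha Two-sided level.
#' @param interval Interval model (see [draw_intervals()]).
#' @param seed Integer seed.
#' @return A list with `rejection_rate`, `n_rep`, `n_pairs`, `alpha`, and
#'   the Monte-Carlo standard error `mc_se` of the rate.
#' @export
null_rejection_rate <- function(n_rep = 10000, n_pairs = 78, alpha = 0.05,
                                interval = cohort_spec()$interval, seed = 1) {
  stopifnot(n_rep >= 1, n_pairs >= 2)
  withr::with_seed(seed, {
    observed <- matrix(draw_intervals(n_rep * n_pairs, interval), nrow = n_pairs)
    estimated <- matrix(draw_intervals(n_rep * n_pairs, interval), nrow = n_pairs)
    reject <- vapply(seq_len(n_rep), function(j) {
      paired_t(observed[, j], estimated[, j], alpha = alpha)$p_value < alpha
    }, logical(1))
  })
  rate <- mean(reject)
  list(
    rejection_rate = rate, n_rep = n_rep, n_pairs = n_pairs, alpha = alpha,
    mc_se = sqrt(alpha * (1 - alpha) / n_rep)
  )
}

#' Replicate the pipeline over many synthetic cohorts
#'
#' Generates `n_rep` cohorts (seeds `seed + 1 .. seed + n_rep`), runs the
#' full triage + counterfactual + paired-test pipeline on each, and
#' collects the per-cohort mean difference between observed and estimated
#' intervals. Used to check that the pipeline recovers the mean benefit
#' implied by the generator's calibration.
#'
#' @param n_rep Number of replicate cohorts.
#' @param spec A [cohort_spec()].
#' @param rs A `triage_ruleset`.
#' @param scn A [scenario()].
#' @param alpha Level for the per-cohort paired test.
#' @param seed Integer base seed.
#' @return A tibble with one row per replicate: `replicate`, `seed`, `n`,
#'   `mean_difference_months`, `p_value`.
#' @export
replicate_mean_difference <- function(n_rep = 200, spec = cohort_spec(),
                                      rs = default_ruleset(),
                                      scn = scenario_base(),
                                      alpha = 0.05, seed = 0) {
  purrr::map_dfr(seq_len(n_rep), function(i) {
    cohort <- generate_cohort(spec, seed = seed + i)
    cf <- run_counterfactual(cohort, rs, scn)
    cmp <- paired_t(cf$observed_interval_months, cf$estimated_interval_months,
                    alpha = alpha)
    tibble::tibble(
      replicate = i, seed = seed + i, n = cmp$n,
      mean_difference_months = cmp$mean_difference_months,
      p_value = cmp$p_value
    )
  })
}
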