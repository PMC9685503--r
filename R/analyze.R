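# End-to-end analysis: triage -> counterfactual (base + sensitivity) ->
# paired comparison (with outlier-rule variants) -> determinant screen ->
# optional Bayesian regression, plus JSON results and a human report.

#' Run the full evaluation pipeline on a cohort
#'
#' Applies the triage ruleset, assigns counterfactual intervals under each
#' scenario, compares observed vs estimated intervals with the paired t
#' test — once on all pairs and once per outlier-exclusion rule (pairs
#' whose *observed* interval is flagged are dropped) — tabulates the
#' advice/management deltas for nonbenign records, screens the six putative
#' interval determinants, and optionally fits the Bayesian regression.
#'
#' @param cohort A valid cohort tibble.
#' @param rs A `triage_ruleset`.
#' @param scenarios Named list of [scenario()] objects.
#' @param outlier_rules Character subset of
#'   `c("none", "sd_2_5", "tukey_1_5_iqr")`.
#' @param alpha Two-sided level for the paired tests.
#' @param imaging_counts_as_adequate Passed to [management_delta()].
#' @param bayes Fit the Bayesian regression of the observed interval on the
#'   six determinants (complete cases, intercept added)?
#' @param draws,burn_in,chains,seed Bayesian sampler settings (see
#'   [bayesian_regression()]).
#' @return An object of class `triage_analysis`: a list of tibbles
#'   (`outcomes`, `intervals`, `comparisons`, `management`, `determinants`,
#'   `posterior`) plus `n` and `config`. Every number in the rendered
#'   report also appears, unrounded, in this object / its JSON form.
#' @export
analyze_cohort <- function(cohort, rs = default_ruleset(),
                           scenarios = list(base = scenario_base(),
                                            sensitivity = scenario_sensitivity()),
                           outlier_rules = c("none", "sd_2_5", "tukey_1_5_iqr"),
                           alpha = 0.05, imaging_counts_as_adequate = TRUE,
                           bayes = FALSE, draws = 5000, burn_in = 1000,
                           chains = 4, seed = 1) {
  cohort <- validate_cohort(cohort, strict = FALSE)
  stopifnot(length(scenarios) >= 1)
  outlier_rules <- match.arg(outlier_rules, several.ok = TRUE)

  cfs <- purrr::map(scenarios, ~ run_counterfactual(cohort, rs, .x))

  outcomes <- purrr::imap_dfr(cfs, function(cf, scen) {
    cf |>
      dplyr::count(.data$tumor_class, .data$outcome, name = "n") |>
      dplyr::mutate(scenario = scen, .before = 1)
  }) |>
    dplyr::filter(.data$scenario == names(scenarios)[1]) |>
    dplyr::select(-"scenario")

  intervals <- purrr::imap_dfr(cfs, function(cf, scen) {
    strata <- list(overall = cf)
    for (cl in unique(cf$tumor_class)) strata[[cl]] <- cf[cf$tumor_class == cl, ]
    purrr::imap_dfr(strata, function(dat, stratum) {
      tibble::tibble(
        scenario = scen, stratum = stratum, n = nrow(dat),
        mean_observed = mean(dat$observed_interval_months),
        mean_estimated = mean(dat$estimated_interval_months),
        mean_difference = mean(dat$difference_months)
      )
    })
  })

  comparisons <- purrr::imap_dfr(cfs, function(cf, scen) {
    purrr::map_dfr(outlier_rules, function(rule) {
      if (rule == "none") {
        cmp <- paired_t(cf$observed_interval_months, cf$estimated_interval_months,
                        alpha = alpha)
      } else {
        ex <- exclude_outliers(cf$observed_interval_months, rule = rule)
        keep <- setdiff(seq_len(nrow(cf)), ex$excluded_idx)
        cmp <- paired_t(cf$observed_interval_months[keep],
                        cf$estimated_interval_months[keep], alpha = alpha,
                        excluded_ids = cf$patient_id[ex$excluded_idx])
      }
      dplyr::mutate(tidy(cmp), scenario = scen, outlier_rule = rule, .before = 1)
    })
  })

  nb <- cfs[[1]] |> dplyr::filter(.data$tumor_class == "nonbenign")
  management <- if (nrow(nb) > 0) {
    nb |>
      management_delta(imaging_counts_as_adequate = imaging_counts_as_adequate) |>
      dplyr::count(.data$changed, .data$direction, name = "n")
  } else {
    tibble::tibble(changed = logical(), direction = character(), n = integer())
  }

  determinants <- dplyr::bind_rows(
    dplyr::mutate(determinant_screen(cohort), stratum = "overall", .before = 1),
    if (sum(cohort$tumor_class == "nonbenign") >= 3) {
      nb_cohort <- cohort[cohort$tumor_class == "nonbenign", ]
      dplyr::mutate(determinant_screen(nb_cohort), stratum = "nonbenign", .before = 1)
    }
  )

  posterior <- NULL
  if (bayes) {
    pool <- tibble::tibble(
      intercept = 1,
      distance_km = cohort$distance_km,
      age_years = cohort$age_years,
      n_signs = as.numeric(n_signs(cohort$signs)),
      size_mm = size_mm(cohort$size_radiological_mm, cohort$size_clinical_mm),
      depth_deep = dplyr::case_when(cohort$depth == "deep_or_mixed" ~ 1,
                                    cohort$depth == "superficial" ~ 0,
                                    TRUE ~ NA_real_),
      imaging_performed = as.numeric(cohort$imaging_performed)
    )
    complete <- stats::complete.cases(pool)
    fit <- bayesian_regression(
      cohort$observed_interval_months[complete], as.matrix(pool[complete, ]),
      draws = draws, burn_in = burn_in, chains = chains, seed = seed
    )
    posterior <- dplyr::mutate(tidy(fit), n_used = sum(complete), .before = 1)
  }

  structure(
    list(
      n = nrow(cohort),
      outcomes = outcomes,
      intervals = intervals,
      comparisons = comparisons,
      management = management,
      determinants = determinants,
      posterior = posterior,
      config = list(
        ruleset = rs$name,
        scenarios = purrr::map(scenarios, unclass),
        outlier_rules = outlier_rules,
        alpha = alpha,
        imaging_counts_as_adequate = imaging_counts_as_adequate,
        seed = seed
      )
    ),
    class = "triage_analysis"
  )
}

#' @export
print.triage_analysis <- function(x, ...) {
  cat(sprintf("Triage evaluation of %d patients (ruleset `%s`)\n", x$n, x$config$ruleset))
  cat("\nTriage outcomes:\n"); print(x$outcomes)
  cat("\nInterval comparisons:\n")
  print(dplyr::select(x$comparisons, "scenario", "outlier_rule", "n",
                      "mean_difference_months", "ci_low", "ci_high", "p_value"))
  invisible(x)
}

#' Write full-precision analysis results as JSON
#'
#' @param analysis A `triage_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "triage_analysis"))
  jsonlite::write_json(unclass(analysis), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Render a human-readable report
#'
#' A pure function of the analysis object (hence of its JSON form): every
#' printed number exists unrounded in the JSON. Means are rounded to one or
#' two decimals and interval bounds to four, mirroring the usual reporting
#' style.
#'
#' @param analysis A `triage_analysis`.
#' @return Character vector of report lines.
#' @export
render_report <- function(analysis) {
  stopifnot(inherits(analysis, "triage_analysis"))
  lines <- c(
    sprintf("Triage evaluation report (n = %d, ruleset `%s`, alpha = %g)",
            analysis$n, analysis$config$ruleset, analysis$config$alpha),
    "",
    "Triage outcome counts:"
  )
  for (i in seq_len(nrow(analysis$outcomes))) {
    r <- analysis$outcomes[i, ]
    lines <- c(lines, sprintf("  %-10s %-22s %3d", r$tumor_class, r$outcome, r$n))
  }
  lines <- c(lines, "", "Mean intervals (months):")
  for (i in seq_len(nrow(analysis$intervals))) {
    r <- analysis$intervals[i, ]
    lines <- c(lines, sprintf(
      "  %-12s %-10s n=%-3d observed %.2f  estimated %.2f  difference %.2f",
      r$scenario, r$stratum, r$n, r$mean_observed, r$mean_estimated, r$mean_difference
    ))
  }
  lines <- c(lines, "", "Paired comparisons (observed - estimated):")
  for (i in seq_len(nrow(analysis$comparisons))) {
    r <- analysis$comparisons[i, ]
    lines <- c(lines, sprintf(
      "  %-12s %-14s n=%-3d mean %.4f  CI [%.4f, %.4f]  p=%.4g%s",
      r$scenario, r$outlier_rule, r$n, r$mean_difference_months,
      r$ci_low, r$ci_high, r$p_value,
      if (r$n_excluded > 0) sprintf("  (%d excluded)", r$n_excluded) else ""
    ))
  }
  if (nrow(analysis$management) > 0) {
    lines <- c(lines, "", "Management change (nonbenign, advice vs real life):")
    for (i in seq_len(nrow(analysis$management))) {
      r <- analysis$management[i, ]
      lines <- c(lines, sprintf("  changed=%-5s %-13s %3d", r$changed, r$direction, r$n))
    }
  }
  lines <- c(lines, "", "Determinant screen (Pearson r against the observed interval):")
  for (i in seq_len(nrow(analysis$determinants))) {
    r <- analysis$determinants[i, ]
    lines <- c(lines, sprintf(
      "  %-10s %-18s r=%s  p=%s  n=%d%s",
      r$stratum, r$covariate,
      ifelse(is.na(r$pearson_r), "NA", sprintf("%+.3f", r$pearson_r)),
      ifelse(is.na(r$p_value), "NA", sprintf("%.3f", r$p_value)),
      r$n_used,
      ifelse(is.na(r$note), "", paste0("  [", r$note, "]"))
    ))
  }
  if (!is.null(analysis$posterior)) {
    lines <- c(lines, "", "Bayesian regression (posterior median, 95% CrI):")
    for (i in seq_len(nrow(analysis$posterior))) {
      r <- analysis$posterior[i, ]
      lines <- c(lines, sprintf(
        "  %-18s %+.4f  [%+.4f, %+.4f]%s",
        r$term, r$median, r$cri_low, r$cri_high,
        ifelse(r$significant, "  *", "")
      ))
    }
  }
  lines
}
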