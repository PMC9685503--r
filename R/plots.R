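# ggplot2 graphics for the result objects.

#' @export
autoplot.paired_comparison <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = "paired comparison",
                                    y = .data$mean_difference_months)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Mean difference (months)",
                  title = sprintf("Observed - estimated interval (n = %d)", object$n)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.triage_analysis <- function(object, ...) {
  dat <- object$comparisons
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$outlier_rule,
                                    y = .data$mean_difference_months,
                                    colour = .data$scenario)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4), size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2,
                           position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Outlier rule", y = "Mean difference (months)",
                  colour = "Scenario",
                  title = "Potential referral-interval reduction") +
    ggplot2::theme_minimal()
}

#' Observed vs estimated interval shift plot
#'
#' One segment per patient from the observed to the estimated interval,
#' coloured by triage outcome — a visual of how much referral time the
#' advice would have bought per patient.
#'
#' @param cf A counterfactual result tibble from [run_counterfactual()].
#' @return A ggplot object.
#' @export
plot_interval_shift <- function(cf) {
  stopifnot(all(c("observed_interval_months", "estimated_interval_months",
                  "outcome") %in% names(cf)))
  dat <- dplyr::arrange(cf, .data$observed_interval_months)
  dat$rank <- seq_len(nrow(dat))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$rank,
                                       y = .data$observed_interval_months,
                                       xend = .data$rank,
                                       yend = .data$estimated_interval_months,
                                       colour = .data$outcome),
                          alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(x = .data$rank,
                                     y = .data$observed_interval_months), size = 0.8) +
    ggplot2::labs(x = "Patient (ranked by observed interval)",
                  y = "Interval to expert center (months)",
                  colour = "Triage advice") +
    ggplot2::theme_minimal()
}
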