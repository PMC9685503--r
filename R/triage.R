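# Management-optimality classification and real-life vs advice deltas.

#' Classify real-life management as optimal or nonoptimal
#'
#' For a nonbenign soft tissue tumor, expert-center referral is the optimal
#' first management; anything else (nonexpert biopsy or surgery, watchful
#' waiting with or without imaging) is nonoptimal. Optimality is defined
#' only for nonbenign tumors, so any benign record raises an error — callers
#' must filter first.
#'
#' @param real_management Character vector of management categories.
#' @param tumor_class Character vector (recycled) of tumor classes.
#' @return Character vector `"optimal"`/`"nonoptimal"`.
#' @export
classify_optimality <- function(real_management, tumor_class) {
  check_enum(real_management, management_levels, "real_management")
  check_enum(tumor_class, tumor_classes, "tumor_class")
  n <- max(length(real_management), length(tumor_class))
  real_management <- rep_len(real_management, n)
  tumor_class <- rep_len(tumor_class, n)
  if (any(tumor_class == "benign")) {
    abort("optimality is defined only for nonbenign tumors; filter benign records first")
  }
  ifelse(real_management == "referral_expert", "optimal", "nonoptimal")
}

#' Compare real-life management with the triage advice
#'
#' Labels each nonbenign record with whether the triage advice would have
#' changed the adequacy of management, and in which direction. The advice is
#' considered adequate when it is expert referral or — by default — a
#' complementary-imaging request (imaging is a step on the referral
#' pathway); real-life management is adequate when [classify_optimality()]
#' calls it optimal.
#'
#' @param data A data frame with columns `real_management`, `outcome` and
#'   `tumor_class` (e.g. the output of [triage()]); all records must be
#'   nonbenign.
#' @param imaging_counts_as_adequate Logical switch: treat the
#'   complementary-imaging advice as adequate (default `TRUE`).
#' @return The input tibble with logical `changed` and
#'   `direction` (`to_adequate` / `to_inadequate` / `none`) columns added.
#' @export
management_delta <- function(data, imaging_counts_as_adequate = TRUE) {
  stopifnot(is.data.frame(data))
  needed <- c("real_management", "outcome", "tumor_class")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("management_delta needs columns: ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  adequate_outcomes <- if (imaging_counts_as_adequate) {
    c("refer_expert", "complementary_imaging")
  } else {
    "refer_expert"
  }
  real_adequate <- classify_optimality(data$real_management, data$tumor_class) == "optimal"
  app_adequate <- data$outcome %in% adequate_outcomes
  data$changed <- app_adequate != real_adequate
  data$direction <- dplyr::case_when(
    app_adequate & !real_adequate ~ "to_adequate",
    !app_adequate & real_adequate ~ "to_inadequate",
    TRUE ~ "none"
  )
  data
}
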