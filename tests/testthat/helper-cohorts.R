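# In-code fixtures shared across test files.

# A small fully-specified cohort with hand-computable summaries.
hand_cohort <- function() {
  tibble::tibble(
    patient_id = c("H1", "H2", "H3", "H4"),
    tumor_class = c("nonbenign", "nonbenign", "benign", "nonbenign"),
    age_years = c(40, 50, 60, 70),
    sex = c("female", "male", "female", "male"),
    distance_km = c(10, 20, 30, 100),
    size_clinical_mm = c(60, 90, 30, NA),
    size_radiological_mm = c(70, 100, NA, 120),
    depth = c("deep_or_mixed", "deep_or_mixed", "superficial", "unknown"),
    signs = list(c("growth", "pain"), "growth", character(0), "pain"),
    imaging_performed = c(TRUE, TRUE, FALSE, TRUE),
    imaging_pattern = c("heterogeneous_suspicious", "homogeneous_other",
                        "none", "heterogeneous_suspicious"),
    real_management = c("referral_expert", "surgery_nonexpert",
                        "followup_no_imaging", "biopsy_nonexpert"),
    observed_interval_months = c(3, 12, 6, 24),
    histology = c("liposarcoma", "leiomyosarcoma", "lipoma", "myxofibrosarcoma")
  )
}

# The two cases described in the study narrative: a superficial sub-cm
# dermatofibrosarcoma and a deep 120 mm suspicious mass.
narrative_cohort <- function() {
  read_cohort(system.file("extdata/example_cohort.csv", package = "sarctriage"))
}

# Random valid cohort for round-trip property tests.
random_cohort <- function(n, seed) {
  generate_cohort(cohort_spec(n_total = n), seed = seed)
}

# comparable data frame: drop the provenance audit attribute
plain <- function(cohort) {
  attr(cohort, "provenance") <- NULL
  as.data.frame(cohort)
}

outcome_rank <- function(outcome) {
  match(outcome, c("local_management", "complementary_imaging", "refer_expert"))
}
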