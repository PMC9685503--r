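# Patient-level cohort schema, validation and CSV persistence.
#
# A cohort is an ordinary tibble with one row per soft-tissue-mass case and
# a fixed set of columns; `signs` is a list-column of character vectors so a
# record can carry any subset of the four clinical signs.

#' Enumerated levels used by the cohort schema
#'
#' Constants naming the legal tokens for each categorical cohort field.
#' Enums are serialized to CSV as these lowercase tokens.
#'
#' @name cohort-levels
#' @keywords internal
NULL

tumor_classes <- c("benign", "nonbenign")
sex_levels <- c("female", "male")
depth_levels <- c("superficial", "deep_or_mixed", "unknown")
sign_levels <- c("growth", "pain", "hardness", "shrinkage")
pattern_levels <- c(
  "lipomatous_homogeneous", "homogeneous_other",
  "heterogeneous_suspicious", "none"
)
management_levels <- c(
  "followup_no_imaging", "followup_imaging", "biopsy_nonexpert",
  "surgery_nonexpert", "referral_expert"
)
# triage outcomes ordered by escalation: local < imaging < referral
outcome_levels <- c("local_management", "complementary_imaging", "refer_expert")

cohort_columns <- c(
  "patient_id", "tumor_class", "age_years", "sex", "distance_km",
  "size_clinical_mm", "size_radiological_mm", "depth", "signs",
  "imaging_performed", "imaging_pattern", "real_management",
  "observed_interval_months", "histology"
)

#' Number of clinical signs per record
#'
#' Counts the distinct signs (growth, pain, hardness, shrinkage) carried by
#' each record; this is the "number of clinical signs" determinant.
#'
#' @param signs A list-column of character vectors (as in a cohort tibble).
#' @return Integer vector of counts in 0..4.
#' @export
n_signs <- function(signs) {
  vapply(signs, function(s) length(unique(s[!is.na(s) & nzchar(s)])), integer(1))
}

#' Tumor size with radiological precedence
#'
#' The triage rules and the size determinant use the radiological size when
#' available and fall back to the clinical size otherwise, because the
#' decision algorithm is grounded in first imaging results.
#'
#' @param size_radiological_mm,size_clinical_mm Numeric vectors (mm).
#' @return Numeric vector of sizes in mm (NA when both are missing).
#' @export
size_mm <- function(size_radiological_mm, size_clinical_mm) {
  dplyr::coalesce(size_radiological_mm, size_clinical_mm)
}

parse_signs <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    sort(unique(strsplit(cell, "|", fixed = TRUE)[[1]]))
  })
}

format_signs <- function(signs) {
  vapply(signs, function(s) paste(sort(unique(s)), collapse = "|"), character(1))
}

check_enum <- function(x, levels, column, allow_na = FALSE) {
  bad <- which(!(x %in% levels) & !(allow_na & is.na(x)))
  if (length(bad) > 0) {
    abort(sprintf(
      "column `%s`: unknown token %s at row %s (allowed: %s)",
      column, paste(sQuote(unique(x[bad])), collapse = ", "),
      paste(bad, collapse = ", "), paste(levels, collapse = ", ")
    ))
  }
}

#' Validate a cohort table
#'
#' Checks the cohort schema and its invariants: unique non-missing patient
#' ids, legal enum tokens, positive sizes, nonnegative observed intervals,
#' and the consistency rule that `imaging_performed` is `FALSE` exactly when
#' `imaging_pattern` is `"none"`. Violations raise an error naming the row
#' and column. One check is warn-level only: a `followup_no_imaging`
#' management on a record with prior imaging is reported (the management
#' category describes decisions after discovery, so it can legitimately
#' coexist with imaging) — as a warning when `strict = TRUE`, as a message
#' otherwise; offending rows are always kept.
#'
#' @param cohort A data frame with the cohort columns; `signs` may be either
#'   a list-column or a `|`-separated character column.
#' @param strict Logical; escalate warn-level findings to warnings.
#' @return The validated cohort as a tibble (invisibly usable in pipes).
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) abort("cohort must contain at least one record")
  if (!is.list(cohort$signs)) cohort$signs <- parse_signs(cohort$signs)
  # canonical sign order so serialization round-trips are the identity
  cohort$signs <- lapply(cohort$signs, function(s) sort(unique(as.character(s))))

  if (anyNA(cohort$patient_id) || any(!nzchar(cohort$patient_id))) {
    abort(sprintf(
      "column `patient_id`: missing id at row %s",
      paste(which(is.na(cohort$patient_id) | !nzchar(cohort$patient_id)), collapse = ", ")
    ))
  }
  dup <- duplicated(cohort$patient_id)
  if (any(dup)) {
    abort(sprintf(
      "column `patient_id`: duplicate id %s at row %s",
      paste(sQuote(unique(cohort$patient_id[dup])), collapse = ", "),
      paste(which(dup), collapse = ", ")
    ))
  }

  check_enum(cohort$tumor_class, tumor_classes, "tumor_class")
  check_enum(cohort$sex, sex_levels, "sex")
  check_enum(cohort$depth, depth_levels, "depth")
  check_enum(cohort$imaging_pattern, pattern_levels, "imaging_pattern")
  check_enum(cohort$real_management, management_levels, "real_management")
  bad_signs <- which(vapply(cohort$signs, function(s) any(!(s %in% sign_levels)), logical(1)))
  if (length(bad_signs) > 0) {
    abort(sprintf("column `signs`: unknown token at row %s", paste(bad_signs, collapse = ", ")))
  }

  check_numeric <- function(x, column, lower, strict_lower, allow_na) {
    na_bad <- if (allow_na) rep(FALSE, length(x)) else is.na(x)
    oob <- !is.na(x) & (if (strict_lower) x <= lower else x < lower)
    bad <- which(na_bad | oob)
    if (length(bad) > 0) {
      abort(sprintf(
        "column `%s`: value out of range (or missing where required) at row %s",
        column, paste(bad, collapse = ", ")
      ))
    }
  }
  check_numeric(cohort$age_years, "age_years", 0, TRUE, allow_na = FALSE)
  check_numeric(cohort$distance_km, "distance_km", 0, FALSE, allow_na = FALSE)
  check_numeric(cohort$size_clinical_mm, "size_clinical_mm", 0, TRUE, allow_na = TRUE)
  check_numeric(cohort$size_radiological_mm, "size_radiological_mm", 0, TRUE, allow_na = TRUE)
  check_numeric(cohort$observed_interval_months, "observed_interval_months", 0, FALSE, allow_na = FALSE)

  if (!is.logical(cohort$imaging_performed) || anyNA(cohort$imaging_performed)) {
    abort("column `imaging_performed`: must be TRUE/FALSE with no missing values")
  }
  inconsistent <- which(cohort$imaging_performed == (cohort$imaging_pattern == "none"))
  if (length(inconsistent) > 0) {
    abort(sprintf(
      "column `imaging_pattern`: inconsistent with `imaging_performed` at row %s (pattern is 'none' iff no imaging was performed)",
      paste(inconsistent, collapse = ", ")
    ))
  }

  soft <- which(cohort$real_management == "followup_no_imaging" & cohort$imaging_performed)
  if (length(soft) > 0) {
    msg <- sprintf(
      "row %s: real_management 'followup_no_imaging' on a record with prior imaging (kept)",
      paste(soft, collapse = ", ")
    )
    if (strict) warn(msg) else message(msg)
  }
  cohort
}

#' Read a cohort from CSV
#'
#' Reads a UTF-8 comma-separated cohort table (header = the documented field
#' names, enums as lowercase tokens, `signs` as `|`-separated tokens, missing
#' values as empty cells) and validates it. Missing numeric cells become
#' `NA`, never zero.
#'
#' @param path Path to the CSV file.
#' @param strict Passed to [validate_cohort()].
#' @return A validated cohort tibble; its `provenance` attribute records the
#'   source path.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      tumor_class = readr::col_character(),
      age_years = readr::col_double(),
      sex = readr::col_character(),
      distance_km = readr::col_double(),
      size_clinical_mm = readr::col_double(),
      size_radiological_mm = readr::col_double(),
      depth = readr::col_character(),
      signs = readr::col_character(),
      imaging_performed = readr::col_logical(),
      imaging_pattern = readr::col_character(),
      real_management = readr::col_character(),
      observed_interval_months = readr::col_double(),
      histology = readr::col_character()
    ),
    na = "", progress = FALSE, show_col_types = FALSE
  )
  cohort <- validate_cohort(raw, strict = strict)
  attr(cohort, "provenance") <- path
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field for field. Missing cells are written empty, never as 0.
#'
#' @param cohort A valid cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort, strict = FALSE)
  out <- cohort
  out$signs <- format_signs(out$signs)
  readr::write_csv(out[cohort_columns], path, na = "")
  invisible(path)
}

#' Descriptive summary of a cohort
#'
#' Counts and proportions for every categorical field (plus the prevalence
#' of each clinical sign) and mean/SD/median/quartiles/range for every
#' numeric field, overall and stratified by tumor class. Proportions are
#' computed on non-missing denominators and the denominator is reported.
#'
#' @param cohort A valid cohort tibble.
#' @return An object of class `cohort_summary`: a list with tibbles
#'   `categorical` and `numeric`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort, strict = FALSE)
  strata <- list(overall = cohort)
  for (cl in intersect(tumor_classes, unique(cohort$tumor_class))) {
    strata[[cl]] <- dplyr::filter(cohort, .data$tumor_class == cl)
  }

  cat_fields <- c("tumor_class", "sex", "depth", "imaging_performed",
                  "imaging_pattern", "real_management")
  categorical <- purrr::imap_dfr(strata, function(dat, stratum) {
    per_field <- purrr::map_dfr(cat_fields, function(field) {
      x <- as.character(dat[[field]])
      keep <- !is.na(x)
      tab <- table(x[keep])
      tibble::tibble(
        stratum = stratum, field = field, level = names(tab),
        n = as.integer(tab), denominator = sum(keep),
        proportion = as.integer(tab) / sum(keep)
      )
    })
    sign_rows <- purrr::map_dfr(sign_levels, function(sg) {
      present <- vapply(dat$signs, function(s) sg %in% s, logical(1))
      tibble::tibble(
        stratum = stratum, field = "sign", level = sg,
        n = sum(present), denominator = nrow(dat),
        proportion = mean(present)
      )
    })
    dplyr::bind_rows(per_field, sign_rows)
  })

  num_fields <- c("age_years", "distance_km", "size_clinical_mm",
                  "size_radiological_mm", "observed_interval_months")
  numeric <- purrr::imap_dfr(strata, function(dat, stratum) {
    purrr::map_dfr(num_fields, function(field) {
      x <- dat[[field]]
      ok <- x[!is.na(x)]
      q <- if (length(ok) > 0) quantile(ok, c(.25, .5, .75), type = 7) else rep(NA_real_, 3)
      tibble::tibble(
        stratum = stratum, field = field,
        n = length(ok), n_missing = sum(is.na(x)),
        mean = if (length(ok)) mean(ok) else NA_real_,
        sd = if (length(ok) > 1) sd(ok) else if (length(ok) == 1) 0 else NA_real_,
        median = q[[2]], q1 = q[[1]], q3 = q[[3]],
        min = if (length(ok)) min(ok) else NA_real_,
        max = if (length(ok)) max(ok) else NA_real_
      )
    })
  })

  structure(list(categorical = categorical, numeric = numeric),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n-- categorical --\n")
  print(x$categorical, n = 20)
  cat("-- numeric --\n")
  print(x$numeric, n = 20)
  invisible(x)
}
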