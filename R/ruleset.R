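# Declarative first-match triage rulesets.
#
# A ruleset is an ordered list of rules; each rule is a conjunction of
# conditions over the triage-relevant fields (size with radiological
# precedence, depth, imaging pattern, whether imaging was performed, and the
# clinical signs) plus the advised outcome. Evaluation is first-match-wins
# and total: a default outcome catches anything no rule matches.

rule_fields <- c("size", "depth", "imaging_pattern", "imaging_performed", "signs")
rule_ops <- c("eq", "ge", "lt", "in", "any_sign", "no_signs")

#' Build a triage rule condition
#'
#' @param field One of `size`, `depth`, `imaging_pattern`,
#'   `imaging_performed`, `signs`. `size` resolves with radiological
#'   precedence via [size_mm()].
#' @param op One of `eq`, `ge`, `lt`, `in`, `any_sign`, `no_signs`. A
#'   condition on a missing field value evaluates to `FALSE`.
#' @param value Comparison value (ignored for `no_signs`).
#' @return A condition list usable inside [rule()].
#' @export
condition <- function(field, op, value = NULL) {
  if (!field %in% rule_fields) abort(paste0("unknown rule field: ", field))
  if (!op %in% rule_ops) abort(paste0("unknown rule op: ", op))
  list(field = field, op = op, value = value)
}

#' Build a triage rule
#'
#' @param id Unique rule identifier (recorded as `fired_rule` for audit).
#' @param advise The outcome advised when all conditions hold: one of
#'   `refer_expert`, `complementary_imaging`, `local_management`.
#' @param ... Conditions built with [condition()]; all must hold (AND).
#' @return A rule list usable inside [ruleset()].
#' @export
rule <- function(id, advise, ...) {
  if (!advise %in% outcome_levels) abort(paste0("unknown outcome: ", advise))
  conds <- list(...)
  list(id = id, advise = advise, when = conds)
}

#' Assemble a triage ruleset
#'
#' @param ... Rules built with [rule()], in evaluation order.
#' @param default_outcome Outcome returned when no rule matches (`NULL`
#'   makes the ruleset non-total, which [validate_ruleset()] reports).
#' @param name Optional ruleset name.
#' @return An object of class `triage_ruleset`.
#' @export
ruleset <- function(..., default_outcome = NULL, name = "custom") {
  rules <- list(...)
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate rule ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!is.null(default_outcome) && !default_outcome %in% outcome_levels) {
    abort(paste0("unknown default outcome: ", default_outcome))
  }
  structure(list(name = name, rules = rules, default_outcome = default_outcome),
            class = "triage_ruleset")
}

#' The default triage ruleset
#'
#' A reconstruction of the three-way orientation decision for soft tissue
#' masses, built from the published red flags (size over 5 cm, depth, recent
#' growth, pain; suspicious heterogeneous imaging) with a conservative
#' default. The authoritative decision tree behind the mobile app is not
#' public, so this ruleset is a documented reconstruction shipped as an
#' editable configuration, not a claim of fidelity:
#'
#' * `R1` suspicious heterogeneous imaging: refer to expert center;
#' * `R2a`/`R2b` imaged and (size >= 50 mm or deep): refer;
#' * `R3a`–`R3c` not imaged and (size >= 50 mm, deep, or any of growth /
#'   pain / hardness): complementary imaging;
#' * `R4` imaged, homogeneous lipomatous, superficial, < 50 mm, no signs:
#'   possible local management;
#' * `R5` imaged, homogeneous non-lipomatous, superficial, < 30 mm, no
#'   signs: possible local management;
#' * `R6` anything else not imaged: complementary imaging;
#' * default (imaged, nothing above): refer.
#'
#' "Over 5 cm" is implemented as `>= 50` mm — ties go to the alarming side.
#' `shrinkage` is collected but used by no default rule; custom rulesets may
#' use it.
#'
#' @return A `triage_ruleset`.
#' @export
default_ruleset <- function() {
  ruleset(
    rule("R1", "refer_expert",
         condition("imaging_pattern", "eq", "heterogeneous_suspicious")),
    rule("R2a", "refer_expert",
         condition("imaging_performed", "eq", TRUE),
         condition("size", "ge", 50)),
    rule("R2b", "refer_expert",
         condition("imaging_performed", "eq", TRUE),
         condition("depth", "eq", "deep_or_mixed")),
    rule("R3a", "complementary_imaging",
         condition("imaging_performed", "eq", FALSE),
         condition("size", "ge", 50)),
    rule("R3b", "complementary_imaging",
         condition("imaging_performed", "eq", FALSE),
         condition("depth", "eq", "deep_or_mixed")),
    rule("R3c", "complementary_imaging",
         condition("imaging_performed", "eq", FALSE),
         condition("signs", "any_sign", c("growth", "pain", "hardness"))),
    rule("R4", "local_management",
         condition("imaging_performed", "eq", TRUE),
         condition("imaging_pattern", "eq", "lipomatous_homogeneous"),
         condition("depth", "eq", "superficial"),
         condition("size", "lt", 50),
         condition("signs", "no_signs")),
    rule("R5", "local_management",
         condition("imaging_performed", "eq", TRUE),
         condition("imaging_pattern", "eq", "homogeneous_other"),
         condition("depth", "eq", "superficial"),
         condition("size", "lt", 30),
         condition("signs", "no_signs")),
    rule("R6", "complementary_imaging",
         condition("imaging_performed", "eq", FALSE)),
    default_outcome = "refer_expert",
    name = "fsg_default"
  )
}

# Evaluate one condition vectorized over the prepared field columns.
eval_condition <- function(cond, fields) {
  if (cond$field == "signs") {
    if (cond$op == "no_signs") {
      return(lengths(fields$signs) == 0)
    }
    if (cond$op == "any_sign") {
      return(vapply(fields$signs, function(s) any(s %in% cond$value), logical(1)))
    }
    abort(paste0("op `", cond$op, "` not applicable to field `signs`"))
  }
  x <- fields[[cond$field]]
  out <- switch(cond$op,
    eq = x == cond$value,
    ge = x >= cond$value,
    lt = x < cond$value,
    `in` = x %in% cond$value,
    abort(paste0("op `", cond$op, "` not applicable to field `", cond$field, "`"))
  )
  out & !is.na(out)
}

prepare_rule_fields <- function(data) {
  signs <- if (is.list(data$signs)) data$signs else parse_signs(data$signs)
  list(
    size = size_mm(data$size_radiological_mm, data$size_clinical_mm),
    depth = data$depth,
    imaging_pattern = data$imaging_pattern,
    imaging_performed = data$imaging_performed,
    signs = signs
  )
}

# First-match evaluation over a prepared field list; returns outcome and
# fired rule id per row (NA outcome where nothing matched and no default).
match_rules <- function(rs, fields, n) {
  outcome <- rep(NA_character_, n)
  fired <- rep(NA_character_, n)
  open <- rep(TRUE, n)
  for (r in rs$rules) {
    if (!any(open)) break
    hit <- Reduce(`&`, lapply(r$when, eval_condition, fields = fields), rep(TRUE, n))
    take <- open & hit
    outcome[take] <- r$advise
    fired[take] <- r$id
    open <- open & !take
  }
  if (!is.null(rs$default_outcome) && any(open)) {
    outcome[open] <- rs$default_outcome
    fired[open] <- "default"
  }
  list(outcome = outcome, fired_rule = fired)
}

#' Apply a triage ruleset to patient records
#'
#' Evaluates the ruleset first-match-wins on each row and records which rule
#' fired (audit trail). A record with no evaluable field — both sizes
#' missing and no imaging pattern — raises an "insufficient information"
#' error naming the patient, never a silent default.
#'
#' @param data A data frame with at least the triage fields
#'   (`patient_id`, `size_clinical_mm`, `size_radiological_mm`, `depth`,
#'   `imaging_performed`, `imaging_pattern`, `signs`).
#' @param rs A `triage_ruleset`, by default [default_ruleset()].
#' @return The input tibble with `outcome` and `fired_rule` columns added.
#' @export
triage <- function(data, rs = default_ruleset()) {
  stopifnot(is.data.frame(data), inherits(rs, "triage_ruleset"))
  data <- tibble::as_tibble(data)
  fields <- prepare_rule_fields(data)
  no_info <- is.na(fields$size) & (is.na(fields$imaging_pattern) | fields$imaging_pattern == "none")
  if (any(no_info)) {
    ids <- if ("patient_id" %in% names(data)) data$patient_id[no_info] else which(no_info)
    abort(paste0(
      "insufficient information to triage record(s): ",
      paste(ids, collapse = ", "),
      " (no size and no imaging pattern)"
    ))
  }
  m <- match_rules(rs, fields, nrow(data))
  if (anyNA(m$outcome)) {
    abort("ruleset is not total: some records matched no rule and no default outcome is set")
  }
  data$outcome <- m$outcome
  data$fired_rule <- m$fired_rule
  data
}

#' Probe grid of triage inputs
#'
#' Exhaustive grid over the triage enums crossed with a size grid spanning
#' the default thresholds, respecting the pattern/imaging consistency
#' invariant. Used for ruleset validation and for exhaustive property
#' checks (totality, determinism, monotone escalation).
#'
#' @param sizes Numeric size grid (mm).
#' @return A tibble of synthetic triage inputs.
#' @export
probe_grid <- function(sizes = c(5, 9, 29, 30, 49, 50, 51, 120)) {
  sign_subsets <- unlist(lapply(0:4, function(k) {
    utils::combn(sign_levels, k, simplify = FALSE)
  }), recursive = FALSE)
  base <- tidyr::expand_grid(
    size = sizes,
    depth = depth_levels,
    imaging_pattern = pattern_levels,
    signs_idx = seq_along(sign_subsets)
  )
  base$imaging_performed <- base$imaging_pattern != "none"
  base$signs <- sign_subsets[base$signs_idx]
  tibble::tibble(
    patient_id = paste0("probe", seq_len(nrow(base))),
    size_clinical_mm = base$size,
    size_radiological_mm = base$size,
    depth = base$depth,
    imaging_performed = base$imaging_performed,
    imaging_pattern = base$imaging_pattern,
    signs = base$signs
  )
}

#' Static checks on a triage ruleset
#'
#' Reports duplicate rule ids, rules that never fire on the probe grid
#' (shadowed by earlier rules or unsatisfiable), and non-total coverage
#' (some probe record matches no rule and no default outcome exists).
#'
#' @param rs A `triage_ruleset`.
#' @param probe Probe records, by default [probe_grid()].
#' @return A tibble of findings (`type`, `rule_id`, `message`); zero rows
#'   means no findings.
#' @export
validate_ruleset <- function(rs, probe = probe_grid()) {
  stopifnot(inherits(rs, "triage_ruleset"))
  findings <- tibble::tibble(type = character(), rule_id = character(), message = character())
  ids <- vapply(rs$rules, `[[`, character(1), "id")
  for (dup in unique(ids[duplicated(ids)])) {
    findings <- dplyr::add_row(findings, type = "duplicate_id", rule_id = dup,
                               message = paste0("rule id `", dup, "` is not unique"))
  }
  fields <- prepare_rule_fields(probe)
  m <- match_rules(rs, fields, nrow(probe))
  for (id in setdiff(ids, unique(m$fired_rule))) {
    findings <- dplyr::add_row(findings, type = "unreachable", rule_id = id,
                               message = paste0("rule `", id, "` never fires on the probe grid"))
  }
  if (anyNA(m$outcome)) {
    findings <- dplyr::add_row(findings, type = "non_total", rule_id = NA_character_,
                               message = "some probe records match no rule and no default outcome is set")
  }
  findings
}

#' @export
print.triage_ruleset <- function(x, ...) {
  cat("Triage ruleset `", x$name, "` (", length(x$rules), " rules, first match wins)\n", sep = "")
  for (r in x$rules) {
    conds <- vapply(r$when, function(cond) {
      paste(cond$field, cond$op, paste(format(cond$value), collapse = ","))
    }, character(1))
    cat(sprintf("  %-4s %s  <=  %s\n", r$id, r$advise, paste(conds, collapse = " & ")))
  }
  cat("  default:", x$default_outcome %||% "<none>", "\n")
  invisible(x)
}

#' Read / write a ruleset as YAML
#'
#' Serializes the ordered rules, their conditions and the default outcome to
#' a YAML document, so rulesets can be edited and shared as configuration.
#' The shipped default is available via
#' `system.file("extdata/rulesets/fsg_default.yaml", package = "sarctriage")`.
#'
#' @param path YAML file path.
#' @return `read_ruleset()` a `triage_ruleset`; `write_ruleset()` `path`,
#'   invisibly.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) abort(paste0("ruleset not found: ", path))
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc$rules, function(r) {
    conds <- lapply(r$when, function(cond) {
      value <- cond$value
      if (!is.null(value) && cond$field == "imaging_performed") value <- as.logical(value)
      condition(cond$field, cond$op, value)
    })
    do.call(rule, c(list(id = r$id, advise = r$advise), conds))
  })
  do.call(ruleset, c(rules, list(default_outcome = doc$default, name = doc$name %||% "unnamed")))
}

#' @rdname read_ruleset
#' @param rs A `triage_ruleset` to serialize.
#' @export
write_ruleset <- function(rs, path) {
  stopifnot(inherits(rs, "triage_ruleset"))
  doc <- list(
    name = rs$name,
    rules = lapply(rs$rules, function(r) {
      list(id = r$id, advise = r$advise,
           when = lapply(r$when, function(cond) {
             cond[!vapply(cond, is.null, logical(1))]
           }))
    }),
    default = rs$default_outcome
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
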