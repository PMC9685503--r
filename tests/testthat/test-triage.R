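make_record <- function(size = NA_real_, depth = "superficial",
                        pattern = "none", imaged = pattern != "none",
                        signs = character(0)) {
  tibble::tibble(
    patient_id = "X1",
    size_clinical_mm = size, size_radiological_mm = NA_real_,
    depth = depth, imaging_performed = imaged, imaging_pattern = pattern,
    signs = list(signs)
  )
}

test_that("default ruleset reproduces the narrative orientation examples", {
  # deep 120 mm suspicious symptomatic mass: direct referral
  r <- triage(make_record(120, "deep_or_mixed", "heterogeneous_suspicious",
                          signs = c("growth", "pain")))
  expect_equal(r$outcome, "refer_expert")
  # superficial 9 mm homogeneous sign-free mass: possible local management
  r <- triage(make_record(9, "superficial", "homogeneous_other"))
  expect_equal(r$outcome, "local_management")
  # deep 60 mm mass without prior imaging: complementary imaging first
  r <- triage(make_record(60, "deep_or_mixed", "none"))
  expect_equal(r$outcome, "complementary_imaging")
  # superficial 20 mm homogeneous lipomatous mass: local management
  r <- triage(make_record(20, "superficial", "lipomatous_homogeneous"))
  expect_equal(r$outcome, "local_management")
})

test_that("triage is auditable and refuses uninformative records", {
  r <- triage(make_record(120, "deep_or_mixed", "heterogeneous_suspicious"))
  expect_equal(r$fired_rule, "R1")
  expect_error(triage(make_record()), "insufficient information.*X1")
  # a record with imaging but no size is still evaluable
  r2 <- triage(make_record(NA, "deep_or_mixed", "heterogeneous_suspicious"))
  expect_equal(r2$outcome, "refer_expert")
})

test_that("triage is total and deterministic on the probe grid", {
  grid <- probe_grid()
  a <- triage(grid)
  b <- triage(grid)
  expect_false(anyNA(a$outcome))
  expect_true(all(a$outcome %in% c("local_management", "complementary_imaging",
                                   "refer_expert")))
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$fired_rule, b$fired_rule)
})

test_that("suspicious imaging always yields direct referral", {
  grid <- probe_grid()
  sus <- triage(grid[grid$imaging_pattern == "heterogeneous_suspicious", ])
  expect_true(all(sus$outcome == "refer_expert"))
})

test_that("adding an alarming feature never de-escalates the advice", {
  grid <- probe_grid()
  base_rank <- outcome_rank(triage(grid)$outcome)

  aggravate <- function(mutated) outcome_rank(triage(mutated)$outcome)

  # size crossing 50 mm upward
  g <- grid
  small <- !is.na(g$size_radiological_mm) & g$size_radiological_mm < 50
  g$size_radiological_mm[small] <- 51
  g$size_clinical_mm[small] <- 51
  expect_true(all(aggravate(g) >= base_rank))

  # superficial -> deep
  g <- grid
  g$depth[g$depth == "superficial"] <- "deep_or_mixed"
  expect_true(all(aggravate(g) >= base_rank))

  # homogeneous imaging -> suspicious
  g <- grid
  homog <- g$imaging_pattern %in% c("lipomatous_homogeneous", "homogeneous_other")
  g$imaging_pattern[homog] <- "heterogeneous_suspicious"
  expect_true(all(aggravate(g) >= base_rank))

  # adding a clinical sign
  g <- grid
  g$signs <- lapply(g$signs, function(s) unique(c(s, "pain")))
  expect_true(all(aggravate(g) >= base_rank))
})

test_that("ruleset static checks find shadowed rules and missing defaults", {
  expect_equal(nrow(validate_ruleset(default_ruleset())), 0)

  shadowed <- ruleset(
    rule("A", "refer_expert", condition("size", "ge", 50)),
    rule("B", "local_management", condition("size", "ge", 50)),
    default_outcome = "complementary_imaging"
  )
  f <- validate_ruleset(shadowed)
  expect_true(any(f$type == "unreachable" & f$rule_id == "B"))

  partial <- ruleset(
    rule("A", "refer_expert", condition("size", "ge", 50)),
    default_outcome = NULL
  )
  f2 <- validate_ruleset(partial)
  expect_true(any(f2$type == "non_total"))
  expect_error(triage(make_record(20, "superficial", "homogeneous_other"), partial),
               "not total")
})

test_that("rulesets survive a YAML round trip", {
  rs <- default_ruleset()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ruleset(rs, path)
  back <- read_ruleset(path)
  grid <- probe_grid()
  expect_identical(triage(grid, back)$outcome, triage(grid, rs)$outcome)
  expect_identical(triage(grid, back)$fired_rule, triage(grid, rs)$fired_rule)
  expect_error(read_ruleset(withr::local_tempfile()), "not found")
})

test_that("optimality is defined for nonbenign tumors only", {
  expect_equal(classify_optimality("referral_expert", "nonbenign"), "optimal")
  expect_equal(classify_optimality("surgery_nonexpert", "nonbenign"), "nonoptimal")
  expect_equal(classify_optimality("followup_no_imaging", "nonbenign"), "nonoptimal")
  expect_error(classify_optimality("referral_expert", "benign"), "nonbenign")
})

test_that("management deltas compare advice adequacy with real-life adequacy", {
  df <- tibble::tibble(
    tumor_class = "nonbenign",
    real_management = c("surgery_nonexpert", "referral_expert", "referral_expert",
                        "followup_no_imaging"),
    outcome = c("refer_expert", "local_management", "refer_expert",
                "complementary_imaging")
  )
  out <- management_delta(df)
  expect_equal(out$changed, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$direction, c("to_adequate", "to_inadequate", "none", "to_adequate"))

  # with imaging not counting as adequate, the imaging advice stops rescuing
  out2 <- management_delta(df, imaging_counts_as_adequate = FALSE)
  expect_equal(out2$direction[4], "none")

  df$tumor_class[1] <- "benign"
  expect_error(management_delta(df), "nonbenign")
})
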