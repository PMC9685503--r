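---
title: "Methods: counterfactual evaluation of soft-tissue-mass triage rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual evaluation of soft-tissue-mass triage rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarctriage)
```

## The evaluation design

`sarctriage` evaluates a three-way triage aid for soft tissue masses
retrospectively: every patient in a cohort is triaged from the information
available at the first medical description, and the advice is mapped to a
counterfactual "estimated" interval to an expert center, which is compared
pairwise with the interval actually observed. The design deliberately stops
at the interval: it does not model what complementary imaging would have
found, nor survival — the counterfactual claim is about referral time only.

The interval map is the heart of the design. Direct referral is assumed to
cost 1 month and an imaging detour 2 months (a deliberately conservative
local-practice assumption); a benign tumor correctly kept local costs 0
months; and a *nonbenign* tumor advised local management is assigned its
own observed interval — the advice buys that patient nothing, which
penalizes the rule for its misses rather than hiding them. The sensitivity
scenario replaces 1/2 with 3/6 months; scenarios are first-class objects
(`scenario()`), and `scenario(imaging >= refer)` is enforced because an
imaging detour cannot accelerate referral.

## The triage ruleset

The decision logic is a first-match-wins ordered rule list over five
fields: size (radiological size takes precedence over clinical size, since
the underlying algorithm is grounded in first imaging results), depth,
imaging pattern, whether imaging was performed, and the clinical signs.
The shipped default (`default_ruleset()`, also as YAML in
`extdata/rulesets/fsg_default.yaml`) is a *reconstruction* from the
published red flags — size over 5 cm, depth, recent growth and pain should
trigger MRI; heterogeneous suspicious imaging should trigger referral —
plus a conservative default: an imaged mass matching nothing else is
referred, an unimaged one is sent to imaging. The authoritative decision
tree of the mobile application is not public, so no claim of fidelity is
made; the ruleset is configuration, not truth, and `validate_ruleset()`
checks any edit for shadowed rules and coverage gaps against an exhaustive
probe grid.

Choices worth calling out:

* **"Over 5 cm" is implemented as ≥ 50 mm.** Ties go to the alarming side,
  matching the aid's stated intent to avoid missing malignancy.
* **Disjunctions are split into sibling rules** (R2a/R2b rather than one
  rule with an OR), so the audit trail (`fired_rule`) pinpoints which limb
  fired. First-match semantics make the two forms equivalent.
* **`shrinkage` is collected but unused** by the default rules; its place
  in the original tree is unknown and custom rulesets may use it.
* **Monotone escalation** is a tested invariant of the default ruleset:
  crossing 50 mm upward, going deep, turning suspicious on imaging, or
  adding a sign never moves the advice toward local management.
* A record with no size and no imaging pattern is not triageable and
  raises an explicit error rather than falling through to a default.

Whether the imaging advice counts as "adequate" when scoring management
changes is not derivable from the published tables; the package counts it
as adequate by default (imaging is a step on the referral pathway) and
exposes `imaging_counts_as_adequate = FALSE` for the strict reading.

## Statistical layer

* **Paired comparison.** The classical paired Student t (one-sample t on
  differences); no Welch variant exists for paired data. Zero-variance
  differences are degenerate: an all-zero difference vector returns t = 0,
  p = 1 with a zero-width interval (the series are identical), while a
  nonzero constant difference raises an error reporting the constant.
* **Outlier rules.** The mean + 2.5 SD rule is applied to the *observed*
  times and upper-tail only: referral delays are strictly positive and
  right-skewed, and only implausibly long times are suspect. A symmetric
  variant and Tukey fences (quartiles by linear interpolation,
  `quantile(type = 7)`; fixed here because conventions differ) are
  provided. Exclusion is not idempotent under the SD rule (masking); this
  is documented rather than "fixed".
* **Power.** Exact noncentral-t power for the two-sided paired design. The
  SD behind the original sample-size choice is not published; the package
  back-derives it from a reported 95% CI via `sd_from_ci()` (half-width
  divided by the t quantile, times √n) and labels it as back-derived.
  At n = 60 pairs, an 8-month true benefit and the back-derived SD of
  14.81 months, power is 0.984 ≥ 0.90.
* **Determinant screen.** Pearson correlations (two-sided, pairwise
  complete) of the observed interval with distance, age, number of signs
  (|signs|, 0–4), size, depth (deep = 1, unknown excluded) and prior
  imaging (0/1; the point-biserial correlation is a Pearson r). No
  multiplicity correction by default — mirroring the evaluated analysis —
  with Holm available. Zero-variance covariates are flagged, not dropped.
* **Bayesian regression.** The published analysis names only "MCMC with a
  95% credibility-interval rule"; model, priors and variable set are
  unstated. The package's choice: normal–inverse-gamma conjugate priors
  (coefficients centered at 0 with variance `1e4` times the response's
  scale; the scale uses `max(var(y), mean(y)^2)` so the prior stays proper
  for near-constant responses), IG(10⁻³, 10⁻³) noise, Gibbs sampling with
  4 chains × 5000 retained draws after 1000 burn-in by default, covariates
  = the six determinants on complete cases. All are arguments. The sampler
  is validated against the closed-form conjugate posterior at fixed noise
  variance and against a null-coefficient coverage simulation.

## The synthetic generator

No patient-level data accompany the evaluated study, so `generate_cohort()`
emulates its population: 78 patients, benign fraction 18/78 (binomial by
default, exact under `stratified = TRUE`). Numeric fields use truncated
distributions whose published "(x–y)" spans are read as min–max truncation
bounds (they match the printed extremes; true quartiles are not
recoverable): observed intervals are truncated log-normal on [1, 85]
months calibrated to mean 9.14 (log-normal chosen for a strictly positive
right-skewed delay; a gamma family is switchable), ages truncated normal
with median 60.5 on [21, 92], distances log-normal with median 69 km on
[1, 1103], sizes log-normal with class-specific medians (90/102 mm
clinical/radiological nonbenign, 60/40 benign). Calibration solves for the
location parameter by root-finding in z-space, which is stable even when a
truncation bound sits far in a tail, and an unreachable target raises a
calibration error.

Coupling between features and class is generated through a latent advice
category: each record first draws its advice from the class-conditional
mixture (46/13/1 of 60 nonbenign; 13/3/2 of 18 benign), then draws
features consistent with that advice under the default ruleset —
referral records are suspicious on imaging (or imaged, deep/large),
imaging-advice records lack prior imaging, local-advice records are small
superficial homogeneous sign-free masses. This is the calibration that
matters for the headline quantity: it pins the expected estimated interval
near 1.28 months against the observed mean of 9.14, an expected paired
reduction of about 7.9 months. Benign records never carry pain (a 0/18
prevalence in the emulated population). Missing sizes are generated only
among imaged suspicious records so every record stays triageable, and
depth is unknown with probability 6/60.

What the generator does **not** emulate: within-class marginal size
distributions are distorted by the advice conditioning (local-advice
records are forced small, non-suspicious referrals forced deep or ≥ 50
mm); management category is drawn independently of advice (the real
cross-table is unpublished), except that watchful-waiting-without-imaging
is placed on records without imaging; intervals are independent of all
covariates (consistent with the null determinant finding, and what makes
the screen's 5% rejection property testable); histology is a label, not
biology. Passing tests therefore show the pipeline is correct and
calibrated *to these conditions*, not that the triage aid works on real
patients.

`make_fixture_cohort()` is different in kind: a deterministic, hand-built
60-record nonbenign cohort whose advice histogram is exactly 46/13/1. Its
single local-advice case is a superficial 9 mm sign-free
dermatofibrosarcoma with an observed interval of 12 months — the value
obtained by solving the published base-scenario mean (1.4 months) against
the 46 × 1 + 13 × 2 contribution of the other records — which makes the
fixture's scenario means exact arithmetic: 84/60 = 1.4 and 228/60 = 3.8
months. The real-life management marginals (5/6/9/13/27) are distributed
so that follow-up-without-imaging falls on non-imaged records; the
local-advice case is set as referred in real life, the direction that
makes it the one advice-induced loss.

## Problem sizes and tolerances

The test suite checks the paired test's empirical size over 10,000 null
cohorts of 78 pairs (±3 Monte-Carlo SE around 5%), power against a 10⁵
replicate Monte-Carlo oracle, recovery of the calibrated mean reduction
over 60 replicate cohorts (±3 SE of the replicate mean), coverage of the
credible interval over 150 null fits, and the screen's null rejection rate
over 300 cohorts; `scripts/acceptance.R` uses 200 replicate cohorts for
the recovery quantity. Exact claims (fixture arithmetic, assignment
constants, round-trips) are asserted exactly. Whole-cohort published means
are internally inconsistent with their per-group arithmetic at the 0.1
month level (e.g. 103/78 ≈ 1.32 against a printed 1.4), so only the
nonbenign fixture arithmetic, which reconciles exactly, is asserted
exactly; the whole-cohort reduction is checked as a stochastic recovery.

## Known limitations

The default ruleset is a documented reconstruction of an unpublished tree;
the published benign-side advice marginals (all benign patients imaged,
yet three advised "complementary imaging") are unreachable under any
first-match ruleset of this form, and the generator reproduces the advice
marginal rather than the benign imaging prevalence, a trade worth about
0.04 months on the whole-cohort estimated mean. Management × advice
cross-tables are not asserted anywhere because the published marginals do
not identify them. The Bayesian model is one defensible choice among many,
exposed as configuration rather than claimed as the original.
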