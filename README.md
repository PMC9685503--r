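# sarctriage

Soft tissue sarcomas do best when they reach an expert sarcoma center
before anyone operates, yet many soft tissue masses are biopsied, excised
("whoops" surgery) or simply watched outside the expert network, and months
pass between the first medical description of a mass and its presentation
to an expert multidisciplinary tumor board (MTB). `sarctriage` implements
an in-silico evaluation of a rule-based triage aid for this problem: a
configurable first-match decision rule over simple first-encounter features
(size in mm, depth, imaging pattern, clinical signs) that returns one of
three orientations — direct expert referral, complementary imaging first,
or possible local management — and a counterfactual analysis of how much
referral time that advice would have bought.

It is written for biostatisticians and clinical epidemiologists who want to
reproduce, stress-test or re-calibrate this style of evaluation: everything
is tibble-in / tibble-out, pipeable, seeded, and runs end to end on a
synthetic cohort generator calibrated to published cohort descriptives, so
no patient-level data are required.

## The model

For patient *i* with observed interval *T<sub>i</sub>* (months from first
medical description to expert-center MTB), the triage outcome
*A<sub>i</sub>* ∈ {refer, imaging, local} determines a counterfactual
estimated interval

```
T*_i = 1                if A_i = refer        (3 under the sensitivity scenario)
       2                if A_i = imaging      (6 under the sensitivity scenario)
       0                if A_i = local and the tumor is benign
       T_i              if A_i = local and the tumor is nonbenign
```

The primary comparison is the classical paired Student t test on
*D<sub>i</sub> = T<sub>i</sub> − T\*<sub>i</sub>*, reported as the mean
difference with its 95% CI and two-sided p at α = 0.05, with variants
excluding extreme observed times (upper-tail mean + 2.5 SD rule, or Tukey
fences Q1 − 1.5 IQR / Q3 + 1.5 IQR). Around it sit the supporting
analyses: exact noncentral-t power for the paired design, a Pearson screen
of six putative interval determinants (distance, age, number of signs,
size, depth, prior imaging), and a Bayesian linear regression (Gibbs
sampler, normal–inverse-gamma priors) that calls a coefficient significant
when its 95% credible interval excludes 0.

## Worked example

```r
library(sarctriage)

cohort <- generate_cohort(cohort_spec(), seed = 1)   # 78 synthetic patients
analysis <- analyze_cohort(cohort)
writeLines(render_report(analysis))
```

```
Triage evaluation report (n = 78, ruleset `fsg_default`, alpha = 0.05)

Triage outcome counts:
  benign     complementary_imaging    1
  benign     local_management         1
  benign     refer_expert            14
  nonbenign  complementary_imaging   12
  nonbenign  local_management         1
  nonbenign  refer_expert            49

Mean intervals (months):
  base         overall    n=78  observed 8.27  estimated 1.16  difference 7.11
  ...

Paired comparisons (observed - estimated):
  base         none           n=78  mean 7.1149  CI [5.4246, 8.8052]  p=1.869e-12
  base         sd_2_5         n=75  mean 6.2189  CI [4.8142, 7.6236]  p=3.616e-13  (3 excluded)
  ...
```

Reading: on this synthetic cohort the triage advice would have referred 63
of 78 patients directly or after one imaging step; the base scenario turns
a mean observed interval of 8.27 months into an estimated 1.16 months, a
paired mean reduction of 7.11 months (95% CI 5.42–8.81) that survives both
outlier-exclusion rules. The determinant screen (bottom of the report)
shows no covariate significantly correlated with the observed interval, as
expected — the generator draws intervals independently of the covariates.

Other entry points: `triage()` (per-record advice with the fired rule for
audit), `run_counterfactual()` (the paired dataset), `paired_t()`,
`paired_power()`, `exclude_outliers()`, `determinant_screen()`,
`bayesian_regression()` (with `tidy()`/`glance()` methods),
`make_fixture_cohort()` (a deterministic 60-patient nonbenign cohort whose
advice mix is exactly 46/13/1), `autoplot()` and `plot_interval_shift()`
for figures, and `read_ruleset()`/`write_ruleset()` for YAML rule
configurations (the shipped default is
`inst/extdata/rulesets/fsg_default.yaml`).

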