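---
title: "Deriving and validating an integer risk score for silent atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating an integer risk score for silent atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdash)
```

## The problem

Silent atrial fibrillation (SAF) — AF detected on prolonged ECG monitoring in
a subject who reports no symptoms — is common in the elderly and carries the
thromboembolic risk of overt AF without the warning signs. Screening an
entire elderly population with weeks of continuous ECG is expensive, so a
cheap triage rule is valuable: an integer score computed from routinely
available clinical facts that flags who is (and, just as importantly, who is
not) worth monitoring.

`mrdash` implements the full analysis chain behind such a score:

1. **Synthetic cohort generation** — elderly screening cohorts with known
   ground truth, so every downstream stage is testable without patient data.
2. **Phenotyping** — guideline definitions of hypertension, diabetes, CKD,
   obesity, biomarker elevation, and the ">30 s ECG episode" AF rule.
3. **Association analysis** — group comparisons and univariate/multivariable
   logistic odds ratios, with optional poststratification weights.
4. **Score derivation** — the MR-DASH procedure: repeated 2/3–1/3 random
   splits, per-split multivariable fits, significance counting, and
   rounded-odds-ratio point assignment.
5. **Validation** — ROC analysis with DeLong confidence intervals and
   cutoff selection by minimal distance to the ideal corner (0, 1).

## Phenotype definitions

A subject is AF-positive if and only if at least one confirmed ECG episode
lasts *strictly longer than* 30 s; an episode of exactly 30 s does not
count, and durations are compared exactly as stored, without rounding.
Silent AF is detected AF in an asymptomatic subject; symptoms without
detected AF contribute nothing.

The condition flags follow the clinical guidelines:

| flag | rule |
|------|------|
| hypertension (`ha`) | mean SBP ≥ 140 mmHg, or mean DBP ≥ 90 mmHg, or antihypertensive treatment |
| diabetes (`dm`) | HbA1c ≥ 6.5%, or glucose-lowering treatment |
| CKD (`ckd`) | CKD-EPI 2009 eGFR < 60 mL/min/1.73 m², or ACR ≥ 30 mg/g |
| obesity | BMI ≥ 30 kg/m² |
| `ntprobnp_high` | NT-proBNP > 125 pg/mL (strict) |
| `hscrp_high` | hs-CRP > 5 mg/L (strict) |
| `age75` | age ≥ 75 years |

Two unit/definition choices were genuinely open and are resolved as follows.
The NT-proBNP threshold is taken as 125 **pg/mL**, the standard reference
limit (the alternative ng/mL reading would be a thousandfold larger and
physiologically meaningless as a population cut). The CKD-EPI race
coefficient is fixed at 1, appropriate for a European population sample, but
is exposed as `phenotype_thresholds(race_coef =)`. Hypertension is assessed
on the *mean* of all recorded BP measurements rather than requiring the
criterion at every visit. Missing required fields lead to complete-case
exclusion with a per-field log (the `"exclusions"` attribute); no imputation
is attempted.

## The synthetic cohort generator

`generate_cohort()` emulates a nationwide cross-sectional screening study of
adults aged ≥ 65: `n = 3014` subjects by default, age drawn from a normal
distribution with mean 77.5 y and SD 7.9 y truncated at 65, and seventeen
binary risk factors at the published whole-population prevalences (male sex
50.9%, diabetes 29.2%, heart failure 22.3%, CKD 33.3%, hypertension 80.7%,
elevated NT-proBNP 75.9%, and so on — `default_covariate_prevalences()`).

**Condition flags are realised through laboratory values.** Rather than
drawing, say, a diabetes flag *and* an HbA1c independently, the generator
draws the latent flag at its prevalence and then draws labs conditional on
it (HbA1c mixture for diabetics/non-diabetics, BP conditional on
hypertension and treatment, creatinine obtained by analytically inverting
the CKD-EPI equation at a target eGFR, and so on). Guideline phenotyping
therefore recovers each flag exactly, and the flag prevalences are exact
Bernoulli draws rather than by-products of distribution tails. The
conditional distribution parameters live in
`default_lab_distributions()` on the spec, not in code.

**Outcomes.** Silent AF is drawn from a logistic model in the published
adjusted silent-AF odds ratios (age OR 1.36 per 5 years above 65, male 2.58,
stroke/TIA 1.59, diabetes 1.48, heart failure 2.06, CKD 1.39, NT-proBNP
2.37, …), with the intercept calibrated by monotone bisection
(`calibrate_intercept()`) so the population SAF prevalence is 9.3%.
Symptomatic AF is then drawn among the remaining subjects from the
overall-AF effect sizes, calibrated so total AF is 22.6%. This construction
honours both published effect-size sets and both prevalences at once, and it
makes the symptomatic fraction among AF equal 401/680 in expectation. It
also means symptoms are automatically more frequent in subjects with
coronary heart disease, obesity or thyroid disease — the factors whose
overall-AF odds ratios exceed their silent-AF ones — without a separate
symptom model; we preferred this to an ad-hoc three-covariate symptom model
because it keeps silent AF *exactly* logistic in the silent-AF effects,
which is what makes parameter-recovery testing meaningful. The symptom flag
itself is modelled as a given boolean: no ascertainment instrument is
simulated.

**Episodes and monitoring.** Every AF-positive subject receives at least one
episode longer than 30 s (1 + Poisson(2) episodes, durations
30 s + lognormal); a configurable fraction (default 15%) of AF-negative
subjects receives only sub-30-s episodes, specifically to exercise the
duration filter. Effective monitoring time is lognormal with median
23 d 10 h 26 min, truncated below at 12 min; episodes are placed uniformly
within the monitoring window.

**What the generator does *not* model.** Covariates are independent by
default because only marginal prevalences are published; real comorbidity
correlation (e.g. CKD with heart failure) is absent unless you supply a
`covariate_correlation` matrix, which activates a Gaussian-copula draw with
the requested latent correlations (marginals preserved). No ECG waveforms,
no detection error (detected AF equals true AF by construction), no
missingness, no survey design (region/environment strata are not generated;
`poststratify()` works on any categorical columns you provide). Passing
tests on synthetic cohorts therefore demonstrates that the *procedures* are
correct and that the score behaves as published **given** the published
effect sizes — not that those effect sizes hold in any new population.

## Association analysis

`contingency_or()` gives the 2×2 cross-product odds ratio with the Wald
interval (`SE = sqrt(1/a + 1/b + 1/c + 1/d)`); a zero cell triggers the
Haldane–Anscombe 0.5 correction and flags the estimate.
`fit_logistic()` is a maximum-likelihood logistic fit (IRLS/Newton,
convergence tolerance 1e-12, ≤ 100 iterations) returning Wald odds-ratio
tables — Wald rather than profile-likelihood intervals, matching standard
SPSS-style output. Rank-deficient designs fail naming the collinear
columns; separation fails naming the worst predictor. Group tests use the
Pearson chi-square without continuity correction and, for age, a
pooled-variance t-test by default (`welch = TRUE` for the unequal-variance
form). Weights from `poststratify()` enter as frequency weights and move
point estimates only; design-based (complex-survey) variance is explicitly
out of scope and the multivariable models are unweighted by default, since
it is not documented whether the published models were weighted.

## Score derivation

The eligible population is everyone **without overt (symptomatic) AF**: the
score discriminates silent AF from no AF among people who would not present
clinically. `run_draws()` repeats, five times by default:

1. split the eligible ids 2/3 (derivation) / 1/3 (validation) by simple
   random sampling without replacement (`round(2n/3)` derivation; splits are
   unstratified — no stratification is documented for the original
   procedure);
2. fit silent AF on the six factors — male sex, CKD, diabetes, age ≥ 75,
   stroke/TIA, heart failure — on the derivation subset.

`assign_points()` then counts, per factor, the draws with Wald p < 0.05. A
factor significant in ≥ 4 of 5 draws scores `round(mean OR)` points, rounded
half **away from zero** and floored at 1; a factor significant in ≤ 3 draws
scores 1 point. Applied to the published five-draw odds-ratio table this
yields M = 2, R(enal) = 1, D(iabetes) = 1, A(ge) = 3, S(troke/TIA) = 2,
H(eart failure) = 2 — maximum 11. Two readings of "mean OR" (over all
draws, or over the significant draws only) give identical points on the
published table; both are implemented (`or_average`), defaulting to all
draws. The published summary table prints 1 point for heart failure while
the derivation rule and the accompanying text give 2; the package follows
the rule, and the 1-point variant is available via
`point_overrides = c(heart_failure = 1)`.

NT-proBNP is deliberately **not** a score factor, although it predicts
silent AF: the score is meant to be computable in a routine consultation
without a blood draw.

## ROC validation

`roc_curve()` places candidate cutoffs at midpoints between consecutive
distinct scores plus sentinels — for an integer score these are the
half-integer thresholds, so a cutoff of 4.5 means "5 or more points screens
positive" ("positive" is always *strictly greater than* the cutoff). The
AUC is the trapezoid area, which on a step ROC equals the pair-counting
concordance statistic with ties counted ½ (asserted to 1e-12 in the tests);
its 95% CI is DeLong's placement-variance interval — deterministic, unlike a
bootstrap. `optimal_cutoff()` minimises the Euclidean distance
√((1−sens)² + (1−spec)²) to the corner (0, 1), breaking ties toward the
lower cutoff (the more sensitive operating point — preferable for a
rule-out screen). `evaluate_draws()` selects the cutoff on the derivation
subset only and applies it unchanged to validation, so validation labels
never influence the operating point; a re-derived validation cutoff can be
reported alongside (`re_derive_validation = TRUE`) but never replaces the
primary result. Draws whose subset has one outcome class or constant scores
are flagged degenerate and excluded from summary means.

## Numerical choices and degenerate inputs

* Intercept calibration: bisection on [−40, 40] to an achieved-prevalence
  tolerance of 1e-6; unachievable targets (outside (0, 1), or non-finite
  predictors) fail with a diagnostic.
* Point rounding: half away from zero (`floor(x + 0.5)` for positive x),
  because base R's banker's rounding would turn a mean OR of 2.5 into 2.
* Splits of fewer than 10 subjects are refused by default (`min_n`
  relaxable for toy examples).
* Episode durations are compared in seconds with exact arithmetic on the
  stored value.
* Empty episode lists are AF-negative; an all-positive or all-negative
  outcome aborts a logistic fit or ROC with an explicit error rather than a
  silent NaN.

## Problem sizes used by the tests

The test suite generates its own data: boundary and oracle checks run on
fixtures of tens of subjects; distributional recovery uses cohorts of
50,000 (three seeds, with fitted log odds ratios averaged across seeds to
damp Monte Carlo error at the 10% recovery tolerance); discrimination
checks use five cohorts of 3,014 — the study-scale size — averaging the
five-draw mean AUC across cohorts; Wald CI coverage uses 1,000 replicates
of n = 400. These sizes were chosen so each check's Monte Carlo error is
small relative to the tolerance it is asserted at.

## Known limitations

* Independent covariates (unless a copula correlation is supplied) make the
  synthetic multivariable odds ratios cleaner than real ones; collinearity
  between score factors in real cohorts will widen per-draw variability.
* The generator's detected AF equals true AF; sensitivity of the monitoring
  platform is not modelled, so synthetic prevalences are "true" prevalences.
* Wald inference is first-order; for very sparse factors the intervals are
  approximate (the zero-cell correction is flagged, not hidden).
* Poststratification adjusts point estimates only; standard errors ignore
  the weighting.
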