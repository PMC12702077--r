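---
title: "Validating a two-drug glycaemic treatment selection model across ethnicity groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a two-drug glycaemic treatment selection model across ethnicity groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycalibr)
```

## The problem

SGLT2-inhibitors (SGLT2i) and DPP4-inhibitors (DPP4i) are the two most
common second-line glucose-lowering drug classes in type 2 diabetes.
Treatment selection models predict, from routine clinical features, which
of the two will lower a patient's HbA1c more at six months. Before such a
model is deployed in a new population — and in particular before it is
trusted across ethnicity groups it was not developed in — its predictions
must be externally validated and, where needed, recalibrated.

`glycalibr` implements a three-step validation of a two-drug selection
model in observational data, run separately for each of four UK ethnicity
analysis groups (White, South Asian, Black, and Mixed/Other pooled):

1. **Model updating.** A closed testing procedure decides, per
   (ethnicity group, drug class) cell, between the original model
   (Model 1), an intercept update (Model 2, recalibration-in-the-large)
   and an intercept-plus-slope update (Model 3).
2. **Calibration of predicted differences.** The cohort is split into
   deciles of updated predicted SGLT2i − DPP4i difference; within each
   decile the mean prediction is compared with the covariate-adjusted
   observed difference between the two arms.
3. **Clinical subgroups.** Patients are stratified by clinically relevant
   thresholds of predicted benefit, and unadjusted HbA1c response, weight
   change and discontinuation are summarized per drug class.

Because real primary-care records are licence-restricted, the package
ships a synthetic observational cohort generator with planted ground
truth; every stage of the pipeline can therefore be tested against a known
answer.

## The model representation

The selection model is a linear model of achieved 6-month HbA1c
(mmol/mol) in the five routine features: baseline HbA1c, current age, BMI,
eGFR and log-ALT. Continuous features may enter through a 3-knot
restricted cubic spline (RCS); an SGLT2i indicator contributes a drug main
effect plus drug-by-feature interactions. The per-patient *predicted
differential treatment effect* is the difference between the SGLT2i and
DPP4i predictions at identical covariates; negative values favour SGLT2i.

`rcs_basis()` returns the two basis columns of a 3-knot RCS: the identity,
and a restricted truncated-power cubic term that is exactly zero at and
below the first knot and exactly linear beyond the last. The nonlinear
column is divided by the squared knot span so that all coefficients in a
model file stay on the outcome scale — model documents remain legible.
Knot positions are data of the `model_spec` (conventionally the
10th/50th/90th percentiles of the development covariate), never code.

The shipped specification (`default_model_spec()`, also in
`inst/extdata/standin_model.yaml`) is a **synthetic stand-in**, not a
published or fitted model. Its signs follow the clinical narrative —
higher baseline HbA1c, higher BMI, higher eGFR and younger age shift the
predicted benefit towards SGLT2i — and its 13 non-intercept coefficients
give a realistic parameter count for the closed test's degrees of freedom.

## The closed testing procedure

For a cell with observed outcomes $y$ and model predictions $\hat y$, the
three candidate updates are nested:

* Model 1: use $\hat y$ as-is;
* Model 2: $\hat y + a$, with $a$ the mean of $y - \hat y$ (the OLS
  solution of an intercept-only model for the residual — exactly the
  average over- or under-prediction);
* Model 3: $a + b\,\hat y$, with $(a, b)$ from OLS of $y$ on $\hat y$.

Each model is scored by the profile Gaussian log-likelihood
$\mathrm{LL} = -\tfrac n2\,(\log 2\pi + \log(\mathrm{RSS}/n) + 1)$, with
the variance at its maximum-likelihood value (ML, not REML, because
likelihood-ratio tests require it). By construction
$\mathrm{RSS}_3 \le \mathrm{RSS}_2 \le \mathrm{RSS}_1$, so
$\mathrm{LL}_3 \ge \mathrm{LL}_2 \ge \mathrm{LL}_1$ on every input — a
property the suite asserts unconditionally. Test 1 compares Models 2 and
1, test 2 compares Models 3 and 2; if test 2 is significant Model 3 is
chosen, else if test 1 is significant Model 2, else Model 1, at
$\alpha = 5\%$.

### Degrees of freedom: two conventions

The procedure is conventionally described with $df = m$ for test 1 and
$df = m + 1$ for test 2, where $m$ is the number of estimated
non-intercept parameters of the original model ($m$ is always counted
from the model file, never hard-coded). Those df match tests against a
fully *revised* (re-fitted) model. The recalibration models actually
compared here differ by **one** free parameter per step, so the
likelihood-ratio statistics are asymptotically $\chi^2_1$ under the null.
Both conventions are implemented:

* `df_convention = "literal"` (default): $df = m$ and $m+1$. With a
  realistic $m$ this makes the tests deliberately conservative — updates
  are adopted only on overwhelming evidence, and under the null the
  original model is kept essentially always.
* `df_convention = "nesting"`: $df = 1$ for both tests. This is the
  convention under which the p-values are uniform under the null; the
  package's type-I calibration checks (and the acceptance script's
  rejection-rate computation) therefore use it, asserting an empirical
  rejection rate of test 1 inside the exact binomial 99% interval around
  5% over 1000 replicate null cohorts.

Power, for orientation: test 1's noncentrality is about
$n\,(s/\sigma)^2$ for a planted shift $s$ and noise SD $\sigma$. At
$\sigma = 12$ a cell of $n = 5000$ detects $s = -0.9$ essentially always
under the nesting convention, but only ~70% of the time under the literal
one; the qualitative-pattern checks at $n = 50{,}000$ are powered under
either.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate a UK primary-care second-line
cohort:

* **Ethnicity mix** 78.5 / 14.4 / 4.6 / 2.5% (White / South Asian / Black
  / Mixed+Other, the pooled share split evenly between Mixed and Other).
* **Covariates** are truncated-normal draws (rejection sampling) with
  means/SDs typical of such cohorts: baseline HbA1c 73.5 (14) mmol/mol,
  age 61 (11.5) y, BMI 32.5 (6.5) kg/m², eGFR 91 (17), log-ALT 3.3 (0.5).
  Truncation bounds sit strictly inside the eligibility bounds so that
  eligibility violations arise only from rows planted via
  `ineligible_frac` — distribution tests and filter tests stay separate.
  The truncation at HbA1c 54 is asymmetric and lifts the realized mean by
  ≈2.3 mmol/mol; the suite tests sample means against the closed-form
  truncated-normal expectation.
* **Treatment assignment** is a logistic propensity model: SGLT2i
  initiators are younger with higher HbA1c, BMI and eGFR (confounding by
  indication, ≈37% SGLT2i). Zeroing the coefficients yields randomized
  arms — the configuration used when a test needs an unconfounded truth.
* **Outcomes.** The record nearest the 6-month target equals the truth
  model's prediction for the assigned drug, plus the configured
  (ethnicity group, drug) intercept shift, plus Gaussian noise
  (`noise_sd = 12` mmol/mol — a free parameter chosen to give absolute
  RMSEs in the low teens, the realistic range for 6-month HbA1c). The
  primary record's month is Normal(6.7, 2.8) clipped to the 3–15 month
  window; up to two decoy records per row (one in-window but strictly
  farther from the target, one out-of-window) exist solely to exercise
  window selection.
* **Default shifts** are the miscalibration pattern the framework is
  meant to detect: DPP4i responses under-predicted by 1.6–3 mmol/mol
  (White −1.6, South Asian −2.6, Black −3.0, Mixed/Other −2.6), SGLT2i
  accurate in non-White groups and shifted −0.9 for White.
  `zero_shift_map()` gives the null scenario.
* **Secondary outcomes**: weight change is drawn per drug (SGLT2i mean
  −2.5 kg vs DPP4i −0.3 kg); discontinuation is Bernoulli with a per-drug
  logit including a slope on the row's *true* benefit, so SGLT2i
  discontinuation is highest in DPP4i-favoured patients — a qualitative
  direction, not a calibrated rate.

What the generator does **not** emulate: longitudinal prescription
histories (stable therapy is a flag), missing data beyond a 0.05% missing
IMD quintile, measurement error in covariates, and secular trends.
Passing tests therefore demonstrate the statistical machinery recovers
known truth under clean conditions; they are not evidence about any real
population.

## Cohort construction

`build_cohort()` applies, in order: the strict eligibility bounds
(baseline HbA1c >53 and <120 mmol/mol, eGFR >45, not insulin-treated,
stable therapy), complete-case filtering on the five predictors, then
outcome-window selection. Window endpoints are treated as inclusive
(month 3 and month 15 both qualify); equidistant records resolve to the
earlier month. Ethnicity from multiple recorded codes resolves by
plurality, then most-recent code among tied groups, then alphabetically
with a warning — the last tie-break is arbitrary but deterministic.
Changing the target month from 6 to 12 (the longer-term sensitivity
outcome) re-ranks records inside the same window and provably never
changes cohort membership.

## Decile calibration and its numerical choices

Decile boundaries are type-7 empirical quantiles; a value equal to an
interior cut point falls in the lower decile, so heavy ties collapse
downward (all-identical input lands in decile 1 with a warning). The
within-decile observed arm contrast is OLS of achieved HbA1c on the
SGLT2i indicator, adjusted for baseline HbA1c, current/ever drug-class
counts (categorical — they are counts, not continuous features), outcome
month, eGFR, log-ALT, age and BMI. Continuous covariates use 3-knot RCS
with knots at the within-subset 10/50/90th percentiles, degrading to
linear when knots collide and dropping out when constant (which also
makes the estimate reduce exactly to the raw difference in arm means when
all covariates are constant). Whether the outcome month is splined is a
switch (`spline_month`), since either reading is defensible; IMD quintile
joins the adjustment set only in the sensitivity configuration, and only
complete-IMD rows enter that fit. Confidence intervals are Wald with the
Gaussian 1.96 critical value — these are large-n OLS fits. Per-decile
models are fitted within the decile, not as one interacted global model.

Subgroup boundaries place each endpoint on the stronger-benefit side
(−5 and −3 outward on the SGLT2i side, +3 outward on the DPP4i side; 0
counts as SGLT2i 0–3), making the five labels a partition — the choice is
unit-tested. Mean CIs are t-intervals; discontinuation CIs are Wilson,
which behaves better in small cells than the Wald interval.

## Pipeline guards and problem sizes

`run_validation()` skips a (group, drug) cell below `min_n = 100` rows
for the closed test, and skips a group's decile calibration below 300
rows (ten deciles of thirty, versus ~17–25 adjustment parameters per
decile fit); both guards warn. These are pragmatic estimability
thresholds, not clinical rules.

The package's statistical checks use: 200 replicates × n = 5000
single-cell cohorts per planted-shift recovery; 1000 replicates ×
n = 2000 for type-I calibration; n = 50,000 for the qualitative
shifted-scenario pattern; n = 10,000 randomized cohorts for decile
coverage. These sizes put Monte-Carlo error well below the effects being
recovered (e.g. the recovery SE of a planted shift is
$(12/\sqrt{5000})/\sqrt{200} \approx 0.012$ mmol/mol) while keeping the
whole suite in minutes on one CPU.

## Known limitations

* The stand-in model is synthetic; conclusions about the *published*
  selection model require its actual coefficient file.
* The literal df convention makes the closed test conservative by
  design; users who want nominal type-I behaviour should select
  `df_convention = "nesting"`.
* The generator's outcome model coincides with the model family being
  validated, so model-form misspecification is not exercised; Model 3's
  slope test is checked via planted-slope scenarios instead.
* Observational confounding is handled by covariate adjustment only —
  matching, weighting or doubly robust estimators are out of scope, as is
  re-fitting (revising) the model's coefficients.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(sim = sim_config(n = 50000, seed = 7))
report <- run_validation(cfg)
report$decisions[, c("ethnicity", "drug", "chosen", "a", "p1", "p2")]
plot_calibration(report$calibration)
plot_subgroups(report$subgroups, "discontinuation")
```
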