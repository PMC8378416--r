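---
title: "Modelling stroke outcome and individualized EVT benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stroke outcome and individualized EVT benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtbenefit)
```

## The model

`evtbenefit` is built around one estimator: a cumulative-logit
(proportional-odds) model of the 90-day modified Rankin Scale,

$$\mathrm{logit}\, P(\mathrm{mRS} \le j \mid x) = \alpha_{j+1} + x^\top\beta,
\qquad j = 0,\dots,5,$$

with six strictly increasing cutpoints $\alpha_1 < \dots < \alpha_6$ and a
single coefficient vector shared across all thresholds (the
proportional-odds assumption). We orient the model so that **positive
coefficients mean better outcomes**: the probability of functional
independence is then literally $P(\mathrm{mRS} \le 2)$, the model's primary
prediction target. The linear predictor contains eleven baseline terms
(age, NIHSS, systolic blood pressure, glucose, IV alteplase, diabetes,
prestroke mRS, ASPECTS, occlusion location, collateral grade,
onset-to-groin time, with prior stroke in the original configuration), a
treatment indicator, and treatment interactions with onset-to-groin time
and collateral grade (plus prior stroke in the original configuration), so
the relative treatment effect can decline with time to treatment and rise
with collateral quality. Individualized benefit is

$$b(x) = P(\mathrm{mRS} \le 2 \mid x, \mathrm{evt}=1) -
         P(\mathrm{mRS} \le 2 \mid x, \mathrm{evt}=0),$$

evaluated by forcing the treatment indicator (and its interactions) to 1
and to 0; the patient's recorded treatment is deliberately ignored. Through
the logistic link, $b(x)$ is automatically modified by baseline prognosis —
it vanishes for patients whose baseline risk sits at either extreme and
peaks near $P(\text{good}) \approx 0.5$ — which is why benefit-based
selection differs from risk-based selection.

Fixed codings, chosen where the field leaves them open: occlusion location
enters as two indicators (ICA/ICA-T and M2) against the most common M1
reference; collateral grade and prestroke mRS enter as single linear 0–3
and 0–5 scores in both main effects and interactions; onset-to-groin time
enters linearly in minutes, uncentered. Glucose may enter two ways, because
reported effect estimates in this literature are phrased per 10 mg/dL below
and above 120 mg/dL while the fitting machinery is usually spline-based: a
**piecewise-linear** form $(x, \max(0, x - 120))$ whose two coefficients
are directly interpretable as the slope below the knot and the change in
slope above it (the default), and a **restricted cubic spline** (natural
spline, linear beyond the boundary knots, Harrell's truncated-power
parameterization with nonlinear terms scaled by the squared boundary span)
with default knots at 80/120/180 mg/dL. Both are selectable in
`glucose_term()`; the two shipped presets are `spec_original()` (prior
stroke in, no glucose) and `spec_updated()` (glucose in, prior stroke out).
Coefficient *values* are never baked into a preset: they come from fitting
or are supplied explicitly to the generator.

## Fitting and numerical choices

`fit_mrs_model()` maximizes the multinomial likelihood by Newton–Raphson on
the analytic gradient and observed information of the *mean*
log-likelihood, with step halving; steps that would break the strict
ordering of the cutpoints are rejected and halved, so monotonicity holds by
construction throughout. Starting cutpoints are the empirical cumulative
logits of the outcome (clipped away from 0/1), starting coefficients zero.
Convergence requires the max-norm of the mean log-likelihood gradient to
fall below `tol = 1e-8`; a fit that cannot reach it (separation, flat
likelihood) is returned with `converged = FALSE` **and a warning**, never
silently. The covariance of $(\alpha, \beta)$ is the inverse observed
information at the maximum. Category probabilities are successive
differences of the cumulative inverse-logits, floored at zero against
roundoff; per-observation probabilities are floored at `1e-300` inside the
likelihood so log-likelihoods stay finite under extreme separation.

Model updating follows the standard sequence: likelihood-ratio tests
(`lr_test()`, refusing non-nested specs or differing sample sizes) to add
the glucose term and to drop prior stroke; a refit of the combined cohorts
with a derivation-vs-validation indicator (`refit_with_cohort_adjustment()`,
reference = first cohort label); and intercept-only recalibration
(`recalibrate_intercepts()`), which shifts all six cutpoints by one offset
$\delta$ maximizing the external likelihood with $\beta$ frozen — our
convention is `cutpoints_new = cutpoints + delta`, so a population with
systematically better outcomes yields a positive $\delta$.

## Validation metrics

Discrimination: `c_binary()` is Harrell's C for the functional-independence
prediction (ties count 1/2); `c_ordinal()` ranks patients by a single score
— the model's linear predictor, the standard though rarely spelled-out
choice — and counts, over all pairs with different mRS, how often the
patient with the better mRS has the higher score. Both are computed by a
sort-and-count kernel (O(L² n log n) for L outcome levels) that the test
suite verifies against exhaustive O(n²) enumeration and against
`survival::concordance`. Calibration: the slope is the coefficient of a
logistic regression of the observed binary outcome on the logit of the
predicted probability; the intercept ("calibration-in-the-large") comes
from the same regression with the logit entered as a fixed offset;
predictions at 0/1 are clipped at `1e-8` with a warning.

Confidence intervals use the percentile bootstrap with the model held
fixed (external-validation bootstrap — performance measures are
recomputed on resampled patients, the model is not refitted): with $B$
resamples the 95% interval endpoints are the $\lceil 0.025B\rceil$-th and
$\lfloor 0.975B\rfloor$-th order statistics — exactly the 50th and 1950th
of $B = 2000$. Resamples on which a metric is undefined (e.g. a single
outcome class) are redrawn and counted; more than 5% of $B$ failing aborts
the interval rather than reporting a silently selected one.

## Benefit evaluation

The **c-for-benefit** asks whether the model ranks *benefit* correctly, not
just outcome. Treated and control patients are matched on predicted
benefit: the larger arm is randomly down-sampled (seeded) to the smaller
arm's size, both arms are sorted by predicted benefit and paired rank by
rank — deterministic given the seed, and provably no worse than any random
pairing in within-pair benefit distance; a greedy nearest-neighbour matcher
is available behind a flag for sensitivity analysis. A pair's predicted
benefit is the arithmetic mean of its members'; its observed benefit is the
treated member's good-outcome indicator minus the control's, in
$\{-1, 0, 1\}$. The c-for-benefit is then the concordance between predicted
and observed pair benefit over all pairs-of-pairs with different observed
benefit, ties in predicted benefit counting 1/2 and observed-benefit ties
excluded from numerator and denominator (mirroring the Harrell convention;
all-tied observed benefit is reported as undefined, not as 0.5). Whether to
reuse or drop surplus controls is not settled in this literature;
down-sampling was chosen for determinism and independence of pairs.

Benefit *calibration* groups patients on predicted benefit — quintiles of
the cohort's own distribution, or the three fixed classes with cut points
at exactly 1% and 10% predicted benefit — and compares each group's mean
predicted benefit with the observed arm difference in functional
independence. In an all-treated registry there is no control arm; the
package follows the standard workaround of contrasting successful
(eTICI ≥ 2b) against unsuccessful reperfusion. That output is labelled a
*surrogate* contrast and is never interpreted as causal benefit:
reperfusion is itself an outcome, and no propensity adjustment is
attempted (deliberately out of scope).

## The synthetic generator: what it emulates and what it does not

Real patient-level stroke trial and registry data are not publicly
shareable, so every stage runs on synthetic cohorts with known ground
truth. `cohort_spec()` bundles size, design, covariate laws, the true
model, optional correlation, missingness and seed; `generate_cohort()` is
bit-reproducible given the seed.

* **Covariate laws** (all configurable, all synthetic — none is an estimate
  from patient data): age ~ truncated normal (68 ± 13 y, 18–100); NIHSS ~
  integer truncated normal (16 ± 5); SBP ~ 145 ± 24 mmHg; glucose ~
  log-normal with median 120 mg/dL; IV alteplase 85%; diabetes 15%;
  prestroke mRS mostly 0; ASPECTS skewed toward 8–10; occlusion 25/60/15%
  ICA/M1/M2; collateral grades 7/25/40/28%; onset-to-groin uniform on
  60–390 min (the 6.5-hour treatment window); prior stroke 10%. Covariates
  are independent by default; a Gaussian copula can impose rank correlation
  (used in the tests to make regression imputation meaningfully better than
  mode imputation).
* **True models.** The `"original"` truth has treatment log-odds 0.77 with
  interactions −0.002/min of onset-to-groin and +0.15/collateral grade, a
  null prior-stroke effect, and no glucose effect; the `"updated"` truth
  adds piecewise-linear glucose slopes matching common odds ratios of about
  0.97 per 10 mg/dL below 120 and 0.98 above. Cutpoints were fixed once so
  that, at the default laws, the control arm reaches functional
  independence with probability ≈ 0.25 and the treated arm ≈ 0.38 —
  plausible trial-scale marginals. At these values the median predicted
  benefit sits near 11–12% and external C-statistics near 0.74/0.69,
  i.e. the generator reproduces the *scale* of real-world performance
  without using any patient data.
* **Potential outcomes** under control and treatment are drawn with one
  shared uniform per patient (comonotone coupling), so individual benefit
  is well defined in fixtures and retained (`po_mrs_control/treated`) for
  oracle checks; every marginal statistic depends only on the per-arm
  distributions, which the coupling leaves untouched.
* **Registry mode** treats everyone, draws reperfusion success from a
  logistic model on covariates whose intercept is solved so the realized
  marginal hits `p_reperf` (default 0.7), and draws the observed outcome
  under the treated arm if reperfusion succeeded and under the control arm
  if not. This is an explicit, documented simplification standing in for
  unmodelled procedure failure; it makes reperfusion a valid surrogate in
  the generator by construction.
* **Missingness** is MCAR per field (`inject_missingness()`), with
  outcomes never blanked — cohorts with missing outcomes are excluded, not
  imputed. `impute_cohort()` applies mean/mode imputation for fields ≤ 5%
  missing and deterministic single-regression imputation (linear or
  multinomial-logistic on the complete covariates, no noise draw) above the
  threshold. Multiple imputation is a deliberate scope reduction to keep
  every pipeline stage deterministic.

What the generator does **not** emulate: between-trial clustering,
non-MCAR missingness mechanisms, a realistic joint covariate distribution
beyond the optional copula, perfusion-imaging predictors, or
time-to-event outcomes. Passing tests therefore demonstrate the
*statistical machinery* is correct under the stated laws, not that any
particular coefficient value transfers to real patients.

## The orchestrated study

`run_study()` chains the workflow at synthetic scale: fit the original
configuration on a derivation trial; validate on an independent trial
(report, benefit quintiles, c-for-benefit); LR tests for adding glucose and
dropping prior stroke on the combined trials; cohort-adjusted refit of the
updated configuration; validate on an all-treated registry (the registry's
predictions use the validation cohort's baseline level via the cohort
indicator), with the three-class surrogate benefit table and surrogate
c-for-benefit; optional intercept recalibration. The master seed fans out
to fixed named per-stage offsets, so adding a stage never perturbs earlier
stages and two runs with one seed are bit-identical. All artifacts (cohort
CSVs, model JSONs at 17 significant digits, validation tables, pair
tables, a `study.json` summary) are written so any single stage can be
re-run in isolation.

Problem sizes used by the packaged checks are deliberate: 20,000 patients
for coefficient recovery (every coefficient within 3 estimated SE of
truth), 10,000 for self-calibration of the true model (slope within
1 ± 0.05), 50,000 for benefit-quintile self-consistency (each quintile
within twice the exact Monte-Carlo SE of the observed arm contrast — that
SE includes both the Bernoulli outcome noise and the covariate-split term
$\mathrm{var}(p_1 + p_0)/n$ arising from randomizing a finite group into
arms), 1,000 replicate null trials of n = 2,000 for the type-I error of
the glucose LR test (nominal 5%, accepted within 3–7%), and 2,000 patients
per cohort for end-to-end determinism.

## Known limitations

* The default glucose effect is anchored to the weak reported odds ratios
  (0.97/0.98 per 10 mg/dL); at a few thousand patients an LR test has
  little power against it, so the power-path integration test uses a
  deliberately stronger configured effect. This mirrors the real tension
  between "statistically selected" and "clinically retained" predictors.
* The proportional-odds assumption is imposed, not tested; the generator
  satisfies it by construction, so these tests cannot detect its failure
  in real data.
* The registry surrogate equates reperfusion success with receiving the
  treated potential outcome; real registries have partial reperfusion,
  procedure risk, and confounded reperfusion success.
* Boundary cutpoints are weakly identified when extreme mRS levels are
  rare; the fitter warns when levels are unobserved.

```{r example}
cfg <- study_config(n_derivation = 1000, n_validation = 1000,
                    n_registry = 1000, B = 50, seed = 1)
st <- run_study(cfg)
st
```
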