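---
title: "Modelling kidney-function decline with a misclassification-aware multi-state model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling kidney-function decline with a misclassification-aware multi-state model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdhmm)
```

## The model and its assumptions

`ckdhmm` models chronic kidney disease as a continuous-time Markov chain on
five living eGFR stages — G1/2 (> 60 ml/min/1.73m²), G3a (45–59), G3b
(30–44), G4 (15–29), G5 (< 15) — plus an absorbing death state. G1 and G2
are pooled: above 60 ml/min the eGFR value itself carries little prognostic
signal, and the pooled stage stabilises estimation. Three structural
assumptions define the model class:

1. **Uni-directionality.** True kidney function only deteriorates
   (stage k can move instantaneously only to stage k+1 or to death). Observed
   improvements in eGFR are attributed to misclassification, not recovery.
   This is the model's strongest substantive commitment; it is appropriate
   for chronic decline in an ageing population but deliberately excludes
   acute, reversible kidney injury.
2. **Markov property.** Conditional on the current true stage, age and
   covariates, the past trajectory is uninformative. Patients whose
   function previously declined quickly are not modelled as faster
   progressors beyond what their current state implies.
3. **Conditionally independent misclassification.** Each eGFR test reads a
   category from a row-stochastic emission matrix depending only on the true
   current stage, with support limited to a neighbour band: by default an
   observation can fall at most two stages from the truth (a true G1/2 can
   read G3a or G3b, never G4 or G5; a true G3b can read anything living).
   Death is always recorded correctly, is never emitted by a living stage,
   and is dated exactly.

Transition intensities scale multiplicatively with binary covariates (male
sex, heart failure, cancer, optionally hypertension and diabetes) and with
annually updated age. All progression intensities share one multiplier per
covariate, and all death intensities another — a deliberate economy
(2 parameters per covariate instead of 18) matching how such effects are
reported: e.g. "each year of age multiplies kidney-function transition
probabilities by 1.08 and death transition probabilities by 1.09".

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| baseline intensities `q_prog` (4), `q_death` (5) | /year | preset per cohort | reference profile: woman, 60, no heart failure/cancer |
| `age_mult` (prog, death) | hazard ratio per year of age | 1.08, 1.09 | centred at age 60; the values the model class reports on primary-care data |
| covariate multipliers | hazard ratio | 1 | per-covariate, shared across transitions |
| emission band | stages | 2 | the quoted misclassification rules permit two-stage errors (G1/2 ↔ G3b); a ±1 band would forbid them |
| emission off-diagonals | probability | preset | free parameters in fitting (multinomial logit per row) |
| likelihood `age_update` | — | `interval_start` | standard panel-data convention; `"annual"` splits intervals at integer-age anniversaries and is exact for the simulator's refresh scheme |
| likelihood `init` | — | `"obs"` | true state at the first test taken as observed (standard panel-HMM default); `"emission"` treats the first test as misclassified too, with a prior over living stages |
| `use_censor` | — | `TRUE` | adds the survival factor from last test to the administrative censor time for known-alive patients; without it, exactly observed deaths plus truncation at the last test overstate death rates |

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the statistical structure of primary-care
eGFR panel data: entry ages drawn from published age-band frequencies per
albuminuria stratum, covariate prevalences from the same tables, baseline
stage occupancy from the published eGFR distributions, irregular test times
(exponential renewal with mean gap 1 year by default, or a "doctor's care"
scheme whose gap is keyed to the last observed stage: 12 months at G1/2–G3a
tightening to 3 months at G4–G5), true trajectories simulated with
intensities refreshed at integer age anniversaries, misclassified readings
through the emission matrix, exactly dated deaths, administrative censoring
uniform on 2–9 years of follow-up (an open cohort over a nine-year study
window), and the "at least three eGFR tests" eligibility rule.

Baseline one-year progression probabilities of the four presets sit inside
the ranges this model class produces on UK primary-care data
(unmeasured 0.75–1.3%/yr, normo- 1.5–2.5%, micro- 3.4–5.4%,
macroalbuminuria 3.1–11.9%); the unmeasured preset is anchored to the
quoted reference-profile values (1.1% G1/2→G3a, 0.7% death, 2.9%
misclassification to G3a, G3b transition 1.0%). Death probabilities,
covariate multipliers and the remaining emission entries are stated
assumptions chosen at realistic magnitudes, not published estimates.

The generator does **not** simulate continuous creatinine/eGFR values (the
model is stage-level), correlation between baseline stage and age or
comorbidity (stage, age and covariates are drawn independently),
patient-initiated "self-selection" testing (an informative-observation
mechanism that would bias any panel-data estimator and is out of scope), or
transfer-out processes other than administrative censoring. Passing tests
therefore demonstrate estimator correctness under the model's own
assumptions — not robustness to the ways real primary-care records violate
them.

## Numerical choices

* **Matrix exponential.** Generators are upper triangular, so `exp(tQ)` is
  computed by the Parlett recurrence (exact for triangular matrices with
  separated diagonals) and falls back to scaling-and-squaring with a Taylor
  kernel whenever two total exit rates come within `1e-6` (relative) of each
  other. The fallback never refuses input: non-finite parameter excursions
  during optimisation propagate to an infeasible (−∞) likelihood instead of
  an exception. Both routes are cross-checked in the tests against
  `Matrix::expm` and a truncated series.
* **Gradients.** The score is computed analytically by backpropagation
  through the forward recursion; the derivative of each interval kernel is
  contracted through the adjoint of the Fréchet derivative of the matrix
  exponential (Daleckiĭ–Kreĭn on the triangular fast path, a block
  exponential otherwise). Unit tests verify the full gradient against
  central finite differences in all convention combinations.
* **Optimisation.** BFGS on unconstrained transforms (log rates, log
  multipliers, per-row multinomial logits) from a deterministic crude start:
  observed transition counts over person-time with a half-count floor,
  emission off-diagonals at 0.05. Optional jittered multi-starts are
  available (`n_starts`); the default is a single start — with analytic
  gradients and this start we have not observed distinct local optima, and
  restarts triple the cost of every experiment.
* **Confidence intervals.** Wald intervals from the observed information
  (central finite differences of the analytic gradient), back-transformed;
  emission probabilities use a delta-method standard error mapped through
  the logit so intervals stay inside (0, 1). CIs are only reported when the
  Hessian is positive definite.
* **Ties and degenerate input.** Viterbi ties break toward the less severe
  stage (conservative about disease severity, and deterministic). Zero exit
  rates yield infinite sojourn times, flagged rather than raised. A
  probability-scale age multiplier that would exceed 1 is capped with a
  warning — `apply_age_multiplier()` exists to reproduce the conventional
  probability-scale presentation and is documented as a small-probability
  approximation (within 6% of the exact intensity-scale value for annual
  probabilities ≤ 2%, multipliers ≤ 1.1 and up to 20 years).

## Design decisions that were genuinely open

* **Initial state at the first test.** Panel HMM software must decide what
  the first observation means. Default: it is the truth (`init = "obs"`).
  Alternative (`init = "emission"`): it is misclassified like every other
  test, with a prior that can be uniform, empirical, or user-supplied.
  Truth-known recovery experiments use the second convention with the
  generator's initial distribution, because the generator emits the first
  test through the emission matrix like any other.
* **Age updating.** The simulator refreshes intensities at integer age
  anniversaries; the likelihood default holds covariates at each interval's
  start. The mismatch is quantified in the tests (a few hundredths of a
  log-likelihood unit per test at realistic parameters) and an exact
  annual-splitting likelihood is available; recovery experiments use it so
  that the estimand coincides with the generator.
* **The ≥3-test rule and selection.** Requiring three tests preferentially
  removes patients who die soon after entry, so a fit to the filtered
  cohort targets a survivor-biased estimand — death intensities fitted to
  filtered synthetic data come out roughly half the generating values. The
  generator retains the rule (it is part of the emulated study design), but
  the recovery experiment disables it; readers of real-data results from
  this model class should note the same selection operates there.
* **Monitoring definitions.** The false-positive probability counts *any*
  observed stage change in a patient whose true stage is unchanged; the
  true-positive requires the observed stage to move in the progression
  direction, conditional on true progression to a more severe living stage.
  Both directional variants are returned. Death within the horizon is
  reported separately (monitoring a dead patient is undefined); a flag
  folds it into progression, and only with death included is the
  progression probability guaranteed monotone in the horizon.
* **Calibration conditioning.** Predicted category distributions for each
  held-out test condition on all of that patient's earlier tests (filtered
  forward distribution) and on being alive to be tested; first-test-only
  conditioning is available. Bins default to 1 year.
* **Grading intervals.** Under-/over-grading CIs are Wilson score intervals
  on pooled test counts, ignoring within-patient correlation — matching how
  such tables are usually presented; a patient-level bootstrap is available.

## Problem sizes used in the validation suite

The packaged experiments were sized for a single CPU: oracle equivalence on
200 random records of up to 6 observations (exhaustive enumeration over
210 non-decreasing hidden sequences each); parameter recovery on 20
replicate cohorts of 5,000 simulated patients (31 parameters per fit,
coverage pooled over 620 parameter–replicate pairs); Monte-Carlo
verification of monitoring metrics with 100,000 paths per preset and
baseline stage; calibration self-consistency on a held-out cohort with at
least 20,000 predictable observations.

## Known limitations

* No recovery transitions and no acute-kidney-injury state; the model
  cannot represent transient dips in true function.
* No patient-level random effects: heterogeneity beyond the covariates is
  absorbed into the misclassification and intensity estimates.
* Misclassification probabilities are covariate-independent within a
  cohort.
* The eligibility-filter selection effect described above applies to any
  real cohort assembled with a minimum-test rule.
* Hypertension/diabetes removal follows a CI-based reading ("drop both when
  no multiplier's 95% CI excludes 1") of a qualitative published procedure.
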