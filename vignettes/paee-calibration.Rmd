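---
title: "Calibrating multi-sensor energy-expenditure models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating multi-sensor energy-expenditure models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paeecal)
```

## The problem

Free-living physical activity energy expenditure (PAEE) cannot be measured
directly outside the laboratory; wearable sensors must be calibrated against
a criterion.  For people with traumatic lower-limb amputation the stakes are
higher than usual: gait asymmetries raise the metabolic cost of walking, and
prediction equations built on non-injured adults systematically misestimate
their energy expenditure.  `paeecal` implements the full
calibration-and-validation workflow for this setting:

1. compute criterion PAEE from respiratory gas exchange (indirect
   calorimetry),
2. fit population-specific linear models predicting PAEE from hip-worn
   accelerometer counts (PAC) and heart rate (HR),
3. cross-validate them leaving out one participant at a time, and
4. quantify agreement (Pearson r, SEE, Bland–Altman limits of agreement,
   per-activity error statistics).

Because individual-level data from amputee cohorts are rarely shareable, the
package also ships a synthetic-cohort generator that emulates the published
group-level structure of a three-group treadmill study (unilateral amputees,
n = 9; bilateral amputees, n = 10; non-injured active controls, n = 9), so
the entire pipeline runs — and is tested — end-to-end with no external data.

## Criterion energy expenditure

Total energy expenditure during each stage comes from the abbreviated Weir
equation,

$$\mathrm{TEE}\ (\mathrm{kcal\,min^{-1}}) = 3.941\,\dot{V}O_2 + 1.106\,\dot{V}CO_2,$$

with gas volumes in L·min⁻¹, averaged over the **final 2 minutes** of each
5-minute stage (steady state is reached within 3 minutes; the transient is
discarded).  Protein oxidation is neglected — participants are fasted and
urinary nitrogen is unmeasured — and dietary-induced thermogenesis is treated
as negligible for the same reason.  The coefficient pair is exposed through
`weir_coefficients()` so an alternate variant can be supplied.

Criterion PAEE subtracts resting metabolic rate converted to the same units:
$\mathrm{PAEE} = \mathrm{TEE} - \mathrm{RMR}/1440$.  Negative PAEE values are
*flagged, never clipped*: truncation at zero would bias the mean difference
and shrink the limits of agreement precisely where method disagreement is
informative.

Two derived quantities follow the same per-participant referencing.
RMR-referenced METs, $\mathrm{TEE}/(\mathrm{RMR}/1440)$, equal 1.0 at rest by
construction and reproduce the reference bilateral value at the slowest speed
(4.4) within 1 %; the fixed-convention alternative (3.5 mL O₂·kg⁻¹·min⁻¹) is
available as a switch in `compute_mets()` but is not the default because it
does not reproduce the study tables.  The physiological cost index,

$$\mathrm{PCI} = \frac{\mathrm{HR}_{\mathrm{work}} - \mathrm{HR}_{\mathrm{rest}}}{v\ (\mathrm{m\,min^{-1}})},$$

uses the *pre-set treadmill velocities* rather than self-selected walking
speed.  `pci_table()` reports both the mean of per-subject PCIs (primary) and
the ratio-of-group-means form; with a common pre-set velocity the two
coincide exactly whenever all participants contribute a rest stage, so the
pair mostly serves as a consistency diagnostic against published rounded
tables.

## Calibration and cross-validation

`fit_paee_model()` fits ordinary least squares
$\mathrm{PAEE} = \beta_0 + \beta_1\,\mathrm{PAC} + \beta_2\,\mathrm{HR}$ per
group; an HR-only comparator drops the PAC column but reuses the same
machinery.  Records enter one per completed participant-task, using the
final-2-minute steady-state means.  **Walking tasks only** are used by
default: the published validity statistics are restricted to treadmill
walking, and the shipped reference equations do not pass through the rest
point (the unilateral equation predicts ≈0.29 kcal·min⁻¹ at resting heart
rate, not 0), so constraining the fit through rest would distort the
ambulatory calibration.  `include_rest = TRUE` is available.

Cross-validation leaves out one **participant** per fold, not one
observation: with 7 stage records per subject, observation-level folds would
leak within-subject information and flatter the model.  The term
"bootstrapping" sometimes attached to this procedure in the applied
literature is interpreted here as the leave-one-out resampling itself; a true
participant bootstrap (resampling with replacement, `bootstrap_models()`) is
provided as a separate, optional layer.

Rank deficiency (e.g. constant HR in a fold) raises a singular-fit error
naming the offending column at fit time, and skips the fold with a warning
under cross-validation.

## Agreement statistics

Differences are **predicted − criterion** throughout, so a method that
underestimates shows a negative bias.  Limits of agreement are
$\bar d \pm 1.96\,\mathrm{SD}(d)$ with the sample SD (n − 1); the multiplier
is a visible argument, not a buried constant.  SEE uses denominator
$n - p$ with $p = 3$ for the two-predictor model (intercept counted) and
$p = 2$ for the HR-only comparator.  MAPE excludes pairs with
criterion ≤ 0 — percentage error is undefined at rest where criterion PAEE
is zero by construction; "across all activities" is therefore interpreted as
across walking activities.  MAE ≤ RMSE holds by the power-mean inequality
and is asserted as an invariant in the tests.

The design sample-size computation uses the normal-approximation
paired/one-sample form
$n = \lceil ((z_{1-\alpha/2} + z_{1-\beta})/d)^2 \rceil$, which reproduces
the study's minimum of 8 participants at $d = 1.0$, $\alpha = 0.05$,
power 0.8.  (A paired two-sided form was chosen because it is the only
standard form that yields 8 at these inputs.)

## The synthetic cohort

The generator's defaults *are* the study conditions: group sizes 9/10/9;
group RMR distributions 1776 ± 269, 1596 ± 178 and 1846 ± 191 kcal·day⁻¹;
resting HR 66 ± 11, 67 ± 10 and 54 ± 4 bpm; the 8-stage battery (rest, five
flat speeds 0.48–1.34 m·s⁻¹, 3 % and 5 % gradients at 0.89 m·s⁻¹, 5 min
each); group-by-task target means of PAC, HR, RER and PAEE; per-group-task
completion probabilities equal to the published completer counts divided by
group size (so, e.g., the bilateral group completes the fastest stage with
probability 2/10); and the three published equations as generating models
with residual SDs set to the published SEE values (0.78, 0.96, 0.48
kcal·min⁻¹).

Mechanically, for each completed participant-task:

- Steady-state PAC is the group-task target scaled by the participant's
  *economy factor*, a mean-one lognormal multiplier (sdlog 0.15) shared
  across that participant's tasks — the device that carries between-subject
  correlation in task energy cost.  The mean-one parameterisation
  ($\mu = -\sigma^2/2$) keeps group means on target rather than inflated by
  $e^{\sigma^2/2}$.
- Steady-state HR is the participant's own resting HR plus the
  economy-scaled group HR reserve for the task, so HR variation is anchored
  to individual resting physiology.
- Epoch streams run at 30-s epochs with an exponential approach to steady
  state (time constant 45 s — any value that saturates within 3 min is
  downstream-invisible, since only the final 2 minutes are averaged) and
  independent epoch jitter (25 counts·min⁻¹, 1.5 bpm).
- Criterion PAEE is the generating model evaluated at the **realized**
  final-2-min sensor means plus Gaussian residual noise.  Generating the
  criterion from the realized means (rather than the latent targets) is
  deliberate: it makes the noiseless pipeline recover the generating
  coefficients to machine precision and keeps noisy-parameter recovery free
  of errors-in-variables attenuation, which the package's statistical
  guarantees assert.  The corollary is that simulated group-mean PAEE
  converges to the *model-implied* value at the target PAC/HR, which sits
  within ~7 % of the published PAEE means — the same discrepancy the
  published equations show against their own source table.
- Gas streams are generated noise-free given the realized steady-state TEE,
  by inverting the Weir relation at the group-task RER
  ($\dot{V}O_2 = \mathrm{TEE}/(3.941 + 1.106\,\mathrm{RER})$,
  $\dot{V}CO_2 = \mathrm{RER}\,\dot{V}O_2$).  Criterion noise therefore
  enters exactly once, through the model residual, and the Weir round trip
  is exact by construction.  At rest, PAEE is exactly 0 and PAC exactly 0.
- Task-level realisation noise (PAC 400 counts·min⁻¹, HR 6 bpm) sits on top
  of the economy factor.  These two defaults are the one place the study
  tables gave no direct value; they were fixed once at values giving
  group-level dispersion of the same order as (somewhat below) the published
  SDs, and are not tuned thereafter.
- A residual draw extreme enough to push TEE below 0.05 kcal·min⁻¹
  (≈ −4 SD) is floored there with a warning — a living participant cannot
  expend zero energy, and an exactly-zero V̇O₂ would make RER undefined.

Determinism: one master seed; every participant, dropout draw and
activity derives its own substream seed from (seed, id, task), so a dataset
is a pure function of (configuration, seed), independent of evaluation
order.  Dropout is independent Bernoulli by default; the optional monotone
mode (failing one flat speed fails all faster flat speeds) alters marginal
completion rates downward and is therefore off by default, since the
published table reports counts, not a mechanism.

What the generator does *not* emulate: raw accelerometer waveforms or ECG,
within-task autocorrelation beyond the onset transient, RER drift within a
stage, day-to-day biological variation, and any systematic nonlinearity
between sensors and energy cost.  Passing tests therefore demonstrate that
the *pipeline* is correct and unbiased under the assumed generating
structure — not that the shipped equations are valid in new human data.

## Problem sizes and numerical tolerances

The test suite runs the full 28-participant cohort for end-to-end checks,
200 single-group replicates (9 participants × 8 tasks each) for the
parameter-recovery guarantee (|bias| < 2 Monte-Carlo SE for all three
coefficients), 10⁵ Gaussian draws for limits-of-agreement coverage
(95 % ± 1 %), and machine-precision assertions (≤ 10⁻⁹ relative) for the
noiseless identities: OLS vs explicit normal equations, Weir round trip,
and LOOCV error on noiseless data.  Datasets round-trip through delimited
text at 15 significant digits (~10⁻¹² relative).

## Worked example

```{r, eval = FALSE}
library(paeecal)
ds <- run_simulate(default_config(seed = 42))
report <- run_validate(ds)
report$agreement
run_worked_examples()
```

## Known limitations

- The shipped reference equations are fixtures; the package cannot validate
  them against the original raw data, which are not public.  The
  worked-example checks verify only their internal consistency with the
  published group-mean tables.
- The proprietary multi-sensor device that served as comparator in the
  source study is represented solely as an external prediction column
  (`run_validate(external = ...)`); its branched-model equations are not
  public and are not re-implemented.
- Between-group inference (ANOVA with multiplicity correction) is out of
  scope; the package computes the descriptive ratio bands only.
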