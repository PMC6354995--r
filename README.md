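# paeecal

Calibration and validation of multi-sensor physical activity energy
expenditure (PAEE) prediction models, built for populations with atypical
gait — specifically unilateral and bilateral lower-limb amputees alongside
non-injured controls.

Wrist- and hip-worn devices estimate PAEE from accelerometer counts, but
prediction equations derived in non-injured adults transfer poorly to
people with amputations, whose metabolic cost of walking is substantially
higher.  `paeecal` implements the laboratory workflow used to build and
judge population-specific alternatives:

- **criterion PAEE** from indirect calorimetry via the abbreviated Weir
  equation, `TEE = 3.941·V̇O₂ + 1.106·V̇CO₂` (kcal·min⁻¹), averaged over the
  final 2 min of each 5-min stage, minus per-minute resting metabolic rate;
- **calibration**: ordinary least squares
  `PAEE = β₀ + β₁·PAC + β₂·HR` per group (PAC = accelerometer
  counts·min⁻¹, HR = heart rate in bpm), with an HR-only comparator and
  support for externally supplied prediction columns;
- **leave-one-participant-out cross-validation**, so every reported
  prediction is out-of-sample at the subject level;
- **agreement statistics**: Pearson r/R², standard error of the estimate,
  Bland–Altman bias ± 1.96·SD limits of agreement, and per-activity MAE,
  MAPE, signed error and RMSE;
- supporting physiology: RMR-referenced METs, the physiological cost index
  `PCI = (HR_work − HR_rest) / velocity (m·min⁻¹)`, between-group HR
  ratios, and a paired sample-size computation;
- a **synthetic cohort generator** whose defaults reproduce the published
  group structure of a three-group treadmill study (9/10/9 participants;
  rest + five speeds 0.48–1.34 m·s⁻¹ + two gradients; group-specific
  PAC/HR/PAEE targets, dropout at the faster speeds), so the whole
  pipeline runs end-to-end with no external data.

## Worked example

```r
library(paeecal)

ds <- run_simulate(default_config(seed = 42))
ds
#> Synthetic PAEE dataset: 28 participants, 197 completed participant-tasks,
#> 1970 epochs (seed 42)

report <- run_validate(ds)
report
#> PAEE validation report (seed 42)
#>
#> Agreement:
#>        group  method     r r_squared   see     bias loa_half_width  n
#> 1  bilateral  fitted 0.430     0.185 1.186 -0.02947          2.271 46
#> 2    control  fitted 0.841     0.708 0.529  0.01074          1.019 63
#> 3 unilateral  fitted 0.799     0.639 0.740  0.00512          1.426 60
#> 4  bilateral hr_only 0.326     0.106 1.222 -0.02607          2.367 46
#> 5    control hr_only 0.665     0.442 0.724  0.00483          1.407 63
#> 6 unilateral hr_only 0.797     0.635 0.738 -0.00163          1.435 60
#> 7  bilateral printed 0.536     0.287 1.121 -0.09565          2.140 46
#> 8    control printed 0.859     0.738 0.509 -0.09365          0.964 63
#> 9 unilateral printed 0.781     0.610 0.771 -0.01280          1.484 60

report$models$unilateral
#> PAEE model (unilateral, fitted): PAEE = 0.000136*PAC + 0.058566*HR -2.932055
#>   r = 0.814, R^2 = 0.663, SEE = 0.715 kcal/min, n = 60
```

Reading the table: each `fitted` row is the group's own PAC+HR equation
evaluated strictly out-of-sample (leave-one-participant-out); `hr_only`
drops the accelerometer; `printed` applies the shipped reference equations
directly.  `r` is the correlation between predicted and criterion PAEE,
`see` the residual SD in kcal·min⁻¹, and `bias ± loa_half_width` the
Bland–Altman 95 % limits of agreement.  Near-zero bias for the fitted rows
is expected (cross-validated OLS); the combined-sensor model beats HR alone
in every group.  The bilateral group carries the widest limits — fewer
completed stages (dropout at the faster speeds) and the largest residual
variance, mirroring the reference study.

Embedded reference-table checks (published equations vs their own
group-mean tables, PCI, METs, HR-ratio bands, design sample size):

```r
checks <- run_worked_examples()
all(checks$pass)
#> TRUE
```

A thin command-line wrapper is included:

```sh
Rscript inst/cli.R simulate --seed 1 --out data_dir
Rscript inst/cli.R validate --seed 1 --out report_dir
Rscript inst/cli.R worked-examples   # nonzero exit on any failed check
```

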