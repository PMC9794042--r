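---
title: "Population pharmacokinetics of a weekly LNG/EE transdermal patch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of a weekly LNG/EE transdermal patch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchpk)
```

## The problem

A combined contraceptive transdermal delivery system (TDS) containing 2.6 mg
levonorgestrel (LNG) and 2.3 mg ethinyl estradiol (EE) is worn for one week at
a time, delivering nominally 120 µg/day LNG and 30 µg/day EE. The approved
regimen is three consecutive weekly patches followed by a patch-free week. An
*extended* regimen — 12 consecutive weekly patches (84 days) followed by a
patch-free week — raises the question of whether hormone exposure keeps
accumulating beyond the first cycle. `patchpk` implements the population
pharmacokinetic (popPK) machinery to answer that question by simulation:
structural models for both hormones, population simulation with
interindividual variability (IIV), noncompartmental analysis (NCA) of the
simulated profiles, a synthetic rich-sampling trial generator, and a small
nonlinear mixed-effects estimator so that the model-development step itself is
testable by parameter recovery.

## Structural models

Both hormones use one-compartment disposition (clearance $CL$, volume $V$,
elimination rate constant $k = CL/V$) with *two parallel absorption routes*,
reflecting a patch that both releases drug at a roughly constant rate and
builds a skin depot:

* **EE** — a zero-order infusion into the central compartment for the whole
  wear period ($D_1 = 168$ h, fixed), carrying a fraction $F_{rel}$ of the
  absorbed dose, in parallel with a first-order depot (rate constant $k_a$)
  receiving the remainder as a bolus at application.
* **LNG** — a zero-order infusion into the central compartment for $D_1 =
  168$ h carrying $(1-F_{rel})$ of the absorbed dose, in parallel with a
  zero-order infusion of duration $D_2$ into a depot that drains first-order
  ($k_a$) into the central compartment.

Overall bioavailability is fixed ($F = 0.30$ for EE, $F = 0.27$ for LNG):
$F$ and the route split $F_{rel}$ are not simultaneously identifiable from
patch data alone, so only $F_{rel}$ is estimated. The LNG model additionally
carries multiplicative week-3 effects on $V$ and $CL$, a between-week shift
plausibly related to SHBG induction.

All solutions are closed-form. A running zero-order infusion gives
$C(t) = (R_0/CL)(1-e^{-kt})$; a finite infusion is that response minus the
same response delayed by the duration (superposition). The depot bolus is the
Bateman function, with the analytic limit $A_0 k t e^{-kt}/V$ when
$|k_a - k|/k < 10^{-8}$. The LNG depot infusion is the convolution of the
Bateman kernel with the infusion window, again assembled by superposition of
running responses. Multi-dose profiles superpose all weekly applications with
no state resetting. An independent ODE integration (`ode_oracle()`, `deSolve`
at rtol $10^{-11}$ with mass-balance tracking) verifies the analytic
superposition to $10^{-6}$ relative in the test suite.

**Dose basis.** The model dose is the labeled patch content multiplied by $F$
(so 690 µg/week EE, 702 µg/week LNG reach the circulation at typical values).
A delivered-amount basis (210 / 840 µg per week with $F = 1$) is available via
`default_patch_amount(..., basis = "delivered")`. The labeled-content basis is
a convention, not a claim about absolute absorption; only the product
$F \times \text{dose}$ is identified.

**EE depot input shape.** The EE first-order route receives its dose as a
bolus into the depot at application time. This is the minimal reading of
"first-order absorption from a dosing compartment"; any input shape fast
compared to $1/k_a$ would be indistinguishable.

**Week-effect convention.** The week-3 multipliers persist from week 3
through week 12 (`week_effect_mode = "persist"`, the default; `"week3_only"`
is available). Persistence is the conservative steady-state assumption: with
it, weeks 3 and 12 share one parameter set and differ only through
superposition carry-over, which is what the week-3 ≈ week-12 exposure
comparison is probing. In a profile the switch is applied piecewise in time
(t ≥ 336 h uses the adjusted parameters for the whole superposition), keeping
each analyzed week window internally consistent.

**Units.** Internally hours, litres and nanograms; ng/L is numerically equal
to pg/mL, so concentrations are reported without conversion and window AUCs
are divided by 1000 to give h·ng/mL.

## Population model

IIV is log-normal on $CL$, $V$, $k_a$ and logit-normal on $F_{rel}$ (which
keeps the route split inside $[0,1]$; the transform choice matters little at
the fitted magnitudes). Each drug carries IIV only on its own parameter set —
$V$, $CL$, $k_a$ for EE; $V$, $CL$, $F_{rel}$ for LNG — and `omega` is
diagonal (no covariances are reported for this model family, so none are
modelled). Residual error is proportional by default (additive and combined
are available); it is used only when generating synthetic observations, never
in the extended-regimen simulations, which include IIV but no residual noise.

Randomness uses one master seed with per-subject substreams derived
deterministically, so subject *i*'s parameters do not depend on how many
subjects are simulated or in what order.

## Calibrated default parameters

The fitted parameter estimates behind the published exposure tables are not
available in machine-readable form, so the shipped typical values are
**derived**, not transcribed: `calibrate_population()` tunes the typical
values (and for LNG the depot duration and week-3 multipliers) so that the
simulated geometric-mean NCA summaries of the extended regimen approximate
the published reference summaries (`reference_nca_targets()`: e.g. EE week-1
geometric-mean AUC(0–168) 5.47 h·ng/mL and Cmax 40.8 pg/mL), with a fixed
seed and 400 simulated individuals per objective evaluation, alternating a
typical-value fit with a one-dimensional rescaling of `omega_CL` to the
week-1 AUC geometric CV% (clearance is what drives AUC variability). The
remaining IIV magnitudes (`omega_V` = 0.25, `omega_ka` = 0.3,
`omega_F_rel` = 0.4 on the logit scale) and the 15% proportional residual CV
are fixed, field-typical choices — within the assay's reported 2–16% CV range
and the 30–40% between-subject CVs of the exposure summaries. The calibrated
files under `inst/extdata/` are labelled accordingly: they reproduce exposure
summaries; they are not any study's estimates.

## Synthetic trial generator

`ati_cl14_design()` reproduces the rich cycle-2 sampling design used for
model development: 18 subjects, samples at pre-dose and 6, 12, 24, 48, 72,
120, 144, 168 h after the week-1 and week-3 applications, plus 174, 180, 192,
216, 240 h after the third application — 23 samples per subject, 414 records
per drug. Assay lower limits of quantification are 2 pg/mL (EE) and 50 pg/mL
(LNG); observations below the limit are flagged BLQ and censored. The
pre-dose sample is the running-superposition trough at the instant before
application (so the week-1 pre-dose is identically zero and always BLQ).
These offsets yield 23 distinct times, so no deduplication at window joins is
needed. `generate_trial()` adds residual error per the population model's
`sigma` and refuses to generate "observed" data without noise unless
explicitly asked. Output is a long CSV; a NONMEM-style event dataset writer
(`ID`/`TIME`/`AMT`/`RATE`/`CMT`/`DV`/`EVID`/`MDV`/`BLQ`) is provided for
interoperability.

What the generator does *not* emulate: assay runs and batch effects, dropout
and adherence, the oral-contraceptive comparator arm, or between-cycle
physiological drift (SHBG dynamics). Passing recovery tests on these
synthetic trials therefore demonstrates internal consistency of the
estimation machinery under the stated error model, not robustness to the
misspecifications real data would carry.

## Estimation

Two estimators share the fixed constraints ($F$ fixed per drug, $D_1 = 168$
h; BLQ records dropped by default, with LLOQ/2 substitution as an option):

* `fit_two_stage()` — per-subject weighted least squares (proportional
  weights) on log/logit-transformed parameters, then pooling:
  back-transformed means for typical values, transformed-scale sample SDs for
  `omega`, pooled RMS proportional residual for `sigma`. Fast, and a good
  initializer.
* `fit_laplace()` — maximizes the Laplace-approximated marginal likelihood:
  for each subject the joint negative log-density $g(\eta)$ is minimized over
  the 3-dimensional random effect by a damped Newton iteration with central
  finite differences (compiled; warm-started across outer iterations), and
  the marginal contribution is $-2\log L_i \approx 2g(\hat\eta_i) -
  d\log 2\pi + \log|H_i|$ with $H_i$ the finite-difference Hessian at the
  mode. The outer problem runs bounded quasi-Newton (`nlminb`) on transformed
  fixed effects, log IIV SDs and the log residual SD (relative tolerance
  $10^{-6}$); RSEs come from the observed information of the outer objective
  by the delta method. Degenerate directions (an `omega` driven to its lower
  bound) are reported with `NA` RSEs rather than a spurious number.

Diagnostics mirror standard popPK qualification: `gof_diagnostics()` returns
population and individual predictions, individual weighted residuals and
FO-linearized conditional weighted residuals as a tidy table;
`vpc()` simulates replicate trials at the observed design and returns
5th/50th/95th percentile bands (median and 90% band across replicates) next
to the observed percentiles.

The recovery study in the test suite — 20 replicate synthetic EE trials of 50
subjects at the rich design with 15% proportional error — recovers the
typical values with median relative bias within 10% and the IIV SDs within
±50%, which is the qualification bar for using the estimator as a
model-development stand-in. The EE model is used because its absorption
parameter ($k_a$) is the harder of the two drugs' third parameters to
identify; 50 subjects and 20 replicates keep the full suite to a few minutes
on one CPU.

## Noncompartmental analysis

Per simulated individual and week window (week $w$ spans $[(w-1)\cdot168,\,
w\cdot168]$ h inclusive, hourly grid, 169 points):

* **AUC(0–168)** by the linear-up/log-down trapezoid: linear on rising, flat
  or non-positive segments; $\,(C_1-C_2)\Delta t/\ln(C_1/C_2)$ on strictly
  decreasing positive segments. The log rule is exact on monoexponential
  decay regardless of grid spacing (asserted to $10^{-12}$ in the tests);
  equal consecutive concentrations use the linear rule (the log rule is 0/0).
* **Cmax / Tmax** — grid argmax, earliest tie; Tmax reported as elapsed time
  within the window. Tmax summary cells are marked "NC" (not calculated), the
  convention for simulated fixed-grid profiles.
* **Css(0–168)** = AUC(0–168)/168; **Css(48–168)** divides the $[48,168]$
  partial AUC by 120.
* **Accumulation ratios** AR AUC and AR Cmax: the subject's week-3 or
  week-12 value over the same subject's week-1 value, computed per subject
  and then summarized. For geometric means this is exactly the ratio of the
  weekly geometric means — an algebraic identity the suite asserts to
  $10^{-12}$.

Summaries report n, arithmetic mean, SD, CV%, geometric mean and geometric
CV% ($100\sqrt{e^{s^2}-1}$, $s$ the SD of natural logs), rounded to 3
significant figures at the reporting boundary only.

## Steady-state behaviour and a boundary caveat

With weekly dosing and a single governing exponential of half-life $\le 40$
h, the superposition closed form puts the week-12 vs week-3 AUC difference
below 0.1% (at exactly 40 h it is 0.096%). That bound does **not** extend to
every dual-route parameterization: when absorption and elimination are *both*
slow (half-lives near 40 h), the series kinetics produce a
$t e^{-kt}$-type approach to steady state that equilibrates more slowly than
its terminal slope suggests, and measured differences reach 0.10–0.15% at
typical values — and 0.2% (EE) to 0.9% (LNG) for full simulated populations,
where the IIV tail contributes individuals with slower kinetics. The test
suite therefore asserts the 0.1% bound in the regime where the closed form
yields it, and asserts the population-level statement at the magnitudes the
simulations actually produce (week 12 exceeds week 3 by well under 1%):
steady state by week 3, no notable further accumulation through week 12.

## Numerical choices

* Analytic kernels switch to series limits when $|k_a-k|/k < 10^{-8}$.
* The ODE oracle integrates segment-by-segment between input
  discontinuities (rtol $10^{-11}$, atol scaled to total input mass) so no
  event is stepped over.
* Inner Laplace Newton: convergence when the gradient norm falls below
  $10^{-8}$ or the step improves the objective by less than $10^{-10}$;
  Levenberg damping when the Hessian is not positive definite; if the final
  numerical Hessian degenerates, the prior curvature $\Omega^{-1}$ bounds the
  determinant.
* Outer optimizer bounds: log-omega in $[\log 10^{-3}, \log 3]$, log-sigma in
  $[\log 10^{-3}, \log 2]$, logit-$F_{rel}$ in $[-12, 12]$.
* Two runs with the same seed and configuration produce byte-identical
  machine-readable outputs; simulation output is invariant to subject
  ordering.

## Problem sizes

Defaults follow the simulation design: 1000 individuals, hourly grids,
weeks 1, 3 and 12. The test suite scales down where the property does not
need the full size (15–200 individuals for shape and invariance checks; 50
subjects × 20 replicates for recovery; 400 individuals per calibration
objective evaluation), sizes chosen so each property is tested at meaningful
resolution.

## Known limitations

* One-compartment disposition only; no enterohepatic recirculation, SHBG
  binding dynamics or dermal-depot physiology.
* No covariate machinery (the source data were too small for covariate
  analysis; BMI/weight effects are out of scope).
* The Laplace estimator is a compact qualification tool, not a drop-in for
  commercial estimators; exact FOCE-I equivalence is not claimed, and
  bootstrap confidence intervals are not provided.
* Calibrated defaults reproduce exposure *summaries*; individual-level
  features (e.g. the exact Tmax distribution) are constrained only weakly by
  those targets.

## A worked example

```{r example, eval = FALSE}
pop <- default_population("EE")
reg <- weekly_regimen(n_weeks = 12, drug = "EE")
sim <- simulate_population(pop, reg, weeks = c(1, 3, 12), n = 1000,
                           seed = 20221227)
nca <- nca_by_week(sim, weeks = c(1, 3, 12))
format_summary_table(nca$summary)
```

The same pipeline, config-driven and with all report tables written to disk,
is `run_extended_regimen(run_config(...))`, or `patchpk simulate --config
config.yaml --out results/` from the shell (see `inst/exec/patchpk`).
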