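# patchpk

Population pharmacokinetics of a weekly combined contraceptive transdermal
patch (levonorgestrel 2.6 mg / ethinyl estradiol 2.3 mg per patch, delivering
nominally LNG 120 µg/day and EE 30 µg/day), built to answer a regimen
question by simulation: if the patch is worn for **12 consecutive weeks**
(84 days) instead of the approved 3-weeks-on / 1-week-off cycle, do hormone
exposures keep accumulating, or is steady state reached early?

The package is aimed at pharmacometricians and clinical pharmacologists who
want a fully reproducible, testable version of that workflow: structural
models → population simulation → noncompartmental analysis → report tables,
plus the machinery to qualify the model-development step itself (synthetic
trial generation and mixed-effects estimation with goodness-of-fit and VPC
diagnostics).

## The models

Both hormones use one-compartment disposition (CL, V, k = CL/V) with two
parallel absorption routes:

* **EE** — zero-order infusion into the central compartment for the whole
  168-h wear period (fraction F_rel of the absorbed dose) in parallel with a
  first-order depot (rate constant ka) receiving the remainder;
  overall bioavailability fixed at F = 0.30.
* **LNG** — zero-order infusion into the central compartment for 168 h
  (fraction 1 − F_rel) in parallel with a zero-order infusion of duration D2
  into a first-order depot (fraction F_rel); F fixed at 0.27, plus
  multiplicative week-3 effects on V and CL.

F is fixed because F and F_rel are not jointly identifiable from patch data.
All profiles are closed-form superpositions over the weekly applications
(infusion step responses and the Bateman function); an independent ODE
integration (`ode_oracle()`) verifies them to 1e-6 relative. Interindividual
variability is log-normal (logit-normal for F_rel) on each drug's own IIV
set. Weekly NCA uses the linear-up/log-down trapezoid (exact on
monoexponential decay), Css = AUC(0–168)/168, and per-subject accumulation
ratios against week 1.

The shipped typical values (`inst/extdata/*_population.yaml`) are **derived
calibration output**: `calibrate_population()` tunes them so the simulated
geometric-mean exposure summaries match published reference summaries for
this product. They are not transcribed study estimates (those are not
publicly machine-readable).

## Worked example

Simulate 1000 individuals over the 12-week extended regimen and summarize
weekly exposure:

```r
library(patchpk)
pop <- default_population("EE")
reg <- weekly_regimen(n_weeks = 12, drug = "EE")
sim <- simulate_population(pop, reg, weeks = c(1, 3, 12), n = 1000,
                           seed = 20221227)
nca <- nca_by_week(sim, weeks = c(1, 3, 12))
out <- format_summary_table(nca$summary)
out[out$statistic %in% c("geo_mean", "geo_cv_pct"), ]
```

```
 week  statistic cmax tmax auc_0_168 css_0_168 css_48_168 ar_cmax ar_auc
    1   geo_mean 41.3   NC      5.55      33.1       34.3      NC     NC
    1 geo_cv_pct 27.7   NC        30        30       34.4      NC     NC
    3   geo_mean 48.6   NC      6.54      38.9       36.5    1.18   1.18
    3 geo_cv_pct 31.3   NC      35.7      35.7       38.4    5.34   7.87
   12   geo_mean 48.6   NC      6.54      38.9       36.5    1.18   1.18
   12 geo_cv_pct 31.3   NC      35.8      35.8       38.5    5.42   7.96
```

Reading it: geometric-mean EE Cmax rises from 41.3 pg/mL in week 1 to
48.6 pg/mL in week 3 — an accumulation ratio of 1.18 — and is unchanged at
week 12. AUC(0–168) behaves the same way (6.54 h·ng/mL at weeks 3 and 12),
i.e. steady state is reached by week 3 with no further accumulation over the
extended regimen. Tmax is marked NC (not calculated), the convention for
simulated fixed-grid profiles.

The config-driven equivalent, which writes per-subject NCA, summary tables,
mean-profile overlays, AUC box-plot data and a run manifest:

```r
run_extended_regimen(run_config(NULL, out_dir = "results", seed = 20221227))
```

or from the shell via the thin CLI (`inst/exec/patchpk`): subcommands
`simulate`, `nca`, `gen-trial`, `fit`, `vpc`, `calibrate`.

Model qualification tools: `ati_cl14_design()` + `generate_trial()` emulate
the 18-subject rich-sampling cycle-2 design (23 samples/subject, LLOQ 2 and
50 pg/mL); `fit_two_stage()` and `fit_laplace()` estimate the population
model back from such data; `gof_diagnostics()` and `vpc()` produce the
standard diagnostics. See the methods vignette
(`vignettes/patchpk-methods.Rmd`) for the models, assumptions, numerical
choices and limitations.

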