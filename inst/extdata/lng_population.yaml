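# LNG population model — DERIVED calibration output (calibrate_population()),
# not transcribed study estimates. Typical values tuned so the simulated
# extended-regimen geometric-mean NCA summaries approximate the published
# reference summaries; omega_CL matched to the week-1 AUC geometric CV%.
# ka sits at the calibration's physiological upper bound (2/h): the summary
# targets do not identify the depot absorption rate once its route fraction
# is small and fast.
drug: LNG
theta:
  CL: 2.5878929
  V: 129.2126627
  ka: 2.0
  F_total: 0.27
  F_rel: 0.1317496
  D1: 168.0
  D2: 25.0950304
  wk3_V_mult: 1.0236296
  wk3_CL_mult: 0.8149881
omega:
  CL: 0.4319137
  V: 0.25
  ka: 0.0
  F_rel: 0.4
sigma:
  kind: proportional
  prop: 0.15
  add: 0.0
week_effect_mode: persist
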