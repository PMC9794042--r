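# EE population model — DERIVED calibration output (calibrate_population()),
# not transcribed study estimates. Typical values tuned so the simulated
# extended-regimen geometric-mean NCA summaries approximate the published
# reference summaries; omega_CL matched to the week-1 AUC geometric CV%.
drug: EE
theta:
  CL: 105.734062
  V: 2733.1881722
  ka: 0.018098
  F_total: 0.3
  F_rel: 0.6621418
  D1: 168.0
  D2: 0.0
  wk3_V_mult: 1.0
  wk3_CL_mult: 1.0
omega:
  CL: 0.3451061
  V: 0.25
  ka: 0.3
  F_rel: 0.0
sigma:
  kind: proportional
  prop: 0.15
  add: 0.0
week_effect_mode: persist
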