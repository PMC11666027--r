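# Default end-to-end pipeline configuration for run_pipeline().
# Mirrors the package's reference operating conditions: full factorial
# synthetic stability study, four-rung model ladder with parametric
# bootstrap, and a 1000-subject Monte Carlo PTA grid (3 daily doses x 4
# bottle-renewal intervals x 3 temperatures x 2 elevated MICs x 4
# renal-function groups). The full grid is compute-intensive (order of an
# hour on one core); trim `pta.n` or the factor lists for exploration.
seed: 20240101
stability:
  synthetic:
    brands: [A, E, I, Q, R, V, X]
    temperatures: [25, 30, 37]
    concentrations: [1, 2]
    times: [0, 1, 2, 3, 4, 5, 6, 7, 8]
    missing_rate: 0.0387
models: [1, 2, 3, 4]
final_model: 3
bootstrap:
  n_iter: 500
  sample_size: 365
cmin_ratio:
  renewal_h: [3, 6, 8]
  dose_mg: 1000
profiles:
  dose_mg: 1000
  renewal_h: 8
  horizon_h: 48
pta:
  daily_doses_g: [3, 4.5, 6]
  renewal_h: [3, 4, 6, 8]
  temperatures: [25, 30, 37]
  concentration: 1
  mics: [8, 16]
  clcr_groups: [50, 90, 130, 150]
  n: 1000
  target_fraction: 0.98
  include_no_degradation: true
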