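# meropta

Meropenem is an unstable drug in solution: once a bottle is reconstituted it
starts to hydrolyse, and the warmer and more concentrated the solution, the
faster the loss. That matters clinically because the most effective way to
dose meropenem against poorly susceptible Gram-negative pathogens is
*continuous infusion* (CI) — which leaves the solution hanging at room
temperature for hours. `meropta` is an R package for quantifying this
trade-off end to end: it estimates first-order in-bottle degradation kinetics
from stability experiments with linear mixed-effects models, then propagates
the estimated rate constant into a two-compartment population-PK Monte Carlo
simulation to ask the question intensivists and pharmacists actually care
about: **how much probability of target attainment (PTA) does degradation
cost, and does earlier bottle renewal or a higher dose buy it back?**

It is aimed at pharmacometricians and hospital-pharmacy researchers studying
prolonged beta-lactam infusion, particularly in warm climates where ambient
ward temperatures reach 30–37 °C.

## The model

**Stage 1 — degradation kinetics.** Concentration ratios C/C0 from a
factorial stability study (7 brands × 25/30/37 °C × 1 or 2 g/48 mL × 0–8 h;
378 design points on 42 bottle runs) follow first-order kinetics on the
natural-log scale:

```
log(C/C0) = mu + theta_i − (beta0 + beta1[T] + beta2[Cinfu] + beta3[B])·t + eta_i·t + eps
```

where `beta0` is the degradation rate constant k_deg (h⁻¹) at the reference
condition (25 °C, 1 g/48 mL), `beta1`/`beta2`/`beta3` are slope increments
for temperature, infusion concentration and brand, `theta_i`/`eta_i` are a
random intercept and slope for bottle run *i*, and `eps` is residual error.
The model ladder (time only → +temperature → +concentration → +brand) is
fitted by maximum likelihood with `lme4` and compared by likelihood-ratio
tests; uncertainty comes from a parametric bootstrap, and per-run conditional
modes give brand-level degradation summaries. A synthetic-data generator
(`simulate_stability()`) reproduces the full design so the whole pipeline is
testable without laboratory data.

**Stage 2 — PK/PD consequences.** The fitted k_deg enters the infusion term
of a two-compartment population-PK model:

```
dAc/dt = Dose·e^(−kdeg·t)/Tinf − Ac·(Cl/Vc + Q/Vc) + Ap·Q/Vp   (t ≤ Tinf)
dAp/dt = Ac·Q/Vc − Ap·Q/Vp
```

with the bottle clock resetting at each renewal. Monte Carlo populations with
log-normal inter-individual (Cl 27.1%, Vc 31.5%, Vp 16.9%) and inter-occasion
(Cl 12.5%) variability, and creatinine clearance driving clearance through a
power model, yield day-one PTA for the 98% fT>MIC target across dose ×
renewal-interval × temperature × MIC × renal-function scenarios. The shipped
popPK configuration (`inst/extdata/poppk-meropenem-synthetic.yaml`) carries
clearly labelled synthetic stand-in typical values; swap in your model of
record for clinical work.

## Worked example

```r
library(meropta)

# a realistic synthetic stability study (fixed seed, ~4% sample loss)
x <- simulate_stability(stability_design(), seed = 1)   # 362 usable rows
fit <- fit_degradation(x, covariate_set = 3)
fit
#> Mixed-effects degradation fit (covariate set 3, ML, n = 362, units = 42)
#>   beta0 (reference kdeg, 1/h): 0.00753
#>   temperature increments: 25=0.00000, 30=0.00507, 37=0.01958
#>   concentration increments: 1=0.00000, 2=0.00488
#>   omega1=0.00175 omega2=0.00095 sigma=0.00953
#>   logLik 1139.5  AIC -2261.1  BIC -2226.1  [singular fit]

k <- kdeg_for_condition(fit, temperature = 37, concentration = 2)  # 0.032 1/h
remaining_fraction(k, t = 8)                                       # 0.774
```

So at 37 °C and 2 g/48 mL, only ~77% of the nominal dose is still intact when
an 8 h bottle runs out. What does that do to exposure and target attainment?

```r
poppk <- read_poppk_config()
typ <- apply_covariates(poppk, poppk$reference[c("clcr", "weight", "albumin")])
steady_state_cmin_ratio(ci_regimen(1000, renewal_h = 8), k, typ)   # 0.819

subj <- sample_subjects(poppk, 200, seed = 2, clcr = 80.8)
compute_pta(subj, ci_regimen(1000, renewal_h = 8), kdeg = k, mic = c(2, 4, 8, 16))
#>   mic_mg_L   n n_attained   pta    ci_lo  ci_hi
#> 1        2 200        200 1.000 0.981725 1.0000
#> 2        4 200        199 0.995 0.972458 0.9999
#> 3        8 200         94 0.470 0.399233 0.5417
#> 4       16 200          1 0.005 0.000127 0.0275
```

The steady-state trough dips 18% below the no-degradation level at the worst
storage condition, yet PTA stays at 100% for susceptible pathogens (MIC ≤ 2
mg/L); the degradation penalty only bites at elevated MICs, where dose
escalation (`pta_scenario_grid()`) shows what is needed to restore the 90%
threshold. `run_pipeline()` drives the whole chain from a YAML config and
writes every table as CSV plus a JSON manifest; `render_reports()` turns the
tables into the standard decay-curve, profile, PTA-vs-MIC, PTA-vs-Clcr and
banded dose-grid figures.

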