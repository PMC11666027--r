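---
title: "Methods: from in-bottle meropenem degradation to infusion target attainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from in-bottle meropenem degradation to infusion target attainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meropta)
```

`meropta` chains two models: a linear mixed-effects description of
first-order meropenem degradation in the infusion bottle, and a
two-compartment population-PK Monte Carlo simulation in which the degrading
bottle is the drug input. This vignette records the assumptions, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
data generator can and cannot tell you about real data.

## 1. The degradation model

Concentration ratios \(C/C_0\) measured on a bottle over time follow
first-order kinetics, so on the natural-log scale

\[
\log(C/C_0)_{ij} = \mu + \theta_i
  - \big(\beta_0 + \beta_1[T_i] + \beta_2[C_{infu,i}] + \beta_3[B_i]\big)\,t_{ij}
  + \eta_i\,t_{ij} + \varepsilon_{ij},
\]

with unit \(i\) one prepared bottle run (one brand x temperature x
concentration combination; the full design has 42 such units observed at 9
time points), \(\theta_i \sim N(0, \omega_1^2)\) a run-level intercept,
\(\eta_i \sim N(0, \omega_2^2)\) a run-level slope deviation, and
\(\varepsilon \sim N(0, \sigma^2)\) residual assay error. The natural log is
deliberate: the slope is then a degradation rate *constant* in h\(^{-1}\) and
the remaining fraction is \(e^{-k_{deg} t}\), which is also the form the PK
input term uses. All covariates act multiplicatively on time, i.e. on the
rate, never as main effects — temperature does not shift the ratio at
\(t = 0\), it accelerates the decay.

Temperature (25/30/37 °C) and infusion concentration (1 or 2 g/48 mL) are
unordered categorical factors with the mildest level as reference. An
Arrhenius-type continuous temperature term would extrapolate; the categorical
form reports exactly what was studied and `kdeg_for_condition()` refuses
levels outside the fitted space.

**Estimation.** The ladder (`covariate_set` 1–4: time only, +temperature,
+concentration, +brand) is fitted by **maximum likelihood**, not REML,
because the rungs differ in fixed effects: only ML deviances support the
likelihood-ratio tests and information criteria that drive model selection.
The random intercept and slope are allowed to correlate (`re_correlation =
TRUE`), giving parameter counts of 6/8/9/15 along the ladder; an uncorrelated
variant is available. Wald p-values accompany the coefficient table
(`estimates_table()`); with 300+ observations they are near-identical to
Satterthwaite results.

**Uncertainty.** `bootstrap_intervals()` implements a parametric bootstrap:
simulate a new response vector from the fitted model (fresh random effects
and residuals on the observed design), take a without-replacement subsample,
refit, and read percentile intervals off the successful refits. The default
is 500 iterations with the full observed row count as subsample size; both
are configurable upward (a production analysis would use several thousand).
Refits that error or fail to converge are dropped and counted, never imputed.

**Conditional modes.** Run-level degradation summaries come from the BLUPs
\(\hat\theta_i, \hat\eta_i\); the run-specific rate constant is the
fixed-effect rate minus \(\hat\eta_i\). As \(\omega_2 \to 0\) these shrink to
zero, which the test suite checks.

## 2. The synthetic stability generator

`simulate_stability()` forward-simulates the model above on any
`stability_design()`. Its defaults are the study conditions the package is
built around:

* the full factorial design: 7 brands, 25/30/37 °C, 1 and 2 g/48 mL, hourly
  samples 0–8 h — 378 points on 42 units;
* fixed effects and variance components from `degradation_truth()`
  (reference rate 0.0086 h\(^{-1}\); increments +0.0045 at 30 °C, +0.0185 at
  37 °C, +0.0042 at 2 g/48 mL; \(\omega_1 = 0.0064\), \(\omega_2 = 0.0015\),
  \(\sigma = 0.0101\); brand increments zero, since brand was not a
  significant covariate — simulating non-zero `beta3` is supported for power
  studies of the brand test);
* missing-completely-at-random loss of non-zero-time points at rate 13/336,
  reproducing the ~13 lost samples of a realistic campaign of this size.

Two conventions deserve comment. First, the 0 h sample *defines* \(C_0\), so
by construction its ratio is exactly 1; the generator therefore emits time-0
ratios as 1 and applies residual noise only at \(t > 0\). Second, for
parameter-recovery experiments this convention is deliberately switched off
(`noise_at_zero = TRUE`) so that simulated data and fitted model share one
likelihood — recovery of \(\sigma\) is only a well-posed question when the 42
time-zero rows are not noise-free by fiat. The acceptance script uses this
switch; the default emulation of a real campaign does not.

What the generator does *not* emulate: HPLC peak areas, calibration-curve
error, assay drift between days, non-MCAR sample loss, or any departure from
log-linear decay (e.g. pH drift late in the run). Passing tests therefore
demonstrate that the *pipeline* recovers the truth under the stated model,
not that the model is an exhaustive description of bench data.

A numerical note on model selection: with 42 units and between-unit slope
covariates, the \(\chi^2\) reference for the LRT is conservative in the tail
(empirical size at the 5% level is below nominal; a Kenward-Roger-style F
reference would be sharper). The ladder therefore errs toward *not* adding
covariates, which is the safe direction for this analysis.

## 3. The infusion/PK model

The drug input is the paper-and-pencil consequence of first-order loss in the
bottle: a bottle hung at event start \(s\) delivers
\(\text{rate}(t) = (Dose/T_{inf})\,e^{-k_{deg}(t-s)}\) while it runs. Key
semantics, all encoded in `build_infusion_schedule()`:

* **Bottle clock.** In continuous infusion with renewal, every new bottle is
  freshly prepared: the decay exponent resets at each renewal. A
  `renew_clock = FALSE` mode keeps one clock for the never-renewed
  comparison.
* **Loading dose.** 500 mg over 30 min by default, also subject to
  degradation (negligible over 30 min, but consistent; `degrade_loading =
  FALSE` switches it off). Maintenance dosing starts when the loading
  infusion ends.
* **Delivered fraction.** Integrating the input rate gives
  \((1 - e^{-k T_{inf}})/(k T_{inf})\) of the nominal dose actually reaching
  the patient per bottle (`delivered_fraction()`), continuously extended to 1
  at \(k = 0\) and cross-checked against quadrature in the tests.
* Infusion concentration (1 vs 2 g/48 mL) enters **only** through the
  selected \(k_{deg}\); bag volume is not modelled hemodynamically.

Disposition is the standard two-compartment linear model (amounts
\(A_c, A_p\); parameters \(Cl, V_c, V_p, Q\)), integrated with
`deSolve::lsoda` at rtol 1e-8/atol 1e-10. Integration **restarts at every
event and occasion boundary**, so the discontinuous forcing is never smoothed
across a renewal; a cumulative-elimination state rides along for mass-balance
checks. An independent fixed-step RK4 integrator in the test helpers verifies
agreement to below 0.1%.

Steady state for the trough ratio \(C_{min}/C_{no\text{-}deg}\) is
operationalised as: simulate at least ten terminal half-lives of maintenance
cycles, then stop when consecutive within-cycle minima differ by less than
0.1%. The no-degradation reference is the closed form
\(C_{no\text{-}deg} = \text{rate}/Cl\). The ratio is bounded between
\(e^{-k\tau}\) (instantaneous tracking) and the delivered fraction (perfect
buffering); where a patient sits between those bounds depends on the
disposition time constants, which is why the trough penalty is a PK question
and not just a chemistry one.

**Population parameters.** The typical values and covariate model live in a
YAML file, because they are *configuration*: the shipped
`poppk-meropenem-synthetic.yaml` provides literature-informed synthetic
stand-ins for a critically ill adult population (Cl 12 L/h at creatinine
clearance 80.8 mL/min scaling as \((Clcr/80.8)^{0.62}\); Vc 10.8 L scaling
with weight/70; Vp 12.6 L; Q 18.6 L/h; reference covariates Clcr 80.8
mL/min, 70 kg, albumin 2.8 g/dL; albumin is carried but inert in the default
form). These are plausible for meropenem — with them the steady-state trough
penalty at 8 h renewal spans ~5–18% across the studied storage conditions —
but they are not a published model fit; any conclusion that depends on them
should be re-run with the user's model of record. All PK-dependent checks in
the test suite are conditional on this file in exactly this sense.

## 4. Monte Carlo PTA

`sample_subjects()` draws Cl, Vc, Vp log-normally around the
covariate-adjusted typical values. The reported CVs (27.1/31.5/16.9%, IOV
12.5% on Cl) are interpreted with the **exact** convention
\(\omega = \sqrt{\log(1 + CV^2)}\) and median parameterization (typical value
= median); the common \(\omega \approx CV\) approximation is selectable since
reported %CVs rarely state their convention. One IOV occasion is one dosing
interval, multiplier resampled per occasion and applied to Cl. Creatinine
clearance is uniform on 30–160 mL/min by default — bracketing the 5th–95th
percentile range typical of ICU cohorts — or fixed per group for
renal-function-stratified runs; augmented renal clearance is a reporting
label (Clcr > 130), never a model switch.

The target is **98% fT>MIC on day one** (window 0–24 h from the start of the
loading dose): the 2% allowance is exactly the first 30 min of the loading
ramp, during which no regimen can be above the MIC. `fraction_time_above_mic()`
locates threshold crossings by linear interpolation between grid points
(grid 0.05 h by default) rather than counting grid samples, so the 98%
threshold is not quantized by the grid. Concentrations are compared to the
MIC as total drug (`free_fraction = 1`), configurable for protein-binding
scenarios; a 4xMIC analysis is a MIC multiplier away.

`compute_pta()` simulates each subject once per regimen/condition and
evaluates **all MICs on the shared profiles**; `pta_scenario_grid()`
additionally reuses the same subjects (same seed) across doses, renewal
intervals and storage conditions. Every monotonicity statement in the test
suite (PTA falls with MIC, with \(k_{deg}\), with Clcr; rises with dose) is
therefore a common-random-numbers comparison, free of Monte Carlo sign
noise. Binomial uncertainty is reported as exact Clopper-Pearson intervals.

The production population size is 1000 subjects per scenario, the
conventional size at which binomial noise (\(\approx 1.6\%\) at PTA 50%) is
small against the 90% decision threshold. The routine test suite uses
scaled-down sizes chosen as the package's own testing design — 200 subjects
for monotonicity suites, 1000 where a point value is asserted, 200 refits in
the parameter-recovery experiment — with tolerances widened to the
corresponding Monte Carlo error.

## 5. Degenerate inputs, ties, and guard rails

* `ratio <= 0` is a hard error (the log is undefined); missing ratios are
  dropped with a counted warning, mirroring how lost assay samples are
  handled in practice.
* A requested covariate with fewer than two observed levels is a contrast
  error, not a silent drop.
* Non-convergence anywhere (ladder fit, bootstrap refit, subject simulation)
  is flagged and counted, never imputed; `compute_pta()` reports failures
  via attribute and warning rather than quietly shrinking the denominator.
* A fitted \(k_{deg} < 0\) is numerically allowed but warned about; the
  studied factor space gives no physical reading of a negative rate.
* Events are active on \([start, start+duration)\): at a renewal instant the
  fresh bottle's rate applies, which keeps the input right-continuous and
  the renewal jump unambiguous.
* `delivered_fraction()` switches to its limit value 1 below
  \(k T_{inf} < 10^{-12}\) to avoid 0/0.

## 6. Known limitations

* The stability stage models ratios, not assay chemistry: calibration error
  and day effects are folded into \(\sigma\).
* Missingness is MCAR; if real sample loss clustered in hot conditions the
  fitted increments would shift.
* No Arrhenius interpolation between temperatures, no kinetic orders other
  than first, no pH/light covariates.
* The PK stage excludes renal replacement therapy, nonlinear kinetics and
  tissue penetration; "PTA" here is a plasma construct.
* The shipped popPK constants are synthetic stand-ins (Section 3); absolute
  PTA values inherit their uncertainty, while within-package contrasts
  (degraded vs fresh, CI vs EI) are more robust.
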