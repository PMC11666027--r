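# Population-PK configuration: meropenem, critically ill adults,
# two-compartment disposition with linear elimination.
#
# SYNTHETIC STAND-IN. The typical values and the clearance-creatinine
# covariate form below are plausible, literature-informed values for
# meropenem in critical illness; they are NOT estimates from any single
# published model fit and must be reviewed (and replaced with the model of
# record) before clinical interpretation. The variability terms (IIV/IOV
# CVs) and reference covariates are the simulation settings used throughout
# this package.
model: two_compartment_infusion
typical:
  cl_l_per_h: 12.0     # total clearance at the reference Clcr
  vc_l: 10.8           # central volume at the reference weight
  vp_l: 12.6           # peripheral volume
  q_l_per_h: 18.6      # inter-compartmental clearance
covariates:
  reference:
    clcr_ml_min: 80.8
    weight_kg: 70
    albumin_g_dl: 2.8
  cl_clcr_exponent: 0.62       # Cl = cl_l_per_h * (Clcr/80.8)^0.62
  vc_weight_proportional: true # Vc = vc_l * weight/70
variability:
  iiv_cv_percent:
    cl: 27.1
    vc: 31.5
    vp: 16.9
  iov_cv_percent_cl: 12.5      # one occasion = one dosing interval
  lognormal_convention: exact  # omega^2 = log(1 + CV^2)
free_fraction: 1.0             # total drug compared to the MIC
clcr_uniform_range_ml_min: [30, 160]
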