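test_that("infusion schedules expand regimens with per-bottle clocks", {
  ci <- build_infusion_schedule(ci_regimen(1000, 8), horizon_h = 24,
                                kdeg = 0.0313)
  expect_equal(nrow(ci), 4)  # loading dose + 3 bottles
  expect_equal(ci$start, c(0, 0.5, 8.5, 16.5))
  expect_equal(ci$duration, c(0.5, 8, 8, 8))
  expect_equal(ci$clock_start, ci$start)  # every bottle starts fresh

  ei <- build_infusion_schedule(ei_regimen(1000, 8, 3), horizon_h = 24,
                                kdeg = 0)
  expect_equal(ei$duration, c(0.5, 3, 3, 3))
  expect_error(ei_regimen(1000, 8, 9), "exceeds")
  expect_error(ci_regimen(1000, 8, loading_duration_h = 0),
               "loading_duration_h > 0")

  norenew <- build_infusion_schedule(ci_regimen(1000, 8), 24, 0.0313,
                                     renew_clock = FALSE)
  expect_equal(unique(norenew$clock_start[-1]), 0.5)

  # each bottle's input rate at its own end equals (dose/Tinf) e^(-kdeg Tinf)
  expect_equal(input_rate(16.5 - 1e-9, ci), 125 * exp(-0.0313 * 8),
               tolerance = 1e-6)
})

test_that("input rate sums active degradation-modified infusions", {
  ev <- build_infusion_schedule(ci_regimen(1000, 8, loading_dose_mg = 0), 24, 0)
  expect_equal(input_rate(c(0.1, 4, 7.9), ev), rep(125, 3))
  evk <- build_infusion_schedule(ci_regimen(1000, 8, loading_dose_mg = 0), 24,
                                 0.0313)
  expect_equal(input_rate(8 - 1e-9, evk), 125 * exp(-0.0313 * 8), tolerance = 1e-6)
  expect_equal(input_rate(8, evk), 125)  # fresh bottle at the renewal instant
  gap <- build_infusion_schedule(ei_regimen(1000, 8, 3, loading_dose_mg = 0),
                                 24, 0.02)
  expect_equal(input_rate(5, gap), 0)   # between infusions
  expect_error(input_rate(-1, gap), ">= 0")
})

test_that("delivered fraction matches quadrature of the input rate", {
  expect_equal(delivered_fraction(0, 8), 1)
  expect_equal(delivered_fraction(1e-14, 3), 1)
  expect_equal(delivered_fraction(0.0313, 8), 0.8846, tolerance = 1e-4)
  # numerical quadrature of the event input rate, to 1e-8
  for (k in c(0.0086, 0.0313, 0.2)) {
    ev <- build_infusion_schedule(ci_regimen(1000, 8, loading_dose_mg = 0),
                                  8, k)
    got <- stats::integrate(function(t) input_rate(t, ev), 0, 8,
                            rel.tol = 1e-12)$value / 1000
    expect_equal(delivered_fraction(k, 8), got, tolerance = 1e-8)
  }
  x <- seq(0, 1, by = 0.05)[-1]
  expect_true(all(diff(delivered_fraction(x, 1)) < 0))
  expect_error(delivered_fraction(-0.1, 8), ">= 0")
})

test_that("covariate model is the identity at reference and monotone in Clcr", {
  p <- poppk_parameters()
  ref <- apply_covariates(p, list(clcr = 80.8, weight = 70, albumin = 2.8))
  expect_equal(ref$cl, p$cl)
  expect_equal(ref$vc, p$vc)
  dbl <- apply_covariates(p, list(clcr = 2 * 80.8, weight = 70, albumin = 2.8))
  expect_equal(dbl$cl, p$cl * 2^p$cl_clcr_exponent)
  grid <- apply_covariates(p, list(clcr = seq(20, 200, by = 10), weight = 70,
                                   albumin = 2.8))
  expect_true(all(diff(grid$cl) > 0))
  expect_error(apply_covariates(p, list(clcr = 80, weight = 70)), "albumin")
  expect_error(apply_covariates(p, list(clcr = -5, weight = 70, albumin = 2.8)),
               "positive")
})

test_that("profile reaches the closed-form steady state without degradation", {
  pars <- list(cl = 12.5, vc = 10, vp = 12, q = 15)
  ev <- build_infusion_schedule(ci_regimen(1000, 8, loading_dose_mg = 0),
                                120, kdeg = 0)
  prof <- simulate_profile(pars, ev, 120, dt = 0.1)
  expect_equal(tail(prof$conc_mg_L, 1), 125 / 12.5, tolerance = 1e-3)
})

test_that("one-compartment limit decays mono-exponentially", {
  pars <- list(cl = 6, vc = 15, vp = 1, q = 0)
  ev <- data.frame(start = 0, duration = 0.1, dose_mg = 600, kdeg = 0,
                   clock_start = 0)
  class(ev) <- c("infusion_schedule", "data.frame")
  prof <- simulate_profile(pars, ev, 12, dt = 0.01)
  ke <- pars$cl / pars$vc
  c1 <- prof$conc_mg_L[prof$time_h == 1]
  c5 <- prof$conc_mg_L[prof$time_h == 5]
  expect_equal(c5, c1 * exp(-ke * 4), tolerance = 1e-6)
})

test_that("solver agrees with an independent fixed-step RK4 oracle", {
  pars <- typical_pars()
  ev <- build_infusion_schedule(ci_regimen(1000, 8), 24, kdeg = 0.0313)
  prof <- simulate_profile(pars, ev, 24)
  check <- seq(0.5, 24, by = 0.5)
  oracle <- rk4_profile(pars, ev, check, h = 0.002)
  got <- prof$conc_mg_L[match(check, prof$time_h)]
  expect_true(all(abs(got - oracle$conc_mg_L) / max(oracle$conc_mg_L) < 1e-3))
})

test_that("mass balance and dose accounting hold", {
  pars <- typical_pars()
  # without degradation: body + eliminated == infused at every grid time
  ev0 <- build_infusion_schedule(ci_regimen(1000, 8), 24, kdeg = 0)
  prof0 <- simulate_profile(pars, ev0, 24)
  infused <- vapply(prof0$time_h, function(t) {
    sum(pmin(pmax(t - ev0$start, 0), ev0$duration) * ev0$dose_mg / ev0$duration)
  }, 0)
  total <- prof0$A_central + prof0$A_peripheral + prof0$A_eliminated
  expect_equal(total, infused, tolerance = 1e-7)

  # with degradation: one isolated bottle delivers dose * delivered_fraction
  ev1 <- data.frame(start = 0, duration = 8, dose_mg = 1000, kdeg = 0.0313,
                    clock_start = 0)
  class(ev1) <- c("infusion_schedule", "data.frame")
  prof1 <- simulate_profile(pars, ev1, 8)
  end <- nrow(prof1)
  expect_equal(prof1$A_central[end] + prof1$A_peripheral[end] + prof1$A_eliminated[end],
               1000 * delivered_fraction(0.0313, 8), tolerance = 1e-7)
})

test_that("the system is linear and the profile continuous", {
  pars <- typical_pars()
  ev <- build_infusion_schedule(ci_regimen(1000, 8), 24, kdeg = 0.02)
  ev2 <- ev
  ev2$dose_mg <- 2 * ev2$dose_mg
  p1 <- simulate_profile(pars, ev, 24)
  p2 <- simulate_profile(pars, ev2, 24)
  expect_equal(p2$conc_mg_L, 2 * p1$conc_mg_L, tolerance = 1e-7)
  # continuity: grid increments shrink with the spacing (a genuine jump
  # would survive refinement), even across event boundaries
  p_fine <- simulate_profile(pars, ev, 24, dt = 0.0125)
  expect_lt(max(abs(diff(p_fine$conc_mg_L))),
            max(abs(diff(p1$conc_mg_L))) / 3)
  # determinism
  expect_identical(p1$conc_mg_L, simulate_profile(pars, ev, 24)$conc_mg_L)
})

test_that("steady-state trough ratio behaves as first-order theory predicts", {
  pars <- typical_pars()
  reg <- ci_regimen(1000, 8)
  expect_equal(steady_state_cmin_ratio(reg, 0, pars), 1, tolerance = 2e-3)
  r1 <- steady_state_cmin_ratio(reg, 0.0086, pars)
  r2 <- steady_state_cmin_ratio(reg, 0.0313, pars)
  expect_true(r2 < r1 && r1 < 1)
  # bounded below by the fresh-vs-stale rate ratio and above by the
  # delivered-fraction average
  expect_gt(r2, exp(-0.0313 * 8) - 1e-9)
  expect_lt(r2, delivered_fraction(0.0313, 8) + 1e-9)
  expect_error(steady_state_cmin_ratio(ei_regimen(1000, 8, 3), 0.01, pars),
               "continuous")
})
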