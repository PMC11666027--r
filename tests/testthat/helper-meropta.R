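# shared fixtures and independent oracles (kept deliberately dumb and
# separate from the package's own code paths)

typical_pars <- function() list(cl = 12, vc = 10.8, vp = 12.6, q = 18.6)

# zero-variability population for deterministic subject checks
poppk_novar <- function() {
  poppk_parameters(iiv_cv = c(cl = 0, vc = 0, vp = 0), iov_cv_cl = 0)
}

quiet_fit <- function(..., covariate_set = 3) {
  suppressWarnings(fit_degradation(..., covariate_set = covariate_set))
}

# fixed-step RK4 integrator for the two-compartment system with
# degradation-modified infusion forcing; independent of simulate_profile
rk4_profile <- function(pars, events, check_times, h = 0.002) {
  rate_at <- function(t) {
    r <- 0
    for (i in seq_len(nrow(events))) {
      if (t >= events$start[i] && t < events$start[i] + events$duration[i]) {
        r <- r + events$dose_mg[i] / events$duration[i] *
          exp(-events$kdeg[i] * (t - events$clock_start[i]))
      }
    }
    r
  }
  deriv <- function(t, y) {
    r <- rate_at(t)
    c(r - y[1] * (pars$cl / pars$vc + pars$q / pars$vc) + y[2] * pars$q / pars$vp,
      y[1] * pars$q / pars$vc - y[2] * pars$q / pars$vp,
      y[1] * pars$cl / pars$vc)
  }
  horizon <- max(check_times)
  bounds <- sort(unique(c(0, events$start, events$start + events$duration, horizon)))
  bounds <- bounds[bounds <= horizon]
  y <- c(0, 0, 0)
  out <- matrix(NA_real_, length(check_times), 3)
  if (any(check_times == 0)) out[check_times == 0, ] <- rep(y, each = sum(check_times == 0))
  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    inner <- check_times[check_times > a & check_times <= b]
    knots <- sort(unique(c(seq(a, b, length.out = max(2, ceiling((b - a) / h) + 1)),
                           inner, b)))
    for (k in seq_len(length(knots) - 1)) {
      t0 <- knots[k]; dt <- knots[k + 1] - t0
      # evaluate forcing just inside the segment so boundary steps use the
      # active event set of this segment
      k1 <- deriv(min(t0, b - 1e-12), y)
      k2 <- deriv(min(t0 + dt / 2, b - 1e-12), y + dt / 2 * k1)
      k3 <- deriv(min(t0 + dt / 2, b - 1e-12), y + dt / 2 * k2)
      k4 <- deriv(min(t0 + dt, b - 1e-12), y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      hit <- which(abs(check_times - knots[k + 1]) < 1e-12)
      if (length(hit)) out[hit, ] <- rep(y, each = length(hit))
    }
  }
  data.frame(time_h = check_times, conc_mg_L = out[, 1] / pars$vc,
             A_central = out[, 1], A_peripheral = out[, 2],
             A_eliminated = out[, 3])
}

# brute-force fT>MIC by dense-grid counting
dense_ft_above <- function(profile, mic, window, n = 200001) {
  tt <- seq(window[1], window[2], length.out = n)
  cc <- approx(profile$time_h, profile$conc_mg_L, xout = tt)$y
  mean(cc > mic)
}
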