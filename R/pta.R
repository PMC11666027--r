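#' Sample a virtual patient population
#'
#' Draws `n` subjects from the population-PK model: creatinine clearance from
#' a uniform distribution (or fixed, for renal-function-grouped analyses),
#' covariate-adjusted typical parameters via [apply_covariates()], then
#' log-normal inter-individual variability on Cl, Vc and Vp parameterized so
#' the typical value is the median, plus per-occasion log-normal multipliers
#' on Cl (inter-occasion variability, one occasion per dosing interval).
#' With all CVs zero every subject equals the covariate-adjusted typical
#' individual.
#'
#' @param poppk a `poppk` object.
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed; output is reproducible given the seed.
#' @param clcr either a length-2 range (mL/min) for uniform sampling
#'   (default: the config's range) or a single fixed value.
#' @param weight,albumin covariates, fixed across subjects by default.
#' @param n_occasions number of inter-occasion multipliers drawn per subject
#'   (enough columns must exist for the schedule later simulated).
#' @return data.frame with `id`, `clcr`, `weight`, `albumin`, `cl`, `vc`,
#'   `vp`, `q`; the IOV multiplier matrix (n x n_occasions) is attached as
#'   attribute `iov`, and the generating `poppk` as attribute `poppk`.
#' @export
sample_subjects <- function(poppk, n, seed = NULL, clcr = NULL,
                            weight = NULL, albumin = NULL, n_occasions = 16) {
  stopifnot(inherits(poppk, "poppk"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(clcr)) clcr <- poppk$clcr_range
  if (is.null(weight)) weight <- poppk$reference$weight
  if (is.null(albumin)) albumin <- poppk$reference$albumin
  clcr_i <- if (length(clcr) == 2) {
    if (clcr[1] >= clcr[2]) stop("invalid clcr range: min >= max")
    runif(n, clcr[1], clcr[2])
  } else rep(clcr, n)
  typ <- apply_covariates(poppk, list(clcr = clcr_i, weight = weight,
                                      albumin = albumin))
  om <- vapply(c("cl", "vc", "vp"), function(p) {
    .lnorm_sd(poppk$iiv_cv[[p]], poppk$lognormal_convention)
  }, 0)
  out <- data.frame(
    id = seq_len(n),
    clcr = clcr_i,
    weight = weight,
    albumin = albumin,
    cl = typ$cl * exp(rnorm(n, 0, om[["cl"]])),
    vc = typ$vc * exp(rnorm(n, 0, om[["vc"]])),
    vp = typ$vp * exp(rnorm(n, 0, om[["vp"]])),
    q = typ$q
  )
  om_iov <- .lnorm_sd(poppk$iov_cv_cl, poppk$lognormal_convention)
  attr(out, "iov") <- matrix(exp(rnorm(n * n_occasions, 0, om_iov)),
                             nrow = n, ncol = n_occasions)
  attr(out, "poppk") <- poppk
  out
}

#' Fraction of a time window spent above the MIC
#'
#' Computes fT>MIC on a simulated profile: the fraction of `window` during
#' which `free_fraction * C(t) > mic`, locating threshold crossings exactly
#' by linear interpolation between grid points. For the aggressive
#' 4xMIC target pass `mic = 4 * mic`.
#'
#' @param profile a `pk_profile` (or data.frame with `time_h`, `conc_mg_L`).
#' @param mic minimum inhibitory concentration (mg/L), > 0.
#' @param window numeric length-2 evaluation window (h), inside the profile
#'   grid.
#' @param free_fraction unbound fraction applied to the concentrations.
#' @return fraction in `[0, 1]`.
#' @export
fraction_time_above_mic <- function(profile, mic, window = c(0, 24),
                                    free_fraction = 1) {
  stopifnot(mic > 0, length(window) == 2, window[1] < window[2])
  tt <- profile$time_h
  cc <- profile$conc_mg_L * free_fraction
  if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9) {
    stop("evaluation window extends outside the simulated grid")
  }
  keep <- tt > window[1] & tt < window[2]
  t2 <- c(window[1], tt[keep], window[2])
  c2 <- c(approx(tt, cc, xout = window[1])$y, cc[keep],
          approx(tt, cc, xout = window[2])$y)
  dt <- diff(t2)
  a <- c2[-length(c2)] - mic
  b <- c2[-1] - mic
  above <- ifelse(
    a > 0 & b > 0, dt,
    ifelse(a <= 0 & b <= 0, 0,
           dt * pmax(a, b) / abs(a - b))
  )
  sum(above) / (window[2] - window[1])
}

#' PTA band label
#'
#' Bins PTA values into the conventional reporting bands `<50`, `50-80`,
#' `80-90` and `>=90` percent.
#'
#' @param pta numeric vector of attainment probabilities in `[0, 1]`.
#' @return factor with levels `"<50"`, `"50-80"`, `"80-90"`, `">=90"`.
#' @export
pta_band <- function(pta) {
  cut(pta, breaks = c(-Inf, 0.5, 0.8, 0.9, Inf), right = FALSE,
      labels = c("<50", "50-80", "80-90", ">=90"))
}

# occasions (one per infusion event) with the subject's IOV multipliers
.occasions_for <- function(events, horizon, iov_row) {
  starts <- sort(unique(events$start))
  ends <- c(starts[-1], max(horizon, max(events$start + events$duration)))
  n_occ <- length(starts)
  if (length(iov_row) < n_occ) {
    stop("subjects were sampled with fewer IOV occasions (", length(iov_row),
         ") than the schedule needs (", n_occ, ")")
  }
  data.frame(start = starts, end = ends, cl_mult = iov_row[seq_len(n_occ)])
}

#' Probability of target attainment for one regimen and condition
#'
#' Simulates every subject's day-one profile under the shared infusion
#' schedule (same events for all subjects; each subject keeps their own
#' inter-occasion clearance multipliers), computes fT>MIC over the evaluation
#' window, and counts the subjects reaching `target_fraction`. All MICs are
#' evaluated on the same simulated profiles, so comparisons across MIC use
#' common random numbers.
#'
#' @param subjects output of [sample_subjects()].
#' @param regimen a `regimen`.
#' @param kdeg degradation rate constant (1/h) for the infused solution.
#' @param mic vector of MICs (mg/L).
#' @param target_fraction required fT>MIC (default 0.98).
#' @param window evaluation window in hours (default day one, `c(0, 24)`).
#' @param dt simulation grid resolution (h).
#' @param degrade_loading logical, see [build_infusion_schedule()].
#' @return data.frame with one row per MIC: `mic_mg_L`, `n`, `n_attained`,
#'   `pta`, `ci_lo`, `ci_hi` (95% Clopper-Pearson). Subjects whose simulation
#'   fails are flagged via a warning and the `n_failed` attribute, never
#'   silently dropped.
#' @export
compute_pta <- function(subjects, regimen, kdeg, mic,
                        target_fraction = 0.98, window = c(0, 24),
                        dt = 0.05, degrade_loading = TRUE) {
  stopifnot(nrow(subjects) >= 1, length(mic) >= 1)
  poppk <- attr(subjects, "poppk")
  ff <- if (is.null(poppk)) 1 else poppk$free_fraction
  events <- build_infusion_schedule(regimen, horizon_h = window[2],
                                    kdeg = kdeg,
                                    degrade_loading = degrade_loading)
  iov <- attr(subjects, "iov")
  if (is.null(iov)) iov <- matrix(1, nrow(subjects), nrow(events))
  ft <- matrix(NA_real_, nrow(subjects), length(mic))
  n_failed <- 0L
  for (i in seq_len(nrow(subjects))) {
    prof <- tryCatch(
      simulate_profile(
        list(cl = subjects$cl[i], vc = subjects$vc[i],
             vp = subjects$vp[i], q = subjects$q[i]),
        events, horizon_h = window[2], dt = dt,
        occasions = .occasions_for(events, window[2], iov[i, ])
      ),
      error = function(e) e
    )
    if (inherits(prof, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    for (j in seq_along(mic)) {
      ft[i, j] <- fraction_time_above_mic(prof, mic[j], window, ff)
    }
  }
  if (n_failed > 0) {
    warning(n_failed, " subject simulation(s) failed; PTA computed on the ",
            nrow(subjects) - n_failed, " remaining subjects", call. = FALSE)
  }
  ok <- !is.na(ft[, 1])
  n <- sum(ok)
  if (n == 0) stop("all subject simulations failed")
  x <- colSums(ft[ok, , drop = FALSE] >= target_fraction)
  out <- data.frame(
    mic_mg_L = mic,
    n = n,
    n_attained = as.integer(x),
    pta = x / n,
    ci_lo = ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1)),
    ci_hi = ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  )
  attr(out, "n_failed") <- n_failed
  attr(out, "target_fraction") <- target_fraction
  attr(out, "window") <- window
  attr(out, "kdeg") <- kdeg
  out
}

#' PTA over a grid of dosing, degradation and renal-function scenarios
#'
#' Enumerates daily dose x bottle-renewal interval x storage condition x MIC
#' x renal-function group and computes one PTA per cell. Subjects are sampled
#' once per renal-function group and reused across all doses, renewal
#' intervals and storage conditions (common random numbers), and all MICs are
#' evaluated on shared profiles, so every monotonicity comparison across the
#' grid is variance-reduced. Continuous infusion is assumed: each bottle
#' contains the daily dose divided over the day and is renewed every
#' `renewal_h` hours.
#'
#' @param config list with elements
#'   `daily_doses_g` (numeric), `renewal_h` (numeric), `temperatures`
#'   (degrees C), `concentration` (single g/48 mL level, default 1),
#'   `mics` (mg/L), `clcr_groups` (fixed Clcr values, or NULL to sample the
#'   configured uniform range as a single group), `n` (subjects per group,
#'   default 1000), `seed`, `model` (a `degradation_fit` or
#'   `degradation_params` used for kdeg lookup; default
#'   [degradation_truth()]), `poppk` (default [read_poppk_config()]),
#'   `target_fraction` (default 0.98), `window` (default `c(0, 24)`),
#'   `include_no_degradation` (default TRUE adds a kdeg = 0 reference
#'   condition), `loading_dose_mg`/`loading_duration_h` (default 500/0.5),
#'   `dt` (default 0.05).
#' @return data.frame with columns `daily_dose_g`, `dose_mg`, `renewal_h`,
#'   `temperature_C`, `conc_g_per_48mL`, `kdeg_h`, `mic_mg_L`, `clcr_group`,
#'   `n`, `pta`, `ci_lo`, `ci_hi`, `band`.
#' @export
pta_scenario_grid <- function(config) {
  cfg <- config
  for (nm in c("daily_doses_g", "renewal_h", "temperatures", "mics")) {
    if (is.null(cfg[[nm]]) || length(cfg[[nm]]) == 0) {
      stop("scenario grid config is missing or empty: ", nm)
    }
  }
  if (is.null(cfg$concentration)) cfg$concentration <- 1
  if (is.null(cfg$n)) cfg$n <- 1000
  if (is.null(cfg$seed)) stop("scenario grid config requires an explicit seed")
  if (is.null(cfg$model)) cfg$model <- degradation_truth()
  if (is.null(cfg$poppk)) cfg$poppk <- read_poppk_config()
  if (is.null(cfg$target_fraction)) cfg$target_fraction <- 0.98
  if (is.null(cfg$window)) cfg$window <- c(0, 24)
  if (is.null(cfg$include_no_degradation)) cfg$include_no_degradation <- TRUE
  if (is.null(cfg$loading_dose_mg)) cfg$loading_dose_mg <- 500
  if (is.null(cfg$loading_duration_h)) cfg$loading_duration_h <- 0.5
  if (is.null(cfg$dt)) cfg$dt <- 0.05

  conds <- data.frame(temperature_C = cfg$temperatures)
  conds$kdeg <- vapply(conds$temperature_C, function(tp) {
    kdeg_for_condition(cfg$model, tp, cfg$concentration)
  }, 0)
  if (cfg$include_no_degradation) {
    conds <- rbind(data.frame(temperature_C = NA_real_, kdeg = 0), conds)
  }
  groups <- if (is.null(cfg$clcr_groups)) list(NULL) else as.list(cfg$clcr_groups)

  res <- list()
  for (g in seq_along(groups)) {
    subj <- sample_subjects(cfg$poppk, cfg$n, seed = cfg$seed + g,
                            clcr = groups[[g]])
    glabel <- if (is.null(groups[[g]])) {
      sprintf("uniform %g-%g", cfg$poppk$clcr_range[1], cfg$poppk$clcr_range[2])
    } else as.character(groups[[g]])
    for (dd in cfg$daily_doses_g) {
      for (rn in cfg$renewal_h) {
        dose_mg <- dd * 1000 * rn / 24
        reg <- ci_regimen(dose_mg, renewal_h = rn,
                          loading_dose_mg = cfg$loading_dose_mg,
                          loading_duration_h = cfg$loading_duration_h)
        for (ci in seq_len(nrow(conds))) {
          p <- compute_pta(subj, reg, kdeg = conds$kdeg[ci], mic = cfg$mics,
                           target_fraction = cfg$target_fraction,
                           window = cfg$window, dt = cfg$dt)
          res[[length(res) + 1]] <- data.frame(
            daily_dose_g = dd, dose_mg = dose_mg, renewal_h = rn,
            temperature_C = conds$temperature_C[ci],
            conc_g_per_48mL = cfg$concentration,
            kdeg_h = conds$kdeg[ci],
            mic_mg_L = p$mic_mg_L, clcr_group = glabel,
            n = p$n, pta = p$pta, ci_lo = p$ci_lo, ci_hi = p$ci_hi
          )
        }
      }
    }
  }
  out <- do.call(rbind, res)
  out$band <- pta_band(out$pta)
  rownames(out) <- NULL
  out
}
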