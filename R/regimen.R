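#' Dosing regimens for prolonged meropenem infusion
#'
#' `ci_regimen()` describes continuous infusion delivered as back-to-back
#' bottles renewed every `renewal_h` hours (each renewal restarts the bottle's
#' degradation clock); `ei_regimen()` describes extended infusion, where each
#' dose is infused over `tinf_h` hours and the line then rests until the next
#' interval. Both start with a loading dose (default 500 mg over 30 min)
#' after which maintenance dosing begins immediately.
#'
#' @param dose_mg maintenance dose per administration (mg): one bottle for CI,
#'   one infusion for EI.
#' @param renewal_h bottle renewal interval (h) for CI; the dosing interval
#'   and infusion duration coincide.
#' @param interval_h dosing interval (h) for EI.
#' @param tinf_h infusion duration (h) for EI; must not exceed `interval_h`.
#' @param loading_dose_mg loading dose (mg); 0 suppresses it.
#' @param loading_duration_h loading-dose infusion duration (h).
#' @return object of class `regimen`.
#' @examples
#' ci_regimen(1000, renewal_h = 8)            # 1 g q8h continuous, 3 g/day
#' ei_regimen(1000, interval_h = 8, tinf_h = 3)  # 1 g q8h over 3 h
#' @export
ci_regimen <- function(dose_mg, renewal_h, loading_dose_mg = 500,
                       loading_duration_h = 0.5) {
  new_regimen("ci", dose_mg, interval_h = renewal_h, tinf_h = renewal_h,
              loading_dose_mg, loading_duration_h)
}

#' @rdname ci_regimen
#' @export
ei_regimen <- function(dose_mg, interval_h, tinf_h, loading_dose_mg = 500,
                       loading_duration_h = 0.5) {
  new_regimen("ei", dose_mg, interval_h, tinf_h, loading_dose_mg,
              loading_duration_h)
}

new_regimen <- function(mode, dose_mg, interval_h, tinf_h, loading_dose_mg,
                        loading_duration_h) {
  stopifnot(dose_mg > 0, interval_h > 0, tinf_h > 0,
            loading_dose_mg >= 0, loading_duration_h > 0)
  if (tinf_h > interval_h) stop("infusion duration exceeds the dosing interval")
  if (mode == "ci" && tinf_h != interval_h) {
    stop("continuous infusion requires back-to-back bottles (tinf == interval)")
  }
  structure(list(mode = mode, dose_mg = dose_mg, interval_h = interval_h,
                 tinf_h = tinf_h, loading_dose_mg = loading_dose_mg,
                 loading_duration_h = loading_duration_h),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("%s: %g mg every %g h (infused over %g h)%s\n",
              if (x$mode == "ci") "Continuous infusion (bottle renewal)" else "Extended infusion",
              x$dose_mg, x$interval_h, x$tinf_h,
              if (x$loading_dose_mg > 0) {
                sprintf("; loading dose %g mg over %g h", x$loading_dose_mg,
                        x$loading_duration_h)
              } else ""))
  invisible(x)
}

#' Expand a regimen into timed infusion events
#'
#' Produces the sequence of infusion events over the simulation horizon: the
#' loading dose at t = 0 followed by maintenance infusions starting when the
#' loading infusion ends and repeating every dosing interval. Each event
#' carries its own degradation clock (`clock_start`): by default the clock is
#' the event's own start time, so every renewed bottle starts fresh; with
#' `renew_clock = FALSE` all maintenance events share the first bottle's
#' clock, modelling a solution that is hung once and never replaced.
#'
#' @param regimen a `regimen`.
#' @param horizon_h simulation horizon (h), at least one dosing interval.
#' @param kdeg degradation rate constant (1/h) of the prepared solution.
#' @param degrade_loading logical; subject the loading-dose solution to the
#'   same degradation (default TRUE; the effect over 30 min is negligible).
#' @param renew_clock logical; reset the degradation clock at each renewal
#'   (default TRUE).
#' @return data.frame of class `infusion_schedule` with columns `start`,
#'   `duration`, `dose_mg`, `kdeg`, `clock_start` (all times in h).
#' @examples
#' build_infusion_schedule(ci_regimen(1000, 8), horizon_h = 24, kdeg = 0.0313)
#' @export
build_infusion_schedule <- function(regimen, horizon_h, kdeg,
                                    degrade_loading = TRUE,
                                    renew_clock = TRUE) {
  stopifnot(inherits(regimen, "regimen"))
  if (kdeg < 0) stop("kdeg must be >= 0")
  if (horizon_h < regimen$interval_h) {
    stop("horizon must cover at least one dosing interval")
  }
  ld <- regimen$loading_dose_mg > 0
  t0 <- if (ld) regimen$loading_duration_h else 0
  starts <- seq(t0, horizon_h - 1e-9, by = regimen$interval_h)
  ev <- data.frame(
    start = starts,
    duration = regimen$tinf_h,
    dose_mg = regimen$dose_mg,
    kdeg = kdeg,
    clock_start = if (renew_clock) starts else starts[1]
  )
  if (ld) {
    ev <- rbind(
      data.frame(start = 0, duration = regimen$loading_duration_h,
                 dose_mg = regimen$loading_dose_mg,
                 kdeg = if (degrade_loading) kdeg else 0,
                 clock_start = 0),
      ev
    )
  }
  rownames(ev) <- NULL
  class(ev) <- c("infusion_schedule", "data.frame")
  ev
}

#' Instantaneous drug input rate from the infusion line
#'
#' Sum over all events active at `t` of the degradation-modified infusion
#' rate `dose/duration * exp(-kdeg * (t - clock_start))`. Events are active
#' on `[start, start + duration)`, so at a renewal instant the rate jumps
#' back up to the fresh-bottle value. Zero outside all events.
#'
#' @param t time (h); vectorized.
#' @param events an `infusion_schedule`.
#' @return input rate in mg/h, same length as `t`.
#' @export
input_rate <- function(t, events) {
  if (any(t < 0)) stop("t must be >= 0")
  out <- numeric(length(t))
  for (i in seq_len(nrow(events))) {
    act <- t >= events$start[i] & t < events$start[i] + events$duration[i]
    if (any(act)) {
      out[act] <- out[act] + events$dose_mg[i] / events$duration[i] *
        exp(-events$kdeg[i] * (t[act] - events$clock_start[i]))
    }
  }
  out
}

#' Fraction of the nominal dose actually delivered
#'
#' Integral of the degradation-modified input rate over the infusion,
#' relative to the nominal dose:
#' `(1 - exp(-kdeg * tinf)) / (kdeg * tinf)`, continuously extended to 1 at
#' `kdeg = 0`. Strictly decreasing in `kdeg * tinf`.
#'
#' @param kdeg degradation rate constant (1/h), >= 0; vectorized.
#' @param tinf infusion (bottle) duration in hours, > 0.
#' @return dimensionless fraction in (0, 1].
#' @examples
#' delivered_fraction(0.0313, 8)  # ~0.884
#' @export
delivered_fraction <- function(kdeg, tinf) {
  if (any(kdeg < 0)) stop("kdeg must be >= 0")
  if (any(tinf <= 0)) stop("tinf must be > 0")
  x <- kdeg * tinf
  out <- ifelse(x < 1e-12, 1, -expm1(-x) / x)
  unname(out)
}
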