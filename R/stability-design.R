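#' Factorial design of the in-bottle stability experiment
#'
#' Builds the Cartesian product of brand, temperature, infusion concentration
#' and sampling time. One experimental unit (one prepared bottle followed over
#' time) corresponds to each brand x temperature x concentration combination,
#' so the default seven-brand design has 7 x 3 x 2 x 9 = 378 design points on
#' 42 units.
#'
#' @param brands character vector of brand codes.
#' @param temperatures numeric vector of storage temperatures (degrees C).
#' @param concentrations numeric vector of infusion concentrations, expressed
#'   as grams of meropenem per 48 mL (so `1` means 1 g/48 mL).
#' @param times numeric vector of sampling times in hours; must contain 0,
#'   the sample that defines the initial concentration C0.
#' @return data.frame with columns `brand`, `temperature_C`,
#'   `conc_g_per_48mL`, `time_h`, `unit_id`.
#' @examples
#' d <- stability_design()
#' nrow(d)                      # 378
#' length(unique(d$unit_id))    # 42
#' @export
stability_design <- function(brands = c("A", "E", "I", "Q", "R", "V", "X"),
                             temperatures = c(25, 30, 37),
                             concentrations = c(1, 2),
                             times = 0:8) {
  if (length(brands) == 0 || length(temperatures) == 0 ||
      length(concentrations) == 0 || length(times) == 0) {
    stop("all design factors (brands, temperatures, concentrations, times) must be non-empty")
  }
  if (!0 %in% times) stop("`times` must include 0: the 0 h sample defines C0")
  if (any(times < 0)) stop("negative sampling times are not allowed")
  d <- expand.grid(
    brand = as.character(brands),
    temperature_C = as.numeric(temperatures),
    conc_g_per_48mL = as.numeric(concentrations),
    time_h = sort(as.numeric(times)),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  d$unit_id <- paste(d$brand, d$temperature_C, d$conc_g_per_48mL, sep = "_")
  d[order(d$unit_id, d$time_h), c("brand", "temperature_C", "conc_g_per_48mL",
                                  "time_h", "unit_id")]
}

#' Reference degradation parameters for meropenem in 0.9% saline
#'
#' Fixed effects and variance components of the final mixed-effects
#' degradation model estimated from a seven-brand meropenem stability
#' experiment (1 and 2 g/48 mL in saline at 25/30/37 degrees C over 8 h).
#' The model is, on the natural-log concentration-ratio scale,
#' \deqn{\log(C/C_0) = \mu + \theta_i - (\beta_0 + \beta_1[T] + \beta_2[C_{infu}])\,t + \eta_i t + \epsilon}
#' with unit-level random intercept \eqn{\theta_i} (SD `omega1`), random slope
#' \eqn{\eta_i} (SD `omega2`) and residual SD `sigma`. All rate terms are in
#' 1/h; the reference condition is 25 degrees C, 1 g/48 mL, where the
#' degradation rate constant is `beta0`. Brand increments (`beta3`) are zero:
#' brand was not a significant covariate.
#'
#' These values serve as the default truth of [simulate_stability()] and as a
#' ready-made model object for [kdeg_for_condition()] and
#' [remaining_fraction()].
#'
#' @return object of class `degradation_params`; see [degradation_params()].
#' @examples
#' kdeg_for_condition(degradation_truth(), temperature = 37, concentration = 2)
#' @export
degradation_truth <- function() {
  degradation_params(
    mu = -0.0003,
    beta0 = 0.0086,
    beta1 = c(`25` = 0, `30` = 0.0045, `37` = 0.0185),
    beta2 = c(`1` = 0, `2` = 0.0042),
    beta3 = NULL,
    omega1 = 0.0064,
    omega2 = 0.0015,
    sigma = 0.0101
  )
}

#' Specify a degradation model by its parameter values
#'
#' Container for the fixed effects and variance components of the first-order
#' degradation model, used to simulate data or predict degradation rate
#' constants without fitting. Reference levels (first element of `beta1`,
#' `beta2` and, if given, `beta3`) must map to exactly 0.
#'
#' @param mu intercept on the log-ratio scale (dimensionless).
#' @param beta0 time slope (degradation rate constant, 1/h) at the reference
#'   condition.
#' @param beta1 named numeric vector of temperature increments (1/h); names
#'   are temperature levels in degrees C; reference level value 0.
#' @param beta2 named numeric vector of concentration increments (1/h); names
#'   are g/48 mL levels; reference level value 0.
#' @param beta3 optional named numeric vector of brand increments (1/h), or
#'   NULL for no brand effect.
#' @param omega1 SD of the unit-level random intercept.
#' @param omega2 SD of the unit-level random slope (1/h).
#' @param sigma residual SD on the log-ratio scale.
#' @return object of class `degradation_params`.
#' @export
degradation_params <- function(mu, beta0, beta1, beta2, beta3 = NULL,
                               omega1 = 0, omega2 = 0, sigma = 0) {
  stopifnot(is.numeric(mu), is.numeric(beta0),
            is.numeric(beta1), !is.null(names(beta1)),
            is.numeric(beta2), !is.null(names(beta2)))
  if (any(c(omega1, omega2, sigma) < 0)) {
    stop("variance components omega1, omega2, sigma must be >= 0")
  }
  for (b in list(beta1, beta2, beta3)) {
    if (!is.null(b) && !all(is.finite(b))) stop("all effect increments must be finite")
  }
  if (beta1[[1]] != 0 || beta2[[1]] != 0 || (!is.null(beta3) && beta3[[1]] != 0)) {
    stop("the first (reference) level of each increment vector must be exactly 0")
  }
  structure(
    list(
      fixed = list(mu = mu, beta0 = beta0, beta1 = beta1, beta2 = beta2,
                   beta3 = beta3),
      varcomp = list(omega1 = omega1, omega2 = omega2, sigma = sigma)
    ),
    class = "degradation_params"
  )
}

#' @export
print.degradation_params <- function(x, ...) {
  cat("First-order degradation model parameters\n")
  cat(sprintf("  mu (log-ratio intercept): %g\n", x$fixed$mu))
  cat(sprintf("  beta0 (reference kdeg, 1/h): %g\n", x$fixed$beta0))
  cat("  temperature increments (1/h):",
      paste(sprintf("%s=%g", names(x$fixed$beta1), x$fixed$beta1), collapse = ", "), "\n")
  cat("  concentration increments (1/h):",
      paste(sprintf("%s=%g", names(x$fixed$beta2), x$fixed$beta2), collapse = ", "), "\n")
  if (!is.null(x$fixed$beta3)) {
    cat("  brand increments (1/h):",
        paste(sprintf("%s=%g", names(x$fixed$beta3), x$fixed$beta3), collapse = ", "), "\n")
  }
  cat(sprintf("  omega1=%g omega2=%g sigma=%g\n",
              x$varcomp$omega1, x$varcomp$omega2, x$varcomp$sigma))
  invisible(x)
}

# kdeg (1/h) implied by the fixed effects for each row of a design
.kdeg_rows <- function(fixed, design) {
  lev1 <- as.character(design$temperature_C)
  lev2 <- as.character(design$conc_g_per_48mL)
  bad1 <- setdiff(unique(lev1), names(fixed$beta1))
  bad2 <- setdiff(unique(lev2), names(fixed$beta2))
  if (length(bad1)) stop("temperature level(s) not covered by the model: ",
                         paste(bad1, collapse = ", "))
  if (length(bad2)) stop("concentration level(s) not covered by the model: ",
                         paste(bad2, collapse = ", "))
  k <- fixed$beta0 + unname(fixed$beta1[lev1]) + unname(fixed$beta2[lev2])
  if (!is.null(fixed$beta3)) {
    bad3 <- setdiff(unique(design$brand), names(fixed$beta3))
    if (length(bad3)) stop("brand level(s) not covered by the model: ",
                           paste(bad3, collapse = ", "))
    k <- k + unname(fixed$beta3[design$brand])
  }
  k
}

#' Simulate a stability dataset from the degradation model
#'
#' Forward-simulates concentration ratios C/C0 on a stability design under
#' the mixed-effects first-order degradation model. For each experimental
#' unit i a random intercept theta_i ~ N(0, omega1^2) and random slope
#' eta_i ~ N(0, omega2^2) are drawn independently; each observation is
#' \deqn{\log(C/C_0) = \mu + \theta_i - k_{deg}\,t + \eta_i t + \epsilon,\quad \epsilon \sim N(0, \sigma^2)}
#' and the ratio is the exponential of that. By default the 0 h samples are
#' emitted as exactly 1 (the 0 h assay defines C0, so its ratio carries no
#' error); set `noise_at_zero = TRUE` to apply the full model at t = 0 as
#' well, e.g. for parameter-recovery experiments where data and fitted model
#' must share one likelihood. Non-zero-time points are dropped completely at
#' random with probability `missing_rate`, emulating sample loss.
#'
#' @param design design data.frame from [stability_design()].
#' @param params `degradation_params` object (default: [degradation_truth()]).
#' @param missing_rate probability in `[0, 1)` that a t > 0 measurement is
#'   lost; the default reproduces the observed loss of about 13 of the 336
#'   non-zero-time points of the full design.
#' @param seed optional integer seed; the output is bit-identical across
#'   runs for a fixed seed.
#' @param noise_at_zero logical; apply intercept, random effects and residual
#'   noise at t = 0 instead of forcing ratio 1 (default FALSE).
#' @return data.frame with the design columns plus `ratio`.
#' @examples
#' x <- simulate_stability(stability_design(), missing_rate = 0, seed = 1)
#' nrow(x)   # 378
#' @export
simulate_stability <- function(design,
                               params = degradation_truth(),
                               missing_rate = 13 / 336,
                               seed = NULL,
                               noise_at_zero = FALSE) {
  stopifnot(inherits(params, "degradation_params"))
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  vc <- params$varcomp
  units <- unique(design$unit_id)
  theta <- setNames(rnorm(length(units), 0, vc$omega1), units)
  eta <- setNames(rnorm(length(units), 0, vc$omega2), units)
  k <- .kdeg_rows(params$fixed, design)
  eps <- rnorm(nrow(design), 0, vc$sigma)
  lr <- params$fixed$mu + theta[design$unit_id] - k * design$time_h +
    eta[design$unit_id] * design$time_h + eps
  out <- design
  out$ratio <- exp(unname(lr))
  if (!noise_at_zero) out$ratio[out$time_h == 0] <- 1
  if (missing_rate > 0) {
    drop <- out$time_h > 0 & runif(nrow(out)) < missing_rate
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a stability dataset to tidy CSV
#'
#' @param x stability data.frame (`brand`, `temperature_C`,
#'   `conc_g_per_48mL`, `time_h`, `ratio`, `unit_id`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(x, path) {
  cols <- c("brand", "temperature_C", "conc_g_per_48mL", "time_h", "ratio", "unit_id")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
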