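# Model ladder: covariate_set 1 = time only, 2 = + temperature, 3 = +
# infusion concentration (final model), 4 = + brand. All covariates act on
# the time slope (the degradation rate constant), never as main effects.
.ladder_formula <- function(covariate_set, re_correlation = TRUE) {
  rhs <- "time_h"
  if (covariate_set >= 2) rhs <- c(rhs, "time_h:temperature")
  if (covariate_set >= 3) rhs <- c(rhs, "time_h:concentration")
  if (covariate_set >= 4) rhs <- c(rhs, "time_h:brand")
  re <- if (re_correlation) "(1 + time_h | unit_id)" else "(1 + time_h || unit_id)"
  as.formula(paste("log_ratio ~", paste(c(rhs, re), collapse = " + ")))
}

.prepare_fit_data <- function(records) {
  d <- data.frame(
    log_ratio = log(records$ratio),
    time_h = records$time_h,
    temperature = factor(records$temperature_C,
                         levels = sort(unique(records$temperature_C))),
    concentration = factor(records$conc_g_per_48mL,
                           levels = sort(unique(records$conc_g_per_48mL))),
    brand = factor(records$brand, levels = sort(unique(records$brand))),
    unit_id = factor(records$unit_id),
    stringsAsFactors = FALSE
  )
  d
}

.fit_lmer <- function(d, covariate_set, re_correlation = TRUE) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(.ladder_formula(covariate_set, re_correlation), data = d,
               REML = FALSE, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  list(fit = fit, messages = msgs)
}

# fixed effects on the kdeg scale (slopes negated so rate constants are
# positive), with reference levels mapped to exactly 0
.kdeg_scale_fixed <- function(fit, d, covariate_set) {
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  pick <- function(levels, prefix) {
    est <- setNames(numeric(length(levels)), levels)
    s <- setNames(rep(NA_real_, length(levels)), levels)
    for (lv in levels[-1]) {
      nm <- paste0("time_h:", prefix, lv)
      if (!nm %in% names(fe)) stop("coefficient not found: ", nm)
      est[lv] <- -fe[[nm]]
      s[lv] <- se[[nm]]
    }
    list(est = est, se = s)
  }
  out <- list(
    mu = unname(fe[["(Intercept)"]]),
    beta0 = -unname(fe[["time_h"]]),
    beta1 = NULL, beta2 = NULL, beta3 = NULL
  )
  se_out <- list(mu = unname(se[["(Intercept)"]]), beta0 = unname(se[["time_h"]]))
  if (covariate_set >= 2) {
    p <- pick(levels(d$temperature), "temperature")
    out$beta1 <- p$est; se_out$beta1 <- p$se
  }
  if (covariate_set >= 3) {
    p <- pick(levels(d$concentration), "concentration")
    out$beta2 <- p$est; se_out$beta2 <- p$se
  }
  if (covariate_set >= 4) {
    p <- pick(levels(d$brand), "brand")
    out$beta3 <- p$est; se_out$beta3 <- p$se
  }
  list(fixed = out, se = se_out)
}

#' Fit a mixed-effects first-order degradation model
#'
#' Fits, by maximum likelihood, the linear mixed-effects model
#' \deqn{\log(C/C_0) = \mu + \theta_i - (\beta_0 + \beta_1[T] + \beta_2[C_{infu}] + \beta_3[B])\,t + \eta_i t + \epsilon}
#' on stability measurements, where the experimental unit i is one prepared
#' bottle (one brand x temperature x concentration run) carrying a random
#' intercept and a random time slope. `covariate_set` selects the model
#' ladder rung: 1 fits time only, 2 adds temperature increments to the slope,
#' 3 adds infusion-concentration increments (the final model), and 4 adds
#' brand increments. ML (not REML) is used throughout so that information
#' criteria and likelihood-ratio tests are comparable across the ladder.
#'
#' Slope coefficients are reported on the degradation-rate scale (negated),
#' so `beta0` is the rate constant (1/h) at the reference condition (lowest
#' temperature and concentration levels) and the increments are additive.
#'
#' @param records stability data.frame as returned by [simulate_stability()]
#'   or [read_stability_data()].
#' @param covariate_set integer 1-4, see above.
#' @param re_correlation logical; allow correlation between the random
#'   intercept and random slope (default TRUE).
#' @return object of class `degradation_fit` with elements `fixed` (kdeg-scale
#'   fixed effects), `se`, `varcomp` (`omega1`, `omega2`, `re_corr`, `sigma`),
#'   `logLik`, `n_par`, `AIC`, `BIC`, `deviance`, `conditional_modes`,
#'   `converged`, `singular`, the underlying `model` (a `merMod`) and `data`.
#' @examples
#' x <- simulate_stability(stability_design(), missing_rate = 0, seed = 42)
#' fit <- fit_degradation(x, covariate_set = 3)
#' fit$fixed$beta0
#' @export
fit_degradation <- function(records, covariate_set = 3, re_correlation = TRUE) {
  stopifnot(covariate_set %in% 1:4)
  records <- .validate_stability(records, source = "records")
  d <- .prepare_fit_data(records)
  if (nlevels(d$unit_id) < 2) stop("need at least 2 experimental units")
  need <- c(if (covariate_set >= 2) "temperature",
            if (covariate_set >= 3) "concentration",
            if (covariate_set >= 4) "brand")
  for (f in need) {
    if (nlevels(droplevels(d[[f]])) < 2) {
      stop("factor '", f, "' has fewer than 2 observed levels; cannot form contrasts")
    }
  }
  res <- .fit_lmer(d, covariate_set, re_correlation)
  fit <- res$fit
  conv_msgs <- c(res$messages, unlist(fit@optinfo$conv$lme4$messages))
  ll <- logLik(fit)
  vc <- lme4::VarCorr(fit)$unit_id
  re <- lme4::ranef(fit)$unit_id
  ks <- .kdeg_scale_fixed(fit, d, covariate_set)
  structure(
    list(
      covariate_set = covariate_set,
      fixed = ks$fixed,
      se = ks$se,
      varcomp = list(
        omega1 = sqrt(vc[1, 1]),
        omega2 = sqrt(vc[2, 2]),
        re_corr = if (re_correlation) attr(vc, "correlation")[1, 2] else 0,
        sigma = stats::sigma(fit)
      ),
      logLik = as.numeric(ll),
      n_par = attr(ll, "df"),
      AIC = AIC(fit),
      BIC = BIC(fit),
      deviance = -2 * as.numeric(ll),
      n = nrow(d),
      n_units = nlevels(d$unit_id),
      conditional_modes = data.frame(
        unit_id = rownames(re),
        theta_hat = re[["(Intercept)"]],
        eta_hat = re[["time_h"]],
        stringsAsFactors = FALSE
      ),
      converged = length(conv_msgs) == 0,
      convergence_messages = conv_msgs,
      singular = lme4::isSingular(fit),
      re_correlation = re_correlation,
      model = fit,
      data = d
    ),
    class = "degradation_fit"
  )
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects degradation fit (covariate set %d, ML, n = %d, units = %d)\n",
              x$covariate_set, x$n, x$n_units))
  cat(sprintf("  beta0 (reference kdeg, 1/h): %.5f\n", x$fixed$beta0))
  if (!is.null(x$fixed$beta1)) {
    cat("  temperature increments:",
        paste(sprintf("%s=%.5f", names(x$fixed$beta1), x$fixed$beta1), collapse = ", "), "\n")
  }
  if (!is.null(x$fixed$beta2)) {
    cat("  concentration increments:",
        paste(sprintf("%s=%.5f", names(x$fixed$beta2), x$fixed$beta2), collapse = ", "), "\n")
  }
  cat(sprintf("  omega1=%.5f omega2=%.5f sigma=%.5f\n",
              x$varcomp$omega1, x$varcomp$omega2, x$varcomp$sigma))
  cat(sprintf("  logLik %.1f  AIC %.1f  BIC %.1f%s%s\n", x$logLik, x$AIC, x$BIC,
              if (!x$converged) "  [convergence flagged]" else "",
              if (x$singular) "  [singular fit]" else ""))
  invisible(x)
}

#' Per-unit conditional modes of the random effects
#'
#' Best linear unbiased predictions of each experimental unit's random
#' intercept (`theta_hat`) and random time slope (`eta_hat`, log-ratio slope
#' scale: the unit-level degradation rate constant is the fixed-effect rate
#' minus `eta_hat`).
#'
#' @param fit a `degradation_fit`.
#' @return data.frame with `unit_id`, `theta_hat`, `eta_hat`.
#' @export
conditional_modes <- function(fit) {
  stopifnot(inherits(fit, "degradation_fit"))
  fit$conditional_modes
}

#' Likelihood-ratio comparison of a nested model ladder
#'
#' Compares consecutive models fitted by ML on the same records: the test
#' statistic is the deviance difference, degrees of freedom the difference in
#' parameter counts, and the p-value from the chi-squared distribution.
#'
#' @param fits list of `degradation_fit` objects, nested in increasing order.
#' @return data.frame with one row per model: `model`, `n_par`, `AIC`, `BIC`,
#'   `logLik`, `deviance`, `Chisq`, `Df`, `p_value` (first row NA for the
#'   test columns; a zero-df comparison yields `Chisq = 0`, `p_value = NA`).
#' @examples
#' x <- simulate_stability(stability_design(), missing_rate = 0, seed = 42)
#' fits <- lapply(1:3, function(m) fit_degradation(x, m))
#' likelihood_ratio_table(fits)
#' @export
likelihood_ratio_table <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "degradation_fit")))
  n <- vapply(fits, `[[`, 0, "n")
  if (length(unique(n)) != 1) {
    stop("models were fitted on differing record counts: ",
         paste(n, collapse = ", "))
  }
  out <- data.frame(
    model = paste0("Model ", vapply(fits, `[[`, 0, "covariate_set")),
    n_par = vapply(fits, `[[`, 0, "n_par"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    deviance = vapply(fits, `[[`, 0, "deviance"),
    Chisq = NA_real_, Df = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  if (length(fits) > 1) {
    for (i in 2:length(fits)) {
      chisq <- out$deviance[i - 1] - out$deviance[i]
      df <- out$n_par[i] - out$n_par[i - 1]
      out$Chisq[i] <- chisq
      out$Df[i] <- df
      out$p_value[i] <- if (df > 0) pchisq(max(chisq, 0), df, lower.tail = FALSE) else NA_real_
    }
  }
  out
}

# flat named parameter vector used by the bootstrap
.param_vector <- function(fit) {
  v <- c(mu = fit$fixed$mu, beta0 = fit$fixed$beta0)
  add <- function(v, inc, prefix) {
    if (is.null(inc)) return(v)
    for (lv in names(inc)[-1]) v[paste0(prefix, "_", lv)] <- inc[[lv]]
    v
  }
  v <- add(v, fit$fixed$beta1, "temp")
  v <- add(v, fit$fixed$beta2, "conc")
  v <- add(v, fit$fixed$beta3, "brand")
  c(v, omega1 = fit$varcomp$omega1, omega2 = fit$varcomp$omega2,
    sigma = fit$varcomp$sigma)
}

#' Parametric bootstrap confidence intervals for a degradation fit
#'
#' For each iteration a new response vector is simulated from the fitted
#' model (new random effects and residuals on the observed design), a
#' without-replacement subsample of `sample_size` rows is taken, and the
#' model is refitted; interval bounds are the percentile quantiles of the
#' successful refits. Iterations whose refit errors or fails to converge are
#' dropped and counted.
#'
#' @param fit a `degradation_fit`.
#' @param n_iter number of bootstrap iterations (>= 1).
#' @param sample_size rows retained per iteration; defaults to all rows.
#' @param seed optional integer seed for reproducibility.
#' @param level confidence level (default 0.95).
#' @return data.frame with `parameter`, `estimate`, `lower`, `upper`; the
#'   number of successful iterations is attached as attribute `n_success`.
#' @export
bootstrap_intervals <- function(fit, n_iter = 500, sample_size = NULL,
                                seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "degradation_fit"), n_iter >= 1)
  if (is.null(sample_size)) sample_size <- fit$n
  if (sample_size > fit$n) stop("sample_size exceeds the available rows (", fit$n, ")")
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate(fit$model, nsim = n_iter)
  draws <- vector("list", n_iter)
  n_fail <- 0L
  for (i in seq_len(n_iter)) {
    dd <- fit$data
    dd$log_ratio <- sims[[i]]
    idx <- sample.int(fit$n, sample_size)
    draws[[i]] <- tryCatch({
      res <- .fit_lmer(dd[idx, , drop = FALSE], fit$covariate_set, fit$re_correlation)
      refit <- res$fit
      ks <- .kdeg_scale_fixed(refit, dd[idx, , drop = FALSE], fit$covariate_set)
      vc <- lme4::VarCorr(refit)$unit_id
      .param_vector(list(
        fixed = ks$fixed,
        varcomp = list(omega1 = sqrt(vc[1, 1]), omega2 = sqrt(vc[2, 2]),
                       sigma = stats::sigma(refit))
      ))
    }, error = function(e) NULL)
    if (is.null(draws[[i]])) n_fail <- n_fail + 1L
  }
  draws <- draws[!vapply(draws, is.null, TRUE)]
  if (!length(draws)) stop("all bootstrap iterations failed")
  mat <- do.call(rbind, draws)
  alpha <- (1 - level) / 2
  est <- .param_vector(fit)
  out <- data.frame(
    parameter = colnames(mat),
    estimate = unname(est[colnames(mat)]),
    lower = apply(mat, 2, quantile, probs = alpha, names = FALSE),
    upper = apply(mat, 2, quantile, probs = 1 - alpha, names = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_success") <- nrow(mat)
  attr(out, "n_failed") <- n_fail
  out
}

#' Coefficient table for a degradation fit
#'
#' Fixed effects on the degradation-rate scale with standard errors and Wald
#' p-values, followed by the variance components. If a bootstrap table from
#' [bootstrap_intervals()] is supplied its percentile intervals are merged in.
#'
#' @param fit a `degradation_fit`.
#' @param bootstrap optional output of [bootstrap_intervals()].
#' @return data.frame with `parameter`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
estimates_table <- function(fit, bootstrap = NULL) {
  stopifnot(inherits(fit, "degradation_fit"))
  est <- .param_vector(fit)
  se <- c(mu = fit$se$mu, beta0 = fit$se$beta0)
  add_se <- function(se, ses, prefix) {
    if (is.null(ses)) return(se)
    for (lv in names(ses)[-1]) se[paste0(prefix, "_", lv)] <- ses[[lv]]
    se
  }
  se <- add_se(se, fit$se$beta1, "temp")
  se <- add_se(se, fit$se$beta2, "conc")
  se <- add_se(se, fit$se$beta3, "brand")
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(se[names(est)]), stringsAsFactors = FALSE)
  out$p_value <- ifelse(is.na(out$se), NA_real_,
                        2 * pnorm(-abs(out$estimate / out$se)))
  out$ci_lower <- NA_real_
  out$ci_upper <- NA_real_
  if (!is.null(bootstrap)) {
    m <- match(out$parameter, bootstrap$parameter)
    out$ci_lower <- bootstrap$lower[m]
    out$ci_upper <- bootstrap$upper[m]
  }
  out[, c("parameter", "estimate", "se", "ci_lower", "ci_upper", "p_value")]
}

#' Degradation rate constant for a storage condition
#'
#' Adds up the fixed-effect slope contributions for the requested temperature
#' and infusion concentration (plus brand if the model includes brand
#' effects, plus the unit-level conditional-mode adjustment if `unit` is
#' given). Levels outside the fitted/specified factor space are an error:
#' the model never extrapolates.
#'
#' @param object a `degradation_fit` or `degradation_params`.
#' @param temperature storage temperature level (degrees C).
#' @param concentration infusion concentration level (g/48 mL).
#' @param brand optional brand code; only valid when the model includes
#'   brand effects.
#' @param unit optional unit id; adds the unit's conditional-mode slope
#'   deviation (fits only).
#' @return degradation rate constant (1/h). A negative value triggers a
#'   warning (physically implausible inside the studied factor space).
#' @examples
#' kdeg_for_condition(degradation_truth(), 37, 2)  # 0.0313
#' @export
kdeg_for_condition <- function(object, temperature, concentration,
                               brand = NULL, unit = NULL) {
  UseMethod("kdeg_for_condition")
}

.kdeg_from_fixed <- function(fixed, temperature, concentration, brand) {
  tl <- as.character(temperature)
  cl <- as.character(concentration)
  if (is.null(fixed$beta1) && !is.null(fixed$beta2)) {
    stop("model has no temperature term") # ladder guarantees order; defensive
  }
  k <- fixed$beta0
  if (!is.null(fixed$beta1)) {
    if (!tl %in% names(fixed$beta1)) {
      stop("temperature level ", tl, " was not in the model; no extrapolation")
    }
    k <- k + fixed$beta1[[tl]]
  } else if (!missing(temperature)) {
    # time-only model: condition arguments accepted but carry no increments
    k <- k
  }
  if (!is.null(fixed$beta2)) {
    if (!cl %in% names(fixed$beta2)) {
      stop("concentration level ", cl, " was not in the model; no extrapolation")
    }
    k <- k + fixed$beta2[[cl]]
  }
  if (!is.null(brand)) {
    if (is.null(fixed$beta3)) {
      stop("brand effects are not part of this model; drop `brand` or fit covariate set 4")
    }
    if (!as.character(brand) %in% names(fixed$beta3)) {
      stop("brand level ", brand, " was not in the model; no extrapolation")
    }
    k <- k + fixed$beta3[[as.character(brand)]]
  }
  k
}

#' @rdname kdeg_for_condition
#' @export
kdeg_for_condition.degradation_params <- function(object, temperature,
                                                  concentration, brand = NULL,
                                                  unit = NULL) {
  if (!is.null(unit)) stop("unit-level prediction requires a fitted model")
  k <- .kdeg_from_fixed(object$fixed, temperature, concentration, brand)
  if (k < 0) warning("negative degradation rate constant (", signif(k, 4),
                     " 1/h): physically implausible", call. = FALSE)
  unname(k)
}

#' @rdname kdeg_for_condition
#' @export
kdeg_for_condition.degradation_fit <- function(object, temperature,
                                               concentration, brand = NULL,
                                               unit = NULL) {
  k <- .kdeg_from_fixed(object$fixed, temperature, concentration, brand)
  if (!is.null(unit)) {
    cm <- object$conditional_modes
    i <- match(as.character(unit), cm$unit_id)
    if (is.na(i)) stop("unknown unit id: ", unit)
    k <- k - cm$eta_hat[i]  # fitted slope = -(kdeg) + eta
  }
  if (k < 0) warning("negative degradation rate constant (", signif(k, 4),
                     " 1/h): physically implausible", call. = FALSE)
  unname(k)
}

#' Remaining fraction under first-order degradation
#'
#' Fraction of the initial concentration remaining after `t` hours in the
#' bottle: `exp(-kdeg * t)`.
#'
#' @param kdeg degradation rate constant (1/h), >= 0.
#' @param t time in hours, >= 0. Vectorized over both arguments.
#' @return fraction in (0, 1].
#' @examples
#' remaining_fraction(0.0313, 8)  # ~0.779: below 80% after 8 h at 37C, 2 g/48 mL
#' @export
remaining_fraction <- function(kdeg, t) {
  if (any(kdeg < 0)) stop("kdeg must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  exp(-kdeg * t)
}
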