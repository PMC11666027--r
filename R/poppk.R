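#' Population-PK parameter set for the two-compartment infusion model
#'
#' Container for the typical disposition parameters, covariate model and
#' variability terms of a linear two-compartment model with zero-order
#' (degradation-modified) infusion input. Clearance scales with creatinine
#' clearance as a power function around the reference covariate vector and
#' the central volume proportionally with body weight; albumin is carried as
#' a covariate slot but has no effect in this default functional form.
#'
#' @param cl typical total clearance (L/h) at the reference covariates.
#' @param vc typical central volume (L) at the reference weight.
#' @param vp typical peripheral volume (L).
#' @param q typical inter-compartmental clearance (L/h).
#' @param cl_clcr_exponent exponent of the power covariate model
#'   `Cl = cl * (Clcr/ref)^exponent`.
#' @param vc_weight_proportional logical; scale Vc linearly with weight.
#' @param iiv_cv named list/vector of inter-individual variability CVs in
#'   percent for `cl`, `vc`, `vp`.
#' @param iov_cv_cl inter-occasion variability CV (percent) on clearance; one
#'   occasion is one dosing interval.
#' @param reference named list of reference covariates: `clcr` (mL/min),
#'   `weight` (kg), `albumin` (g/dL).
#' @param free_fraction unbound fraction in (0, 1] used when comparing
#'   concentrations with the MIC (default 1: total drug).
#' @param clcr_range default uniform sampling range (mL/min) for creatinine
#'   clearance in Monte Carlo simulation.
#' @param lognormal_convention `"exact"` (log-scale SD
#'   `sqrt(log(1 + CV^2))`) or `"approx"` (log-scale SD = CV).
#' @return object of class `poppk`.
#' @export
poppk_parameters <- function(cl = 12.0, vc = 10.8, vp = 12.6, q = 18.6,
                             cl_clcr_exponent = 0.62,
                             vc_weight_proportional = TRUE,
                             iiv_cv = c(cl = 27.1, vc = 31.5, vp = 16.9),
                             iov_cv_cl = 12.5,
                             reference = list(clcr = 80.8, weight = 70,
                                              albumin = 2.8),
                             free_fraction = 1.0,
                             clcr_range = c(30, 160),
                             lognormal_convention = c("exact", "approx")) {
  lognormal_convention <- match.arg(lognormal_convention)
  if (any(c(cl, vc, vp) <= 0) || q < 0) stop("volumes and clearances must be positive (q >= 0)")
  iiv_cv <- unlist(iiv_cv)
  if (!all(c("cl", "vc", "vp") %in% names(iiv_cv))) {
    stop("iiv_cv must name cl, vc and vp")
  }
  if (any(iiv_cv < 0) || iov_cv_cl < 0) stop("CVs must be >= 0")
  if (free_fraction <= 0 || free_fraction > 1) stop("free_fraction must be in (0, 1]")
  structure(
    list(cl = cl, vc = vc, vp = vp, q = q,
         cl_clcr_exponent = cl_clcr_exponent,
         vc_weight_proportional = isTRUE(vc_weight_proportional),
         iiv_cv = iiv_cv[c("cl", "vc", "vp")],
         iov_cv_cl = iov_cv_cl,
         reference = reference,
         free_fraction = free_fraction,
         clcr_range = as.numeric(clcr_range),
         lognormal_convention = lognormal_convention),
    class = "poppk"
  )
}

#' @export
print.poppk <- function(x, ...) {
  cat("Two-compartment population-PK parameters\n")
  cat(sprintf("  typical: Cl %.2f L/h, Vc %.1f L, Vp %.1f L, Q %.1f L/h\n",
              x$cl, x$vc, x$vp, x$q))
  cat(sprintf("  covariates: Cl ~ (Clcr/%.1f)^%.2f%s\n", x$reference$clcr,
              x$cl_clcr_exponent,
              if (x$vc_weight_proportional) sprintf(", Vc ~ weight/%.0f", x$reference$weight) else ""))
  cat(sprintf("  IIV CV%%: Cl %.1f, Vc %.1f, Vp %.1f; IOV CV%% (Cl): %.1f [%s]\n",
              x$iiv_cv[["cl"]], x$iiv_cv[["vc"]], x$iiv_cv[["vp"]],
              x$iov_cv_cl, x$lognormal_convention))
  cat(sprintf("  free fraction %.2f; default Clcr range %g-%g mL/min\n",
              x$free_fraction, x$clcr_range[1], x$clcr_range[2]))
  invisible(x)
}

#' Read a population-PK configuration file
#'
#' Loads a YAML file into a [poppk_parameters()] object. The package ships a
#' default at `system.file("extdata", "poppk-meropenem-synthetic.yaml",
#' package = "meropta")` whose typical values are literature-informed
#' synthetic stand-ins for a critically ill meropenem population; review them
#' before drawing clinical conclusions.
#'
#' @param path YAML file path; defaults to the shipped configuration.
#' @return object of class `poppk`.
#' @export
read_poppk_config <- function(path = system.file("extdata",
                                                 "poppk-meropenem-synthetic.yaml",
                                                 package = "meropta")) {
  if (!file.exists(path)) stop("popPK config not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("typical", "covariates", "variability")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("popPK config missing section(s): ", paste(miss, collapse = ", "))
  poppk_parameters(
    cl = y$typical$cl_l_per_h,
    vc = y$typical$vc_l,
    vp = y$typical$vp_l,
    q = y$typical$q_l_per_h,
    cl_clcr_exponent = y$covariates$cl_clcr_exponent,
    vc_weight_proportional = isTRUE(y$covariates$vc_weight_proportional),
    iiv_cv = c(cl = y$variability$iiv_cv_percent$cl,
               vc = y$variability$iiv_cv_percent$vc,
               vp = y$variability$iiv_cv_percent$vp),
    iov_cv_cl = y$variability$iov_cv_percent_cl,
    reference = list(clcr = y$covariates$reference$clcr_ml_min,
                     weight = y$covariates$reference$weight_kg,
                     albumin = y$covariates$reference$albumin_g_dl),
    free_fraction = if (is.null(y$free_fraction)) 1.0 else y$free_fraction,
    clcr_range = if (is.null(y$clcr_uniform_range_ml_min)) c(30, 160)
                 else unlist(y$clcr_uniform_range_ml_min),
    lognormal_convention = if (is.null(y$variability$lognormal_convention)) "exact"
                           else y$variability$lognormal_convention
  )
}

#' Covariate-adjusted typical parameters for one patient
#'
#' Evaluates the covariate model at the patient's creatinine clearance,
#' weight and albumin: at the reference covariates the population typical
#' values are returned unchanged.
#'
#' @param poppk a `poppk` object.
#' @param covariates named list with `clcr` (mL/min), `weight` (kg) and
#'   `albumin` (g/dL); all must be positive.
#' @return list with `cl`, `vc`, `vp`, `q` (the patient's typical values).
#' @examples
#' p <- poppk_parameters()
#' apply_covariates(p, list(clcr = 80.8, weight = 70, albumin = 2.8))
#' @export
apply_covariates <- function(poppk, covariates) {
  stopifnot(inherits(poppk, "poppk"))
  for (nm in c("clcr", "weight", "albumin")) {
    if (is.null(covariates[[nm]])) stop("missing required covariate: ", nm)
    if (any(covariates[[nm]] <= 0)) stop("covariate '", nm, "' must be positive")
  }
  cl <- poppk$cl * (covariates$clcr / poppk$reference$clcr)^poppk$cl_clcr_exponent
  vc <- if (poppk$vc_weight_proportional) {
    poppk$vc * (covariates$weight / poppk$reference$weight)
  } else poppk$vc
  list(cl = cl, vc = vc, vp = poppk$vp + 0 * cl, q = poppk$q + 0 * cl)
}

# log-scale SD for a CV given in percent
.lnorm_sd <- function(cv_percent, convention) {
  cv <- cv_percent / 100
  if (convention == "exact") sqrt(log(1 + cv^2)) else cv
}
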