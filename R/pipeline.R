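# degradation_params from a config list (NULL fields fall back to the
# package reference values)
.params_from_config <- function(x) {
  if (is.null(x)) return(degradation_truth())
  ref <- degradation_truth()
  as_inc <- function(v, fallback) {
    if (is.null(v)) return(fallback)
    setNames(as.numeric(unlist(v)), names(unlist(v)))
  }
  degradation_params(
    mu = if (is.null(x$mu)) ref$fixed$mu else x$mu,
    beta0 = if (is.null(x$beta0)) ref$fixed$beta0 else x$beta0,
    beta1 = as_inc(x$beta1, ref$fixed$beta1),
    beta2 = as_inc(x$beta2, ref$fixed$beta2),
    beta3 = if (is.null(x$beta3)) NULL else as_inc(x$beta3, NULL),
    omega1 = if (is.null(x$omega1)) ref$varcomp$omega1 else x$omega1,
    omega2 = if (is.null(x$omega2)) ref$varcomp$omega2 else x$omega2,
    sigma = if (is.null(x$sigma)) ref$varcomp$sigma else x$sigma
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full degradation-to-PTA pipeline
#'
#' Executes the analysis end to end: obtain stability data (from file or the
#' synthetic generator), fit the mixed-effects model ladder and select the
#' final model, tabulate degradation rate constants per condition, compute
#' steady-state trough ratios and day-one PTA scenarios with the
#' population-PK model, and write every table as CSV plus a JSON manifest
#' (inputs, seeds, versions, row counts). Any stage failure aborts with the
#' stage name.
#'
#' @param config a nested list or path to a YAML file. Recognised blocks:
#'   `seed` (required), `stability` (`file` path, or `synthetic` block with
#'   optional `brands`, `temperatures`, `concentrations`, `times`,
#'   `missing_rate`, `noise_at_zero`, `truth` overrides), `models` (ladder
#'   rungs to fit, default 1:4), `final_model` (default 3), `bootstrap`
#'   (`n_iter`, `sample_size`), `poppk` (YAML path; default the shipped
#'   configuration), `cmin_ratio` (`renewal_h`, `dose_mg`), `profiles`
#'   (`dose_mg`, `renewal_h`, `horizon_h`), and `pta` (see
#'   [pta_scenario_grid()]; `model` and `poppk` are filled in automatically).
#' @param out_dir output directory, created if needed.
#' @return the manifest, invisibly (a list; also written to manifest.json).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set an explicit `seed`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "meropta",
    package_version = as.character(utils::packageVersion("meropta")),
    r_version = R.version.string,
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tables = list(), notes = list()
  )
  wr <- function(x, name) {
    path <- file.path(out_dir, name)
    write.csv(x, path, row.names = FALSE)
    manifest$tables[[name]] <<- nrow(x)
    message(sprintf("[%s] wrote %s (%d rows)", "meropta", name, nrow(x)))
    x
  }

  # -- stage 1: stability data ------------------------------------------
  stab <- .stage("stability-data", {
    sc <- config$stability
    if (!is.null(sc$file)) {
      read_stability_data(sc$file)
    } else {
      sy <- if (is.null(sc$synthetic)) list() else sc$synthetic
      design <- stability_design(
        brands = if (is.null(sy$brands)) c("A", "E", "I", "Q", "R", "V", "X") else sy$brands,
        temperatures = if (is.null(sy$temperatures)) c(25, 30, 37) else sy$temperatures,
        concentrations = if (is.null(sy$concentrations)) c(1, 2) else sy$concentrations,
        times = if (is.null(sy$times)) 0:8 else sy$times
      )
      simulate_stability(
        design, params = .params_from_config(sy$truth),
        missing_rate = if (is.null(sy$missing_rate)) 13 / 336 else sy$missing_rate,
        seed = config$seed,
        noise_at_zero = isTRUE(sy$noise_at_zero)
      )
    }
  })
  wr(stab, "stability_data.csv")
  manifest$notes$n_stability_rows <- nrow(stab)

  # -- stage 2: model ladder --------------------------------------------
  models <- if (is.null(config$models)) 1:4 else config$models
  final_set <- if (is.null(config$final_model)) 3 else config$final_model
  fits <- .stage("fit-ladder", lapply(models, function(m) fit_degradation(stab, m)))
  names(fits) <- paste0("model", models)
  wr(likelihood_ratio_table(fits), "model_comparison.csv")
  final <- fits[[paste0("model", final_set)]]
  if (is.null(final)) final <- .stage("fit-final", fit_degradation(stab, final_set))
  boot <- NULL
  nb <- if (is.null(config$bootstrap$n_iter)) 0 else config$bootstrap$n_iter
  if (nb > 0) {
    boot <- .stage("bootstrap", bootstrap_intervals(
      final, n_iter = nb, sample_size = config$bootstrap$sample_size,
      seed = config$seed + 1
    ))
    wr(boot, "bootstrap_ci.csv")
  }
  wr(estimates_table(final, boot), "estimates.csv")
  wr(conditional_modes(final), "conditional_modes.csv")

  # -- stage 3: degradation rate constants ------------------------------
  kdeg_tab <- .stage("kdeg-table", {
    lv1 <- names(final$fixed$beta1)
    lv2 <- names(final$fixed$beta2)
    if (is.null(lv1) || is.null(lv2)) {
      stop("final model must include temperature and concentration (covariate set >= 3)")
    }
    g <- expand.grid(temperature_C = as.numeric(lv1),
                     conc_g_per_48mL = as.numeric(lv2))
    g$kdeg_h <- mapply(function(tp, cn) kdeg_for_condition(final, tp, cn),
                       g$temperature_C, g$conc_g_per_48mL)
    g$remaining_8h <- remaining_fraction(pmax(g$kdeg_h, 0), 8)
    g
  })
  wr(kdeg_tab, "kdeg.csv")

  poppk <- .stage("poppk-config", {
    if (is.null(config$poppk)) read_poppk_config() else read_poppk_config(config$poppk)
  })
  typical <- apply_covariates(poppk, poppk$reference[c("clcr", "weight", "albumin")])

  # -- stage 4: steady-state trough ratios ------------------------------
  if (!isFALSE(config$cmin_ratio$enabled)) {
    cm <- .stage("cmin-ratio", {
      renews <- if (is.null(config$cmin_ratio$renewal_h)) c(3, 6, 8) else config$cmin_ratio$renewal_h
      dose <- if (is.null(config$cmin_ratio$dose_mg)) 1000 else config$cmin_ratio$dose_mg
      g <- merge(kdeg_tab[, c("temperature_C", "conc_g_per_48mL", "kdeg_h")],
                 data.frame(renewal_h = renews))
      g$cmin_ratio <- mapply(function(k, rn) {
        steady_state_cmin_ratio(ci_regimen(dose, rn), kdeg = max(k, 0),
                                pars = typical)
      }, g$kdeg_h, g$renewal_h)
      g$decline_pct <- 100 * (1 - g$cmin_ratio)
      g
    })
    wr(cm, "cmin_ratio.csv")
  }

  # -- stage 5: typical-patient profiles --------------------------------
  prof_tab <- .stage("typical-profiles", {
    pc <- config$profiles
    dose <- if (is.null(pc$dose_mg)) 1000 else pc$dose_mg
    rn <- if (is.null(pc$renewal_h)) 8 else pc$renewal_h
    horizon <- if (is.null(pc$horizon_h)) 24 else pc$horizon_h
    reg <- ci_regimen(dose, rn)
    conds <- rbind(data.frame(label = "no degradation", kdeg = 0),
                   data.frame(label = sprintf("%gC, %g g/48mL",
                                              kdeg_tab$temperature_C,
                                              kdeg_tab$conc_g_per_48mL),
                              kdeg = pmax(kdeg_tab$kdeg_h, 0)))
    do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
      ev <- build_infusion_schedule(reg, horizon, conds$kdeg[i])
      pr <- simulate_profile(typical, ev, horizon)
      data.frame(condition = conds$label[i], kdeg_h = conds$kdeg[i],
                 time_h = pr$time_h, conc_mg_L = pr$conc_mg_L)
    }))
  })
  wr(prof_tab, "typical_profiles.csv")

  # -- stage 6: PTA scenario grid ---------------------------------------
  if (!is.null(config$pta)) {
    pta <- .stage("pta-grid", {
      pcfg <- config$pta
      pcfg$model <- final
      pcfg$poppk <- poppk
      if (is.null(pcfg$seed)) pcfg$seed <- config$seed + 100
      pta_scenario_grid(pcfg)
    })
    wr(pta, "pta_grid.csv")
  }

  manifest$config <- config
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.need_table <- function(out_dir, name) {
  path <- file.path(out_dir, name)
  if (!file.exists(path)) stop(name, " missing from ", out_dir)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Render figures from a pipeline output directory
#'
#' Builds ggplot objects from the CSV tables written by [run_pipeline()]:
#' decay curves per storage condition with the fitted exponential overlaid,
#' the typical-patient concentration profiles, PTA versus MIC, PTA versus
#' renal function, and the banded dose x renewal grid. Reports are views of
#' the written tables: every plotted number comes from a CSV. A missing
#' upstream table is an error naming it.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param which character vector of figures to build; default all of
#'   `"decay"`, `"profiles"`, `"pta_mic"`, `"pta_clcr"`, `"dose_grid"`.
#' @return named list of ggplot objects.
#' @export
render_reports <- function(out_dir, which = c("decay", "profiles", "pta_mic",
                                              "pta_clcr", "dose_grid")) {
  plots <- list()
  band_cols <- c("<50" = "#d73027", "50-80" = "#fc8d59",
                 "80-90" = "#fee08b", ">=90" = "#1a9850")
  if ("decay" %in% which) {
    stab <- .need_table(out_dir, "stability_data.csv")
    kd <- .need_table(out_dir, "kdeg.csv")
    tgrid <- seq(0, max(stab$time_h), length.out = 81)
    fitcurves <- do.call(rbind, lapply(seq_len(nrow(kd)), function(i) {
      data.frame(temperature_C = kd$temperature_C[i],
                 conc_g_per_48mL = kd$conc_g_per_48mL[i],
                 time_h = tgrid,
                 ratio = remaining_fraction(max(kd$kdeg_h[i], 0), tgrid))
    }))
    plots$decay <- ggplot2::ggplot(stab,
        ggplot2::aes(x = .data$time_h, y = .data$ratio)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$brand), alpha = 0.6, size = 1) +
      ggplot2::geom_line(data = fitcurves, linewidth = 0.7) +
      ggplot2::facet_grid(conc_g_per_48mL ~ temperature_C,
                          labeller = ggplot2::label_both) +
      ggplot2::labs(x = "time in bottle (h)", y = "C/C0",
                    title = "Meropenem in-bottle degradation with fitted first-order decay") +
      ggplot2::theme_bw()
  }
  if ("profiles" %in% which) {
    pr <- .need_table(out_dir, "typical_profiles.csv")
    plots$profiles <- ggplot2::ggplot(pr,
        ggplot2::aes(x = .data$time_h, y = .data$conc_mg_L,
                     colour = .data$condition)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "concentration (mg/L)",
                    title = "Typical-patient profiles under in-bottle degradation") +
      ggplot2::theme_bw()
  }
  if ("pta_mic" %in% which || "pta_clcr" %in% which || "dose_grid" %in% which) {
    pta <- .need_table(out_dir, "pta_grid.csv")
    pta$condition <- ifelse(is.na(pta$temperature_C), "no degradation",
                            paste0(pta$temperature_C, "C"))
    if ("pta_mic" %in% which) {
      plots$pta_mic <- ggplot2::ggplot(pta,
          ggplot2::aes(x = factor(.data$mic_mg_L), y = .data$pta,
                       fill = .data$condition)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::geom_hline(yintercept = 0.9, linetype = 2) +
        ggplot2::facet_grid(daily_dose_g ~ renewal_h,
                            labeller = ggplot2::label_both) +
        ggplot2::labs(x = "MIC (mg/L)", y = "PTA (98% fT>MIC)") +
        ggplot2::theme_bw()
    }
    if ("pta_clcr" %in% which) {
      plots$pta_clcr <- ggplot2::ggplot(pta,
          ggplot2::aes(x = suppressWarnings(as.numeric(.data$clcr_group)),
                       y = .data$pta, colour = .data$condition)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::geom_hline(yintercept = 0.9, linetype = 2) +
        ggplot2::facet_grid(daily_dose_g + renewal_h ~ mic_mg_L,
                            labeller = ggplot2::label_both) +
        ggplot2::labs(x = "creatinine clearance (mL/min)",
                      y = "PTA (98% fT>MIC)") +
        ggplot2::theme_bw()
    }
    if ("dose_grid" %in% which) {
      plots$dose_grid <- ggplot2::ggplot(pta,
          ggplot2::aes(x = factor(.data$renewal_h),
                       y = factor(.data$daily_dose_g), fill = .data$band)) +
        ggplot2::geom_tile(colour = "grey30") +
        ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", 100 * .data$pta)),
                           size = 3) +
        ggplot2::scale_fill_manual(values = band_cols, drop = FALSE) +
        ggplot2::facet_grid(clcr_group ~ condition + mic_mg_L) +
        ggplot2::labs(x = "bottle renewal interval (h)", y = "daily dose (g)",
                      fill = "PTA band (%)") +
        ggplot2::theme_bw()
    }
  }
  plots
}
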