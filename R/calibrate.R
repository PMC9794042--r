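#' Reference NCA summary targets for calibration
#'
#' Published summary statistics for the weekly LNG/EE TDS extended-regimen
#' simulation, used as calibration targets: geometric means of Cmax (pg/mL),
#' AUC(0-168) (h·ng/mL) and Css(48-168) (pg/mL) by week, plus the week-1
#' geometric CV% of AUC(0-168). These are target values only; the fitted
#' model parameters behind them are not public, so the shipped typical values
#' are derived by [calibrate_population()] and labelled as such.
#'
#' @param drug `"EE"` or `"LNG"`.
#' @return a data.frame with columns `week`, `parameter`, `target`, plus an
#'   attribute `auc_geo_cv_pct_week1`.
#' @export
reference_nca_targets <- function(drug = c("EE", "LNG")) {
  drug <- match.arg(drug)
  if (drug == "EE") {
    out <- data.frame(
      week = c(1, 1, 3, 3),
      parameter = c("cmax", "auc_0_168", "cmax", "auc_0_168"),
      target = c(40.8, 5.47, 47.9, 6.42))
    attr(out, "auc_geo_cv_pct_week1") <- 30.3
  } else {
    out <- data.frame(
      week = c(1, 1, 1, 3, 3, 3, 12),
      parameter = c("cmax", "auc_0_168", "css_48_168",
                    "cmax", "auc_0_168", "css_48_168", "auc_0_168"),
      target = c(1420, 192, 1250, 2310, 323, 1840, 326))
    attr(out, "auc_geo_cv_pct_week1") <- 31.6
  }
  out
}

# lean geometric-mean NCA on a matrix of week-window profiles
.geo_nca <- function(pop_theta, regimen, subjects_params, weeks, mode) {
  out <- list()
  for (w in weeks) {
    grid <- (w - 1) * 168 + 0:168
    cmax <- auc <- auc48 <- numeric(length(subjects_params))
    for (i in seq_along(subjects_params)) {
      conc <- .pred_fast(subjects_params[[i]], regimen, grid, mode = mode)
      cmax[i] <- max(conc)
      auc[i] <- auc_lin_up_log_down(grid, conc, grid[1], grid[169])
      auc48[i] <- auc_lin_up_log_down(grid, conc, grid[1] + 48, grid[169])
    }
    out[[as.character(w)]] <- list(
      cmax = exp(mean(log(cmax))), auc_0_168 = exp(mean(log(auc))),
      css_48_168 = exp(mean(log(auc48))) / 120 * 1000,
      auc_geo_cv_pct = 100 * sqrt(exp(stats::sd(log(auc))^2) - 1))
  }
  out
}

#' Calibrate typical values against reference NCA summaries
#'
#' Tunes the typical structural parameters (and, for LNG, the depot infusion
#' duration and week-3 multipliers) so that the simulated geometric-mean NCA
#' parameters of the extended regimen approximate the reference targets.
#' Interindividual variability stays on during calibration (fixed seed), and
#' the week-1 AUC geometric CV% target is matched by a one-dimensional
#' adjustment of the clearance IIV after the typical-value fit. The output is
#' a derived parameterization: it reproduces exposure summaries, not any
#' study's estimated parameters.
#'
#' @param pop0 starting [population_model()].
#' @param targets target data.frame from [reference_nca_targets()].
#' @param n_subjects simulated individuals per objective evaluation.
#' @param seed fixed seed for the calibration draws.
#' @param max_iter optimizer iteration cap.
#' @return a calibrated [population_model()]; attribute `calibration` holds
#'   the achieved targets.
#' @export
calibrate_population <- function(pop0, targets = reference_nca_targets(pop0$drug),
                                 n_subjects = 400, seed = 20221227,
                                 max_iter = 150) {
  stopifnot(inherits(pop0, "population_model"))
  drug <- pop0$drug
  regimen <- weekly_regimen(n_weeks = 12, drug = drug)
  free <- if (drug == "EE") c("CL", "V", "ka", "F_rel") else
    c("CL", "V", "ka", "F_rel", "D2", "wk3_V_mult", "wk3_CL_mult")
  weeks <- sort(unique(targets$week))
  template <- .pop_theta_list(pop0)

  eval_geo <- function(theta_p, omega) {
    pop_i <- pop0
    subs <- lapply(seq_len(n_subjects), function(i) {
      eta <- c(CL = 0, V = 0, ka = 0, F_rel = 0)
      freev <- names(omega)[omega > 0]
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(.subject_seed(seed, i))
      if (length(freev)) eta[freev] <- stats::rnorm(length(freev), 0, omega[freev])
      p <- theta_p
      p$CL <- p$CL * exp(eta[["CL"]]); p$V <- p$V * exp(eta[["V"]])
      p$ka <- p$ka * exp(eta[["ka"]])
      if (p$F_rel > 0 && p$F_rel < 1)
        p$F_rel <- .inv_logit(.logit(theta_p$F_rel) + eta[["F_rel"]])
      p
    })
    .geo_nca(theta_p, regimen, subs, weeks, pop0$week_effect_mode)
  }

  omega <- pop0$omega
  cv_target <- attr(targets, "auc_geo_cv_pct_week1")
  v0 <- .theta_to_vec(template, free)
  # physiological box constraints on the transformed scale: absorption no
  # faster than ka = 2/h, depot filling between 8 h and the wear period,
  # week-3 shifts within a factor of 3
  bound_map <- list(CL = log(c(1e-3, 1e4)), V = log(c(0.1, 1e6)),
                    ka = log(c(1e-4, 2)), F_rel = c(-12, 12),
                    D2 = log(c(8, 168)),
                    wk3_V_mult = log(c(1 / 3, 3)),
                    wk3_CL_mult = log(c(1 / 3, 3)))
  bounds <- list(lower = vapply(free, function(nm) bound_map[[nm]][1], 0),
                 upper = vapply(free, function(nm) bound_map[[nm]][2], 0))
  fit <- NULL
  # alternate: fit theta at current omega, then rescale omega_CL to the week-1
  # AUC geometric CV% (AUC variability is clearance-driven); two passes settle
  for (pass in 1:2) {
    obj <- function(v) {
      theta_p <- .vec_to_params(v, free, NULL, template)
      if (theta_p$F_rel <= 0 || theta_p$F_rel >= 1) return(1e10)
      geo <- eval_geo(theta_p, omega)
      err <- 0
      for (r in seq_len(nrow(targets))) {
        sim <- geo[[as.character(targets$week[r])]][[targets$parameter[r]]]
        if (!is.finite(sim) || sim <= 0) return(1e10)
        err <- err + (log(sim) - log(targets$target[r]))^2
      }
      err
    }
    fit <- stats::nlminb(v0, obj, lower = bounds$lower, upper = bounds$upper,
                         control = list(iter.max = max_iter, rel.tol = 1e-8))
    v0 <- fit$par
    theta_hat <- .vec_to_params(fit$par, free, NULL, template)
    if (is.null(cv_target) || omega[["CL"]] == 0) break
    for (rep in 1:3) {
      geo <- eval_geo(theta_hat, omega)
      cv_sim <- geo[[as.character(weeks[1])]]$auc_geo_cv_pct
      s_target <- sqrt(log(1 + (cv_target / 100)^2))
      s_sim <- sqrt(log(1 + (cv_sim / 100)^2))
      omega[["CL"]] <- omega[["CL"]] * s_target / s_sim
    }
  }
  theta_hat <- .vec_to_params(fit$par, free, NULL, template)

  out <- population_model(.as_dual_route(theta_hat), omega = omega,
                          sigma = pop0$sigma,
                          week_effect_mode = pop0$week_effect_mode)
  attr(out, "calibration") <- list(objective = fit$objective,
                                   convergence = fit$convergence,
                                   achieved = eval_geo(theta_hat, omega))
  out
}
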