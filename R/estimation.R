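#' Model settings for estimation
#'
#' Fixes the constraints shared by all estimators: overall bioavailability F is
#' fixed per drug (0.30 EE, 0.27 LNG) because F and the route split F_rel are
#' not simultaneously identifiable, and the central zero-order duration D1 is
#' fixed at 168 h (the wear period). The LNG depot infusion duration D2 is
#' fixed at its initial value by default and may be freed; the LNG week-3
#' multipliers on V and CL are estimated by default.
#'
#' @param drug `"EE"` or `"LNG"`.
#' @param regimen the dosing [weekly_regimen()] underlying the data.
#' @param estimate_F must remain `FALSE`; asking to free F raises an
#'   identifiability error.
#' @param estimate_D2 free the LNG depot infusion duration (default `FALSE`).
#' @param estimate_week3 free the LNG week-3 V/CL multipliers (default `TRUE`
#'   for LNG).
#' @param blq `"drop"` (default) or `"lloq2"` (substitute LLOQ/2).
#' @param F_total fixed overall bioavailability; drug default if `NULL`.
#' @return an object of class `model_settings`.
#' @export
model_settings <- function(drug = c("EE", "LNG"), regimen,
                           estimate_F = FALSE, estimate_D2 = FALSE,
                           estimate_week3 = NULL,
                           blq = c("drop", "lloq2"), F_total = NULL) {
  drug <- match.arg(drug)
  blq <- match.arg(blq)
  if (isTRUE(estimate_F))
    stop("F and F_rel are not simultaneously identifiable from patch data ",
         "alone; F must stay fixed", call. = FALSE)
  stopifnot(inherits(regimen, "regimen"))
  if (is.null(estimate_week3)) estimate_week3 <- drug == "LNG"
  if (is.null(F_total)) F_total <- c(EE = 0.30, LNG = 0.27)[[drug]]
  theta_free <- c("CL", "V", "ka", "F_rel")
  if (drug == "LNG") {
    if (estimate_D2) theta_free <- c(theta_free, "D2")
    if (estimate_week3) theta_free <- c(theta_free, "wk3_V_mult", "wk3_CL_mult")
  }
  eta_names <- if (drug == "EE") c("CL", "V", "ka") else c("CL", "V", "F_rel")
  structure(list(drug = drug, regimen = regimen, F_total = F_total,
                 theta_free = theta_free, eta_names = eta_names, blq = blq),
            class = "model_settings")
}

# ---- transforms ------------------------------------------------------------

# log for positive parameters, logit for F_rel
.to_trans <- function(name, value) if (name == "F_rel") .logit(value) else log(value)
.from_trans <- function(name, value) if (name == "F_rel") .inv_logit(value) else exp(value)

.theta_to_vec <- function(theta, names) {
  vapply(names, function(nm) .to_trans(nm, theta[[nm]]), numeric(1))
}

.vec_to_params <- function(vec, names, settings, template) {
  p <- template
  for (i in seq_along(names)) p[[names[i]]] <- unname(.from_trans(names[i], vec[i]))
  p$k <- p$CL / p$V
  p
}

# lean parameter template (plain list; no validation in hot loops)
.params_template <- function(settings, init_theta = NULL) {
  if (!is.null(init_theta)) {
    th <- init_theta
  } else if (settings$drug == "EE") {
    th <- list(CL = 100, V = 2000, ka = 0.05, F_total = settings$F_total,
               F_rel = 0.7, D1 = 168, D2 = 0, drug = "EE",
               wk3_V_mult = 1, wk3_CL_mult = 1)
  } else {
    th <- list(CL = 10, V = 400, ka = 0.03, F_total = settings$F_total,
               F_rel = 0.5, D1 = 168, D2 = 96, drug = "LNG",
               wk3_V_mult = 1, wk3_CL_mult = 1)
  }
  th[c("CL", "V", "ka", "F_total", "F_rel", "D1", "D2", "drug",
       "wk3_V_mult", "wk3_CL_mult", if (!is.null(th$k)) "k" else NULL)]
}

# parameter-vector layout shared with the compiled kernel (src/kernels.cpp)
.par_vec <- function(p, mode = "persist") {
  c(p$CL, p$V, p$ka, p$F_total, p$F_rel, p$D1, p$D2,
    as.numeric(p$drug == "LNG"), p$wk3_V_mult, p$wk3_CL_mult,
    as.numeric(mode == "week3_only"))
}

# fast prediction on plain parameter lists (compiled mirror of
# .predict_piecewise; agreement asserted in the test suite)
.pred_fast <- function(p, regimen, times, mode = "persist") {
  .cpp_profile(.par_vec(p, mode), regimen$events$t_app,
               regimen$events$amount_mg[1] * 1e6, times)
}

# ---- data preparation ------------------------------------------------------

# split observation records into per-subject blocks after BLQ handling
.prep_subjects <- function(data, settings, min_obs = 1) {
  out <- list()
  dropped <- character(0)
  for (sid in unique(data$subject_id)) {
    d <- data[data$subject_id == sid, ]
    if (settings$blq == "drop") {
      d <- d[!d$blq, ]
    } else {
      d$dv[d$blq] <- d$lloq[d$blq] / 2
    }
    if (nrow(d) < min_obs) {
      dropped <- c(dropped, sid)
      next
    }
    out[[sid]] <- list(subject_id = sid, times = d$time_h, y = d$dv)
  }
  if (length(dropped))
    warning("excluded subject(s) with insufficient quantified data: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out
}

# ---- two-stage estimator ---------------------------------------------------

#' Two-stage population estimate (per-subject WLS, then pooling)
#'
#' Stage 1 fits the structural model to each subject by weighted least squares
#' with proportional weights (residuals `(y - f)/f`), on log/logit-transformed
#' parameters. Stage 2 pools: typical values are the back-transformed means of
#' the per-subject transformed estimates; omega entries (for the drug's IIV
#' parameter set) are the sample SDs on the transformed scale; sigma is the
#' pooled root-mean-square proportional residual.
#'
#' @param data observation records from [generate_trial()] (or same columns).
#' @param settings a [model_settings()].
#' @param init optional [population_model()] supplying starting values.
#' @return an object of class `fit_result`: `estimates`
#'   (a [population_model()]), `rse_pct`, `objective` (approximate -2 log
#'   likelihood), `convergence`, `individual` (per-subject parameter
#'   data.frame), `settings`.
#' @export
fit_two_stage <- function(data, settings, init = NULL) {
  stopifnot(inherits(settings, "model_settings"))
  subjects <- .prep_subjects(data, settings, min_obs = 6)
  if (!length(subjects)) stop("no usable subjects", call. = FALSE)
  template <- .params_template(settings,
                               if (!is.null(init)) .pop_theta_list(init) else NULL)
  free <- settings$theta_free
  start <- .theta_to_vec(template, free)
  regimen <- settings$regimen

  rows <- list()
  n_iter <- 0L
  ok <- TRUE
  for (s in subjects) {
    obj <- function(v) {
      p <- .vec_to_params(v, free, settings, template)
      f <- .pred_fast(p, regimen, s$times)
      if (any(f <= 0)) return(1e10)
      sum(((s$y - f) / f)^2)
    }
    fit <- stats::nlminb(start, obj, control = list(iter.max = 500,
                                                    rel.tol = 1e-12))
    n_iter <- n_iter + fit$iterations
    ok <- ok && fit$convergence == 0
    p_hat <- .vec_to_params(fit$par, free, settings, template)
    f <- .pred_fast(p_hat, regimen, s$times)
    rows[[s$subject_id]] <- c(setNames(fit$par, paste0("t_", free)),
                              wls = fit$objective, n_obs = length(s$y),
                              rss_prop = sum(((s$y - f) / f)^2))
  }
  ind <- as.data.frame(do.call(rbind, rows))
  ind$subject_id <- rownames(ind)
  rownames(ind) <- NULL

  tcols <- paste0("t_", free)
  tmeans <- colMeans(ind[tcols])
  theta_hat <- .vec_to_params(tmeans, free, settings, template)
  omega_hat <- c(CL = 0, V = 0, ka = 0, F_rel = 0)
  for (nm in settings$eta_names) {
    col <- paste0("t_", nm)
    if (col %in% tcols) omega_hat[nm] <- stats::sd(ind[[col]])
  }
  sigma_hat <- sqrt(sum(ind$rss_prop) / sum(ind$n_obs))
  est <- population_model(
    .as_dual_route(theta_hat),
    omega = omega_hat,
    sigma = list(kind = "proportional", prop = max(sigma_hat, 1e-6), add = 0))

  n_s <- nrow(ind)
  se_t <- vapply(tcols, function(cc) stats::sd(ind[[cc]]) / sqrt(n_s), numeric(1))
  rse <- setNames(.rse_from_se(se_t, tmeans, free), free)
  n_obs_tot <- sum(ind$n_obs)
  # approximate -2LL under the pooled proportional-error model
  obj_val <- n_obs_tot * log(2 * pi) + 2 * n_obs_tot * log(sigma_hat) +
    sum(ind$rss_prop) / sigma_hat^2

  structure(list(estimates = est, rse_pct = rse, objective = obj_val,
                 convergence = list(status = if (ok) "converged" else "partial",
                                    iterations = n_iter),
                 individual = ind, settings = settings, method = "two-stage"),
            class = "fit_result")
}

.pop_theta_list <- function(pop) {
  th <- pop$theta
  th[c("CL", "V", "ka", "F_total", "F_rel", "D1", "D2", "drug",
       "wk3_V_mult", "wk3_CL_mult")]
}

.as_dual_route <- function(p) {
  dual_route_params(CL = p$CL, V = p$V, ka = p$ka, F_total = p$F_total,
                    F_rel = p$F_rel, D1 = p$D1, D2 = p$D2, drug = p$drug,
                    wk3_V_mult = p$wk3_V_mult, wk3_CL_mult = p$wk3_CL_mult)
}

# delta-method RSE% on the natural scale from transformed-scale SEs
.rse_from_se <- function(se_t, mean_t, names) {
  vapply(seq_along(names), function(i) {
    if (names[i] == "F_rel") {
      p <- .inv_logit(mean_t[i])
      100 * se_t[i] * (1 - p)
    } else 100 * se_t[i]
  }, numeric(1))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s fit, %s (%d iterations), objective %.4f\n",
              x$method, x$convergence$status, x$convergence$iterations,
              x$objective))
  print(x$estimates)
  if (length(x$rse_pct)) {
    cat("  RSE%:", paste(sprintf("%s=%.1f", names(x$rse_pct), x$rse_pct),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- Laplace estimator -----------------------------------------------------

# finite-difference Hessian of a scalar function (central differences)
.fd_hess <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  hh <- pmax(abs(x), 1) * h
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- hh[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hh[i]^2
    if (i < d) for (j in (i + 1):d) {
      ej <- numeric(d); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  H
}

.logdet_pd <- function(H) {
  ch <- tryCatch(chol(H), error = function(e) NULL)
  jitter <- 1e-8
  while (is.null(ch) && jitter < 1) {
    ch <- tryCatch(chol(H + diag(jitter, nrow(H))), error = function(e) NULL)
    jitter <- jitter * 10
  }
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

#' Laplace-approximation mixed-effects estimator
#'
#' Maximizes the marginal likelihood of the nonlinear mixed-effects model
#' (log-normal/logit-normal random effects on the drug's IIV parameter set,
#' proportional residual error) using the Laplace approximation: for each
#' outer candidate, the per-subject joint log-density is maximized over the
#' subject's random effects (`eta`, warm-started across outer iterations) and
#' the marginal contribution is
#' \deqn{-2\log L_i \approx 2 g(\hat\eta_i) - d\log(2\pi) + \log|H_i|}
#' with `g` the negative joint log-density and `H_i` its Hessian at the mode
#' (central finite differences). The outer problem runs bounded quasi-Newton
#' (`nlminb`) on log/logit-transformed fixed effects, log IIV SDs and the log
#' residual SD. The objective decreases monotonically across accepted outer
#' iterations.
#'
#' @param data observation records from [generate_trial()] (or same columns).
#' @param settings a [model_settings()].
#' @param init a [population_model()] of starting values (e.g. a
#'   [fit_two_stage()] estimate); required.
#' @param control list: `outer_iter` (default 100), `outer_rel_tol` (1e-6),
#'   `inner_iter` (100), `compute_rse` (`TRUE`).
#' @return a `fit_result` (see [fit_two_stage()]); `convergence$status` is
#'   `"converged"` or `"maxiter"` (partial estimates are still returned), and
#'   `eta_hat` holds the final per-subject random-effect modes.
#' @export
fit_laplace <- function(data, settings, init, control = list()) {
  stopifnot(inherits(settings, "model_settings"),
            inherits(init, "population_model"))
  ctl <- utils::modifyList(list(outer_iter = 100, outer_rel_tol = 1e-6,
                                inner_iter = 100, compute_rse = TRUE), control)
  subjects <- .prep_subjects(data, settings, min_obs = 1)
  if (!length(subjects)) stop("no usable subjects", call. = FALSE)
  regimen <- settings$regimen
  free <- settings$theta_free
  enames <- settings$eta_names
  d_eta <- length(enames)
  template <- .params_template(settings, .pop_theta_list(init))

  # outer parameter vector: transformed theta, log omega, log sigma
  om0 <- pmax(init$omega[enames], 0.02)
  sg0 <- max(init$sigma$prop, 0.02)
  par0 <- c(.theta_to_vec(template, free), log(om0), log(sg0))
  n_th <- length(free)
  names(par0) <- c(free, paste0("om_", enames), "sigma")
  lower <- c(rep(-30, n_th), rep(log(1e-3), d_eta), log(1e-3))
  upper <- c(rep(30, n_th), rep(log(3), d_eta), log(2))
  if ("F_rel" %in% free) {
    i <- match("F_rel", free); lower[i] <- -12; upper[i] <- 12
  }

  times_list <- lapply(subjects, `[[`, "times")
  y_list <- lapply(subjects, `[[`, "y")
  etamode <- if (enames[3] == "ka") 0L else 1L
  cache <- new.env(parent = emptyenv())
  cache$eta <- matrix(0, nrow = d_eta, ncol = length(subjects))

  obj <- function(par) {
    theta_p <- .vec_to_params(par[seq_len(n_th)], free, settings, template)
    omega <- exp(par[n_th + seq_len(d_eta)])
    sigma <- exp(par[n_th + d_eta + 1])
    res <- .cpp_laplace_obj(.par_vec(theta_p), regimen$events$t_app,
                            regimen$events$amount_mg[1] * 1e6,
                            times_list, y_list, omega, sigma, cache$eta,
                            etamode, ctl$inner_iter)
    cache$eta <- res$eta
    if (!is.finite(res$objective)) return(1e10)
    res$objective
  }

  fit <- stats::nlminb(par0, obj, lower = lower, upper = upper,
                       control = list(iter.max = ctl$outer_iter,
                                      rel.tol = ctl$outer_rel_tol))
  theta_hat <- .vec_to_params(fit$par[seq_len(n_th)], free, settings, template)
  omega_hat <- c(CL = 0, V = 0, ka = 0, F_rel = 0)
  omega_hat[enames] <- exp(fit$par[n_th + seq_len(d_eta)])
  sigma_hat <- exp(fit$par[n_th + d_eta + 1])
  est <- population_model(.as_dual_route(theta_hat), omega = omega_hat,
                          sigma = list(kind = "proportional",
                                       prop = sigma_hat, add = 0))

  rse <- numeric(0)
  if (isTRUE(ctl$compute_rse)) {
    Hout <- tryCatch(stats::optimHess(fit$par, obj), error = function(e) NULL)
    if (!is.null(Hout)) {
      cov <- tryCatch(2 * solve(Hout), error = function(e) NULL)
      if (!is.null(cov)) {
        dg <- diag(cov)
        dg[dg <= 0] <- NA_real_ # parameters at a bound have no usable SE
        se_t <- sqrt(dg)
        rse <- setNames(.rse_from_se(se_t[seq_len(n_th)],
                                     fit$par[seq_len(n_th)], free), free)
        rse <- c(rse, setNames(100 * se_t[-seq_len(n_th)],
                               c(paste0("omega_", enames), "sigma")))
      }
    }
  }

  status <- if (fit$convergence == 0) "converged" else "maxiter"
  eta_hat <- lapply(seq_along(subjects), function(i)
    setNames(cache$eta[, i], enames))
  names(eta_hat) <- names(subjects)
  structure(list(estimates = est, rse_pct = rse, objective = fit$objective,
                 convergence = list(status = status,
                                    iterations = fit$iterations,
                                    message = fit$message),
                 eta_hat = eta_hat, settings = settings,
                 method = "laplace"),
            class = "fit_result")
}

#' Laplace marginal -2 log-likelihood at a fixed population model
#'
#' Evaluates the Laplace-approximated marginal likelihood of the data under a
#' given [population_model()] without optimizing the fixed effects (the inner
#' per-subject eta modes are still found). Useful for model comparison and for
#' checking that the generating parameters dominate perturbed ones on large
#' datasets.
#'
#' @param data observation records from [generate_trial()].
#' @param settings a [model_settings()].
#' @param pop the [population_model()] to evaluate.
#' @return the -2 log marginal likelihood (scalar).
#' @export
laplace_objective <- function(data, settings, pop) {
  stopifnot(inherits(settings, "model_settings"),
            inherits(pop, "population_model"))
  subjects <- .prep_subjects(data, settings, min_obs = 1)
  enames <- settings$eta_names
  omega <- pmax(pop$omega[enames], 1e-3)
  sigma <- max(pop$sigma$prop, 1e-3)
  etamode <- if (enames[3] == "ka") 0L else 1L
  res <- .cpp_laplace_obj(.par_vec(.pop_theta_list(pop)),
                          settings$regimen$events$t_app,
                          settings$regimen$events$amount_mg[1] * 1e6,
                          lapply(subjects, `[[`, "times"),
                          lapply(subjects, `[[`, "y"),
                          omega, sigma,
                          matrix(0, 3, length(subjects)), etamode, 100L)
  res$objective
}

# ---- diagnostics -----------------------------------------------------------

# per-subject eta mode under a fitted model (re-used by gof/vpc helpers)
.posthoc_etas <- function(fit, subjects) {
  if (!is.null(fit$eta_hat)) return(fit$eta_hat)
  est <- fit$estimates
  settings <- fit$settings
  enames <- settings$eta_names
  omega <- pmax(est$omega[enames], 1e-3)
  sigma <- max(est$sigma$prop, 1e-3)
  theta_p <- .pop_theta_list(est)
  out <- list()
  for (key in names(subjects)) {
    s <- subjects[[key]]
    g <- function(eta) {
      p <- .eta_apply(theta_p, eta, enames)
      f <- .pred_fast(p, settings$regimen, s$times)
      if (any(f <= 0)) return(1e10)
      sum(log(sigma * f) + 0.5 * ((s$y - f) / (sigma * f))^2) +
        0.5 * sum((eta / omega)^2)
    }
    out[[key]] <- stats::nlminb(setNames(numeric(length(enames)), enames), g)$par
  }
  out
}

.eta_apply <- function(theta_p, eta, enames) {
  p <- theta_p
  p$CL <- p$CL * exp(eta[[1]])
  p$V <- p$V * exp(eta[[2]])
  if (enames[3] == "ka") p$ka <- p$ka * exp(eta[[3]])
  else p$F_rel <- .inv_logit(.logit(theta_p$F_rel) + eta[[3]])
  p
}

#' Goodness-of-fit residual tables
#'
#' Produces the standard diagnostic quantities as a tidy table: population
#' prediction (`pred`, at eta = 0), individual prediction (`ipred`, at the
#' subject's posterior eta mode), residuals, individual weighted residuals
#' (`iwres = (y - ipred)/(sigma * ipred)`), and conditional weighted residuals
#' (`cwres`) from a first-order linearization of the model around the eta
#' mode (covariance `J Omega J' + diag((sigma f)^2)`).
#'
#' @param fit a `fit_result`.
#' @param data the observation records that were fitted.
#' @return data.frame with columns `subject_id`, `time_h`, `dv`, `pred`,
#'   `ipred`, `res`, `iwres`, `cwres`.
#' @export
gof_diagnostics <- function(fit, data) {
  settings <- fit$settings
  est <- fit$estimates
  enames <- settings$eta_names
  subjects <- .prep_subjects(data, settings, min_obs = 1)
  etas <- .posthoc_etas(fit, subjects)
  theta_p <- .pop_theta_list(est)
  sigma <- max(est$sigma$prop, 1e-6)
  omega <- pmax(est$omega[enames], 1e-6)
  Om <- diag(omega^2, length(enames))
  out <- list()
  for (key in names(subjects)) {
    s <- subjects[[key]]
    eta <- etas[[key]]
    pred <- .pred_fast(theta_p, settings$regimen, s$times)
    p_i <- .eta_apply(theta_p, eta, enames)
    ipred <- .pred_fast(p_i, settings$regimen, s$times)
    iwres <- (s$y - ipred) / (sigma * pmax(ipred, 1e-12))
    # FO linearization around the eta mode for conditional weighted residuals
    J <- vapply(seq_along(enames), function(m) {
      h <- 1e-4
      ep <- eta; ep[m] <- ep[m] + h
      (.pred_fast(.eta_apply(theta_p, ep, enames), settings$regimen, s$times) -
         ipred) / h
    }, numeric(length(s$times)))
    Vm <- J %*% Om %*% t(J) + diag((sigma * pmax(ipred, 1e-12))^2,
                                   length(s$times))
    resid_lin <- s$y - (ipred - as.numeric(J %*% eta))
    cwres <- tryCatch(as.numeric(solve(t(chol(Vm)), resid_lin)),
                      error = function(e) rep(NA_real_, length(s$times)))
    out[[key]] <- data.frame(subject_id = s$subject_id, time_h = s$times,
                             dv = s$y, pred = pred, ipred = ipred,
                             res = s$y - pred, iwres = iwres, cwres = cwres,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate trials under the fitted model at the observed
#' design (same subject count, sampling times and residual-error model),
#' computes the 5th/50th/95th concentration percentiles per time bin in each
#' replicate, and summarizes each percentile across replicates by its median
#' and a 90% band (5th-95th across replicates). Observed percentiles are
#' returned alongside.
#'
#' @param fit a `fit_result`.
#' @param data the observation records being checked.
#' @param regimen the dosing [weekly_regimen()].
#' @param n_sim number of replicate trials (>= 200 recommended).
#' @param seed RNG seed.
#' @return data.frame with one row per time bin and percentile (`p5`, `p50`,
#'   `p95`): observed value (`observed`), simulated median (`sim_mid`) and
#'   band (`sim_lo`, `sim_hi`).
#' @export
vpc <- function(fit, data, regimen, n_sim = 200, seed = 1) {
  settings <- fit$settings
  est <- fit$estimates
  subjects <- .prep_subjects(data, settings, min_obs = 1)
  # bins with no quantified observation (e.g. the week-1 pre-dose) are dropped
  quant_times <- sort(unique(unlist(lapply(subjects, `[[`, "times"))))
  design_times <- intersect(sort(unique(data$time_h)), quant_times)
  n_subj <- length(subjects)
  probs <- c(p5 = 0.05, p50 = 0.5, p95 = 0.95)

  obs_mat <- sapply(subjects, function(s) {
    v <- rep(NA_real_, length(design_times))
    v[match(s$times, design_times)] <- s$y
    v
  })
  obs_pct <- t(apply(obs_mat, 1, stats::quantile, probs = probs, na.rm = TRUE))

  sim_pct <- array(NA_real_, c(length(design_times), 3, n_sim))
  for (r in seq_len(n_sim)) {
    design <- structure(list(n_subjects = n_subj, sample_times = design_times,
                             lloq = 0, drug = est$drug),
                        class = "sampling_design")
    trial <- generate_trial(est, design, regimen,
                            seed = .subject_seed(seed, r))
    m <- matrix(trial$dv, nrow = length(design_times))
    sim_pct[, , r] <- t(apply(m, 1, stats::quantile, probs = probs,
                              na.rm = TRUE))
  }

  out <- list()
  for (j in seq_along(probs)) {
    band <- apply(sim_pct[, j, , drop = FALSE], 1, stats::quantile,
                  probs = c(0.05, 0.5, 0.95))
    out[[j]] <- data.frame(time_h = design_times,
                           percentile = names(probs)[j],
                           observed = obs_pct[, j],
                           sim_lo = band[1, ], sim_mid = band[2, ],
                           sim_hi = band[3, ], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize a fit result to a report file and parameter table
#'
#' Writes a YAML/JSON report (estimates, RSEs, objective, convergence) and a
#' CSV parameter table with columns `parameter`, `estimate`, `rse_pct`,
#' `transform`, `fixed`.
#'
#' @param fit a `fit_result`.
#' @param report_path structured report path (`.yaml` or `.json`).
#' @param table_path CSV parameter-table path.
#' @return `report_path`, invisibly.
#' @export
write_fit_report <- function(fit, report_path, table_path = NULL) {
  est <- fit$estimates
  th <- est$theta
  free <- fit$settings$theta_free
  rows <- list()
  for (nm in c("CL", "V", "ka", "F_total", "F_rel", "D1", "D2",
               "wk3_V_mult", "wk3_CL_mult")) {
    rows[[nm]] <- data.frame(
      parameter = nm, estimate = th[[nm]],
      rse_pct = if (nm %in% names(fit$rse_pct)) fit$rse_pct[[nm]] else NA_real_,
      transform = if (nm == "F_rel") "logit" else "log",
      fixed = !(nm %in% free), stringsAsFactors = FALSE)
  }
  for (nm in names(est$omega)) {
    rows[[paste0("omega_", nm)]] <- data.frame(
      parameter = paste0("omega_", nm), estimate = est$omega[[nm]],
      rse_pct = NA_real_, transform = "log",
      fixed = !(nm %in% fit$settings$eta_names), stringsAsFactors = FALSE)
  }
  rows$sigma <- data.frame(parameter = "sigma_prop", estimate = est$sigma$prop,
                           rse_pct = NA_real_, transform = "log",
                           fixed = FALSE, stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(table_path))
    utils::write.csv(tab, table_path, row.names = FALSE, quote = FALSE)
  report <- list(method = fit$method, objective = fit$objective,
                 convergence = fit$convergence,
                 drug = est$drug,
                 theta = as.list(tab$estimate[seq_len(9)]),
                 omega = as.list(est$omega), sigma = est$sigma)
  names(report$theta) <- tab$parameter[seq_len(9)]
  .write_config(report, report_path)
  invisible(report_path)
}
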