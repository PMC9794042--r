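#' Population pharmacokinetic model
#'
#' Couples typical-value structural parameters (`theta`) with interindividual
#' variability (IIV, `omega`), a residual-error model (`sigma`) and the week-3
#' effect handling. IIV is log-normal for `CL`, `V` and `ka` (individual value
#' = typical value times `exp(eta)`) and logit-normal for `F_rel`; `omega`
#' entries are standard deviations on those transformed scales.
#'
#' Each drug's model carries IIV on its own parameter set: `V`, `CL` and `ka`
#' for EE; `V`, `CL` and `F_rel` for LNG. With `strict_iiv = TRUE` (default)
#' any other positive omega entry is rejected.
#'
#' @param theta a [dual_route_params()] object (typical values).
#' @param omega named numeric vector of IIV standard deviations on the
#'   transformed scale; names among `CL`, `V`, `ka`, `F_rel`; missing names
#'   mean 0. All entries >= 0.
#' @param sigma residual-error model: a list with `kind`
#'   (`"proportional"`, `"additive"` or `"combined"`), `prop` (CV fraction) and
#'   `add` (SD, pg/mL).
#' @param week_effect_mode `"persist"` (week-3 effects stay on from week 3
#'   onward) or `"week3_only"`.
#' @param strict_iiv enforce the drug's canonical IIV parameter set.
#' @return an object of class `population_model`.
#' @export
population_model <- function(theta,
                             omega = c(CL = 0, V = 0, ka = 0, F_rel = 0),
                             sigma = list(kind = "proportional", prop = 0.2, add = 0),
                             week_effect_mode = c("persist", "week3_only"),
                             strict_iiv = TRUE) {
  stopifnot(inherits(theta, "dual_route_params"))
  week_effect_mode <- match.arg(week_effect_mode)
  om <- c(CL = 0, V = 0, ka = 0, F_rel = 0)
  if (!is.null(names(omega))) {
    bad <- setdiff(names(omega), names(om))
    if (length(bad)) stop("unknown omega entries: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    om[names(omega)] <- omega
  } else stop("omega must be a named vector", call. = FALSE)
  if (any(om < 0)) stop("omega entries must be >= 0", call. = FALSE)
  if (strict_iiv) {
    allowed <- if (theta$drug == "EE") c("CL", "V", "ka") else c("CL", "V", "F_rel")
    extra <- setdiff(names(om)[om > 0], allowed)
    if (length(extra))
      stop(sprintf("%s model allows IIV only on %s (got positive omega for %s)",
                   theta$drug, paste(allowed, collapse = ", "),
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  sigma <- .check_sigma(sigma)
  structure(list(drug = theta$drug, theta = theta, omega = om, sigma = sigma,
                 week_effect_mode = week_effect_mode),
            class = "population_model")
}

.check_sigma <- function(sigma) {
  stopifnot(is.list(sigma), !is.null(sigma$kind))
  kind <- match.arg(sigma$kind, c("proportional", "additive", "combined"))
  prop <- if (is.null(sigma$prop)) 0 else sigma$prop
  add <- if (is.null(sigma$add)) 0 else sigma$add
  if (prop < 0 || add < 0) stop("sigma magnitudes must be >= 0", call. = FALSE)
  list(kind = kind, prop = prop, add = add)
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %s\n", x$drug))
  print(x$theta)
  cat("  omega (transformed-scale SD):",
      paste(sprintf("%s=%.3g", names(x$omega), x$omega), collapse = ", "), "\n")
  cat(sprintf("  sigma: %s (prop %.3g, add %.3g pg/mL); week effects: %s\n",
              x$sigma$kind, x$sigma$prop, x$sigma$add, x$week_effect_mode))
  invisible(x)
}

#' Apply the week-3 effect to an individual's parameters
#'
#' For weeks >= 3 the LNG model multiplies `V` and `CL` by the estimated week-3
#' multipliers (a between-week shift attributed to physiological changes such
#' as SHBG induction); weeks 1-2 are unchanged, and the EE model has no week
#' effects (multipliers are 1).
#'
#' @param params a [dual_route_params()] object.
#' @param week week index (>= 1).
#' @return a `dual_route_params` object, adjusted if `week >= 3`.
#' @export
apply_week_effect <- function(params, week) {
  stopifnot(inherits(params, "dual_route_params"), week >= 1)
  if (week < 3 || (params$wk3_V_mult == 1 && params$wk3_CL_mult == 1))
    return(params)
  out <- params
  out$V <- params$V * params$wk3_V_mult
  out$CL <- params$CL * params$wk3_CL_mult
  out$k <- out$CL / out$V
  out
}

# deterministic per-subject substream seed from one master seed
.subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(i)) %% 2147483629) + 1L
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# individual parameters from typical values and random effects
.individual_params <- function(theta, eta) {
  p <- theta
  p$CL <- theta$CL * exp(eta[["CL"]])
  p$V <- theta$V * exp(eta[["V"]])
  p$ka <- theta$ka * exp(eta[["ka"]])
  if (theta$F_rel > 0 && theta$F_rel < 1) {
    p$F_rel <- .inv_logit(.logit(theta$F_rel) + eta[["F_rel"]])
  }
  p$k <- p$CL / p$V
  p
}

#' Draw individual subjects from a population model
#'
#' Independent per-subject random effects: `eta ~ N(0, omega^2)` on the log
#' scale for `CL`, `V`, `ka` and on the logit scale for `F_rel` (diagonal
#' omega, no covariances). Each subject uses its own deterministic RNG
#' substream derived from the master seed, so realizations do not depend on
#' subject ordering.
#'
#' @param pop a [population_model()].
#' @param n number of subjects (>= 1).
#' @param seed master integer seed.
#' @return a list of `subject_realization` objects: `subject_id`, `eta`
#'   (named vector), `params` (a [dual_route_params()]).
#' @export
draw_subjects <- function(pop, n, seed) {
  stopifnot(inherits(pop, "population_model"), n >= 1)
  lapply(seq_len(n), function(i) {
    eta <- c(CL = 0, V = 0, ka = 0, F_rel = 0)
    free <- names(pop$omega)[pop$omega > 0]
    if (length(free)) {
      old <- .save_rng()
      on.exit(.restore_rng(old), add = TRUE)
      set.seed(.subject_seed(seed, i))
      eta[free] <- stats::rnorm(length(free), 0, pop$omega[free])
    }
    structure(list(subject_id = sprintf("S%04d", i), eta = eta,
                   params = .individual_params(pop$theta, eta)),
              class = "subject_realization")
  })
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate week-window concentration profiles for a population
#'
#' Draws `n` subjects, applies the week-effect convention, and evaluates each
#' subject's noise-free profile on an hourly grid over each requested week
#' window (week w spans `[(w-1)*168, w*168]` h, endpoints inclusive: 169 points
#' per week). Residual variability is never added here, matching the simulation
#' design of the extended-regimen analysis (IIV on, residual off).
#'
#' @param pop a [population_model()].
#' @param regimen a [weekly_regimen()] covering the requested weeks.
#' @param weeks integer vector of week indices to output (e.g. `c(1, 3, 12)`).
#' @param n number of simulated individuals.
#' @param seed master seed for the IIV draws.
#' @return a long data.frame of class `population_sim` with columns
#'   `subject_id`, `drug`, `week`, `time_h`, `conc_pg_ml`.
#' @export
simulate_population <- function(pop, regimen, weeks = c(1, 3, 12), n = 1000,
                                seed = 20221227) {
  stopifnot(inherits(pop, "population_model"), inherits(regimen, "regimen"))
  weeks <- sort(unique(as.integer(weeks)))
  if (any(weeks < 1) || any(weeks > regimen$n_weeks))
    stop("requested weeks beyond the regimen horizon (n_weeks = ",
         regimen$n_weeks, ")", call. = FALSE)
  subjects <- draw_subjects(pop, n, seed)
  grids <- lapply(weeks, function(w) (w - 1) * 168 + 0:168)
  out <- vector("list", length(subjects) * length(weeks))
  idx <- 1L
  for (s in subjects) {
    for (j in seq_along(weeks)) {
      conc <- .predict_piecewise(s$params, regimen, grids[[j]],
                                 mode = pop$week_effect_mode)
      out[[idx]] <- data.frame(subject_id = s$subject_id, drug = pop$drug,
                               week = weeks[j], time_h = grids[[j]],
                               conc_pg_ml = conc, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("population_sim", "data.frame")
  res
}

#' Serialize / load a population model config (YAML or JSON)
#'
#' @param pop a [population_model()].
#' @param path file path; format by extension.
#' @param note optional free-text provenance note stored in the file.
#' @return `path` (write) or a `population_model` (read).
#' @export
write_population_config <- function(pop, path, note = NULL) {
  th <- pop$theta
  x <- list(
    drug = pop$drug,
    theta = list(CL = th$CL, V = th$V, ka = th$ka, F_total = th$F_total,
                 F_rel = th$F_rel, D1 = th$D1, D2 = th$D2,
                 wk3_V_mult = th$wk3_V_mult, wk3_CL_mult = th$wk3_CL_mult),
    omega = as.list(pop$omega),
    sigma = pop$sigma,
    week_effect_mode = pop$week_effect_mode)
  if (!is.null(note)) x$note <- note
  .write_config(x, path)
  invisible(path)
}

#' @rdname write_population_config
#' @export
read_population_config <- function(path) {
  x <- .read_config(path)
  theta <- dual_route_params(CL = x$theta$CL, V = x$theta$V, ka = x$theta$ka,
                             F_total = x$theta$F_total, F_rel = x$theta$F_rel,
                             D1 = x$theta$D1, D2 = x$theta$D2, drug = x$drug,
                             wk3_V_mult = x$theta$wk3_V_mult,
                             wk3_CL_mult = x$theta$wk3_CL_mult)
  population_model(theta, omega = unlist(x$omega), sigma = x$sigma,
                   week_effect_mode = x$week_effect_mode)
}

#' Shipped default population models
#'
#' Loads the package's default population model for a drug from
#' `inst/extdata/<drug>_population.yaml`. These typical values and variances
#' are derived calibration output (see [calibrate_population()] and the file
#' headers), not estimates transcribed from any study report.
#'
#' @param drug `"EE"` or `"LNG"`.
#' @return a [population_model()].
#' @export
default_population <- function(drug = c("EE", "LNG")) {
  drug <- match.arg(drug)
  path <- system.file("extdata", paste0(tolower(drug), "_population.yaml"),
                      package = "patchpk", mustWork = TRUE)
  read_population_config(path)
}
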