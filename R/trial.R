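#' Rich-sampling trial design of the source cycle-2 study
#'
#' Returns the sampling design used for model development: 18 subjects wearing
#' the LNG/EE TDS, sampled during the first and third wear weeks of the cycle
#' at pre-dose and 6, 12, 24, 48, 72, 120, 144 and 168 h after each
#' application, plus 174, 180, 192, 216 and 240 h after the third (last)
#' application — 23 samples per subject. Assay lower limits of quantification
#' are 2 pg/mL (EE) and 50 pg/mL (LNG).
#'
#' @param drug `"EE"` or `"LNG"`.
#' @param n_subjects number of subjects (default 18).
#' @return an object of class `sampling_design`: `n_subjects`, `sample_times`
#'   (h from the cycle's first application, sorted, deduplicated), `lloq`
#'   (pg/mL), `drug`.
#' @export
ati_cl14_design <- function(drug = c("EE", "LNG"), n_subjects = 18) {
  drug <- match.arg(drug)
  offsets <- c(0, 6, 12, 24, 48, 72, 120, 144, 168)
  times <- sort(unique(c(offsets,                 # week-1 application at 0 h
                         2 * 168 + offsets,       # week-3 application at 336 h
                         2 * 168 + c(174, 180, 192, 216, 240))))
  lloq <- c(EE = 2, LNG = 50)[[drug]]
  structure(list(n_subjects = as.integer(n_subjects), sample_times = times,
                 lloq = lloq, drug = drug),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf("<sampling_design> %s: %d subjects x %d samples, LLOQ %g pg/mL\n",
              x$drug, x$n_subjects, length(x$sample_times), x$lloq))
  invisible(x)
}

# residual-error draw: proportional, additive or combined
.add_residual <- function(pred, sigma) {
  n <- length(pred)
  switch(sigma$kind,
         proportional = pred * (1 + stats::rnorm(n, 0, sigma$prop)),
         additive = pred + stats::rnorm(n, 0, sigma$add),
         combined = pred * (1 + stats::rnorm(n, 0, sigma$prop)) +
           stats::rnorm(n, 0, sigma$add))
}

#' Generate a synthetic clinical trial
#'
#' Simulates each design subject under the population model, evaluates the
#' noise-free prediction at the design sampling times (the pre-dose sample at
#' each application is the running-superposition trough at that instant), adds
#' residual error per the model's sigma, and censors observations below the
#' assay LLOQ. The result stands in for the undeposited cycle-2 study data.
#'
#' @param pop a [population_model()]; must carry a positive residual-error
#'   magnitude unless `noise_free = TRUE`.
#' @param design a [ati_cl14_design()] sampling design (same drug).
#' @param regimen a [weekly_regimen()] covering the design's time span.
#' @param seed master seed (IIV substreams and residual draws).
#' @param noise_free generate exact model predictions (testing only).
#' @return data.frame of observation records: `subject_id`, `drug`, `time_h`,
#'   `dv` (pg/mL; `NA` when censored), `blq` (logical), `pred` (the noise-free
#'   prediction, retained for diagnostics), `lloq`.
#' @export
generate_trial <- function(pop, design, regimen, seed = 1, noise_free = FALSE) {
  stopifnot(inherits(pop, "population_model"),
            inherits(design, "sampling_design"),
            inherits(regimen, "regimen"))
  if (pop$drug != design$drug)
    stop("population model and design disagree on drug", call. = FALSE)
  if (max(design$sample_times) > regimen$horizon_h)
    stop("regimen horizon does not cover the sampling design", call. = FALSE)
  s_mag <- pop$sigma$prop + pop$sigma$add
  if (s_mag == 0 && !noise_free)
    stop("residual-error magnitude is zero; observed data must carry noise ",
         "(set noise_free = TRUE to override)", call. = FALSE)

  subjects <- draw_subjects(pop, design$n_subjects, seed)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    pred <- .predict_piecewise(s$params, regimen, design$sample_times,
                               mode = pop$week_effect_mode)
    if (noise_free) {
      dv <- pred
    } else {
      old <- .save_rng()
      set.seed(.subject_seed(seed, i) + 1000000L)
      dv <- pmax(.add_residual(pred, pop$sigma), 0)
      .restore_rng(old)
    }
    blq <- dv < design$lloq
    out[[i]] <- data.frame(subject_id = s$subject_id, drug = pop$drug,
                           time_h = design$sample_times,
                           dv = ifelse(blq, NA_real_, dv), blq = blq,
                           pred = pred, lloq = design$lloq,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Write / read observation records as CSV
#'
#' Values round-trip exactly to at least 6 significant digits (full double
#' precision is written).
#'
#' @param records observation data.frame from [generate_trial()].
#' @param path CSV path.
#' @return `path` (write) or the records data.frame (read).
#' @export
write_observations_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$blq <- as.logical(df$blq)
  df
}

#' Write a NONMEM-style event dataset
#'
#' Emits dosing and observation records in the conventional event format with
#' columns `ID`, `TIME`, `AMT` (ng), `RATE` (ng/h), `CMT`, `DV`, `EVID`,
#' `MDV`, `BLQ`. Each patch application contributes one or two infusion/bolus
#' dose records per absorption route (central zero-order infusions carry
#' `RATE`; EE depot doses are boluses).
#'
#' @param records observation data.frame from [generate_trial()].
#' @param pop the generating [population_model()] (supplies route splits).
#' @param regimen the [weekly_regimen()] used.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nonmem_dataset <- function(records, pop, regimen, path) {
  th <- pop$theta
  masses <- .route_masses(th, regimen$events$amount_mg[1])
  dose_rows <- list()
  for (ta in regimen$events$t_app) {
    if (masses$zero_central > 0)
      dose_rows[[length(dose_rows) + 1]] <-
        data.frame(TIME = ta, AMT = masses$zero_central,
                   RATE = masses$zero_central / th$D1, CMT = 1)
    if (masses$depot > 0)
      dose_rows[[length(dose_rows) + 1]] <-
        data.frame(TIME = ta, AMT = masses$depot,
                   RATE = if (th$drug == "LNG") masses$depot / th$D2 else 0,
                   CMT = 2)
  }
  doses <- do.call(rbind, dose_rows)
  out <- list()
  for (sid in unique(records$subject_id)) {
    id <- match(sid, unique(records$subject_id))
    d <- records[records$subject_id == sid, ]
    obs <- data.frame(ID = id, TIME = d$time_h, AMT = 0, RATE = 0, CMT = 1,
                      DV = ifelse(d$blq, 0, d$dv), EVID = 0,
                      MDV = as.integer(d$blq), BLQ = as.integer(d$blq))
    dos <- data.frame(ID = id, TIME = doses$TIME, AMT = doses$AMT,
                      RATE = doses$RATE, CMT = doses$CMT, DV = 0, EVID = 1,
                      MDV = 1, BLQ = 0)
    all <- rbind(dos, obs)
    out[[length(out) + 1]] <- all[order(all$TIME, -all$EVID), ]
  }
  res <- do.call(rbind, out)
  utils::write.csv(res, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
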