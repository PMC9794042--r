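#' Linear-up/log-down trapezoidal AUC
#'
#' Computes the area under a concentration-time curve between two grid points
#' using the linear trapezoid on rising (or flat, or non-positive) segments and
#' the logarithmic trapezoid \eqn{(C_1 - C_2)\,\Delta t / \ln(C_1/C_2)} on
#' strictly decreasing positive segments. The log rule integrates a
#' monoexponential decline exactly, whatever the grid spacing.
#'
#' @param times time grid (h), sorted; must contain `t_start` and `t_end`
#'   exactly (no interpolation is performed).
#' @param conc concentrations (pg/mL), same length as `times`.
#' @param t_start,t_end integration bounds (h).
#' @return AUC in h·ng/mL (pg·h/mL divided by 1000).
#' @export
#' @examples
#' t <- 0:168
#' auc_lin_up_log_down(t, rep(10, length(t)), 0, 168) # 1.68 h·ng/mL
auc_lin_up_log_down <- function(times, conc, t_start, t_end) {
  stopifnot(length(times) == length(conc))
  i0 <- which(abs(times - t_start) < 1e-9)
  i1 <- which(abs(times - t_end) < 1e-9)
  if (!length(i0) || !length(i1))
    stop("integration bounds must coincide with grid points", call. = FALSE)
  i0 <- i0[1]; i1 <- i1[length(i1)]
  if (i1 <= i0) stop("t_end must exceed t_start on the grid", call. = FALSE)
  c1 <- conc[i0:(i1 - 1)]
  c2 <- conc[(i0 + 1):i1]
  dt <- diff(times[i0:i1])
  lin <- (c1 + c2) / 2 * dt
  use_log <- c1 > c2 & c2 > 0
  auc <- lin
  if (any(use_log))
    auc[use_log] <- (c1[use_log] - c2[use_log]) * dt[use_log] /
      log(c1[use_log] / c2[use_log])
  sum(auc) / 1000
}

#' Cmax and Tmax within a window
#'
#' `cmax` is the maximum observed concentration on the grid inside the window;
#' `tmax` is the earliest time attaining it (grid argmax, no interpolation),
#' reported as elapsed time since the window start.
#'
#' @param profile a [conc_profile()].
#' @param window numeric length-2 `c(t_start, t_end)` (h).
#' @return list with `cmax` (pg/mL) and `tmax` (h, elapsed within window).
#' @export
cmax_tmax <- function(profile, window) {
  stopifnot(inherits(profile, "conc_profile"), length(window) == 2)
  sel <- profile$times >= window[1] - 1e-9 & profile$times <= window[2] + 1e-9
  if (!any(sel)) stop("window contains no grid points", call. = FALSE)
  tt <- profile$times[sel]
  cc <- profile$conc[sel]
  i <- which.max(cc) # which.max returns the first maximum: earliest tie wins
  list(cmax = cc[i], tmax = tt[i] - window[1])
}

#' Average concentration over a window (Css)
#'
#' The average "steady-state" concentration is the window AUC divided by the
#' window length: Css(0-168) = AUC(0-168)/168, and Css(48-168) divides the
#' partial AUC by 120.
#'
#' @param auc window AUC (h·ng/mL).
#' @param t_start,t_end window bounds (h).
#' @return concentration in pg/mL.
#' @export
css <- function(auc, t_start, t_end) {
  if (t_end <= t_start) stop("window must have positive length", call. = FALSE)
  auc / (t_end - t_start) * 1000
}

#' Accumulation ratio
#'
#' Per-subject ratio of a later week's exposure parameter to the same
#' subject's week-1 (reference) value. The geometric mean of paired ratios
#' equals the ratio of the two geometric means exactly.
#'
#' @param value_week parameter value(s) at the later week.
#' @param value_ref paired reference (week-1) value(s), > 0.
#' @return dimensionless ratio(s).
#' @export
accumulation_ratio <- function(value_week, value_ref) {
  if (any(value_ref <= 0)) stop("reference values must be > 0", call. = FALSE)
  value_week / value_ref
}

#' Arithmetic and geometric summary statistics
#'
#' The summary block used for each pharmacokinetic parameter and week:
#' n, arithmetic mean, SD (sample, n-1), arithmetic CV% (100·SD/mean),
#' geometric mean, and geometric CV% (\eqn{100\sqrt{e^{s^2}-1}} with s the SD
#' of natural logs).
#'
#' @param values numeric vector, n >= 2; all > 0 when geometric statistics are
#'   requested.
#' @param geometric compute geometric statistics (default `TRUE`).
#' @return list with `n`, `mean`, `sd`, `cv_pct`, `geo_mean`, `geo_cv_pct`.
#' @export
summary_stats <- function(values, geometric = TRUE) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  out <- list(n = length(values), mean = m, sd = s,
              cv_pct = if (m > 0) 100 * s / m else NA_real_,
              geo_mean = NA_real_, geo_cv_pct = NA_real_)
  if (geometric) {
    if (any(values <= 0)) {
      bad <- which(values <= 0)[1]
      stop("geometric statistics need positive values (element ", bad,
           " is not)", call. = FALSE)
    }
    lv <- log(values)
    out$geo_mean <- exp(mean(lv))
    out$geo_cv_pct <- 100 * sqrt(exp(stats::sd(lv)^2) - 1)
  }
  out
}

# window AUC of one subject-week block on the package's week convention
.week_window <- function(week) c((week - 1) * 168, week * 168)

#' Per-subject, per-week noncompartmental analysis
#'
#' Computes, for each simulated individual and each requested week window
#' (week w spans `[(w-1)*168, w*168]` h): Cmax, Tmax (elapsed within the
#' window), AUC(0-168) by the linear-up/log-down method, Css(0-168) =
#' AUC/168, Css(48-168), and — for non-reference weeks — the accumulation
#' ratios AR Cmax and AR AUC against the same subject's reference week.
#'
#' @param sim a `population_sim` long data.frame from [simulate_population()],
#'   or a list of [conc_profile()] objects covering the requested windows.
#' @param weeks week indices to analyze (default `c(1, 3, 12)`).
#' @param ref_week reference week for accumulation ratios (default 1).
#' @return list with `results` (per-subject data.frame: `subject_id`, `week`,
#'   `cmax`, `tmax`, `auc_0_168`, `css_0_168`, `css_48_168`, `ar_cmax`,
#'   `ar_auc`; AR columns are `NA` for the reference week) and `summary`
#'   (the weekly summary table from [nca_summary_table()]).
#' @export
nca_by_week <- function(sim, weeks = c(1, 3, 12), ref_week = 1) {
  df <- .as_sim_df(sim)
  weeks <- sort(unique(as.integer(weeks)))
  stopifnot(ref_week %in% weeks)

  res <- list()
  for (sid in unique(df$subject_id)) {
    d_s <- df[df$subject_id == sid, ]
    for (w in weeks) {
      win <- .week_window(w)
      d <- d_s[d_s$week == w, ]
      if (nrow(d) < 2)
        stop("subject ", sid, " lacks coverage of week ", w, call. = FALSE)
      prof <- conc_profile(sid, d$drug[1], d$time_h, d$conc_pg_ml)
      cm <- cmax_tmax(prof, win)
      auc <- auc_lin_up_log_down(prof$times, prof$conc, win[1], win[2])
      auc48 <- auc_lin_up_log_down(prof$times, prof$conc, win[1] + 48, win[2])
      res[[length(res) + 1]] <- data.frame(
        subject_id = sid, week = w, cmax = cm$cmax, tmax = cm$tmax,
        auc_0_168 = auc, css_0_168 = css(auc, 0, 168),
        css_48_168 = css(auc48, 48, 168),
        ar_cmax = NA_real_, ar_auc = NA_real_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, res)

  ref <- res[res$week == ref_week, c("subject_id", "cmax", "auc_0_168")]
  names(ref) <- c("subject_id", "cmax_ref", "auc_ref")
  res <- merge(res, ref, by = "subject_id", sort = FALSE)
  nonref <- res$week != ref_week
  res$ar_cmax[nonref] <- accumulation_ratio(res$cmax[nonref], res$cmax_ref[nonref])
  res$ar_auc[nonref] <- accumulation_ratio(res$auc_0_168[nonref], res$auc_ref[nonref])
  res$cmax_ref <- res$auc_ref <- NULL
  res <- res[order(res$subject_id, res$week), ]
  rownames(res) <- NULL

  list(results = res, summary = nca_summary_table(res, ref_week = ref_week))
}

.as_sim_df <- function(sim) {
  if (inherits(sim, "data.frame")) {
    need <- c("subject_id", "drug", "week", "time_h", "conc_pg_ml")
    if (!all(need %in% names(sim)))
      stop("simulation data must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    return(sim)
  }
  if (inherits(sim, "conc_profile")) sim <- list(sim)
  do.call(rbind, lapply(sim, function(p) {
    w <- pmax(ceiling(p$times / 168), 1)
    # grid points at exact week boundaries belong to both windows; assign by
    # expanding each profile over the weeks it covers
    weeks_cov <- unique(c(w, pmax(floor(p$times / 168) + 1, 1)))
    do.call(rbind, lapply(sort(weeks_cov), function(wk) {
      win <- .week_window(wk)
      sel <- p$times >= win[1] - 1e-9 & p$times <= win[2] + 1e-9
      if (!any(sel)) return(NULL)
      data.frame(subject_id = p$subject_id, drug = p$drug, week = wk,
                 time_h = p$times[sel], conc_pg_ml = p$conc[sel],
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Weekly NCA summary table
#'
#' Summarizes per-subject NCA results into the standard reporting layout: one
#' block per week with N, Mean, SD, CV%, Geometric mean and Geometric CV% for
#' each parameter. Tmax cells are marked not calculated (`NA`, printed "NC"),
#' as is conventional for simulated profiles on a fixed grid; AR columns are
#' `NA` for the reference week.
#'
#' @param results per-subject NCA data.frame from [nca_by_week()].
#' @param ref_week reference week (AR columns suppressed there).
#' @param signif_digits significant digits for [format_summary_table()]
#'   consumers; the returned table keeps full precision.
#' @return data.frame with columns `week`, `statistic`, then one column per
#'   parameter (`cmax`, `tmax`, `auc_0_168`, `css_0_168`, `css_48_168`,
#'   `ar_cmax`, `ar_auc`).
#' @export
nca_summary_table <- function(results, ref_week = 1, signif_digits = 3) {
  pars <- c("cmax", "tmax", "auc_0_168", "css_0_168", "css_48_168",
            "ar_cmax", "ar_auc")
  stats_names <- c("n", "mean", "sd", "cv_pct", "geo_mean", "geo_cv_pct")
  out <- list()
  for (w in sort(unique(results$week))) {
    d <- results[results$week == w, ]
    block <- data.frame(week = w, statistic = stats_names,
                        stringsAsFactors = FALSE)
    for (p in pars) {
      v <- d[[p]]
      if (p == "tmax") {
        col <- c(nrow(d), rep(NA_real_, 5)) # Tmax: NC by convention
      } else if (all(is.na(v))) {
        col <- c(0, rep(NA_real_, 5)) # AR at the reference week
      } else {
        s <- summary_stats(v)
        col <- unlist(s[stats_names])
      }
      block[[p]] <- col
    }
    out[[length(out) + 1]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render a summary table at reporting precision
#'
#' Rounds numeric cells to 3 significant figures (the reporting convention)
#' and prints `NA` cells as `"NC"` (not calculated).
#'
#' @param summary_df output of [nca_summary_table()].
#' @param signif_digits significant digits (default 3).
#' @return a character data.frame ready for printing or CSV export.
#' @export
format_summary_table <- function(summary_df, signif_digits = 3) {
  out <- summary_df
  for (nm in setdiff(names(out), c("week", "statistic"))) {
    v <- out[[nm]]
    out[[nm]] <- vapply(seq_along(v), function(i) {
      if (is.na(v[i])) return("NC")
      if (out$statistic[i] == "n") return(format(v[i], scientific = FALSE))
      format(signif(v[i], signif_digits), scientific = FALSE)
    }, character(1))
  }
  out
}
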