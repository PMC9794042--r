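#' Structural parameters for the dual-route one-compartment patch model
#'
#' Bundles one individual's pharmacokinetic parameters for the weekly
#' transdermal delivery system (TDS) models. Both hormones share a
#' one-compartment disposition with two parallel absorption routes; the routes
#' differ by drug:
#'
#' * **EE** — a zero-order infusion directly into the central compartment for
#'   the full wear period (`D1`, fixed at 168 h) carrying `F_rel * F` of the
#'   dose, plus a first-order depot (rate constant `ka`) receiving
#'   `(1 - F_rel) * F` as a bolus at application.
#' * **LNG** — a zero-order infusion into the central compartment for `D1`
#'   carrying `(1 - F_rel) * F`, plus a zero-order infusion of duration `D2`
#'   into a depot that drains first-order (`ka`) into the central compartment,
#'   carrying `F_rel * F`.
#'
#' The LNG model additionally carries multiplicative week-3 effects on `V` and
#' `CL` (see [apply_week_effect()]); for EE both multipliers are 1.
#'
#' Internal units are hours, litres and nanograms throughout; note that ng/L is
#' numerically identical to pg/mL, the reporting unit.
#'
#' @param CL apparent clearance (L/h), > 0.
#' @param V apparent central volume (L), > 0.
#' @param ka first-order absorption rate constant (1/h), > 0.
#' @param F_total overall bioavailability F, in (0, 1]. Fixed at 0.30 (EE) or
#'   0.27 (LNG) in the study models.
#' @param F_rel route-split fraction in \[0, 1\]; the route receiving
#'   `F_rel * F` depends on the drug (see Details).
#' @param D1 duration of the zero-order input into the central compartment (h);
#'   168 h (one wear period) in the study models.
#' @param D2 duration of the zero-order input into the depot (h); LNG only,
#'   0 for EE.
#' @param drug `"EE"` or `"LNG"`; sets the route-split rule.
#' @param wk3_V_mult,wk3_CL_mult multiplicative week-3 effects on `V` and `CL`
#'   (dimensionless, > 0); 1 for EE.
#' @return An object of class `dual_route_params` (a named list).
#' @seealso [simulate_profile()], [weekly_regimen()]
#' @export
#' @examples
#' p <- dual_route_params(CL = 108, V = 2600, ka = 0.05, F_total = 0.30,
#'                        F_rel = 0.8, drug = "EE")
#' p$k # elimination rate constant CL/V
dual_route_params <- function(CL, V, ka, F_total, F_rel,
                              D1 = 168, D2 = 0,
                              drug = c("EE", "LNG"),
                              wk3_V_mult = 1, wk3_CL_mult = 1) {
  drug <- match.arg(drug)
  stopifnot(length(CL) == 1, length(V) == 1, length(ka) == 1)
  if (!is.finite(CL) || CL <= 0) stop("CL must be > 0", call. = FALSE)
  if (!is.finite(V) || V <= 0) stop("V must be > 0", call. = FALSE)
  if (!is.finite(ka) || ka <= 0) stop("ka must be > 0", call. = FALSE)
  if (F_total <= 0 || F_total > 1) stop("F_total must be in (0, 1]", call. = FALSE)
  if (F_rel < 0 || F_rel > 1) stop("F_rel must be in [0, 1]", call. = FALSE)
  if (D1 <= 0) stop("D1 must be > 0", call. = FALSE)
  if (D2 < 0) stop("D2 must be >= 0", call. = FALSE)
  if (drug == "LNG" && D2 == 0) stop("LNG model requires D2 > 0", call. = FALSE)
  if (wk3_V_mult <= 0 || wk3_CL_mult <= 0)
    stop("week-3 multipliers must be > 0", call. = FALSE)
  if (drug == "EE" && (wk3_V_mult != 1 || wk3_CL_mult != 1))
    stop("EE model has no week-3 effects (multipliers must be 1)", call. = FALSE)
  structure(
    list(CL = CL, V = V, ka = ka, k = CL / V,
         F_total = F_total, F_rel = F_rel, D1 = D1, D2 = D2, drug = drug,
         zero_route_fraction_rule = if (drug == "EE") "zero-order" else "first-order",
         wk3_V_mult = wk3_V_mult, wk3_CL_mult = wk3_CL_mult),
    class = "dual_route_params")
}

#' @export
print.dual_route_params <- function(x, ...) {
  cat(sprintf("<dual_route_params> %s model\n", x$drug))
  cat(sprintf("  CL = %.4g L/h, V = %.4g L (k = %.4g 1/h), ka = %.4g 1/h\n",
              x$CL, x$V, x$k, x$ka))
  cat(sprintf("  F = %.3g, F_rel = %.3g (%s route gets F_rel*F), D1 = %g h, D2 = %g h\n",
              x$F_total, x$F_rel, x$zero_route_fraction_rule, x$D1, x$D2))
  if (x$drug == "LNG")
    cat(sprintf("  week-3 effects: V x %.3g, CL x %.3g\n", x$wk3_V_mult, x$wk3_CL_mult))
  invisible(x)
}

#' Weekly patch regimen
#'
#' Builds an ordered sequence of patch-application events: `n_weeks` consecutive
#' weekly applications (168 h apart) followed by a patch-free period. The study
#' regimen is 12 consecutive weeks (84 days) of TDS use followed by a 7-day
#' patch-free period; each TDS contains 2.6 mg LNG and 2.3 mg EE.
#'
#' @param n_weeks number of consecutive weekly applications (>= 1).
#' @param amount_mg drug mass per patch (mg). Defaults per drug via
#'   [default_patch_amount()].
#' @param drug `"EE"` or `"LNG"`.
#' @param patch_free_h patch-free period after the last wear week (h).
#' @return An object of class `regimen` with fields `events` (data.frame with
#'   `t_app`, `amount_mg`, `drug`), `n_weeks`, `patch_free_h`, `horizon_h`.
#' @export
weekly_regimen <- function(n_weeks = 12, amount_mg = default_patch_amount(drug),
                           drug = c("EE", "LNG"), patch_free_h = 168) {
  drug <- match.arg(drug)
  stopifnot(n_weeks >= 1, amount_mg > 0, patch_free_h >= 0)
  events <- data.frame(t_app = 168 * (seq_len(n_weeks) - 1),
                       amount_mg = amount_mg, drug = drug,
                       stringsAsFactors = FALSE)
  structure(list(events = events, n_weeks = n_weeks,
                 patch_free_h = patch_free_h,
                 horizon_h = 168 * n_weeks + patch_free_h),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %d weekly %s patch(es) of %.3g mg, %g h patch-free (horizon %g h)\n",
              x$n_weeks, x$events$drug[1], x$events$amount_mg[1],
              x$patch_free_h, x$horizon_h))
  invisible(x)
}

#' Labeled patch content per drug
#'
#' The TDS contains 2.3 mg EE and 2.6 mg LNG. With `basis = "delivered"` the
#' weekly delivered amounts (210 ug EE, 840 ug LNG, i.e. 30 and 120 ug/day) are
#' returned instead, for use with `F_total = 1`.
#'
#' @param drug `"EE"` or `"LNG"`.
#' @param basis `"label"` (patch content; the default dose basis, multiplied by
#'   F in the model) or `"delivered"`.
#' @return dose in mg.
#' @export
default_patch_amount <- function(drug = c("EE", "LNG"),
                                 basis = c("label", "delivered")) {
  drug <- match.arg(drug)
  basis <- match.arg(basis)
  if (basis == "label") c(EE = 2.3, LNG = 2.6)[[drug]]
  else c(EE = 0.210, LNG = 0.840)[[drug]]
}

#' Concentration-time profile container
#'
#' @param subject_id subject identifier.
#' @param drug `"EE"` or `"LNG"`.
#' @param times monotone non-decreasing time grid (h).
#' @param conc concentrations (pg/mL), same length as `times`, all >= 0.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, drug, times, conc) {
  if (length(times) != length(conc))
    stop("times and conc must have equal length", call. = FALSE)
  if (is.unsorted(times)) stop("times must be non-decreasing", call. = FALSE)
  if (any(conc < -1e-9)) stop("concentrations must be non-negative", call. = FALSE)
  structure(list(subject_id = subject_id, drug = drug,
                 times = as.numeric(times), conc = pmax(as.numeric(conc), 0)),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> subject %s, %s, %d points over [%g, %g] h, Cmax %.4g pg/mL\n",
              x$subject_id, x$drug, length(x$times),
              min(x$times), max(x$times), max(x$conc)))
  invisible(x)
}

#' Write / read concentration profiles as long CSV
#'
#' Columns: `subject_id`, `drug`, `time_h`, `conc_pg_ml`.
#'
#' @param profiles a list of [conc_profile()] objects (or a single one).
#' @param path output CSV path.
#' @return `write_profiles_csv` returns `path` invisibly; `read_profiles_csv`
#'   returns a list of `conc_profile` objects.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "conc_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, drug = p$drug,
               time_h = p$times, conc_pg_ml = p$conc,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "drug", "time_h", "conc_pg_ml")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  split_df <- split(df, list(df$subject_id, df$drug), drop = TRUE)
  out <- lapply(split_df, function(d)
    conc_profile(d$subject_id[1], d$drug[1], d$time_h, d$conc_pg_ml))
  names(out) <- NULL
  out[order(vapply(out, function(p) as.character(p$subject_id), ""))]
}

#' Serialize parameters and regimen to a YAML/JSON config
#'
#' @param params a [dual_route_params()] object.
#' @param regimen a [weekly_regimen()] object.
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, regimen, path) {
  x <- list(
    params = params[c("CL", "V", "ka", "F_total", "F_rel", "D1", "D2",
                      "drug", "wk3_V_mult", "wk3_CL_mult")],
    regimen = list(n_weeks = regimen$n_weeks,
                   amount_mg = regimen$events$amount_mg[1],
                   drug = regimen$events$drug[1],
                   patch_free_h = regimen$patch_free_h))
  .write_config(x, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- .read_config(path)
  params <- do.call(dual_route_params, x$params)
  regimen <- weekly_regimen(n_weeks = x$regimen$n_weeks,
                            amount_mg = x$regimen$amount_mg,
                            drug = x$regimen$drug,
                            patch_free_h = x$regimen$patch_free_h)
  list(params = params, regimen = regimen)
}

.write_config <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
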