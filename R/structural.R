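#' Closed-form concentration kernels for the dual-route patch models
#'
#' These three kernels are the building blocks of the structural models. They
#' are unit-agnostic in mass: a dose rate in mass/h with `V` in litres yields a
#' concentration in mass/L (the package uses ng internally, so ng/L = pg/mL).
#'
#' `conc_zero_order_central()` is a zero-order infusion of rate `R0` for
#' duration `D` directly into the central compartment:
#' \deqn{C(t) = (R_0/CL)(1 - e^{-kt}), \quad t \le D}
#' \deqn{C(t) = (R_0/CL)(1 - e^{-kD}) e^{-k(t-D)}, \quad t > D}
#' with `k = CL/V`.
#'
#' `conc_first_order_depot()` is the Bateman solution for a depot bolus `A0`
#' absorbed first-order with rate constant `ka`:
#' \deqn{C(t) = \frac{A_0 k_a}{V (k_a - k)} (e^{-kt} - e^{-k_a t})}
#' switching to the analytic limit \eqn{A_0 k t e^{-kt}/V} when
#' `|ka - k|/k < 1e-8`.
#'
#' `conc_depot_infusion()` fills the depot at constant rate `R0d` for `D2`
#' hours; the depot drains first-order into the central compartment. The closed
#' form is the running-infusion response minus the same response delayed by
#' `D2` (superposition).
#'
#' @param params a [dual_route_params()] object (supplies `CL`, `V`, `ka`).
#' @param R0,R0d zero-order input rate (mass/h), >= 0.
#' @param D,D2 infusion duration (h), > 0.
#' @param A0 depot bolus amount (mass), >= 0.
#' @param t time(s) since the start of the input (h); vectorized. Negative
#'   times return 0.
#' @return concentration(s), same length as `t`.
#' @export
conc_zero_order_central <- function(params, R0, D, t) {
  stopifnot(inherits(params, "dual_route_params"))
  if (R0 < 0) stop("R0 must be >= 0", call. = FALSE)
  if (D <= 0) stop("infusion duration D must be > 0", call. = FALSE)
  .step_zero_central(params$k, params$CL, R0, t) -
    .step_zero_central(params$k, params$CL, R0, t - D)
}

# running zero-order infusion into central, started at time 0
.step_zero_central <- function(k, CL, R0, t) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (R0 / CL) * (1 - exp(-k * t[pos]))
  out
}

#' @rdname conc_zero_order_central
#' @export
conc_first_order_depot <- function(params, A0, t) {
  stopifnot(inherits(params, "dual_route_params"))
  if (A0 < 0) stop("A0 must be >= 0", call. = FALSE)
  .bateman(params$k, params$ka, params$V, A0, t)
}

.bateman <- function(k, ka, V, A0, t) {
  if (ka <= 0) stop("ka must be > 0", call. = FALSE)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  if (abs(ka - k) / k < 1e-8) {
    out[pos] <- A0 * k * tp * exp(-k * tp) / V
  } else {
    out[pos] <- (A0 * ka) / (V * (ka - k)) * (exp(-k * tp) - exp(-ka * tp))
  }
  out
}

#' @rdname conc_zero_order_central
#' @export
conc_depot_infusion <- function(params, R0d, D2, t) {
  stopifnot(inherits(params, "dual_route_params"))
  if (R0d < 0) stop("R0d must be >= 0", call. = FALSE)
  if (D2 <= 0 && R0d > 0) stop("depot infusion duration D2 must be > 0", call. = FALSE)
  if (R0d == 0) return(numeric(length(t)))
  .step_depot_infusion(params$k, params$ka, params$V, R0d, t) -
    .step_depot_infusion(params$k, params$ka, params$V, R0d, t - D2)
}

# running depot infusion response: depot filled at R0d since t = 0,
# first-order transfer ka to central, elimination k
.step_depot_infusion <- function(k, ka, V, R0d, t) {
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  ekt <- exp(-k * tp)
  if (abs(ka - k) / k < 1e-8) {
    mid <- tp * ekt
  } else {
    mid <- (ekt - exp(-ka * tp)) / (ka - k)
  }
  out[pos] <- (R0d / V) * ((1 - ekt) / k - mid)
  out
}

# per-route input masses (ng) for one dose event, following the drug's
# route-split rule: EE gives F_rel*F to the zero-order central route,
# LNG gives F_rel*F to the first-order (depot) route
.route_masses <- function(params, amount_mg) {
  amt_ng <- amount_mg * 1e6
  f_named <- params$F_rel * params$F_total * amt_ng
  f_other <- (1 - params$F_rel) * params$F_total * amt_ng
  if (params$drug == "EE") {
    list(zero_central = f_named, depot = f_other)
  } else {
    list(zero_central = f_other, depot = f_named)
  }
}

# superposition of all dose events for constant parameters
.profile_at <- function(params, regimen, times) {
  conc <- numeric(length(times))
  masses <- .route_masses(params, regimen$events$amount_mg[1])
  for (t_app in regimen$events$t_app) {
    tt <- times - t_app
    if (masses$zero_central > 0)
      conc <- conc + conc_zero_order_central(params, masses$zero_central / params$D1,
                                             params$D1, tt)
    if (masses$depot > 0) {
      if (params$drug == "EE") {
        conc <- conc + conc_first_order_depot(params, masses$depot, tt)
      } else {
        conc <- conc + conc_depot_infusion(params, masses$depot / params$D2,
                                           params$D2, tt)
      }
    }
  }
  conc
}

#' Simulate a single-subject concentration profile over a weekly regimen
#'
#' Linear superposition of the dual-route closed-form kernels over all patch
#' applications. For the LNG model, times falling in week 3 or later are
#' evaluated with the week-3 effect multipliers applied to `V` and `CL` for the
#' whole superposition (see [apply_week_effect()]); with both multipliers at 1
#' this reduces to a single analytic profile.
#'
#' @param params a [dual_route_params()] object.
#' @param regimen a [weekly_regimen()] object for the same drug.
#' @param times evaluation grid (h), sorted, within `[0, regimen$horizon_h]`.
#' @param subject_id identifier stored in the returned profile.
#' @return a [conc_profile()] with concentrations in pg/mL.
#' @export
#' @examples
#' p <- dual_route_params(CL = 108, V = 2600, ka = 0.05, F_total = 0.30,
#'                        F_rel = 0.8, drug = "EE")
#' reg <- weekly_regimen(n_weeks = 3, drug = "EE")
#' prof <- simulate_profile(p, reg, times = 0:504)
#' max(prof$conc)
simulate_profile <- function(params, regimen, times, subject_id = "typical") {
  stopifnot(inherits(params, "dual_route_params"), inherits(regimen, "regimen"))
  if (params$drug != regimen$events$drug[1])
    stop("params and regimen disagree on drug label", call. = FALSE)
  if (is.unsorted(times)) stop("time grid must be sorted", call. = FALSE)
  if (any(times < 0) || any(times > regimen$horizon_h))
    stop("time grid must lie within [0, horizon]", call. = FALSE)

  conc <- .predict_piecewise(params, regimen, times)
  conc_profile(subject_id, params$drug, times, conc)
}

# week-effect-aware prediction: times in week >= 3 evaluated with the week-3
# multipliers applied to the whole superposition ("persist" mode); in
# "week3_only" mode the multipliers are active only inside the week-3 window
.predict_piecewise <- function(params, regimen, times,
                               mode = c("persist", "week3_only")) {
  mode <- match.arg(mode)
  has_wk3 <- params$wk3_V_mult != 1 || params$wk3_CL_mult != 1
  if (!has_wk3) return(.profile_at(params, regimen, times))
  adj <- if (mode == "persist") times >= 2 * 168 else
    (times >= 2 * 168 & times <= 3 * 168)
  conc <- numeric(length(times))
  if (any(!adj)) conc[!adj] <- .profile_at(params, regimen, times[!adj])
  if (any(adj)) conc[adj] <- .profile_at(apply_week_effect(params, 3L),
                                         regimen, times[adj])
  conc
}

#' Numerically integrated reference solution (verification oracle)
#'
#' Integrates the depot + central two-compartment ODE system with piecewise-
#' constant infusion rates, segment by segment between input discontinuities,
#' using `deSolve::lsoda` at relative tolerance 1e-10. Parameters are held
#' constant over the horizon (no week-effect switching), so it verifies
#' [simulate_profile()] directly whenever the week-3 multipliers are 1, and
#' verifies each parameter regime of the piecewise LNG profile separately
#' otherwise.
#'
#' @inheritParams simulate_profile
#' @param full if `TRUE`, also return the depot, central and eliminated amounts
#'   and cumulative input (ng) at each grid time, for mass-balance checks.
#' @return a [conc_profile()], or (if `full`) a data.frame with columns
#'   `time`, `conc`, `A_depot`, `A_central`, `A_elim`, `input`.
#' @export
ode_oracle <- function(params, regimen, times, subject_id = "oracle",
                       full = FALSE) {
  stopifnot(inherits(params, "dual_route_params"), inherits(regimen, "regimen"))
  if (is.unsorted(times)) stop("time grid must be sorted", call. = FALSE)
  masses <- .route_masses(params, regimen$events$amount_mg[1])
  t_app <- regimen$events$t_app

  # piecewise-constant input rates; EE depot doses are boluses at application
  rate_windows <- list()
  boluses <- data.frame(time = numeric(0), amt = numeric(0))
  for (ta in t_app) {
    if (masses$zero_central > 0)
      rate_windows[[length(rate_windows) + 1]] <-
        c(start = ta, end = ta + params$D1,
          r_central = masses$zero_central / params$D1, r_depot = 0)
    if (masses$depot > 0) {
      if (params$drug == "EE") {
        boluses <- rbind(boluses, data.frame(time = ta, amt = masses$depot))
      } else {
        rate_windows[[length(rate_windows) + 1]] <-
          c(start = ta, end = ta + params$D2,
            r_central = 0, r_depot = masses$depot / params$D2)
      }
    }
  }
  rw <- if (length(rate_windows)) do.call(rbind, rate_windows) else
    matrix(numeric(0), ncol = 4, dimnames = list(NULL, c("start", "end", "r_central", "r_depot")))

  breaks <- sort(unique(c(0, max(times), t_app, rw[, "start"], rw[, "end"],
                          boluses$time)))
  breaks <- breaks[breaks <= max(times) + 1e-9]
  grid <- sort(unique(c(times, breaks)))

  deriv <- function(t, y, p) {
    list(c(p["r_depot"] - params$ka * y[1],
           p["r_central"] + params$ka * y[1] - params$k * y[2],
           params$k * y[2]))
  }

  total_input <- length(t_app) * (masses$zero_central + masses$depot)
  atol <- 1e-15 * max(1, total_input)
  state <- c(A_depot = 0, A_central = 0, A_elim = 0)
  out <- matrix(NA_real_, nrow = length(grid), ncol = 3,
                dimnames = list(NULL, names(state)))
  out[1, ] <- state
  for (seg in seq_len(length(breaks))) {
    t0 <- breaks[seg]
    t1 <- if (seg < length(breaks)) breaks[seg + 1] else max(grid)
    # apply boluses scheduled at the segment start
    hit <- abs(boluses$time - t0) < 1e-9
    if (any(hit)) state["A_depot"] <- state["A_depot"] + sum(boluses$amt[hit])
    idx0 <- which(abs(grid - t0) < 1e-12)
    out[idx0, ] <- matrix(state, nrow = length(idx0), ncol = 3, byrow = TRUE)
    if (t1 <= t0 + 1e-12) next
    active <- rw[rw[, "start"] <= t0 + 1e-9 & rw[, "end"] >= t1 - 1e-9, , drop = FALSE]
    p <- c(r_central = sum(active[, "r_central"]), r_depot = sum(active[, "r_depot"]))
    seg_times <- grid[grid >= t0 - 1e-12 & grid <= t1 + 1e-12]
    if (abs(seg_times[1] - t0) > 1e-12) seg_times <- c(t0, seg_times)
    if (abs(seg_times[length(seg_times)] - t1) > 1e-12) seg_times <- c(seg_times, t1)
    sol <- tryCatch(
      deSolve::lsoda(y = state, times = seg_times, func = deriv, parms = p,
                     rtol = 1e-11, atol = atol),
      error = function(e)
        stop(sprintf("ODE integration failed in segment starting at t = %g h: %s",
                     t0, conditionMessage(e)), call. = FALSE))
    keep <- sol[, "time"] %in% grid
    rows <- match(round(sol[keep, "time"], 9), round(grid, 9))
    out[rows, ] <- sol[keep, c("A_depot", "A_central", "A_elim")]
    state <- sol[nrow(sol), c("A_depot", "A_central", "A_elim")]
  }

  idx <- match(round(times, 9), round(grid, 9))
  conc <- pmax(out[idx, "A_central"], 0) / params$V
  if (full) {
    input <- vapply(times, function(t) {
      rate_in <- if (nrow(rw)) sum(pmin(pmax(t - rw[, "start"], 0),
                                        rw[, "end"] - rw[, "start"]) *
                                     (rw[, "r_central"] + rw[, "r_depot"])) else 0
      rate_in + sum(boluses$amt[boluses$time <= t + 1e-9])
    }, numeric(1))
    return(data.frame(time = times, conc = conc,
                      A_depot = out[idx, "A_depot"],
                      A_central = out[idx, "A_central"],
                      A_elim = out[idx, "A_elim"],
                      input = input))
  }
  conc_profile(subject_id, params$drug, times, conc)
}
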