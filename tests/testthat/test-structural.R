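# structural model closed forms vs independent oracles

test_that("zero-order central infusion matches the closed form", {
  p <- dual_route_params(CL = 1, V = 10, ka = 1, F_total = 0.3, F_rel = 0.8,
                         drug = "EE")
  # long infusion reaches the R0/CL plateau
  expect_equal(conc_zero_order_central(p, R0 = 100, D = 2000, t = 1000),
               100, tolerance = 1e-5)
  # half the plateau after one elimination half-life
  expect_equal(conc_zero_order_central(p, 100, 2000, log(2) / p$k), 50,
               tolerance = 1e-9)
  # no input, no concentration
  expect_identical(conc_zero_order_central(p, 0, 100, c(0, 5, 500)),
                   c(0, 0, 0))
  # continuity across the infusion stop
  eps <- 1e-8
  expect_equal(conc_zero_order_central(p, 100, 24, 24 - eps),
               conc_zero_order_central(p, 100, 24, 24 + eps),
               tolerance = 1e-6)
  expect_error(dual_route_params(CL = -1, V = 10, ka = 1, F_total = 0.3,
                                 F_rel = 0.5, drug = "EE"), "CL")
})

test_that("Bateman depot solution peaks where theory says and handles limits", {
  p <- dual_route_params(CL = 1, V = 10, ka = 1, F_total = 0.3, F_rel = 0.8,
                         drug = "EE")
  k <- 0.1; ka <- 1
  tmax <- log(ka / k) / (ka - k)
  expect_equal(tmax, 2.5584, tolerance = 1e-4)
  cmax <- conc_first_order_depot(p, A0 = 100, t = tmax)
  expect_equal(cmax, 7.74, tolerance = 1e-3)
  # nothing absorbed at t = 0
  expect_identical(conc_first_order_depot(p, 100, 0), 0)
  # instantaneous-absorption limit approaches a bolus
  pf <- dual_route_params(CL = 1, V = 10, ka = 1000 * 0.1, F_total = 0.3,
                          F_rel = 0.8, drug = "EE")
  tt <- seq(5 / pf$ka, 40, by = 0.5)
  bolus <- 100 / 10 * exp(-0.1 * tt)
  expect_lt(max(abs(conc_first_order_depot(pf, 100, tt) - bolus) / bolus), 0.01)
  # ka -> k degeneracy switches to the analytic limit, continuously
  pk <- dual_route_params(CL = 1, V = 10, ka = 0.1 * (1 + 1e-9),
                          F_total = 0.3, F_rel = 0.8, drug = "EE")
  pk2 <- dual_route_params(CL = 1, V = 10, ka = 0.1 * (1 + 1e-7),
                           F_total = 0.3, F_rel = 0.8, drug = "EE")
  expect_equal(conc_first_order_depot(pk, 100, 10),
               conc_first_order_depot(pk2, 100, 10), tolerance = 1e-5)
})

test_that("depot infusion solution agrees with numerical integration", {
  p <- dual_route_params(CL = 5, V = 50, ka = 0.5, F_total = 0.27,
                         F_rel = 0.5, D2 = 24, drug = "LNG")
  # zero input
  expect_identical(conc_depot_infusion(p, 0, 24, c(1, 10, 100)), c(0, 0, 0))
  # never-ending infusion plateaus at R0d/CL (mass balance)
  expect_equal(conc_depot_infusion(p, 100, 1e7, 1e5), 100 / 5,
               tolerance = 1e-6)
  # against an independent ODE integration at t = 24 h
  deriv <- function(t, y, parms) {
    r <- if (t <= 24) 100 else 0
    list(c(r - 0.5 * y[1], 0.5 * y[1] - 0.1 * y[2]))
  }
  sol <- deSolve::lsoda(c(0, 0), times = c(0, 24, 48), deriv, parms = NULL,
                        rtol = 1e-11, atol = 1e-11)
  expect_equal(conc_depot_infusion(p, 100, 24, c(24, 48)),
               sol[2:3, 3] / 50, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("analytic superposition and the ODE oracle agree over random draws", {
  set.seed(101)
  for (drug in c("EE", "LNG")) {
    reg <- weekly_regimen(n_weeks = 3, drug = drug)
    tt <- seq(0, 672, by = 8)
    for (rep in 1:10) {
      p <- rand_params(drug)
      a <- simulate_profile(p, reg, tt)$conc
      o <- ode_oracle(p, reg, tt)$conc
      expect_lt(max(abs(a - o) / pmax(abs(o), 1e-6 * max(o))), 1e-6)
    }
  }
})

test_that("profiles are linear in dose and non-negative", {
  set.seed(7)
  p <- rand_params("LNG")
  tt <- seq(0, 672, by = 4)
  reg1 <- weekly_regimen(n_weeks = 3, amount_mg = 2.6, drug = "LNG")
  reg2 <- weekly_regimen(n_weeks = 3, amount_mg = 5.2, drug = "LNG")
  c1 <- simulate_profile(p, reg1, tt)$conc
  c2 <- simulate_profile(p, reg2, tt)$conc
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_true(all(c1 >= 0))
})

test_that("route degeneracy reduces the superposition to a single kernel", {
  # EE with F_rel = 1: everything through the zero-order central route
  p <- dual_route_params(CL = 10, V = 300, ka = 0.05, F_total = 0.30,
                         F_rel = 1, drug = "EE")
  reg <- weekly_regimen(n_weeks = 1, amount_mg = 2.3, drug = "EE")
  tt <- seq(0, 336, by = 2)
  prof <- simulate_profile(p, reg, tt)
  mass <- 0.30 * 2.3e6
  expect_equal(prof$conc,
               conc_zero_order_central(p, mass / 168, 168, tt),
               tolerance = 1e-12)
})

test_that("weekly superposition reproduces the accumulation closed form", {
  # near-bolus first-order route only: AUC_w / AUC_1 = (1-e^(-wk tau))/(1-e^(-k tau))
  k <- 0.02
  p <- dual_route_params(CL = 2, V = 2 / k, ka = 1000 * k, F_total = 0.3,
                         F_rel = 0, drug = "EE")
  reg <- weekly_regimen(n_weeks = 12, drug = "EE")
  f <- profile_fun(p, reg)
  auc1 <- auc_quadrature(f, 0, 168)
  auc12 <- auc_quadrature(f, 11 * 168, 12 * 168)
  expected <- (1 - exp(-12 * k * 168)) / (1 - exp(-k * 168))
  expect_equal(auc12 / auc1, expected, tolerance = 1e-4)
})

test_that("concentration decays monotonically once all input has stopped", {
  p <- rand_params("EE")
  reg <- weekly_regimen(n_weeks = 2, drug = "EE", patch_free_h = 336)
  # after the last patch is exhausted (t > 168 + D1) there is no input
  tt <- seq(340, 670, by = 2)
  prof <- simulate_profile(p, reg, tt)
  expect_true(all(diff(prof$conc) < 0))
})

test_that("the ODE oracle conserves mass and returns zero without doses", {
  p <- rand_params("LNG")
  reg <- weekly_regimen(n_weeks = 2, drug = "LNG")
  tt <- seq(0, 500, by = 10)
  full <- ode_oracle(p, reg, tt, full = TRUE)
  err <- abs(full$A_depot + full$A_central + full$A_elim - full$input) /
    pmax(full$input, 1)
  expect_lt(max(err), 1e-6)
  # zero-dose regimen: identically zero
  reg0 <- weekly_regimen(n_weeks = 2, drug = "LNG")
  reg0$events$amount_mg <- 1e-300 # numerically zero input
  expect_lt(max(ode_oracle(p, reg0, tt)$conc), 1e-290)
})

test_that("week-effect piecewise profile matches the oracle per regime", {
  p <- dual_route_params(CL = 2.8, V = 112, ka = 0.03, F_total = 0.27,
                         F_rel = 0.55, D2 = 90, drug = "LNG",
                         wk3_V_mult = 0.85, wk3_CL_mult = 0.78)
  reg <- weekly_regimen(n_weeks = 4, drug = "LNG")
  tt_early <- seq(0, 335, by = 5)
  tt_late <- seq(336, 672, by = 6)
  prof_early <- simulate_profile(p, reg, tt_early)$conc
  prof_late <- simulate_profile(p, reg, tt_late)$conc
  base <- p; p3 <- apply_week_effect(p, 3)
  expect_equal(prof_early, ode_oracle(base, reg, tt_early)$conc,
               tolerance = 1e-6)
  expect_equal(prof_late, ode_oracle(p3, reg, tt_late)$conc,
               tolerance = 1e-6)
})

test_that("profile and config serialization round-trip", {
  p <- dual_route_params(CL = 2.8, V = 112, ka = 0.03, F_total = 0.27,
                         F_rel = 0.55, D2 = 90, drug = "LNG")
  reg <- weekly_regimen(n_weeks = 3, drug = "LNG")
  cfgf <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(p, reg, cfgf)
  back <- read_model_config(cfgf)
  expect_equal(back$params$CL, p$CL)
  expect_equal(back$regimen$n_weeks, 3)

  prof <- simulate_profile(p, reg, seq(0, 504, by = 12), subject_id = "S1")
  csvf <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(prof, csvf)
  back2 <- read_profiles_csv(csvf)
  expect_length(back2, 1)
  expect_equal(back2[[1]]$conc, prof$conc, tolerance = 1e-6)
})
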