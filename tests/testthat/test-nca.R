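# noncompartmental analysis: AUC rules, Cmax/Tmax, Css, AR, summaries

test_that("linear-up/log-down AUC reproduces closed-form cases", {
  t <- 0:168
  # constant profile: rectangle via the linear rule (equal endpoints)
  expect_equal(auc_lin_up_log_down(t, rep(10, 169), 0, 168), 1.68,
               tolerance = 1e-12)
  # single falling segment: log trapezoid
  expect_equal(auc_lin_up_log_down(c(0, 1), c(10, 5), 0, 1),
               (5 / log(2)) / 1000, tolerance = 1e-12)
  # log rule integrates a monoexponential exactly on any grid
  k <- 0.07; C0 <- 120
  for (npts in c(10, 47, 169)) {
    tt <- seq(0, 168, length.out = npts)
    cc <- C0 * exp(-k * tt)
    truth <- (C0 / k) * (1 - exp(-k * 168)) / 1000
    expect_equal(auc_lin_up_log_down(tt, cc, 0, 168), truth,
                 tolerance = 1e-12)
  }
  # zeros force the linear rule (no log of 0)
  expect_equal(auc_lin_up_log_down(c(0, 1, 2), c(4, 0, 0), 0, 2),
               2 / 1000, tolerance = 1e-12)
  expect_error(auc_lin_up_log_down(t, rep(1, 169), 0, 200), "bounds")
})

test_that("window AUC is additive at an interior grid point", {
  set.seed(4)
  tt <- 0:168
  cc <- abs(stats::rnorm(169, 50, 20)) + 1
  whole <- auc_lin_up_log_down(tt, cc, 0, 168)
  parts <- auc_lin_up_log_down(tt, cc, 0, 48) +
    auc_lin_up_log_down(tt, cc, 48, 168)
  expect_equal(whole, parts, tolerance = 1e-14)
})

test_that("Cmax/Tmax use the grid argmax with earliest-tie rule", {
  # strictly increasing: Tmax at the window end
  pr <- conc_profile("a", "EE", 0:10, 0:10)
  expect_equal(cmax_tmax(pr, c(0, 10))$tmax, 10)
  # plateau: earliest attaining time
  pr2 <- conc_profile("a", "EE", 0:5, c(0, 1, 5, 5, 2, 1))
  expect_equal(cmax_tmax(pr2, c(0, 5))$tmax, 2)
  # Bateman sampled hourly: argmax at the grid point nearest the true peak
  p <- dual_route_params(CL = 1, V = 10, ka = 1, F_total = 0.3, F_rel = 0.5,
                         drug = "EE")
  tt <- 0:24
  pr3 <- conc_profile("a", "EE", tt, conc_first_order_depot(p, 100, tt))
  expect_equal(cmax_tmax(pr3, c(0, 24))$tmax, 3)
  # elapsed-time reporting within a later window
  pr4 <- conc_profile("a", "EE", 336:340, c(1, 2, 9, 4, 3))
  expect_equal(cmax_tmax(pr4, c(336, 340))$tmax, 2)
})

test_that("Css is the window-average concentration", {
  expect_equal(css(5.47, 0, 168), 32.6, tolerance = 5e-3)
  expect_equal(css(6.42, 0, 168), 38.2, tolerance = 5e-3)
  expect_equal(css(0.168, 0, 168), 1, tolerance = 1e-12)
  expect_error(css(1, 10, 10), "positive length")
})

test_that("accumulation ratios behave and match published ratio arithmetic", {
  expect_equal(accumulation_ratio(5, 5), 1)
  expect_equal(signif(accumulation_ratio(6.42, 5.47), 3), 1.17)
  expect_equal(signif(accumulation_ratio(323, 192), 3), 1.68)
  expect_error(accumulation_ratio(1, 0), "> 0")
})

test_that("summary statistics match their defining formulas", {
  s <- summary_stats(c(1, 10, 100))
  expect_equal(s$geo_mean, 10)
  s2 <- summary_stats(c(10, 10, 10))
  expect_equal(s2$sd, 0)
  expect_equal(s2$cv_pct, 0)
  expect_equal(s2$geo_cv_pct, 0)
  # log-normal sample: geo CV% -> 100*sqrt(e^(s^2)-1)
  set.seed(8)
  x <- exp(stats::rnorm(1e6, 0, 1))
  expect_equal(summary_stats(x)$geo_cv_pct, 100 * sqrt(exp(1) - 1),
               tolerance = 0.01)
  expect_error(summary_stats(c(1, -1, 2)), "positive")
})

test_that("weekly NCA table has the reporting shape and the AR identity", {
  pop <- ee_test_population()
  reg <- weekly_regimen(n_weeks = 12, drug = "EE")
  sim <- simulate_population(pop, reg, weeks = c(1, 3, 12), n = 40, seed = 21)
  out <- nca_by_week(sim, weeks = c(1, 3, 12), ref_week = 1)
  res <- out$results
  expect_equal(nrow(res), 40 * 3)
  expect_true(all(is.na(res$ar_auc[res$week == 1])))
  expect_true(all(!is.na(res$ar_auc[res$week != 1])))

  # geometric mean of per-subject AR equals the ratio of geometric means
  gm <- function(x) exp(mean(log(x)))
  for (w in c(3, 12)) {
    ar_gm <- gm(res$ar_auc[res$week == w])
    ratio <- gm(res$auc_0_168[res$week == w]) / gm(res$auc_0_168[res$week == 1])
    expect_equal(ar_gm, ratio, tolerance = 1e-12)
  }

  # Css(0-168)*168 reproduces the AUC exactly after unit conversion
  expect_equal(res$css_0_168 * 168 / 1000, res$auc_0_168, tolerance = 1e-12)

  # summary layout: 3 week blocks x 6 statistics, Tmax marked NC
  smry <- out$summary
  expect_equal(nrow(smry), 18)
  expect_setequal(unique(smry$week), c(1, 3, 12))
  fmt <- format_summary_table(smry)
  expect_true(all(fmt$tmax[fmt$statistic != "n"] == "NC"))
  expect_true(all(fmt$ar_auc[fmt$week == 1 & fmt$statistic != "n"] == "NC"))

  # superposition monotonicity of accumulation
  expect_gte(gm(res$ar_auc[res$week == 12]), gm(res$ar_auc[res$week == 3]))
  expect_gte(gm(res$ar_auc[res$week == 3]), 1)
  expect_gte(gm(res$ar_cmax[res$week == 12]), gm(res$ar_cmax[res$week == 3]) - 1e-9)
})

test_that("identical weekly profiles give unit ratios and equal summaries", {
  tt <- 0:168
  cc <- 30 + 10 * sin(tt / 20)
  sim <- do.call(rbind, lapply(c(1, 3, 12), function(w)
    data.frame(subject_id = rep(c("A", "B"), each = 169), drug = "EE", week = w,
               time_h = rep((w - 1) * 168 + tt, 2),
               conc_pg_ml = c(cc, cc * 1.3))))
  out <- nca_by_week(sim, weeks = c(1, 3, 12))
  expect_true(all(abs(out$results$ar_auc[out$results$week != 1] - 1) < 1e-12))
  s1 <- out$summary[out$summary$week == 1, -1]
  s12 <- out$summary[out$summary$week == 12, -1]
  expect_equal(s1[c("cmax", "auc_0_168", "css_0_168")],
               s12[c("cmax", "auc_0_168", "css_0_168")], ignore_attr = TRUE)
})

test_that("NCA accepts conc_profile lists covering the windows", {
  p <- ee_test_population()$theta
  reg <- weekly_regimen(n_weeks = 3, drug = "EE")
  profs <- list(simulate_profile(p, reg, 0:504, subject_id = "X"),
                simulate_profile(p, reg, 0:504, subject_id = "Y"))
  out <- nca_by_week(profs, weeks = c(1, 3))
  expect_equal(sort(unique(out$results$subject_id)), c("X", "Y"))
  expect_equal(nrow(out$results), 4)
})
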