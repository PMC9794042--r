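# estimators: two-stage, Laplace, and the qualification diagnostics

reg3 <- weekly_regimen(n_weeks = 3, drug = "EE")

test_that("freeing F alongside F_rel is refused as unidentifiable", {
  expect_error(model_settings("EE", reg3, estimate_F = TRUE),
               "not simultaneously identifiable")
})

test_that("two-stage recovers exactly from noise-free homogeneous data", {
  pop <- ee_test_population(omega = c(CL = 0, V = 0, ka = 0), sigma_prop = 0)
  trial <- generate_trial(pop, ati_cl14_design("EE"), reg3, seed = 1,
                          noise_free = TRUE)
  fit <- fit_two_stage(trial, model_settings("EE", reg3))
  th <- fit$estimates$theta
  for (nm in c("CL", "V", "ka", "F_rel"))
    expect_equal(th[[nm]], pop$theta[[nm]], tolerance = 1e-3)
  expect_true(all(fit$estimates$omega < 1e-4))
  expect_equal(fit$convergence$status, "converged")
})

test_that("two-stage omega_CL lands near truth over a 50-subject trial", {
  pop <- ee_test_population(omega = c(CL = 0.3, V = 0.2, ka = 0.3))
  trial <- generate_trial(pop, ati_cl14_design("EE", 50), reg3, seed = 31)
  fit <- fit_two_stage(trial, model_settings("EE", reg3))
  expect_gt(fit$estimates$omega[["CL"]], 0.2)
  expect_lt(fit$estimates$omega[["CL"]], 0.4)
})

test_that("estimates are equivariant to relabelling subjects", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE"), reg3, seed = 9)
  fit1 <- fit_two_stage(trial, model_settings("EE", reg3))
  relab <- trial
  relab$subject_id <- paste0("Z", relab$subject_id)
  fit2 <- fit_two_stage(relab, model_settings("EE", reg3))
  expect_equal(fit1$estimates$theta$CL, fit2$estimates$theta$CL)
  expect_equal(fit1$estimates$omega, fit2$estimates$omega)
})

test_that("BLQ-free data fit identically under drop and substitute rules", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE"), reg3, seed = 17)
  no_blq <- trial[!trial$blq, ]
  f1 <- fit_two_stage(no_blq, model_settings("EE", reg3, blq = "drop"))
  f2 <- fit_two_stage(no_blq, model_settings("EE", reg3, blq = "lloq2"))
  expect_identical(f1$estimates$theta, f2$estimates$theta)
})

test_that("all-BLQ subjects are excluded with a warning", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE", 4), reg3, seed = 2)
  trial$blq[trial$subject_id == "S0001"] <- TRUE
  trial$dv[trial$subject_id == "S0001"] <- NA_real_
  expect_warning(fit <- fit_two_stage(trial, model_settings("EE", reg3)),
                 "S0001")
  expect_false("S0001" %in% fit$individual$subject_id)
})

test_that("two-stage recovery sharpens as the trial grows", {
  pop <- ee_test_population()
  lt <- log(unlist(pop$theta[c("CL", "V", "ka")]))
  rmse <- vapply(c(18, 50, 100), function(n) {
    errs <- vapply(1:3, function(r) {
      trial <- generate_trial(pop, ati_cl14_design("EE", n), reg3,
                              seed = 7000 + r)
      fit <- fit_two_stage(trial, model_settings("EE", reg3))
      le <- log(unlist(fit$estimates$theta[c("CL", "V", "ka")]))
      sqrt(mean((le - lt)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[3], rmse[2])
})

test_that("Laplace shrinks omega on data generated without variability", {
  pop0 <- ee_test_population(omega = c(CL = 0, V = 0, ka = 0),
                             sigma_prop = 0.1)
  trial <- generate_trial(pop0, ati_cl14_design("EE", 20), reg3, seed = 4)
  settings <- model_settings("EE", reg3)
  init <- ee_test_population(omega = c(CL = 0.2, V = 0.2, ka = 0.2),
                             sigma_prop = 0.1)
  fit <- fit_laplace(trial, settings, init = init,
                     control = list(compute_rse = FALSE))
  expect_true(all(fit$estimates$omega[c("CL", "V", "ka")] < 0.05))
})

test_that("the generating parameters dominate perturbed ones in likelihood", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE", 50), reg3, seed = 12)
  settings <- model_settings("EE", reg3)
  bad_theta <- pop$theta
  bad <- population_model(
    dual_route_params(CL = bad_theta$CL * 2, V = bad_theta$V,
                      ka = bad_theta$ka, F_total = bad_theta$F_total,
                      F_rel = bad_theta$F_rel, drug = "EE"),
    omega = pop$omega, sigma = pop$sigma)
  expect_lt(laplace_objective(trial, settings, pop),
            laplace_objective(trial, settings, bad))
})

test_that("Laplace reports RSEs and a monotone-improved objective", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE", 25), reg3, seed = 23)
  settings <- model_settings("EE", reg3)
  ts <- fit_two_stage(trial, settings)
  fit <- fit_laplace(trial, settings, init = ts$estimates)
  # the optimized objective cannot exceed the objective at the start value
  expect_lte(fit$objective,
             laplace_objective(trial, settings, ts$estimates) + 1e-6)
  expect_true(all(fit$rse_pct[c("CL", "V")] > 0))
})

test_that("goodness-of-fit residuals vanish on a perfect fit", {
  pop <- ee_test_population(omega = c(CL = 0, V = 0, ka = 0), sigma_prop = 0)
  trial <- generate_trial(pop, ati_cl14_design("EE", 6), reg3, seed = 3,
                          noise_free = TRUE)
  fit <- fit_two_stage(trial, model_settings("EE", reg3))
  gof <- gof_diagnostics(fit, trial)
  expect_lt(max(abs(gof$res)), 1e-4 * max(gof$dv))
  expect_lt(max(abs(gof$dv - gof$ipred)), 1e-4 * max(gof$dv))
  expect_true(all(gof$pred > 0))
})

test_that("weighted residuals are calibrated under proportional error", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE"), reg3, seed = 77)
  settings <- model_settings("EE", reg3)
  ts <- fit_two_stage(trial, settings)
  fit <- fit_laplace(trial, settings, init = ts$estimates,
                     control = list(compute_rse = FALSE))
  gof <- gof_diagnostics(fit, trial)
  expect_gt(stats::ks.test(gof$iwres, "pnorm")$p.value, 0.01)
  expect_lt(abs(mean(gof$cwres, na.rm = TRUE)), 0.3)
})

test_that("VPC bands are reproducible and detect gross misfit", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE"), reg3, seed = 5)
  settings <- model_settings("EE", reg3)
  fit <- fit_two_stage(trial, settings)
  b1 <- vpc(fit, trial, reg3, n_sim = 50, seed = 42)
  b2 <- vpc(fit, trial, reg3, n_sim = 50, seed = 42)
  expect_identical(b1, b2)

  # self-consistency: observed medians mostly inside the simulated median band
  med <- b1[b1$percentile == "p50", ]
  inside <- mean(med$observed >= med$sim_lo & med$observed <= med$sim_hi)
  expect_gte(inside, 0.85)

  # constant-zero observations against a positive model: outside everywhere
  zero <- trial
  zero$dv <- 0
  zero$blq <- FALSE
  bz <- vpc(fit, zero, reg3, n_sim = 50, seed = 42)
  bz <- bz[bz$time_h > 0, ]
  expect_true(all(bz$observed < bz$sim_lo | bz$observed > bz$sim_hi))
})

test_that("fit reports serialize to a parameter table", {
  pop <- ee_test_population()
  trial <- generate_trial(pop, ati_cl14_design("EE", 8), reg3, seed = 19)
  fit <- fit_two_stage(trial, model_settings("EE", reg3))
  rep_f <- withr::local_tempfile(fileext = ".yaml")
  tab_f <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(fit, rep_f, tab_f)
  tab <- utils::read.csv(tab_f)
  expect_true(all(c("parameter", "estimate", "rse_pct", "transform",
                    "fixed") %in% names(tab)))
  expect_true(tab$fixed[tab$parameter == "F_total"])
  expect_false(tab$fixed[tab$parameter == "CL"])
})
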