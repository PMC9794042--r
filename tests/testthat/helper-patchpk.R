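# shared fixtures: random parameter draws and small population models

# log-uniform draw over [lo, hi]
runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# random structural parameters; half_life_range constrains both k and ka
rand_params <- function(drug = "EE", half_life_range = NULL) {
  if (is.null(half_life_range)) {
    k <- runif_log(1, 0.005, 0.5)
    ka <- runif_log(1, 0.005, 0.5)
  } else {
    k <- log(2) / stats::runif(1, half_life_range[1], half_life_range[2])
    ka <- log(2) / stats::runif(1, half_life_range[1], half_life_range[2])
  }
  CL <- runif_log(1, 1, 100)
  dual_route_params(CL = CL, V = CL / k, ka = ka,
                    F_total = if (drug == "EE") 0.30 else 0.27,
                    F_rel = stats::runif(1, 0.2, 0.8),
                    D1 = 168, D2 = if (drug == "LNG") runif_log(1, 24, 150) else 0,
                    drug = drug)
}

# small EE population with known parameters, used across estimation tests
ee_test_population <- function(omega = c(CL = 0.25, V = 0.2, ka = 0.3),
                               sigma_prop = 0.15) {
  theta <- dual_route_params(CL = 107, V = 2700, ka = 0.02, F_total = 0.30,
                             F_rel = 0.65, drug = "EE")
  population_model(theta, omega = omega,
                   sigma = list(kind = "proportional", prop = sigma_prop,
                                add = 0))
}

lng_test_population <- function(omega = c(CL = 0.3, V = 0.25, F_rel = 0.4),
                                sigma_prop = 0.15) {
  theta <- dual_route_params(CL = 2.8, V = 112, ka = 0.03, F_total = 0.27,
                             F_rel = 0.55, D2 = 90, drug = "LNG",
                             wk3_V_mult = 0.85, wk3_CL_mult = 0.78)
  population_model(theta, omega = omega,
                   sigma = list(kind = "proportional", prop = sigma_prop,
                                add = 0))
}

# profile as a plain function of (possibly unsorted) time, for quadrature
profile_fun <- function(p, reg) function(t) patchpk:::.profile_at(p, reg, t)

# adaptive-quadrature window AUC, independent of the trapezoid implementation
auc_quadrature <- function(f, lo, hi) {
  stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0)$value
}
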