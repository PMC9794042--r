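// Compiled hot paths: the dual-route concentration kernel and the per-subject
// Laplace inner problem (3-dimensional eta mode finding + log-determinant).
// These mirror the R reference kernels in R/structural.R; agreement is
// asserted in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

// parameter vector layout (see .par_vec() in R/estimation.R):
// 0 CL, 1 V, 2 ka, 3 F_total, 4 F_rel, 5 D1, 6 D2,
// 7 drug (0 = EE, 1 = LNG), 8 wk3_V_mult, 9 wk3_CL_mult,
// 10 week-effect mode (0 = persist, 1 = week3_only)

static inline double step_zero_central(double k, double CL, double R0,
                                       double t) {
  if (t <= 0.0) return 0.0;
  return (R0 / CL) * (1.0 - std::exp(-k * t));
}

static inline double bateman(double k, double ka, double V, double A0,
                             double t) {
  if (t <= 0.0) return 0.0;
  if (std::fabs(ka - k) / k < 1e-8)
    return A0 * k * t * std::exp(-k * t) / V;
  return (A0 * ka) / (V * (ka - k)) * (std::exp(-k * t) - std::exp(-ka * t));
}

static inline double step_depot_inf(double k, double ka, double V, double R0d,
                                    double t) {
  if (t <= 0.0) return 0.0;
  double ekt = std::exp(-k * t);
  double mid;
  if (std::fabs(ka - k) / k < 1e-8) mid = t * ekt;
  else mid = (ekt - std::exp(-ka * t)) / (ka - k);
  return (R0d / V) * ((1.0 - ekt) / k - mid);
}

// superposition at constant parameters
static void profile_const(const double *par, const NumericVector &t_apps,
                          double amount_ng, const NumericVector &times,
                          const std::vector<int> &idx, std::vector<double> &out) {
  double CL = par[0], V = par[1], ka = par[2];
  double k = CL / V;
  double f_named = par[4] * par[3] * amount_ng;
  double f_other = (1.0 - par[4]) * par[3] * amount_ng;
  bool ee = par[7] < 0.5;
  double m_zc = ee ? f_named : f_other;
  double m_dep = ee ? f_other : f_named;
  double D1 = par[5], D2 = par[6];

  for (size_t j = 0; j < idx.size(); ++j) {
    double t = times[idx[j]];
    double c = 0.0;
    for (int e = 0; e < t_apps.size(); ++e) {
      double tt = t - t_apps[e];
      if (tt <= 0.0) continue;
      if (m_zc > 0.0) {
        double r0 = m_zc / D1;
        c += step_zero_central(k, CL, r0, tt) -
             step_zero_central(k, CL, r0, tt - D1);
      }
      if (m_dep > 0.0) {
        if (ee) {
          c += bateman(k, ka, V, m_dep, tt);
        } else {
          double r0d = m_dep / D2;
          c += step_depot_inf(k, ka, V, r0d, tt) -
               step_depot_inf(k, ka, V, r0d, tt - D2);
        }
      }
    }
    out[idx[j]] = c;
  }
}

static void profile_piecewise(const double *par, const NumericVector &t_apps,
                              double amount_ng, const NumericVector &times,
                              std::vector<double> &out) {
  bool has_wk3 = par[8] != 1.0 || par[9] != 1.0;
  int n = times.size();
  out.assign(n, 0.0);
  if (!has_wk3) {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    profile_const(par, t_apps, amount_ng, times, all, out);
    return;
  }
  std::vector<int> base_idx, adj_idx;
  bool persist = par[10] < 0.5;
  for (int i = 0; i < n; ++i) {
    double t = times[i];
    bool adj = persist ? (t >= 336.0) : (t >= 336.0 && t <= 504.0);
    if (adj) adj_idx.push_back(i); else base_idx.push_back(i);
  }
  if (!base_idx.empty())
    profile_const(par, t_apps, amount_ng, times, base_idx, out);
  if (!adj_idx.empty()) {
    double par3[11];
    std::copy(par, par + 11, par3);
    par3[1] = par[1] * par[8]; // V
    par3[0] = par[0] * par[9]; // CL
    profile_const(par3, t_apps, amount_ng, times, adj_idx, out);
  }
}

// [[Rcpp::export(name = ".cpp_profile")]]
NumericVector cpp_profile(NumericVector par, NumericVector t_apps,
                          double amount_ng, NumericVector times) {
  std::vector<double> out;
  profile_piecewise(REAL(par), t_apps, amount_ng, times, out);
  return wrap(out);
}

// ---- Laplace inner problem -------------------------------------------------

struct SubjData {
  std::vector<double> y;
  NumericVector times;
};

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double logit(double p) { return std::log(p / (1.0 - p)); }

// negative joint log-density for one subject at eta (dimension 3)
static double g_eta(const double *eta, const double *base_par,
                    const NumericVector &t_apps, double amount_ng,
                    const SubjData &sd, const double *omega, double sigma,
                    int etamode, std::vector<double> &scratch) {
  double par[11];
  std::copy(base_par, base_par + 11, par);
  par[0] *= std::exp(eta[0]);
  par[1] *= std::exp(eta[1]);
  if (etamode == 0) par[2] *= std::exp(eta[2]);
  else par[4] = invlogit(logit(base_par[4]) + eta[2]);
  profile_piecewise(par, t_apps, amount_ng, sd.times, scratch);
  const double LOG2PI = 1.8378770664093453;
  double g = 0.0;
  for (size_t j = 0; j < sd.y.size(); ++j) {
    double f = scratch[j];
    if (f <= 0.0 || !std::isfinite(f)) return 1e10;
    double r = (sd.y[j] - f) / (sigma * f);
    g += 0.5 * LOG2PI + std::log(sigma * f) + 0.5 * r * r;
  }
  for (int m = 0; m < 3; ++m) {
    double z = eta[m] / omega[m];
    g += 0.5 * z * z + std::log(omega[m]);
  }
  g += 1.5 * LOG2PI;
  return g;
}

// 3x3 determinant
static inline double det3(const double H[3][3]) {
  return H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
         H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
         H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
}

// solve H s = -grad for 3x3 via Cramer; returns false if near-singular
static bool solve3(const double H[3][3], const double *grad, double *s) {
  double d = det3(H);
  if (std::fabs(d) < 1e-300) return false;
  double Hx[3][3];
  for (int c = 0; c < 3; ++c) {
    std::copy(&H[0][0], &H[0][0] + 9, &Hx[0][0]);
    for (int r = 0; r < 3; ++r) Hx[r][c] = -grad[r];
    s[c] = det3(Hx) / d;
  }
  return true;
}

static void fd_grad_hess(const double *eta, const double *base_par,
                         const NumericVector &t_apps, double amount_ng,
                         const SubjData &sd, const double *omega, double sigma,
                         int etamode, std::vector<double> &scratch,
                         double g0, double *grad, double H[3][3]) {
  const double h = 1e-4;
  double e[3], gp[3], gm[3];
  for (int i = 0; i < 3; ++i) {
    std::copy(eta, eta + 3, e);
    e[i] = eta[i] + h;
    gp[i] = g_eta(e, base_par, t_apps, amount_ng, sd, omega, sigma, etamode,
                  scratch);
    e[i] = eta[i] - h;
    gm[i] = g_eta(e, base_par, t_apps, amount_ng, sd, omega, sigma, etamode,
                  scratch);
    grad[i] = (gp[i] - gm[i]) / (2.0 * h);
    H[i][i] = (gp[i] - 2.0 * g0 + gm[i]) / (h * h);
  }
  for (int i = 0; i < 3; ++i)
    for (int j = i + 1; j < 3; ++j) {
      std::copy(eta, eta + 3, e);
      e[i] += h; e[j] += h;
      double gpp = g_eta(e, base_par, t_apps, amount_ng, sd, omega, sigma,
                         etamode, scratch);
      std::copy(eta, eta + 3, e);
      e[i] += h; e[j] -= h;
      double gpm = g_eta(e, base_par, t_apps, amount_ng, sd, omega, sigma,
                         etamode, scratch);
      std::copy(eta, eta + 3, e);
      e[i] -= h; e[j] += h;
      double gmp = g_eta(e, base_par, t_apps, amount_ng, sd, omega, sigma,
                         etamode, scratch);
      std::copy(eta, eta + 3, e);
      e[i] -= h; e[j] -= h;
      double gmm = g_eta(e, base_par, t_apps, amount_ng, sd, omega, sigma,
                         etamode, scratch);
      H[i][j] = H[j][i] = (gpp - gpm - gmp + gmm) / (4.0 * h * h);
    }
}

// damped-Newton mode finding for one subject; returns -2 log L_i (Laplace)
static double laplace_subject(double *eta, const double *base_par,
                              const NumericVector &t_apps, double amount_ng,
                              const SubjData &sd, const double *omega,
                              double sigma, int etamode, int max_iter,
                              std::vector<double> &scratch) {
  double g0 = g_eta(eta, base_par, t_apps, amount_ng, sd, omega, sigma,
                    etamode, scratch);
  double grad[3], H[3][3], s[3], trial[3];
  for (int it = 0; it < max_iter; ++it) {
    fd_grad_hess(eta, base_par, t_apps, amount_ng, sd, omega, sigma, etamode,
                 scratch, g0, grad, H);
    double gnorm = std::sqrt(grad[0] * grad[0] + grad[1] * grad[1] +
                             grad[2] * grad[2]);
    if (gnorm < 1e-8) break;
    double lambda = 0.0;
    bool moved = false;
    for (int tries = 0; tries < 12; ++tries) {
      double Hd[3][3];
      std::copy(&H[0][0], &H[0][0] + 9, &Hd[0][0]);
      for (int i = 0; i < 3; ++i) Hd[i][i] += lambda;
      bool ok = solve3(Hd, grad, s);
      if (ok) {
        for (int i = 0; i < 3; ++i) trial[i] = eta[i] + s[i];
        double gt = g_eta(trial, base_par, t_apps, amount_ng, sd, omega,
                          sigma, etamode, scratch);
        if (gt < g0) {
          double drop = g0 - gt;
          std::copy(trial, trial + 3, eta);
          g0 = gt;
          moved = true;
          if (drop < 1e-10) it = max_iter; // converged
          break;
        }
      }
      lambda = (lambda == 0.0) ? 1e-4 : lambda * 10.0;
    }
    if (!moved) break;
  }
  // final Hessian at the mode for the Laplace determinant
  fd_grad_hess(eta, base_par, t_apps, amount_ng, sd, omega, sigma, etamode,
               scratch, g0, grad, H);
  double d = det3(H);
  if (d <= 0.0) {
    // fall back to the prior curvature if the numerical Hessian degenerates
    d = 1.0;
    for (int i = 0; i < 3; ++i) d *= 1.0 / (omega[i] * omega[i]);
  }
  const double LOG2PI = 1.8378770664093453;
  return 2.0 * g0 - 3.0 * LOG2PI + std::log(d);
}

// [[Rcpp::export(name = ".cpp_laplace_obj")]]
List cpp_laplace_obj(NumericVector par, NumericVector t_apps,
                     double amount_ng, List times_list, List y_list,
                     NumericVector omega, double sigma, NumericMatrix eta0,
                     int etamode, int max_iter) {
  int n = times_list.size();
  NumericMatrix eta_out(3, n);
  double total = 0.0;
  std::vector<double> scratch;
  for (int i = 0; i < n; ++i) {
    SubjData sd;
    sd.times = as<NumericVector>(times_list[i]);
    NumericVector yv = as<NumericVector>(y_list[i]);
    sd.y.assign(yv.begin(), yv.end());
    double eta[3] = {eta0(0, i), eta0(1, i), eta0(2, i)};
    double m2ll = laplace_subject(eta, REAL(par), t_apps, amount_ng, sd,
                                  REAL(omega), sigma, etamode, max_iter,
                                  scratch);
    for (int m = 0; m < 3; ++m) eta_out(m, i) = eta[m];
    if (!std::isfinite(m2ll)) m2ll = 1e10;
    total += m2ll;
  }
  return List::create(_["objective"] = total, _["eta"] = eta_out);
}
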