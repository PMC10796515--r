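#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Two-compartment tumour model:
//   dL/dt = lambda * L * (1 - L/K) - eta * L
//   dN/dt = eta * L - zeta * N
// Radiotherapy at dose times t_i transfers a volume gamma*L from L to N
// instantaneously (total volume conserved across each dose).
//
// Integration between events uses the Dormand-Prince 5(4) embedded
// Runge-Kutta pair with adaptive step size. The system is non-stiff over
// the parameter ranges admitted by the log-uniform box prior.

struct Pars {
  double lambda, K, eta, zeta;
};

static inline void rhs(const Pars &p, const double y[2], double dy[2]) {
  dy[0] = p.lambda * y[0] * (1.0 - y[0] / p.K) - p.eta * y[0];
  dy[1] = p.eta * y[0] - p.zeta * y[1];
}

// Dormand-Prince coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order solution weights (for the error estimate)
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate the smooth system from t0 to t1 in place; returns false on
// step-size collapse.
static bool integrate(const Pars &p, double y[2], double t0, double t1,
                      double rtol, double atol) {
  if (t1 <= t0) return true;
  double t = t0;
  double h = std::min(1.0, t1 - t0);
  const double hmin = 1e-12 * std::max(1.0, t1 - t0);
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], y5[2];
  rhs(p, y, k1);
  int iter = 0;
  while (t < t1) {
    if (++iter > 1000000) return false;
    if (h > t1 - t) h = t1 - t;
    yt[0] = y[0] + h * a21 * k1[0];
    yt[1] = y[1] + h * a21 * k1[1];
    rhs(p, yt, k2);
    yt[0] = y[0] + h * (a31 * k1[0] + a32 * k2[0]);
    yt[1] = y[1] + h * (a31 * k1[1] + a32 * k2[1]);
    rhs(p, yt, k3);
    yt[0] = y[0] + h * (a41 * k1[0] + a42 * k2[0] + a43 * k3[0]);
    yt[1] = y[1] + h * (a41 * k1[1] + a42 * k2[1] + a43 * k3[1]);
    rhs(p, yt, k4);
    yt[0] = y[0] + h * (a51 * k1[0] + a52 * k2[0] + a53 * k3[0] + a54 * k4[0]);
    yt[1] = y[1] + h * (a51 * k1[1] + a52 * k2[1] + a53 * k3[1] + a54 * k4[1]);
    rhs(p, yt, k5);
    yt[0] = y[0] + h * (a61 * k1[0] + a62 * k2[0] + a63 * k3[0] +
                        a64 * k4[0] + a65 * k5[0]);
    yt[1] = y[1] + h * (a61 * k1[1] + a62 * k2[1] + a63 * k3[1] +
                        a64 * k4[1] + a65 * k5[1]);
    rhs(p, yt, k6);
    y5[0] = y[0] + h * (b1 * k1[0] + b3 * k3[0] + b4 * k4[0] + b5 * k5[0] +
                        b6 * k6[0]);
    y5[1] = y[1] + h * (b1 * k1[1] + b3 * k3[1] + b4 * k4[1] + b5 * k5[1] +
                        b6 * k6[1]);
    rhs(p, y5, k7);
    double err = 0.0;
    for (int i = 0; i < 2; i++) {
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / 2.0);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      y[0] = y5[0];
      y[1] = y5[1];
      k1[0] = k7[0];  // FSAL
      k1[1] = k7[1];
      // guard against tiny negative round-off; dynamics keep L, N >= 0
      if (y[0] < 0 && y[0] > -atol) y[0] = 0;
      if (y[1] < 0 && y[1] > -atol) y[1] = 0;
    }
    double fac = 0.9 * std::pow(err > 0 ? err : 1e-10, -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < hmin) return false;
  }
  return true;
}

// Simulate one parameter set over a merged event/observation timeline.
// pars = (lambda, K, gamma, zeta, eta, phi0) on the natural scale.
// Observations coincident with a dose report the post-dose (L, N); the
// total volume V is continuous across doses either way.
static bool sim_one(const double *pars, const std::vector<double> &dose,
                    const std::vector<double> &obs, double rtol, double atol,
                    bool exp_dose, double *Lout, double *Nout) {
  Pars p;
  p.lambda = pars[0];
  p.K = pars[1];
  double gamma = pars[2];
  p.zeta = pars[3];
  p.eta = pars[4];
  double phi0 = pars[5];
  double y[2] = {1.0 - phi0, phi0};
  double t = 0.0;
  size_t io = 0, id = 0;
  const size_t no = obs.size(), nd = dose.size();
  const double keep = exp_dose ? std::exp(-gamma) : 1.0 - gamma;
  // record any observations at exactly t = 0 before any dosing at t > 0
  while (io < no && id < nd && obs[io] <= 0 && dose[id] > 0) {
    Lout[io] = y[0];
    Nout[io] = y[1];
    io++;
  }
  while (io < no || id < nd) {
    bool next_is_dose;
    double tnext;
    if (id >= nd) {
      next_is_dose = false;
      tnext = obs[io];
    } else if (io >= no) {
      next_is_dose = true;
      tnext = dose[id];
    } else if (dose[id] <= obs[io]) {
      next_is_dose = true;  // dose first so coincident obs sees post-dose state
      tnext = dose[id];
    } else {
      next_is_dose = false;
      tnext = obs[io];
    }
    if (tnext > t) {
      if (!integrate(p, y, t, tnext, rtol, atol)) return false;
      t = tnext;
    }
    if (next_is_dose) {
      double transfer = (1.0 - keep) * y[0];
      y[0] -= transfer;
      y[1] += transfer;
      id++;
      // emit every observation at exactly this time (post-dose)
      while (io < no && obs[io] == t) {
        Lout[io] = y[0];
        Nout[io] = y[1];
        io++;
      }
    } else {
      Lout[io] = y[0];
      Nout[io] = y[1];
      io++;
    }
  }
  return true;
}

// [[Rcpp::export(name = ".sim_gtv_cpp")]]
List sim_gtv_cpp(NumericVector pars, NumericVector dose_times,
                 NumericVector obs_times, double rtol = 1e-8,
                 double atol = 1e-10, bool exp_dose = false) {
  std::vector<double> dose(dose_times.begin(), dose_times.end());
  std::vector<double> obs(obs_times.begin(), obs_times.end());
  int n = obs.size();
  NumericVector L(n), N(n);
  bool ok = sim_one(REAL(pars), dose, obs, rtol, atol, exp_dose,
                    REAL(L), REAL(N));
  if (!ok) {
    std::fill(L.begin(), L.end(), NA_REAL);
    std::fill(N.begin(), N.end(), NA_REAL);
  }
  return List::create(_["L"] = L, _["N"] = N, _["ok"] = ok);
}

// Batch simulation: theta rows on the natural scale, one row per particle.
// Returns V (and optionally L, N) at the observation times.
// [[Rcpp::export(name = ".sim_gtv_many_cpp")]]
List sim_gtv_many_cpp(NumericMatrix pars, NumericVector dose_times,
                      NumericVector obs_times, double rtol = 1e-8,
                      double atol = 1e-10, bool exp_dose = false,
                      bool keep_compartments = false) {
  std::vector<double> dose(dose_times.begin(), dose_times.end());
  std::vector<double> obs(obs_times.begin(), obs_times.end());
  int m = pars.nrow(), n = obs.size();
  NumericMatrix V(m, n);
  NumericMatrix L(keep_compartments ? m : 1, keep_compartments ? n : 1);
  NumericMatrix N(keep_compartments ? m : 1, keep_compartments ? n : 1);
  LogicalVector ok(m);
  std::vector<double> Lrow(n), Nrow(n), prow(6);
  for (int j = 0; j < m; j++) {
    for (int k = 0; k < 6; k++) prow[k] = pars(j, k);
    bool good = sim_one(&prow[0], dose, obs, rtol, atol, exp_dose,
                        &Lrow[0], &Nrow[0]);
    ok[j] = good;
    for (int i = 0; i < n; i++) {
      V(j, i) = good ? Lrow[i] + Nrow[i] : NA_REAL;
      if (keep_compartments) {
        L(j, i) = good ? Lrow[i] : NA_REAL;
        N(j, i) = good ? Nrow[i] : NA_REAL;
      }
    }
  }
  if (keep_compartments)
    return List::create(_["V"] = V, _["L"] = L, _["N"] = N, _["ok"] = ok);
  return List::create(_["V"] = V, _["ok"] = ok);
}

// Gaussian log-likelihood of observed fold-change volumes under the model,
// evaluated for each particle: sd = alpha1 + alpha2 * V_model.
// [[Rcpp::export(name = ".loglik_many_cpp")]]
NumericVector loglik_many_cpp(NumericMatrix pars, NumericVector dose_times,
                              NumericVector obs_times, NumericVector v_obs,
                              NumericVector n_obs, double alpha1,
                              double alpha2, double rtol = 1e-8,
                              double atol = 1e-10, bool exp_dose = false) {
  std::vector<double> dose(dose_times.begin(), dose_times.end());
  std::vector<double> obs(obs_times.begin(), obs_times.end());
  int m = pars.nrow(), n = obs.size();
  bool has_n = n_obs.size() == n;
  NumericVector ll(m);
  std::vector<double> Lrow(n), Nrow(n), prow(6);
  const double l2pi = std::log(2.0 * M_PI);
  for (int j = 0; j < m; j++) {
    for (int k = 0; k < 6; k++) prow[k] = pars(j, k);
    if (!sim_one(&prow[0], dose, obs, rtol, atol, exp_dose, &Lrow[0],
                 &Nrow[0])) {
      ll[j] = R_NegInf;
      continue;
    }
    double s = 0.0;
    for (int i = 0; i < n; i++) {
      double V = Lrow[i] + Nrow[i];
      double sd = alpha1 + alpha2 * V;
      if (!(sd > 0) || !std::isfinite(V)) {
        s = R_NegInf;
        break;
      }
      double z = (v_obs[i] - V) / sd;
      s += -0.5 * (z * z + l2pi) - std::log(sd);
      if (has_n && std::isfinite(n_obs[i])) {
        double sdn = alpha1 + alpha2 * Nrow[i];
        if (!(sdn > 0)) {
          s = R_NegInf;
          break;
        }
        double zn = (n_obs[i] - Nrow[i]) / sdn;
        s += -0.5 * (zn * zn + l2pi) - std::log(sdn);
      }
    }
    ll[j] = s;
  }
  return ll;
}
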