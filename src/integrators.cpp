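// Adaptive Dormand-Prince 5(4) integration of the community-membership
// model. The vector field is smooth (normal CDF), not stiff in the
// regimes explored, but tolerances are tight (rtol 1e-9 / atol 1e-12)
// so the stepper and the right-hand sides live in C++.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double inflow, learning, omega, phi, K, p_tilde, mu, sigma;
  double Fq; // F(p_tilde), precomputed
};

inline double norm_cdf(double x, double mu, double sigma) {
  return 0.5 * std::erfc(-(x - mu) / (sigma * M_SQRT2));
}

// model ids: 0 = reduced (S, I, y, p); 1 = raw (S, N, V, D, C);
// 2 = crash-boundary (y, p) with S = K, I -> 0
void rhs(int model, const Params& pr, const double* x, double* dx) {
  if (model == 0) {
    const double S = x[0], I = x[1], y = x[2], p = x[3];
    const double D = pr.K - S - I;
    const double p_bar = y * p + (1.0 - y) * pr.Fq;
    double Delta = pr.p_tilde - p_bar;
    if (Delta < 0.0) Delta = 0.0;
    const double join = pr.inflow * S * I / pr.K;
    dx[0] = pr.phi * D - join;
    dx[1] = join - pr.omega * Delta * y * I;
    dx[2] = pr.learning * Delta * (1.0 - y)
          - pr.omega * Delta * y * (1.0 - y)
          - (pr.inflow * S / pr.K) * y;
    dx[3] = norm_cdf(p_bar, pr.mu, pr.sigma) - p;
  } else if (model == 1) {
    const double S = x[0], N = x[1], V = x[2], D = x[3], C = x[4];
    const double I = N + V;
    const double p = (V > 0.0) ? C / V : pr.Fq;
    const double p_bar = (I > 0.0) ? (N * pr.Fq + V * p) / I : pr.p_tilde;
    double Delta = pr.p_tilde - p_bar;
    if (Delta < 0.0) Delta = 0.0;
    const double join = pr.inflow * S * I / pr.K;
    const double learn = pr.learning * Delta * N;
    const double leave = pr.omega * Delta;
    dx[0] = pr.phi * D - join;
    dx[1] = join - learn;
    dx[2] = learn - leave * V;
    dx[3] = leave * V - pr.phi * D;
    dx[4] = learn * p + V * (norm_cdf(p_bar, pr.mu, pr.sigma) - p) - leave * C;
  } else {
    // boundary (y, p) dynamics at S = K, I -> 0+
    const double y = x[0], p = x[1];
    const double p_bar = y * p + (1.0 - y) * pr.Fq;
    double Delta = pr.p_tilde - p_bar;
    if (Delta < 0.0) Delta = 0.0;
    dx[0] = pr.learning * Delta * (1.0 - y)
          - pr.omega * Delta * y * (1.0 - y)
          - pr.inflow * y;
    dx[1] = norm_cdf(p_bar, pr.mu, pr.sigma) - p;
  }
}

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 35.0 / 384 - 5179.0 / 57600,
             e3 = 500.0 / 1113 - 7571.0 / 16695,
             e4 = 125.0 / 192 - 393.0 / 640,
             e5 = -2187.0 / 6784 + 92097.0 / 339200,
             e6 = 11.0 / 84 - 187.0 / 2100,
             e7 = -1.0 / 40;

} // namespace

// [[Rcpp::export(name = ".cpp_integrate")]]
List cpp_integrate(int model, NumericVector par, NumericVector y0,
                   NumericVector times, double rtol, double atol,
                   double max_step = 0.0) {
  Params pr;
  pr.inflow = par[0]; pr.learning = par[1]; pr.omega = par[2];
  pr.phi = par[3]; pr.K = par[4]; pr.p_tilde = par[5];
  pr.mu = par[6]; pr.sigma = par[7];
  pr.Fq = norm_cdf(pr.p_tilde, pr.mu, pr.sigma);

  const int n = y0.size();
  const int nt = times.size();
  NumericMatrix out(nt, n);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), ynew(n);

  double t = times[0];
  for (int j = 0; j < n; ++j) out(0, j) = y[j];

  if (max_step <= 0.0) max_step = (times[nt - 1] - times[0]);
  double h = std::min(1e-3, max_step);
  rhs(model, pr, y.data(), k1.data());
  bool have_k1 = true;

  long n_steps = 0;
  const long max_steps = 100000000L;

  for (int it = 1; it < nt; ++it) {
    const double t_target = times[it];
    while (t < t_target) {
      if (++n_steps > max_steps)
        stop("integration exceeded the maximum step count at t = %g", t);
      bool hit = false;
      if (t + h >= t_target) { h = t_target - t; hit = true; }
      if (!have_k1) { rhs(model, pr, y.data(), k1.data()); have_k1 = true; }

      for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      rhs(model, pr, ytmp.data(), k2.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      rhs(model, pr, ytmp.data(), k3.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      rhs(model, pr, ytmp.data(), k4.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      rhs(model, pr, ytmp.data(), k5.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      rhs(model, pr, ytmp.data(), k6.data());
      for (int j = 0; j < n; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
      rhs(model, pr, ynew.data(), k7.data());

      double err = 0.0;
      for (int j = 0; j < n; ++j) {
        const double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                               e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        const double sc = atol + rtol * std::max(std::fabs(y[j]),
                                                 std::fabs(ynew[j]));
        const double r = ej / sc;
        err += r * r;
      }
      err = std::sqrt(err / n);

      if (err <= 1.0) {
        t += h;
        y = ynew;
        k1 = k7; // FSAL
        double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        h = std::min(h * fac, max_step);
        if (hit && t >= t_target) break;
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        if (fac < 0.1) fac = 0.1;
        h *= fac;
        if (h < 1e-14 * std::max(1.0, std::fabs(t)))
          stop("step size underflow at t = %g (err = %g)", t, err);
      }
      if (h <= 0.0) stop("non-positive step size at t = %g", t);
    }
    for (int j = 0; j < n; ++j) out(it, j) = y[j];
  }

  return List::create(_["states"] = out, _["n_steps"] = n_steps);
}
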