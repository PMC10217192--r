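#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled order-parameter / noise system
//   dm  = [(1 - xi) m - alpha m^2 - beta m^3 - gamma m^5] dt + sigma dW
//   dxi = G (m^2 - M^2) dt
// Records every `record_stride` steps (including the initial state).
// Uses R's RNG (norm_rand), so set.seed() on the R side controls the draws.
// [[Rcpp::export]]
NumericMatrix em_path_cpp(double alpha, double beta, double gamma,
                          double G, double M, double sigma,
                          double m0, double xi0, double dt,
                          int n_steps, int record_stride, bool clamp_xi) {
  if (dt <= 0.0) stop("dt must be positive");
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (record_stride < 1) stop("record_stride must be >= 1");

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix out(n_rec, 3);
  double m = m0, xi = xi0;
  const double sqdt = std::sqrt(dt);
  const double M2 = M * M;
  out(0, 0) = 0.0; out(0, 1) = m; out(0, 2) = xi;
  int r = 1;
  for (int i = 1; i <= n_steps; ++i) {
    const double m2 = m * m;
    double mn = m + ((1.0 - xi) * m - alpha * m2 - beta * m2 * m
                     - gamma * m2 * m2 * m) * dt;
    if (sigma > 0.0) mn += sigma * sqdt * norm_rand();
    double xin = xi + G * (m2 - M2) * dt;
    if (clamp_xi && xin < 0.0) xin = 0.0;
    m = mn; xi = xin;
    if (!std::isfinite(m) || !std::isfinite(xi))
      stop("non-finite state at step %d (t = %g)", i, i * dt);
    if (i % record_stride == 0 && r < n_rec) {
      out(r, 0) = i * dt; out(r, 1) = m; out(r, 2) = xi;
      ++r;
    }
  }
  return out;
}

// Damped gradient flow of the potential at fixed noise, run to steady state.
// The flow stage selects the basin; a Newton polish on the drift then pins
// the root (the flow alone decays only algebraically on the flat potential
// at a critical noise level).
// [[Rcpp::export]]
double relax_fixed_xi_cpp(double alpha, double beta, double gamma,
                          double xi, double m0,
                          double dt, double tol, int max_steps) {
  double m = m0;
  auto f = [&](double x) {
    const double x2 = x * x;
    return (1.0 - xi) * x - alpha * x2 - beta * x2 * x - gamma * x2 * x2 * x;
  };
  auto fp = [&](double x) {
    const double x2 = x * x;
    return (1.0 - xi) - 2.0 * alpha * x - 3.0 * beta * x2
           - 5.0 * gamma * x2 * x2;
  };
  int i = 0;
  for (; i < max_steps; ++i) {
    const double fv = f(m);
    if (std::fabs(fv) < tol) return m;
    m += fv * dt;
    if (!std::isfinite(m))
      stop("gradient flow diverged (unbounded descent direction)");
    if (i >= 1000000) break;  // hand the flat tail to Newton
  }
  double mn = m;
  for (int k = 0; k < 200; ++k) {
    const double fv = f(mn);
    if (std::fabs(fv) < tol * 1e-3) return mn;
    const double d = fp(mn);
    if (std::fabs(d) < 1e-14) break;
    const double step = fv / d;
    if (!std::isfinite(step) || std::fabs(step) > 1.0) break;
    mn -= step;
  }
  if (std::fabs(f(mn)) < std::fabs(f(m))) m = mn;
  if (std::fabs(f(m)) >= tol)
    warning("relaxation did not reach |drift| < tol");
  return m;
}
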