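#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// Potential gradient dU/dx in kJ/mol/nm.
//   pot_type 0: polynomial; `dc` holds the ascending coefficients of dU/dx.
//   pot_type 1: uniform lookup table of dU/dx starting at gx0 with spacing gdx;
//               linear interpolation inside, linear continuation outside (the
//               table is built to already contain the harmonic wall region, so
//               continuing its end slope extends the same wall).
static inline double eval_grad(double x, int pot_type,
                               const double* dc, int ndc,
                               double gx0, double gdx,
                               const double* gt, int ngt) {
  if (pot_type == 0) {
    double r = 0.0;
    for (int i = ndc - 1; i >= 0; --i) r = r * x + dc[i];
    return r;
  }
  double u = (x - gx0) / gdx;
  if (u <= 0.0) return gt[0] + (gt[1] - gt[0]) * u;
  double nm1 = (double)(ngt - 1);
  if (u >= nm1) return gt[ngt - 1] + (gt[ngt - 1] - gt[ngt - 2]) * (u - nm1);
  int i = (int)u;
  double f = u - (double)i;
  return gt[i] * (1.0 - f) + gt[i + 1] * f;
}

// GLE integrator through the Markovian embedding: the coordinate (x, v) obeys
//   m dv = [ -dU/dx + sum_i k_i (y_i - x) ] dt,      k_i = gamma_i / tau_i,
// and each overdamped auxiliary variable obeys the exact OU update over dt,
//   gamma_i dy_i = -k_i (y_i - x) dt + sqrt(2 kT gamma_i) dW_i.
// Eliminating the y_i yields a GLE with kernel sum_i (gamma_i/tau_i) exp(-t/tau_i).
// Splitting per step (symmetric in the deterministic part):
//   half kick v, half drift x, full exact OU update of y at fixed x,
//   half drift x, recompute force, half kick v.
// [[Rcpp::export]]
List gle_integrate_cpp(double x0, double v0, NumericVector y0,
                       double mass, double kT, double dt,
                       double n_steps, int out_stride, double n_equil,
                       NumericVector gammas, NumericVector taus,
                       int pot_type, NumericVector grad_coefs,
                       double gx0, double gdx, NumericVector grad_tab,
                       int seed, bool store_v) {
  const int nc = gammas.size();
  std::vector<double> k(nc), a(nc), s(nc), y(nc);
  for (int i = 0; i < nc; ++i) {
    k[i] = gammas[i] / taus[i];
    a[i] = std::exp(-dt / taus[i]);
    s[i] = std::sqrt(std::max(0.0, kT / k[i] * (1.0 - a[i] * a[i])));
    y[i] = y0[i];
  }
  const double* dc = grad_coefs.begin();
  const int ndc = grad_coefs.size();
  const double* gt = grad_tab.begin();
  const int ngt = grad_tab.size();

  long long nst = (long long)(n_steps + 0.5);
  long long neq = (long long)(n_equil + 0.5);
  long long nout = nst / out_stride;
  NumericVector xs(nout);
  NumericVector vs(store_v ? nout : 0);

  std::mt19937_64 gen((uint64_t)seed);
  std::normal_distribution<double> nd(0.0, 1.0);

  double x = x0, v = v0;
  double F = -eval_grad(x, pot_type, dc, ndc, gx0, gdx, gt, ngt);
  for (int i = 0; i < nc; ++i) F += k[i] * (y[i] - x);

  const double hdt = 0.5 * dt;
  long long total = neq + nst;
  long long iout = 0;
  for (long long step = 1; step <= total; ++step) {
    v += hdt * F / mass;
    x += hdt * v;
    for (int i = 0; i < nc; ++i)
      y[i] = x + (y[i] - x) * a[i] + s[i] * nd(gen);
    x += hdt * v;
    F = -eval_grad(x, pot_type, dc, ndc, gx0, gdx, gt, ngt);
    for (int i = 0; i < nc; ++i) F += k[i] * (y[i] - x);
    v += hdt * F / mass;
    if ((step & 1023LL) == 0 && !std::isfinite(x + v))
      stop("GLE integration diverged near step " + std::to_string(step));
    if (step > neq) {
      long long idx = step - neq;
      if (idx % out_stride == 0) {
        xs[iout] = x;
        if (store_v) vs[iout] = v;
        ++iout;
      }
    }
  }
  if (!std::isfinite(x + v))
    stop("GLE integration diverged at final step");
  return List::create(_["x"] = xs, _["v"] = vs);
}
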