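#include <Rcpp.h>
using namespace Rcpp;

// Stoichiometry of the four-reaction chemosensing network, species x reaction:
// R1 binding, R2 unbinding, R3 activation (RTKF catalyst), R4 deactivation.
static const int NU[4][4] = {
  {-1,  1,  0,  0},   // RTK
  { 1, -1,  0,  0},   // RTKF
  { 0,  0, -1,  1},   // PI3K (note: column order is reaction)
  { 0,  0,  1, -1}    // PI3KA
};

static inline void props(const double x[4], double k1F, double k2, double k3,
                         double k4, double a[4]) {
  a[0] = k1F * x[0];
  a[1] = k2 * x[1];
  a[2] = k3 * x[1] * x[2];
  a[3] = k4 * x[3];
}

// channel selection convention shared with the R reference path:
// first j with cumsum(a) >= u * a0
static inline int pick(const double a[4], double a0, double u) {
  double target = u * a0, acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    acc += a[j];
    if (acc >= target) return j;
  }
  return 3;
}

// exact SSA for a fixed interval; trailing partial waiting time discarded
static void ssa_advance(double x[4], double k1F, double k2, double k3,
                        double k4, double duration, double firings[4]) {
  double a[4], elapsed = 0.0;
  for (;;) {
    props(x, k1F, k2, k3, k4, a);
    double a0 = a[0] + a[1] + a[2] + a[3];
    if (a0 <= 0.0) break;
    double dt = exp_rand() / a0;
    if (elapsed + dt > duration) break;
    elapsed += dt;
    int j = pick(a, a0, unif_rand());
    for (int i = 0; i < 4; ++i) x[i] += NU[i][j];
    firings[j] += 1.0;
  }
}

//' Compiled tau-leaping window stepper
//'
//' Fast path used by the simulator to advance the chemosensing network over
//' one mechanical window. Mirrors [advance_chemistry()] call-for-call on R's
//' RNG (same Poisson, exponential and uniform draws in the same order), so
//' under the same seed both backends produce bit-identical trajectories.
//'
//' @param x0 Numeric vector of 4 counts (RTK, RTKF, PI3K, PI3KA).
//' @param rates Numeric vector (k1, k2, k3, k4).
//' @param F_nM Chemoattractant concentration (nM).
//' @param duration Window length (seconds).
//' @param eps Leap-condition error bound.
//' @param tau_min,tau_max Clamp bounds for the leap (seconds).
//' @param tau_floor SSA-fallback floor (seconds).
//' @return List with `x` (final counts) and `firings` (per-reaction totals).
//' @export
// [[Rcpp::export]]
List chem_window_cpp(NumericVector x0, NumericVector rates, double F_nM,
                     double duration, double eps = 0.03, double tau_min = 0.5,
                     double tau_max = 1.5, double tau_floor = 1e-3) {
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  const double k1F = rates[0] * F_nM, k2 = rates[1], k3 = rates[2],
               k4 = rates[3];
  const double g[4] = {1.0, 2.0, 2.0, 1.0};
  double firings[4] = {0.0, 0.0, 0.0, 0.0};
  double remaining = duration;
  double a[4];

  RNGScope scope;
  while (remaining > 1e-9) {
    props(x, k1F, k2, k3, k4, a);
    double a0 = a[0] + a[1] + a[2] + a[3];
    if (a0 <= 0.0) break;

    // Cao et al. bounded relative-change criterion
    double tau = R_PosInf;
    for (int i = 0; i < 4; ++i) {
      double mu = 0.0, sig2 = 0.0;
      for (int j = 0; j < 4; ++j) {
        mu += NU[i][j] * a[j];
        sig2 += NU[i][j] * NU[i][j] * a[j];
      }
      if (mu == 0.0 && sig2 == 0.0) continue;
      double bound = eps * x[i] / g[i];
      if (bound < 1.0) bound = 1.0;
      if (mu != 0.0) {
        double t1 = bound / std::fabs(mu);
        if (t1 < tau) tau = t1;
      }
      if (sig2 > 0.0) {
        double t2 = bound * bound / sig2;
        if (t2 < tau) tau = t2;
      }
    }
    if (tau < tau_min) tau = tau_min;
    if (tau > tau_max) tau = tau_max;
    if (tau > remaining) tau = remaining;

    for (;;) {
      double k[4], xn[4];
      for (int j = 0; j < 4; ++j) k[j] = R::rpois(a[j] * tau);
      bool ok = true;
      for (int i = 0; i < 4; ++i) {
        xn[i] = x[i];
        for (int j = 0; j < 4; ++j) xn[i] += NU[i][j] * k[j];
        if (xn[i] < 0.0) ok = false;
      }
      if (ok) {
        for (int i = 0; i < 4; ++i) x[i] = xn[i];
        for (int j = 0; j < 4; ++j) firings[j] += k[j];
        remaining -= tau;
        break;
      }
      tau *= 0.5;
      if (tau < tau_floor) {
        double dt = tau_floor < remaining ? tau_floor : remaining;
        ssa_advance(x, k1F, k2, k3, k4, dt, firings);
        remaining -= dt;
        break;
      }
    }
  }
  return List::create(_["x"] = NumericVector::create(x[0], x[1], x[2], x[3]),
                      _["firings"] = NumericVector::create(
                        firings[0], firings[1], firings[2], firings[3]));
}
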