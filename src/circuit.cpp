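// Core numerics for the basal-ganglia-thalamo-cortical circuit:
// drift and Jacobian of the 7-population firing-rate model, an adaptive
// Dormand-Prince 5(4) integrator (shared by the deterministic system, the
// Gaussian moment closure and a Hopf normal-form toy used in tests), and an
// Euler-Maruyama stepper for the Langevin oracle.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (packed in R by .pack_params):
//  0..13  T16,T47,T21,T26,T31,T36,T57,T42,T53,T64,T45,T75,T71,T17
//  14     include_T17 (0/1)
//  15     s, 16 n
//  17..23 R_i, 24 tau
//  25..31 I_i
//  32     D_input, 33 D_diff
enum { iT16, iT47, iT21, iT26, iT31, iT36, iT57, iT42, iT53, iT64,
       iT45, iT75, iT71, iT17, iINC17, iS, iN, iR0, iTAU = 24, iI0 = 25,
       iDIN = 32, iDDIFF = 33 };

// Protocol vector: [0] target (0 none, else 1-based module index),
// [1] soma_offset, [2] efferent_gain, [3] mode (0 direct, 1 decoupled)
static inline double hillf(double x, double s, double n) {
  double xn = std::pow(x, n);
  return xn / (std::pow(s, n) + xn);
}
static inline double hillfp(double x, double s, double n) {
  double sn = std::pow(s, n), xn = std::pow(x, n);
  double den = sn + xn;
  return n * sn * std::pow(x, n - 1.0) / (den * den);
}

static void circuit_drift(const double* x, const double* p, const double* pr,
                          double* F) {
  const double s = p[iS], n = p[iN], tau = p[iTAU], Din = p[iDIN];
  double f[7], C[7];
  for (int i = 0; i < 7; ++i) {
    f[i] = hillf(x[i], s, n);
    C[i] = tau / p[iR0 + i];
  }
  int target = pr ? (int)pr[0] : 0;
  double off = pr ? pr[1] : 0.0;
  double g = (pr && pr[3] > 0.5) ? pr[2] : 1.0;  // efferent gain (decoupled)
  double g4 = (target == 4) ? g : 1.0;           // source GPi
  double g5 = (target == 5) ? g : 1.0;           // source GPe
  double g7 = (target == 7) ? g : 1.0;           // source STN
  double b[7];
  b[0] = p[iI0 + 0] - x[0] / p[iR0 + 0] + p[iT16] * f[5];
  if (p[iINC17] > 0.5) b[0] += p[iT17] * f[6];
  b[1] = p[iI0 + 1] - x[1] / p[iR0 + 1] + p[iT21] * f[0] + p[iT26] * f[5] + Din;
  b[2] = p[iI0 + 2] - x[2] / p[iR0 + 2] + p[iT31] * f[0] + p[iT36] * f[5] - Din;
  b[3] = p[iI0 + 3] - x[3] / p[iR0 + 3] + g7 * p[iT47] * f[6]
         - p[iT42] * f[1] - g5 * p[iT45] * f[4];
  b[4] = p[iI0 + 4] - x[4] / p[iR0 + 4] + g7 * p[iT57] * f[6] - p[iT53] * f[2];
  b[5] = p[iI0 + 5] - x[5] / p[iR0 + 5] - g4 * p[iT64] * f[3];
  b[6] = p[iI0 + 6] - x[6] / p[iR0 + 6] + p[iT71] * f[0] - g5 * p[iT75] * f[4];
  if (target >= 1 && target <= 7) b[target - 1] += off;
  for (int i = 0; i < 7; ++i) F[i] = b[i] / C[i];
}

static void circuit_jac(const double* x, const double* p, const double* pr,
                        double* A /* 7x7 row-major A[i*7+j] = dF_i/dx_j */) {
  const double s = p[iS], n = p[iN], tau = p[iTAU];
  double fp[7], C[7];
  for (int i = 0; i < 7; ++i) {
    fp[i] = hillfp(x[i], s, n);
    C[i] = tau / p[iR0 + i];
  }
  int target = pr ? (int)pr[0] : 0;
  double g = (pr && pr[3] > 0.5) ? pr[2] : 1.0;
  double g4 = (target == 4) ? g : 1.0;
  double g5 = (target == 5) ? g : 1.0;
  double g7 = (target == 7) ? g : 1.0;
  for (int i = 0; i < 49; ++i) A[i] = 0.0;
  for (int i = 0; i < 7; ++i) A[i * 7 + i] = -1.0 / tau;  // leak: 1/(R_i C_i)
  A[0 * 7 + 5] += p[iT16] * fp[5] / C[0];
  if (p[iINC17] > 0.5) A[0 * 7 + 6] += p[iT17] * fp[6] / C[0];
  A[1 * 7 + 0] += p[iT21] * fp[0] / C[1];
  A[1 * 7 + 5] += p[iT26] * fp[5] / C[1];
  A[2 * 7 + 0] += p[iT31] * fp[0] / C[2];
  A[2 * 7 + 5] += p[iT36] * fp[5] / C[2];
  A[3 * 7 + 6] += g7 * p[iT47] * fp[6] / C[3];
  A[3 * 7 + 1] -= p[iT42] * fp[1] / C[3];
  A[3 * 7 + 4] -= g5 * p[iT45] * fp[4] / C[3];
  A[4 * 7 + 6] += g7 * p[iT57] * fp[6] / C[4];
  A[4 * 7 + 2] -= p[iT53] * fp[2] / C[4];
  A[5 * 7 + 3] -= g4 * p[iT64] * fp[3] / C[5];
  A[6 * 7 + 0] += p[iT71] * fp[0] / C[6];
  A[6 * 7 + 4] -= g5 * p[iT75] * fp[4] / C[6];
}

// Right-hand sides for the shared integrator.
// rhs_type 0: circuit (dim 7); 1: moment closure (dim 14, means then
// diagonal variances, dsigma_ii/dt = 2 A_ii sigma_ii + 2 D_diff);
// 2: Hopf normal form (dim 2, extra = (mu, omega)).
static void rhs_eval(int rhs_type, const double* y, const double* p,
                     const double* pr, const double* extra, double* dy) {
  if (rhs_type == 0) {
    circuit_drift(y, p, pr, dy);
  } else if (rhs_type == 1) {
    circuit_drift(y, p, pr, dy);
    double A[49];
    circuit_jac(y, p, pr, A);
    double Dd = p[iDDIFF];
    for (int i = 0; i < 7; ++i)
      dy[7 + i] = 2.0 * A[i * 7 + i] * y[7 + i] + 2.0 * Dd;
  } else {
    double mu = extra[0], om = extra[1];
    double r2 = y[0] * y[0] + y[1] * y[1];
    dy[0] = mu * y[0] - om * y[1] - y[0] * r2;
    dy[1] = om * y[0] + mu * y[1] - y[1] * r2;
  }
}

// [[Rcpp::export]]
NumericVector bg_drift_cpp(NumericVector x, NumericVector pvec,
                           NumericVector proto) {
  NumericVector F(7);
  circuit_drift(x.begin(), pvec.begin(),
                proto.size() ? proto.begin() : (double*)nullptr, F.begin());
  return F;
}

// [[Rcpp::export]]
NumericMatrix bg_jacobian_cpp(NumericVector x, NumericVector pvec,
                              NumericVector proto) {
  double A[49];
  circuit_jac(x.begin(), pvec.begin(),
              proto.size() ? proto.begin() : (double*)nullptr, A);
  NumericMatrix out(7, 7);
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j) out(i, j) = A[i * 7 + j];
  return out;
}

// Drift evaluated row-wise on a matrix of states (grid closure helper).
// [[Rcpp::export]]
NumericMatrix bg_drift_grid_cpp(NumericMatrix X, NumericVector pvec,
                                NumericVector proto) {
  int m = X.nrow();
  NumericMatrix out(m, 7);
  double x[7], F[7];
  const double* pr = proto.size() ? proto.begin() : (double*)nullptr;
  for (int k = 0; k < m; ++k) {
    for (int i = 0; i < 7; ++i) x[i] = X(k, i);
    circuit_drift(x, pvec.begin(), pr, F);
    for (int i = 0; i < 7; ++i) out(k, i) = F[i];
  }
  return out;
}

// Adaptive Dormand-Prince 5(4), output on the regular grid t0 + k*dt_out.
// Steps are clamped to land exactly on output times.
// [[Rcpp::export]]
List bg_integrate_cpp(int rhs_type, NumericVector y0, NumericVector pvec,
                      NumericVector proto, double t0, double t1,
                      double dt_out, double atol, double rtol,
                      NumericVector extra) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
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
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;

  const int dim = y0.size();
  const int nout = (int)std::floor((t1 - t0) / dt_out + 1e-9) + 1;
  NumericMatrix states(nout, dim);
  NumericVector times(nout);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim), yt(dim), ynew(dim), err(dim);
  const double* p = pvec.begin();
  const double* pr = proto.size() ? proto.begin() : (double*)nullptr;
  const double* ex = extra.size() ? extra.begin() : (double*)nullptr;

  double t = t0;
  times[0] = t0;
  for (int i = 0; i < dim; ++i) states(0, i) = y[i];
  int iout = 1;
  double h = dt_out / 4.0;
  const double hmin = 1e-12, hmax = (t1 - t0);
  long nsteps = 0;
  const long max_steps = 200000000L;
  int status = 0;
  rhs_eval(rhs_type, y.data(), p, pr, ex, k1.data());  // FSAL seed

  while (iout < nout) {
    double t_next = t0 + iout * dt_out;
    if (h > hmax) h = hmax;
    bool hit = false;
    double hstep = h;
    if (t + hstep >= t_next - 1e-12) {
      hstep = t_next - t;
      hit = true;
    }
    // stages
    for (int i = 0; i < dim; ++i) yt[i] = y[i] + hstep * a21 * k1[i];
    rhs_eval(rhs_type, yt.data(), p, pr, ex, k2.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + hstep * (a31 * k1[i] + a32 * k2[i]);
    rhs_eval(rhs_type, yt.data(), p, pr, ex, k3.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + hstep * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs_eval(rhs_type, yt.data(), p, pr, ex, k4.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + hstep * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                              a54 * k4[i]);
    rhs_eval(rhs_type, yt.data(), p, pr, ex, k5.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + hstep * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
    rhs_eval(rhs_type, yt.data(), p, pr, ex, k6.data());
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + hstep * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
    rhs_eval(rhs_type, ynew.data(), p, pr, ex, k7.data());
    double errnorm = 0.0;
    bool finite = true;
    for (int i = 0; i < dim; ++i) {
      err[i] = hstep * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err[i] / sc;
      errnorm += r * r;
      if (!std::isfinite(ynew[i])) finite = false;
    }
    errnorm = std::sqrt(errnorm / dim);
    if (finite && errnorm <= 1.0) {
      t += hstep;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      if (hit) {
        times[iout] = t;
        for (int i = 0; i < dim; ++i) states(iout, i) = y[i];
        ++iout;
      }
    }
    double fac = finite ? 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2) : 0.3;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h = std::min(std::max(h * fac, hmin), hmax);
    if ((!finite && h <= hmin * 2) || ++nsteps > max_steps) {
      status = 1;
      break;
    }
  }
  return List::create(_["time"] = times, _["states"] = states,
                      _["status"] = status, _["n_out"] = iout,
                      _["t_last"] = t);
}

// Euler-Maruyama for dx = F(x) dt + sqrt(2 D) dW, recording every `thin`
// steps. Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
List bg_langevin_cpp(NumericVector x0, NumericVector pvec, NumericVector proto,
                     double duration, double dt, int thin, double bound) {
  const double* p = pvec.begin();
  const double* pr = proto.size() ? proto.begin() : (double*)nullptr;
  double Dd = p[iDDIFF];
  double sig = std::sqrt(2.0 * Dd * dt);
  long nsteps = (long)std::floor(duration / dt + 1e-9);
  long nrec = nsteps / thin + 1;
  NumericMatrix states(nrec, 7);
  NumericVector times(nrec);
  double x[7], F[7];
  for (int i = 0; i < 7; ++i) {
    x[i] = x0[i];
    states(0, i) = x[i];
  }
  times[0] = 0.0;
  long irec = 1;
  int status = 0;
  long step = 0;
  for (step = 1; step <= nsteps; ++step) {
    circuit_drift(x, p, pr, F);
    bool bad = false;
    for (int i = 0; i < 7; ++i) {
      x[i] += F[i] * dt + (sig > 0 ? sig * norm_rand() : 0.0);
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > bound) bad = true;
    }
    if (bad) {
      status = 1;
      break;
    }
    if (step % thin == 0) {
      times[irec] = step * dt;
      for (int i = 0; i < 7; ++i) states(irec, i) = x[i];
      ++irec;
    }
  }
  return List::create(_["time"] = times, _["states"] = states,
                      _["status"] = status, _["n_rec"] = irec,
                      _["t_last"] = (step - 1) * dt);
}
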