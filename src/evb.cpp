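// Two-state EVB energetics and Langevin (BAOAB) window sampling for the
// collinear toy reacting system.  All coordinates are one-dimensional
// positions in Angstrom; energies kcal/mol, time fs, mass amu, temperature K.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// unit bridge: acceleration [A/fs^2] = ACC * force[kcal/mol/A] / mass[amu]
static const double ACC   = 4.184e-4;
static const double GASR  = 1.987204e-3;  // kcal mol^-1 K^-1
static const double COULK = 332.0636;     // kcal A / (mol e^2)

struct State {
  NumericMatrix morse;  // i j D b r0
  NumericMatrix harm;   // i j k r0 flat   (j == 0 -> site term 0.5*k*(x_i - r0)^2)
  NumericMatrix buck;   // i j A B C rsoft
  std::vector<double> q;
  double shift;
  std::vector<int> qi, qj;
  std::vector<double> qq;
};

static State unpack_state(List st, int n) {
  State S;
  S.morse = as<NumericMatrix>(st["morse"]);
  S.harm  = as<NumericMatrix>(st["harmonic"]);
  S.buck  = as<NumericMatrix>(st["buckingham"]);
  NumericVector q = st["charges"];
  if ((int)q.size() != n) stop("charge vector length does not match particle count");
  S.q.assign(q.begin(), q.end());
  S.shift = as<double>(st["shift"]);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double p = S.q[i] * S.q[j];
      if (p != 0.0) { S.qi.push_back(i); S.qj.push_back(j); S.qq.push_back(p); }
    }
  return S;
}

// Potential energy of one diabatic state; accumulates forces into f if non-null.
static double eval_state(const State& S, const double* x, double* f) {
  double e = S.shift;
  for (int r = 0; r < S.morse.nrow(); ++r) {
    int i = (int)S.morse(r, 0) - 1, j = (int)S.morse(r, 1) - 1;
    double D = S.morse(r, 2), b = S.morse(r, 3), r0 = S.morse(r, 4);
    double dx = x[i] - x[j], d = std::fabs(dx), s = dx >= 0 ? 1.0 : -1.0;
    double ex = std::exp(-b * (d - r0)), om = 1.0 - ex;
    e += D * (om * om - 1.0);
    if (f) { double g = 2.0 * D * om * b * ex; f[i] -= g * s; f[j] += g * s; }
  }
  for (int r = 0; r < S.harm.nrow(); ++r) {
    int i = (int)S.harm(r, 0) - 1, j1 = (int)S.harm(r, 1);
    double k = S.harm(r, 2), r0 = S.harm(r, 3);
    int flat = (int)S.harm(r, 4);
    if (j1 <= 0) {               // absolute-coordinate (bath tether) term
      double d = x[i] - r0;
      e += 0.5 * k * d * d;
      if (f) f[i] -= k * d;
    } else {
      int j = j1 - 1;
      double dx = x[i] - x[j], d = std::fabs(dx), s = dx >= 0 ? 1.0 : -1.0;
      double dd = d - r0;
      if (flat && dd < 0) continue;   // flat-bottom restraint: one-sided
      e += 0.5 * k * dd * dd;
      if (f) { double g = k * dd; f[i] -= g * s; f[j] += g * s; }
    }
  }
  for (int r = 0; r < S.buck.nrow(); ++r) {
    int i = (int)S.buck(r, 0) - 1, j = (int)S.buck(r, 1) - 1;
    double A = S.buck(r, 2), B = S.buck(r, 3), C = S.buck(r, 4), rs = S.buck(r, 5);
    double dx = x[i] - x[j], d = std::fabs(dx), s = dx >= 0 ? 1.0 : -1.0;
    double rep = A * std::exp(-B * d);
    double d2 = d * d, d6 = d2 * d2 * d2;
    double rs2 = rs * rs, rs6 = rs2 * rs2 * rs2;
    double den = d6 + rs6;            // rsoft = 0 recovers plain -C/r^6
    e += rep - C / den;
    if (f) {
      double g = -B * rep + 6.0 * C * d6 / (d * den * den);
      f[i] -= g * s; f[j] += g * s;
    }
  }
  for (size_t p = 0; p < S.qq.size(); ++p) {
    int i = S.qi[p], j = S.qj[p];
    double dx = x[i] - x[j], d = std::fabs(dx), s = dx >= 0 ? 1.0 : -1.0;
    double v = COULK * S.qq[p] / d;
    e += v;
    if (f) { double g = -v / d; f[i] -= g * s; f[j] += g * s; }
  }
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_diabatic(List packed, NumericVector x) {
  int n = as<int>(packed["n"]);
  if ((int)x.size() != n) stop("coordinate vector length does not match particle count");
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i])) stop("invalid configuration: non-finite coordinate");
  State s1 = unpack_state(packed["state1"], n);
  State s2 = unpack_state(packed["state2"], n);
  NumericVector out(2);
  out[0] = eval_state(s1, x.begin(), 0);
  out[1] = eval_state(s2, x.begin(), 0);
  return out;
}

// BAOAB Langevin propagation on the mapping potential
//   eps_m = lambda*eps1 + (1 - lambda)*eps2.
// Uses R's RNG stream (seed from R with set.seed before calling).
// Records (eps1, eps2) every step after the first nequil steps.
// [[Rcpp::export]]
List cpp_run_window(List packed, NumericVector x0, NumericVector v0,
                    double lambda, int nsteps, int nequil,
                    double dt, double temperature, double gamma_fs,
                    NumericVector mass, bool draw_velocities) {
  int n = as<int>(packed["n"]);
  State s1 = unpack_state(packed["state1"], n);
  State s2 = unpack_state(packed["state2"], n);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(n), f1(n), f2(n), frc(n);
  double kT = GASR * temperature;
  double c1 = std::exp(-gamma_fs * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  RNGScope scope;
  if (draw_velocities) {
    for (int i = 0; i < n; ++i)
      v[i] = std::sqrt(kT * ACC / mass[i]) * norm_rand();
  } else {
    for (int i = 0; i < n; ++i) v[i] = v0[i];
  }

  std::fill(f1.begin(), f1.end(), 0.0);
  std::fill(f2.begin(), f2.end(), 0.0);
  double e1 = eval_state(s1, x.data(), f1.data());
  double e2 = eval_state(s2, x.data(), f2.data());
  for (int i = 0; i < n; ++i) frc[i] = lambda * f1[i] + (1.0 - lambda) * f2[i];

  int nrec = nsteps - nequil;
  NumericVector eps1(nrec), eps2(nrec);
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      v[i] += 0.5 * dt * ACC * frc[i] / mass[i];
      x[i] += 0.5 * dt * v[i];
      v[i] = c1 * v[i] + c2 * std::sqrt(kT * ACC / mass[i]) * norm_rand();
      x[i] += 0.5 * dt * v[i];
    }
    std::fill(f1.begin(), f1.end(), 0.0);
    std::fill(f2.begin(), f2.end(), 0.0);
    e1 = eval_state(s1, x.data(), f1.data());
    e2 = eval_state(s2, x.data(), f2.data());
    for (int i = 0; i < n; ++i) {
      frc[i] = lambda * f1[i] + (1.0 - lambda) * f2[i];
      v[i] += 0.5 * dt * ACC * frc[i] / mass[i];
    }
    if (!R_finite(e1) || !R_finite(e2) ||
        std::fabs(e1) > 1e6 || std::fabs(e2) > 1e6) {
      stop("integration instability at lambda = %f, step %d (|energy| > 1e6 kcal/mol)",
           lambda, step + 1);
    }
    if (step >= nequil) { eps1[step - nequil] = e1; eps2[step - nequil] = e2; }
  }
  return List::create(_["eps1"] = eps1, _["eps2"] = eps2,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()));
}

// Gradient of the mapping potential, used by quench/minimisation checks.
// [[Rcpp::export]]
NumericVector cpp_mapping_gradient(List packed, NumericVector x, double lambda) {
  int n = as<int>(packed["n"]);
  State s1 = unpack_state(packed["state1"], n);
  State s2 = unpack_state(packed["state2"], n);
  std::vector<double> f1(n, 0.0), f2(n, 0.0);
  eval_state(s1, x.begin(), f1.data());
  eval_state(s2, x.begin(), f2.data());
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = -(lambda * f1[i] + (1.0 - lambda) * f2[i]);
  return g;
}
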