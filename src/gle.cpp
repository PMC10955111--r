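// Generalized Langevin integrator along the path coordinate s.
//
// Memory friction is realized by a Markovian embedding: each exponential
// kernel component xi_i(t) = A_i exp(-t/tau_i) corresponds to an auxiliary
// acceleration-like Ornstein-Uhlenbeck variable z_i (units Angstrom/ps^2 in
// the mass-weighted s frame) obeying
//     dz_i = (-z_i/tau_i - A_i v) dt + sqrt(2 kT A_i / (m tau_i)) dW,
// which reproduces the memory force  -m \int xi(t-t') v(t') dt'  plus a
// fluctuating force satisfying the fluctuation-dissipation theorem.
// The z substep uses the exact OU propagator with v frozen over dt;
// the deterministic part is a velocity-Verlet splitting; an optional
// memoryless (white-noise) friction gamma0 is applied as an exact
// half-step velocity OU on either side (BAOAB-style).
//
// All energies here are in amu Angstrom^2 / ps^2; the R wrappers convert
// from kcal/mol at the boundary.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct ForceTable {
  const double *f;
  int n;
  double s0, h, k_wall;
  // piecewise-linear interpolation, harmonic wall beyond the grid
  double operator()(double s) const {
    double x = (s - s0) / h;
    if (!(x > 0.0)) return f[0] + k_wall * (s0 - s);  // also catches NaN
    if (x >= n - 1.0) return f[n - 1] + k_wall * (s0 + h * (n - 1) - s);
    int i = static_cast<int>(x);
    double w = x - i;
    return f[i] * (1.0 - w) + f[i + 1] * w;
  }
};

}  // namespace

// [[Rcpp::export(name = ".gle_integrate_cpp")]]
List gle_integrate_cpp(NumericVector s_grid, NumericVector force_grid,
                       double mass, double kT_amu,
                       NumericVector A, NumericVector tau, double gamma0,
                       double dt, int n_steps, int sample_every,
                       double s_init, double v_init, NumericVector z_init,
                       double bias_k, double bias_center,
                       bool constrain_s, double seed) {
  const int nb = A.size();
  if (tau.size() != nb) stop("A and tau length mismatch");
  if (z_init.size() != nb) stop("z_init length mismatch");
  if (s_grid.size() < 2) stop("force table needs at least 2 grid points");
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (sample_every < 1) stop("sample_every must be >= 1");

  ForceTable ftab{force_grid.begin(), static_cast<int>(s_grid.size()),
                  s_grid[0], s_grid[1] - s_grid[0], 10.0 * 418.4};

  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // OU propagator coefficients per bath
  std::vector<double> c1(nb), csig(nb), atau(nb);
  for (int i = 0; i < nb; ++i) {
    if (tau[i] <= 0.0) stop("bath relaxation times must be > 0");
    c1[i] = std::exp(-dt / tau[i]);
    double var_st = kT_amu * A[i] / mass;
    csig[i] = std::sqrt(var_st * (1.0 - c1[i] * c1[i]));
    atau[i] = A[i] * tau[i];
  }
  const double cg = std::exp(-0.5 * gamma0 * dt);
  const double sg = std::sqrt(kT_amu / mass * (1.0 - cg * cg));

  const int n_samp = n_steps / sample_every + 1;
  NumericVector out_s(n_samp), out_v(n_samp), out_fpot(n_samp);
  NumericMatrix out_z(n_samp, nb);

  double s = s_init, v = constrain_s ? 0.0 : v_init;
  std::vector<double> z(z_init.begin(), z_init.end());

  auto accel = [&](double ss) {
    double f = ftab(ss);
    if (bias_k > 0.0) f -= bias_k * (ss - bias_center);
    return f / mass;
  };

  auto record = [&](int idx) {
    out_s[idx] = s;
    out_v[idx] = v;
    out_fpot[idx] = ftab(s);
    for (int i = 0; i < nb; ++i) out_z(idx, i) = z[i];
  };
  record(0);

  int isamp = 1;
  for (int step = 1; step <= n_steps; ++step) {
    if (constrain_s) {
      // s held on the dividing surface: baths evolve freely (v = 0)
      for (int i = 0; i < nb; ++i)
        z[i] = c1[i] * z[i] + csig[i] * gauss(rng);
    } else {
      if (gamma0 > 0.0) v = cg * v + sg * gauss(rng);
      double zsum = 0.0;
      for (int i = 0; i < nb; ++i) zsum += z[i];
      v += 0.5 * dt * (accel(s) + zsum);
      s += 0.5 * dt * v;
      for (int i = 0; i < nb; ++i) {
        double zinf = -atau[i] * v;
        z[i] = zinf + c1[i] * (z[i] - zinf) + csig[i] * gauss(rng);
      }
      s += 0.5 * dt * v;
      zsum = 0.0;
      for (int i = 0; i < nb; ++i) zsum += z[i];
      v += 0.5 * dt * (accel(s) + zsum);
      if (gamma0 > 0.0) v = cg * v + sg * gauss(rng);
    }
    if (!std::isfinite(s) || !std::isfinite(v)) {
      stop("trajectory diverged (non-finite state) at step %d; "
           "reduce dt or soften the bias", step);
    }
    if (step % sample_every == 0) record(isamp++);
  }

  return List::create(_["s"] = out_s, _["v"] = out_v,
                      _["f_pot"] = out_fpot, _["z"] = out_z,
                      _["state"] = List::create(_["s"] = s, _["v"] = v,
                                                _["z"] = NumericVector(z.begin(), z.end())));
}
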