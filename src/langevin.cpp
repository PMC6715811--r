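#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Harmonic forces of the loop-anchored bead-spring chain.
// Bond potential: kappa/2 (|d| - r0)^2 for consecutive beads,
// omega/2 (|d| - r0)^2 for loop-anchor pairs; r0 = 0 gives the exactly
// Gaussian (normal-mode solvable) chain, r0 = a the finite-rest-length one.
static inline void add_spring_force(std::vector<double>& f,
                                    const std::vector<double>& x,
                                    int i, int j, double k, double r0) {
  double dx = x[3 * j] - x[3 * i];
  double dy = x[3 * j + 1] - x[3 * i + 1];
  double dz = x[3 * j + 2] - x[3 * i + 2];
  if (r0 == 0.0) {
    f[3 * i] += k * dx; f[3 * i + 1] += k * dy; f[3 * i + 2] += k * dz;
    f[3 * j] -= k * dx; f[3 * j + 1] -= k * dy; f[3 * j + 2] -= k * dz;
  } else {
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len < 1e-12) return;  // force direction undefined at exact overlap
    double c = k * (len - r0) / len;
    f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
    f[3 * j] -= c * dx; f[3 * j + 1] -= c * dy; f[3 * j + 2] -= c * dz;
  }
}

static void compute_forces(std::vector<double>& f,
                           const std::vector<double>& x, int N,
                           double kappa, double omega, double r0,
                           const IntegerMatrix& loops) {
  std::fill(f.begin(), f.end(), 0.0);
  for (int i = 0; i < N - 1; ++i) add_spring_force(f, x, i, i + 1, kappa, r0);
  for (int l = 0; l < loops.nrow(); ++l) {
    add_spring_force(f, x, loops(l, 0) - 1, loops(l, 1) - 1, omega, r0);
  }
}

// BAOAB splitting of underdamped Langevin dynamics with unit mass:
//   B: v += dt/2 f;  A: x += dt/2 v;  O: v <- c1 v + c2 sqrt(kT) xi
// Friction coefficient gamma = xi (mass = 1). One force evaluation per step.
// [[Rcpp::export]]
List grmc_langevin_cpp(int N, double kappa, double omega, double xi, double kT,
                       double r0, IntegerMatrix loops, NumericMatrix x_init,
                       double dt, int n_steps, int burn_in, int save_every,
                       int seed, IntegerMatrix pairs, double rc,
                       bool save_traj) {
  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = x_init(i, a);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  double sv = std::sqrt(kT);  // Maxwell-Boltzmann, mass = 1
  if (kT > 0.0) {
    for (int i = 0; i < 3 * N; ++i) v[i] = sv * gauss(rng);
  }

  double c1 = std::exp(-xi * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * sv;

  int n_pairs = pairs.nrow();
  std::vector<long long> contact(n_pairs, 0);
  std::vector<double> sum_r(n_pairs, 0.0), sum_r2(n_pairs, 0.0);

  int total = burn_in + n_steps;
  int n_saved = 0;
  int max_saved = n_steps / save_every;
  NumericVector traj;
  if (save_traj) traj = NumericVector(static_cast<R_xlen_t>(3) * N * max_saved);

  double ke_acc = 0.0;
  long long ke_n = 0;

  compute_forces(f, x, N, kappa, omega, r0, loops);
  double hdt = 0.5 * dt;

  for (int step = 1; step <= total; ++step) {
    for (int i = 0; i < 3 * N; ++i) {
      v[i] += hdt * f[i];
      x[i] += hdt * v[i];
    }
    if (kT > 0.0) {
      for (int i = 0; i < 3 * N; ++i) v[i] = c1 * v[i] + c2 * gauss(rng);
    } else {
      for (int i = 0; i < 3 * N; ++i) v[i] = c1 * v[i];
    }
    for (int i = 0; i < 3 * N; ++i) x[i] += hdt * v[i];
    compute_forces(f, x, N, kappa, omega, r0, loops);
    for (int i = 0; i < 3 * N; ++i) v[i] += hdt * f[i];

    if (step > burn_in && (step - burn_in) % save_every == 0) {
      // blow-up guard
      if (!std::isfinite(x[0]) || !std::isfinite(x[3 * N - 1])) {
        stop("numerical blow-up at step %d: non-finite coordinates (reduce dt)",
             step);
      }
      double ke = 0.0;
      for (int i = 0; i < 3 * N; ++i) ke += v[i] * v[i];
      ke_acc += ke / (3.0 * N);
      ke_n += 1;

      for (int p = 0; p < n_pairs; ++p) {
        int m = pairs(p, 0) - 1, n = pairs(p, 1) - 1;
        double dx = x[3 * m] - x[3 * n];
        double dy = x[3 * m + 1] - x[3 * n + 1];
        double dz = x[3 * m + 2] - x[3 * n + 2];
        double d2 = dx * dx + dy * dy + dz * dz;
        double d = std::sqrt(d2);
        sum_r[p] += d;
        sum_r2[p] += d2;
        if (d <= rc) contact[p] += 1;
      }
      if (save_traj && n_saved < max_saved) {
        for (int i = 0; i < N; ++i)
          for (int a = 0; a < 3; ++a)
            traj[static_cast<R_xlen_t>(n_saved) * 3 * N + a * N + i] =
              x[3 * i + a];
        ++n_saved;
      }
    }
  }

  NumericVector contact_out(n_pairs), sr(n_pairs), sr2(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    contact_out[p] = static_cast<double>(contact[p]);
    sr[p] = sum_r[p];
    sr2[p] = sum_r2[p];
  }
  NumericMatrix xfin(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) xfin(i, a) = x[3 * i + a];

  List out = List::create(
    _["contact"] = contact_out, _["sum_r"] = sr, _["sum_r2"] = sr2,
    _["n_saved"] = ke_n,
    _["kinetic_temp"] = ke_n > 0 ? ke_acc / ke_n : NA_REAL,
    _["x_final"] = xfin);
  if (save_traj) {
    traj.attr("dim") = IntegerVector::create(N, 3, n_saved);
    out["trajectory"] = traj;
  }
  return out;
}
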