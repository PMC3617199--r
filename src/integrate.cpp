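#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// BAOAB Langevin integration over the in-repo toy force fields.
// Units: length A, time ps, mass amu, energy kcal/mol.
// Noise uses R's RNG so that set.seed() gives bitwise-reproducible runs.

static const double KCAL_TO_AKMA = 418.4; // kcal/mol -> amu*A^2/ps^2

// ff_type: 0 = none, 1 = harmonic tethers, 2 = elastic network
static void compute_forces(int ff_type,
                           const NumericMatrix &x,
                           const NumericVector &tether_k,
                           const NumericMatrix &tether_ref,
                           const IntegerVector &pairs_i,
                           const IntegerVector &pairs_j,
                           const NumericVector &pair_k,
                           const NumericVector &pair_d0,
                           NumericMatrix &f) {
  int n = x.nrow();
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) f(i, d) = 0.0;
  if (ff_type == 1) {
    for (int i = 0; i < n; ++i) {
      double k = tether_k[i];
      if (k <= 0) continue;
      for (int d = 0; d < 3; ++d) f(i, d) = -k * (x(i, d) - tether_ref(i, d));
    }
  } else if (ff_type == 2) {
    int np = pairs_i.size();
    for (int p = 0; p < np; ++p) {
      int i = pairs_i[p] - 1, j = pairs_j[p] - 1;
      double dx = x(i, 0) - x(j, 0);
      double dy = x(i, 1) - x(j, 1);
      double dz = x(i, 2) - x(j, 2);
      double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dist < 1e-12) continue;
      double fm = -pair_k[p] * (dist - pair_d0[p]) / dist;
      f(i, 0) += fm * dx; f(i, 1) += fm * dy; f(i, 2) += fm * dz;
      f(j, 0) -= fm * dx; f(j, 1) -= fm * dy; f(j, 2) -= fm * dz;
    }
  }
}

// [[Rcpp::export]]
List integrate_langevin_cpp(int ff_type,
                            NumericMatrix x_init, NumericMatrix v_init,
                            NumericVector mass, LogicalVector movable,
                            NumericVector tether_k, NumericMatrix tether_ref,
                            IntegerVector pairs_i, IntegerVector pairs_j,
                            NumericVector pair_k, NumericVector pair_d0,
                            double dt, double gamma, double kT,
                            int n_steps,
                            NumericMatrix ext_force,
                            bool pull, int pull_atom, NumericVector pull_dir,
                            double pull_k, double pull_v,
                            int sample_every,
                            IntegerVector record_atoms) {
  int n = x_init.nrow();
  NumericMatrix x(clone(x_init));
  NumericMatrix v(clone(v_init));
  NumericMatrix f(n, 3);
  bool have_ext = ext_force.nrow() == n;
  int pa = pull_atom - 1;

  double x0_proj = 0.0; // pull-atom projection at start
  if (pull) {
    x0_proj = x(pa, 0) * pull_dir[0] + x(pa, 1) * pull_dir[1] +
              x(pa, 2) * pull_dir[2];
  }

  double c1 = std::exp(-gamma * dt);
  double kT_akma = kT * KCAL_TO_AKMA;
  std::vector<double> sig(n);
  for (int i = 0; i < n; ++i)
    sig[i] = std::sqrt(kT_akma * (1.0 - c1 * c1) / mass[i]);

  int n_samples = (sample_every > 0) ? n_steps / sample_every + 1 : 0;
  NumericMatrix samples(pull && n_samples ? n_samples : 0, 2);
  int nrec = record_atoms.size();
  NumericMatrix traj((nrec && n_samples) ? n_samples : 0, 3 * nrec);
  int sample_idx = 0;

  // spring tension (kcal/mol/A) along the pull direction at time t
  auto spring_force = [&](double t) {
    double proj = x(pa, 0) * pull_dir[0] + x(pa, 1) * pull_dir[1] +
                  x(pa, 2) * pull_dir[2];
    return pull_k * (pull_v * t - (proj - x0_proj));
  };
  auto record = [&](double t) {
    if (sample_every <= 0) return;
    if (pull && samples.nrow() > 0) {
      samples(sample_idx, 0) = pull_v * t;
      samples(sample_idx, 1) = spring_force(t);
    }
    for (int r = 0; r < nrec; ++r) {
      int ai = record_atoms[r] - 1;
      for (int d = 0; d < 3; ++d) traj(sample_idx, 3 * r + d) = x(ai, d);
    }
    sample_idx++;
  };

  auto add_bias = [&](double t) {
    if (have_ext)
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) f(i, d) += ext_force(i, d);
    if (pull) {
      double fs = spring_force(t);
      for (int d = 0; d < 3; ++d) f(pa, d) += fs * pull_dir[d];
    }
  };

  compute_forces(ff_type, x, tether_k, tether_ref, pairs_i, pairs_j,
                 pair_k, pair_d0, f);
  add_bias(0.0);
  record(0.0);

  RNGScope rng;
  double half = 0.5 * dt;
  for (int step = 0; step < n_steps; ++step) {
    double t1 = (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (!movable[i]) continue;
      double invm = KCAL_TO_AKMA / mass[i];
      for (int d = 0; d < 3; ++d) {
        v(i, d) += half * f(i, d) * invm;           // B
        x(i, d) += half * v(i, d);                  // A
      }
    }
    if (gamma > 0 || kT > 0) {
      for (int i = 0; i < n; ++i) {
        if (!movable[i]) continue;
        for (int d = 0; d < 3; ++d)
          v(i, d) = c1 * v(i, d) + sig[i] * norm_rand();   // O
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!movable[i]) continue;
      for (int d = 0; d < 3; ++d) x(i, d) += half * v(i, d);  // A
    }
    compute_forces(ff_type, x, tether_k, tether_ref, pairs_i, pairs_j,
                   pair_k, pair_d0, f);
    add_bias(t1);
    for (int i = 0; i < n; ++i) {
      if (!movable[i]) continue;
      double invm = KCAL_TO_AKMA / mass[i];
      for (int d = 0; d < 3; ++d) v(i, d) += half * f(i, d) * invm;  // B
    }
    if ((step + 1) % (sample_every > 0 ? sample_every : n_steps + 1) == 0)
      record(t1);
    if ((step & 255) == 0) {
      for (int d = 0; d < 3; ++d) {
        double xx = x(0, d);
        if (!std::isfinite(xx) || std::fabs(xx) > 1e8)
          stop("numerical blow-up at step %d", step + 1);
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      if (!std::isfinite(x(i, d)))
        stop("numerical blow-up at step %d", n_steps);

  return List::create(_["x"] = x, _["v"] = v,
                      _["samples"] = samples, _["traj"] = traj,
                      _["n_samples"] = sample_idx);
}
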