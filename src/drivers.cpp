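#include "model.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// NAM committor batch.
//
// The fibril (all dumbbells in `pos`, frozen) sits with the COM of its
// terminal dumbbell 0 at the origin. For each trajectory a mobile dumbbell of
// the species opposite to dumbbell 0 is launched from a uniformly random
// point on the sphere of radius b1 (Angstrom) with a uniformly random bond
// orientation, and propagated until one of
//   lock   : rcom < lock_rcom  and q < lock_q   (checked first)
//   dock   : rcom < dock_dist        (COM separations in Angstrom)
//   escape : rcom > b2
// fires, all relative to the terminal dumbbell. Outcome codes:
// 1 = docked, 2 = escaped, 3 = direct lock, 0 = censored (max_steps).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_nam_batch(NumericMatrix pos, IntegerVector species,
                   NumericVector params, double b1, double b2,
                   double dock_dist, double lock_rcom, double lock_q,
                   int n_traj, double max_steps) {
  Params P = parse_params(params);
  int nf = species.size();          // fibril dumbbells
  int nd = nf + 1;                  // + mobile
  int mob_species = (species[0] == 1) ? 2 : 1;

  std::vector<int> spec(nd), mob(nd, 0), role(nd, -1);
  for (int d = 0; d < nf; ++d) { spec[d] = species[d]; role[d] = d; }
  spec[nf] = mob_species;
  mob[nf] = 1;

  Workspace W;
  std::vector<double> x0(3 * 2 * nd), x, f(3 * 2 * nd);
  for (int p = 0; p < 2 * nf; ++p)
    for (int k = 0; k < 3; ++k) x0[3 * p + k] = pos(p, k);

  IntegerVector outcome(n_traj);
  NumericVector steps_taken(n_traj);
  NumericMatrix fin(n_traj, 6);   // final mobile atom positions (diagnostics)
  const double r0 = P.r0;

  for (int t = 0; t < n_traj; ++t) {
    x = x0;
    // random direction and bond orientation
    double dir[3], bd[3];
    do { for (int k = 0; k < 3; ++k) dir[k] = norm_rand(); } while (norm3(dir) < 1e-8);
    do { for (int k = 0; k < 3; ++k) bd[k] = norm_rand(); } while (norm3(bd) < 1e-8);
    double nr1 = norm3(dir), nr2 = norm3(bd);
    for (int k = 0; k < 3; ++k) {
      double com = b1 * dir[k] / nr1;
      double half = 0.5 * r0 * bd[k] / nr2;
      x[3 * 2 * nf + k] = com - half;
      x[3 * (2 * nf + 1) + k] = com + half;
    }
    int out = 0;
    double s = 0;
    {
      // classify the starting point: a launch inside the dock criterion is
      // docked at step zero
      double rc, q;
      pair_coords(x.data(), 0, nf, r0, 0.0, &rc, &q);
      if (rc < lock_rcom && q < lock_q) out = 3;
      else if (rc < dock_dist) out = 1;
      else if (rc > b2) out = 2;
    }
    for (; out == 0 && s < max_steps; ++s) {
      std::fill(f.begin(), f.end(), 0.0);
      energy_forces(x.data(), nd, spec.data(), mob.data(), role.data(), 0.0, P,
                    f.data(), true, W);
      em_step(x.data(), nd, mob.data(), 0.0, P, f.data(), 1.0);
      double rc, q;
      pair_coords(x.data(), 0, nf, r0, 0.0, &rc, &q);
      if (spec[0] == 2) {  // terminal is B: recompute with roles swapped
        pair_coords(x.data(), nf, 0, r0, 0.0, &rc, &q);
      }
      if (rc < lock_rcom && q < lock_q) { out = 3; break; }
      if (rc < dock_dist) { out = 1; break; }
      if (rc > b2) { out = 2; break; }
    }
    outcome[t] = out;
    steps_taken[t] = (s < max_steps) ? s + 1 : max_steps;
    for (int i = 0; i < 2; ++i)
      for (int k = 0; k < 3; ++k) fin(t, 3 * i + k) = x[3 * (2 * nf + i) + k];
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["steps"] = steps_taken,
                      _["final_mobile"] = fin);
}

// ---------------------------------------------------------------------------
// One umbrella-sampling window: harmonic biases kr/2 (rcom - c_r)^2 +
// kq/2 (q - c_q)^2 on the (rcom, q) pair between the mobile dumbbell and the
// frozen terminal dumbbell 0. Returns the post-equilibration 2-D histogram
// on the supplied grid plus window means for overlap diagnostics.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_umbrella_window(NumericMatrix pos, IntegerVector species,
                         NumericVector params, double c_r, double c_q,
                         double kr, double kq, int n_equil, int n_prod,
                         int stride, NumericVector r_edges,
                         NumericVector q_edges) {
  Params P = parse_params(params);
  int nf = species.size();
  int nd = nf + 1;
  int mob_species = (species[0] == 1) ? 2 : 1;
  std::vector<int> spec(nd), mob(nd, 0), role(nd, -1);
  for (int d = 0; d < nf; ++d) { spec[d] = species[d]; role[d] = d; }
  spec[nf] = mob_species;
  mob[nf] = 1;

  Workspace W;
  std::vector<double> x(3 * 2 * nd), f(3 * 2 * nd);
  for (int p = 0; p < 2 * nf; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = pos(p, k);

  // initial mobile placement on the free (-z) side at the window centre
  const double r0 = P.r0;
  double qc = std::max(-0.99, std::min(0.99, c_q));
  double bhat[3] = {std::sqrt(1.0 - qc * qc), -qc, 0.0};
  double com[3] = {0.0, 0.0, -c_r};
  for (int k = 0; k < 3; ++k) {
    x[3 * 2 * nf + k] = com[k] - 0.5 * r0 * bhat[k];
    x[3 * (2 * nf + 1) + k] = com[k] + 0.5 * r0 * bhat[k];
  }

  int nr = r_edges.size() - 1, nq = q_edges.size() - 1;
  NumericMatrix counts(nr, nq);
  double sum_r = 0, sum_q = 0, sum_r2 = 0, sum_q2 = 0;
  int n_samp = 0;
  double dr_bin = r_edges[1] - r_edges[0], dq_bin = q_edges[1] - q_edges[0];

  int total = n_equil + n_prod;
  for (int s = 0; s < total; ++s) {
    std::fill(f.begin(), f.end(), 0.0);
    energy_forces(x.data(), nd, spec.data(), mob.data(), role.data(), 0.0, P,
                  f.data(), true, W);
    // bias force on the tracked pair
    double rc, q;
    pair_coords(x.data(), 0, nf, r0, 0.0, &rc, &q);
    double dUdr = kr * (rc - c_r), dUdq = kq * (q - c_q);
    {
      // chain rule identical to the Gaussian terms; here A = dumbbell 0 (frozen,
      // no force needed), B = mobile. Only mobile atoms receive bias force.
      double bA[3], bB[3], u[3];
      for (int k = 0; k < 3; ++k) {
        bA[k] = x[3 * 1 + k] - x[3 * 0 + k];
        bB[k] = x[3 * (2 * nf + 1) + k] - x[3 * 2 * nf + k];
        u[k] = (x[3 * 0 + k] + 0.5 * bA[k]) - (x[3 * 2 * nf + k] + 0.5 * bB[k]);
      }
      double ru = norm3(u);
      double v[3], bAxu[3];
      cross3(bB, bA, v);
      cross3(bA, u, bAxu);
      double K = r0 * r0;
      for (int k = 0; k < 3; ++k) {
        double uh = u[k] / ru;
        double ds3 = -0.5 * v[k] - bAxu[k];
        double ds4 = -0.5 * v[k] + bAxu[k];
        double dq3 = (ds3 + q * K * 0.5 * uh) / (K * ru);
        double dq4 = (ds4 + q * K * 0.5 * uh) / (K * ru);
        double drc = -0.5 * uh;
        f[3 * 2 * nf + k] -= dUdr * drc + dUdq * dq3;
        f[3 * (2 * nf + 1) + k] -= dUdr * drc + dUdq * dq4;
      }
    }
    em_step(x.data(), nd, mob.data(), 0.0, P, f.data(), 1.0);
    if (s >= n_equil && (s - n_equil + 1) % stride == 0) {
      pair_coords(x.data(), 0, nf, r0, 0.0, &rc, &q);
      sum_r += rc; sum_q += q; sum_r2 += rc * rc; sum_q2 += q * q;
      ++n_samp;
      if (rc >= r_edges[0] && rc < r_edges[nr] && q >= q_edges[0] && q < q_edges[nq]) {
        int ir = (int)std::floor((rc - r_edges[0]) / dr_bin);
        int iq = (int)std::floor((q - q_edges[0]) / dq_bin);
        if (ir >= 0 && ir < nr && iq >= 0 && iq < nq) counts(ir, iq) += 1.0;
      }
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["counts"] = counts, _["n_samples"] = n_samp,
      _["mean_r"] = sum_r / n_samp, _["mean_q"] = sum_q / n_samp,
      _["sd_r"] = std::sqrt(std::max(0.0, sum_r2 / n_samp - (sum_r / n_samp) * (sum_r / n_samp))),
      _["sd_q"] = std::sqrt(std::max(0.0, sum_q2 / n_samp - (sum_q / n_samp) * (sum_q / n_samp))));
}

// ---------------------------------------------------------------------------
// Saddle-restrained ensemble: run with stiff biases at (c_r, c_q) and store
// mobile-dumbbell snapshots every `stride` steps after equilibration.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_saddle_snapshots(NumericMatrix pos, IntegerVector species,
                                   NumericVector params, double c_r,
                                   double c_q, double kr, double kq,
                                   int n_equil, int stride, int n_snap) {
  // reuse the umbrella machinery by inlining a small variant
  Params P = parse_params(params);
  int nf = species.size();
  int nd = nf + 1;
  int mob_species = (species[0] == 1) ? 2 : 1;
  std::vector<int> spec(nd), mob(nd, 0), role(nd, -1);
  for (int d = 0; d < nf; ++d) { spec[d] = species[d]; role[d] = d; }
  spec[nf] = mob_species; mob[nf] = 1;
  Workspace W;
  std::vector<double> x(3 * 2 * nd), f(3 * 2 * nd);
  for (int p = 0; p < 2 * nf; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = pos(p, k);
  const double r0 = P.r0;
  double qc = std::max(-0.99, std::min(0.99, c_q));
  double bhat[3] = {std::sqrt(1.0 - qc * qc), -qc, 0.0};
  for (int k = 0; k < 3; ++k) {
    x[3 * 2 * nf + k] = -c_r * (k == 2) - 0.5 * r0 * bhat[k];
    x[3 * (2 * nf + 1) + k] = -c_r * (k == 2) + 0.5 * r0 * bhat[k];
  }
  NumericMatrix snaps(n_snap, 6);
  int got = 0, s = 0;
  while (got < n_snap) {
    std::fill(f.begin(), f.end(), 0.0);
    energy_forces(x.data(), nd, spec.data(), mob.data(), role.data(), 0.0, P,
                  f.data(), true, W);
    double rc, q;
    pair_coords(x.data(), 0, nf, r0, 0.0, &rc, &q);
    double dUdr = kr * (rc - c_r), dUdq = kq * (q - c_q);
    double bA[3], bB[3], u[3];
    for (int k = 0; k < 3; ++k) {
      bA[k] = x[3 * 1 + k] - x[3 * 0 + k];
      bB[k] = x[3 * (2 * nf + 1) + k] - x[3 * 2 * nf + k];
      u[k] = (x[3 * 0 + k] + 0.5 * bA[k]) - (x[3 * 2 * nf + k] + 0.5 * bB[k]);
    }
    double ru = norm3(u);
    double v[3], bAxu[3];
    cross3(bB, bA, v);
    cross3(bA, u, bAxu);
    double K = r0 * r0;
    for (int k = 0; k < 3; ++k) {
      double uh = u[k] / ru;
      double ds3 = -0.5 * v[k] - bAxu[k];
      double ds4 = -0.5 * v[k] + bAxu[k];
      double dq3 = (ds3 + q * K * 0.5 * uh) / (K * ru);
      double dq4 = (ds4 + q * K * 0.5 * uh) / (K * ru);
      double drc = -0.5 * uh;
      f[3 * 2 * nf + k] -= dUdr * drc + dUdq * dq3;
      f[3 * (2 * nf + 1) + k] -= dUdr * drc + dUdq * dq4;
    }
    em_step(x.data(), nd, mob.data(), 0.0, P, f.data(), 1.0);
    ++s;
    if (s > n_equil && s % stride == 0) {
      for (int i = 0; i < 2; ++i)
        for (int k = 0; k < 3; ++k) snaps(got, 3 * i + k) = x[3 * (2 * nf + i) + k];
      ++got;
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return snaps;
}

// ---------------------------------------------------------------------------
// Short unbiased bursts for the saddle diffusion tensor: from each snapshot,
// propagate t_steps and record (rcom*r0 [Angstrom], q) at t_steps/2 and
// t_steps relative to the frozen terminal dumbbell 0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_tensor_batch(NumericMatrix pos, IntegerVector species,
                               NumericVector params, NumericMatrix snaps,
                               int t_steps) {
  Params P = parse_params(params);
  int nf = species.size();
  int nd = nf + 1;
  int mob_species = (species[0] == 1) ? 2 : 1;
  std::vector<int> spec(nd), mob(nd, 0), role(nd, -1);
  for (int d = 0; d < nf; ++d) { spec[d] = species[d]; role[d] = d; }
  spec[nf] = mob_species; mob[nf] = 1;
  Workspace W;
  std::vector<double> x0(3 * 2 * nd), x, f(3 * 2 * nd);
  for (int p = 0; p < 2 * nf; ++p)
    for (int k = 0; k < 3; ++k) x0[3 * p + k] = pos(p, k);
  int n = snaps.nrow();
  int half = t_steps / 2;
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("r0", "q0", "r_half", "q_half",
                                          "r_full", "q_full");
  for (int i = 0; i < n; ++i) {
    x = x0;
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 3; ++k) x[3 * (2 * nf + j) + k] = snaps(i, 3 * j + k);
    {
      double rc, q;
      pair_coords(x.data(), 0, nf, P.r0, 0.0, &rc, &q);
      out(i, 0) = rc; out(i, 1) = q;
    }
    for (int s = 0; s < t_steps; ++s) {
      std::fill(f.begin(), f.end(), 0.0);
      energy_forces(x.data(), nd, spec.data(), mob.data(), role.data(), 0.0, P,
                    f.data(), true, W);
      em_step(x.data(), nd, mob.data(), 0.0, P, f.data(), 1.0);
      if (s + 1 == half || s + 1 == t_steps) {
        double rc, q;
        pair_coords(x.data(), 0, nf, P.r0, 0.0, &rc, &q);
        if (s + 1 == half) { out(i, 2) = rc; out(i, 3) = q; }
        else { out(i, 4) = rc; out(i, 5) = q; }
      }
    }
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
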