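#include "model.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, IntegerVector species, IntegerVector mobile,
                IntegerVector role, double box, NumericVector params,
                bool active_only = false) {
  Params P = parse_params(params);
  int nd = species.size();
  Workspace W;
  std::vector<double> x(3 * 2 * nd);
  for (int p = 0; p < 2 * nd; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = pos(p, k);
  EnergyTerms E = energy_forces(x.data(), nd, species.begin(), mobile.begin(),
                                role.begin(), box, P, nullptr, active_only, W);
  double tot = E.total();
  bool capped = tot > P.ecap;
  if (capped) tot = P.ecap;
  return List::create(
      _["energy"] = tot, _["capped"] = capped,
      _["terms"] = NumericVector::create(
          _["bond"] = E.bond, _["lj_atom"] = E.lj_atom, _["lj_com"] = E.lj_com,
          _["wca"] = E.wca, _["wall"] = E.wall, _["channel"] = E.channel,
          _["tilt"] = E.tilt));
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector species,
                         IntegerVector mobile, IntegerVector role, double box,
                         NumericVector params, bool active_only = false) {
  Params P = parse_params(params);
  int nd = species.size();
  Workspace W;
  std::vector<double> x(3 * 2 * nd), f(3 * 2 * nd, 0.0);
  for (int p = 0; p < 2 * nd; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = pos(p, k);
  energy_forces(x.data(), nd, species.begin(), mobile.begin(), role.begin(),
                box, P, f.data(), active_only, W);
  NumericMatrix out(2 * nd, 3);
  for (int p = 0; p < 2 * nd; ++p)
    for (int k = 0; k < 3; ++k) out(p, k) = f[3 * p + k];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pair_coordinates(NumericMatrix dumbbell_a,
                                   NumericMatrix dumbbell_b, double r0,
                                   double box = 0.0) {
  std::vector<double> x(12);
  for (int i = 0; i < 2; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = dumbbell_a(i, k);
      x[6 + 3 * i + k] = dumbbell_b(i, k);
    }
  double rc, q;
  pair_coords(x.data(), 0, 1, r0, box, &rc, &q);
  if (!R_finite(rc) || ISNA(q))
    stop("pair coordinates undefined: zero COM separation");
  return NumericVector::create(_["rcom"] = rc, _["q"] = q);
}

// [[Rcpp::export]]
double cpp_lj(double r, double eps, double rm) {
  return lj_pair(r, eps, rm, nullptr);
}

// [[Rcpp::export]]
double cpp_wca(double r, double eps, double rm) {
  return wca_pair(r, eps, rm, nullptr);
}

// Generic propagator. Optionally records (step, rcom, q) of a tracked unlike
// dumbbell pair every `stride` steps, and can stop when the tracked pair's
// rcom leaves [stop_rcom_lo, stop_rcom_hi].
// [[Rcpp::export]]
List cpp_bd_run(NumericMatrix pos, IntegerVector species, IntegerVector mobile,
                IntegerVector role, double box, NumericVector params, int n_steps,
                double noise_scale = 1.0, int track_a = -1, int track_b = -1,
                int stride = 0, double stop_rcom_lo = -1.0,
                double stop_rcom_hi = -1.0, int check_every = 1) {
  Params P = parse_params(params);
  int nd = species.size();
  Workspace W;
  std::vector<double> x(3 * 2 * nd), f(3 * 2 * nd);
  for (int p = 0; p < 2 * nd; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = pos(p, k);

  bool track = track_a >= 0 && track_b >= 0 && stride > 0;
  std::vector<double> rec;
  int steps_done = 0;
  std::string reason = "max_steps";

  for (int s = 0; s < n_steps; ++s) {
    std::fill(f.begin(), f.end(), 0.0);
    energy_forces(x.data(), nd, species.begin(), mobile.begin(), role.begin(),
                  box, P, f.data(), true, W);
    for (double fv : f)
      if (!R_finite(fv)) stop("non-finite force at step %d", s);
    em_step(x.data(), nd, mobile.begin(), box, P, f.data(), noise_scale);
    ++steps_done;
    if (track && (s + 1) % stride == 0) {
      double rc, q;
      pair_coords(x.data(), track_a, track_b, P.r0, box, &rc, &q);
      rec.push_back((s + 1) * P.dt);
      rec.push_back(rc);
      rec.push_back(q);
    }
    if (stop_rcom_hi > 0.0 && (s + 1) % check_every == 0) {
      double rc, q;
      pair_coords(x.data(), track_a, track_b, P.r0, box, &rc, &q);
      if (rc < stop_rcom_lo) { reason = "below"; break; }
      if (rc > stop_rcom_hi) { reason = "above"; break; }
    }
  }

  NumericMatrix out(2 * nd, 3);
  for (int p = 0; p < 2 * nd; ++p)
    for (int k = 0; k < 3; ++k) out(p, k) = x[3 * p + k];
  NumericMatrix traj(rec.size() / 3, 3);
  for (int i = 0; i < traj.nrow(); ++i)
    for (int k = 0; k < 3; ++k) traj(i, k) = rec[3 * i + k];
  colnames(traj) = CharacterVector::create("time_s", "rcom", "q");
  return List::create(_["pos"] = out, _["steps"] = steps_done,
                      _["reason"] = reason, _["traj"] = traj);
}

// Metropolis Monte Carlo on the same energy function (energy-only route,
// used as an independent equilibrium oracle for the BD integrator).
// Histograms (rcom, q) of the pair (track_a, track_b) on a fixed grid.
// [[Rcpp::export]]
List cpp_mc_hist(NumericMatrix pos, IntegerVector species, IntegerVector mobile,
                 IntegerVector role, double box, NumericVector params,
                 int n_moves, double delta,
                 int track_a, int track_b, NumericVector r_edges,
                 NumericVector q_edges, int stride = 10) {
  Params P = parse_params(params);
  int nd = species.size();
  std::vector<double> x(3 * 2 * nd);
  for (int p = 0; p < 2 * nd; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = pos(p, k);
  std::vector<int> mob_particles;
  for (int d = 0; d < nd; ++d)
    if (mobile[d]) { mob_particles.push_back(2 * d); mob_particles.push_back(2 * d + 1); }
  if (mob_particles.empty()) stop("no mobile particles");

  int nr = r_edges.size() - 1, nq = q_edges.size() - 1;
  NumericMatrix counts(nr, nq);
  Workspace W;
  auto etot = [&]() {
    EnergyTerms E = energy_forces(x.data(), nd, species.begin(), mobile.begin(),
                                  role.begin(), box, P, nullptr, true, W);
    return std::min(E.total(), P.ecap);
  };
  double e0 = etot();
  int accepted = 0;
  for (int m = 0; m < n_moves; ++m) {
    int p = mob_particles[(int)std::floor(unif_rand() * mob_particles.size())];
    double old_[3];
    for (int k = 0; k < 3; ++k) {
      old_[k] = x[3 * p + k];
      x[3 * p + k] += delta * (2.0 * unif_rand() - 1.0);
    }
    double e1 = etot();
    if (e1 <= e0 || unif_rand() < std::exp(e0 - e1)) {
      e0 = e1; ++accepted;   // energies already beta-reduced (kBT units)
    } else {
      for (int k = 0; k < 3; ++k) x[3 * p + k] = old_[k];
    }
    if ((m + 1) % stride == 0) {
      double rc, q;
      pair_coords(x.data(), track_a, track_b, P.r0, box, &rc, &q);
      if (rc >= r_edges[0] && rc < r_edges[nr] && q >= q_edges[0] && q < q_edges[nq]) {
        int ir = (int)std::floor((rc - r_edges[0]) / (r_edges[1] - r_edges[0]));
        int iq = (int)std::floor((q - q_edges[0]) / (q_edges[1] - q_edges[0]));
        if (ir >= 0 && ir < nr && iq >= 0 && iq < nq) counts(ir, iq) += 1.0;
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["acceptance"] = (double)accepted / n_moves);
}
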