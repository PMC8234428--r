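#include "model.h"
using namespace Rcpp;

// Seeded fibril growth at fixed monomer concentration in a periodic box.
//
// Fibril members are frozen; free dumbbells (n_free of EACH species) move by
// overdamped BD. A free dumbbell of the species opposite to the active
// terminal that satisfies the lock criterion (rcom < lock_rcom, q < lock_q,
// both relative to the active terminal) for `persistence` consecutive steps
// is annexed to the fibril (frozen in place); the event time is recorded and
// a fresh dumbbell of the same species is inserted at a random
// non-overlapping position, so the free count of each species is conserved.
//
// Anti-nucleation bookkeeping every `check_interval` steps: free-free unlike
// pairs with rcom < dimer_rcom are split and both members re-inserted at
// random; free dumbbells within the dock radius of the passive terminal
// (dumbbell 0) are likewise relocated ("evictions").
// [[Rcpp::export]]
List cpp_growth_box(NumericMatrix fibril_pos, IntegerVector fibril_species,
                    NumericVector params, double box, int n_free,
                    double n_steps, double lock_rcom, double lock_q,
                    int persistence, double dimer_rcom, double dock_dist,
                    int check_interval, int max_events, double min_insert_dist) {
  Params P = parse_params(params);
  const double r0 = P.r0;
  int L0 = fibril_species.size();
  int cap = L0 + 2 * n_free + max_events + 1;
  int nd = L0 + 2 * n_free;

  Workspace W;
  std::vector<double> x(3 * 2 * cap, 0.0), f(3 * 2 * cap, 0.0);
  std::vector<int> spec(cap, 0), mob(cap, 0), role(cap, -1);
  for (int d = 0; d < L0; ++d) { spec[d] = fibril_species[d]; role[d] = d; }
  for (int p = 0; p < 2 * L0; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = fibril_pos(p, k);

  // random insertion with overlap rejection
  auto insert_dumbbell = [&](int d) -> bool {
    for (int attempt = 0; attempt < 1000; ++attempt) {
      double com[3], bd[3];
      for (int k = 0; k < 3; ++k) com[k] = box * unif_rand();
      do { for (int k = 0; k < 3; ++k) bd[k] = norm_rand(); } while (norm3(bd) < 1e-8);
      double nb = norm3(bd);
      double cand[6];
      for (int k = 0; k < 3; ++k) {
        cand[k] = com[k] - 0.5 * r0 * bd[k] / nb;
        cand[3 + k] = com[k] + 0.5 * r0 * bd[k] / nb;
      }
      bool ok = true;
      for (int p = 0; p < 2 * nd && ok; ++p) {
        if (p / 2 == d) continue;
        for (int i = 0; i < 2 && ok; ++i) {
          double dd[3];
          for (int k = 0; k < 3; ++k) dd[k] = cand[3 * i + k] - x[3 * p + k];
          min_image(dd, box);
          if (norm3(dd) < min_insert_dist) ok = false;
        }
      }
      if (ok) {
        for (int i = 0; i < 2; ++i)
          for (int k = 0; k < 3; ++k) x[3 * (2 * d + i) + k] = cand[3 * i + k];
        return true;
      }
    }
    return false;
  };

  // initial free dumbbells, alternating species
  for (int j = 0; j < 2 * n_free; ++j) {
    int d = L0 + j;
    spec[d] = (j % 2 == 0) ? 1 : 2;
    mob[d] = 1;
    if (!insert_dumbbell(d)) stop("insertion failure: box too crowded");
  }

  int active = L0 - 1;               // growing end = last fibril dumbbell
  std::vector<int> persist(cap, 0);
  std::vector<double> event_steps;
  int n_dimer_splits = 0, n_evictions = 0;
  bool insert_failed = false;

  int role_next = L0;
  for (double s = 0; s < n_steps; ++s) {
    std::fill(f.begin(), f.begin() + 3 * 2 * nd, 0.0);
    energy_forces(x.data(), nd, spec.data(), mob.data(), role.data(), box, P,
                  f.data(), true, W);
    em_step(x.data(), nd, mob.data(), box, P, f.data(), 1.0);

    // lock detection at the active end
    int term_spec = spec[active];
    int locked_d = -1;
    for (int d = L0; d < nd; ++d) {
      if (!mob[d] || spec[d] == term_spec) continue;
      double rc, q;
      if (term_spec == 1) pair_coords(x.data(), active, d, r0, box, &rc, &q);
      else pair_coords(x.data(), d, active, r0, box, &rc, &q);
      if (rc < lock_rcom && q < lock_q) {
        if (++persist[d] >= persistence && locked_d < 0) locked_d = d;
      } else {
        persist[d] = 0;
      }
    }
    if (locked_d >= 0) {
      mob[locked_d] = 0;
      persist[locked_d] = 0;
      role[locked_d] = role_next++;
      active = locked_d;
      event_steps.push_back(s + 1);
      int d_new = nd;
      spec[d_new] = spec[locked_d];
      mob[d_new] = 1;
      ++nd;
      if (!insert_dumbbell(d_new)) { insert_failed = true; break; }
      if ((int)event_steps.size() >= max_events) break;
    }

    // anti-nucleation and passive-end bookkeeping
    if (((long long)(s + 1)) % check_interval == 0) {
      for (int a = L0; a < nd; ++a) {
        if (!mob[a]) continue;
        // passive-end eviction (unlike species only; like species cannot dock)
        if (spec[a] != spec[0]) {
          double rc, q;
          if (spec[0] == 1) pair_coords(x.data(), 0, a, r0, box, &rc, &q);
          else pair_coords(x.data(), a, 0, r0, box, &rc, &q);
          if (rc < dock_dist) {
            if (!insert_dumbbell(a)) { insert_failed = true; break; }
            persist[a] = 0;
            ++n_evictions;
            continue;
          }
        }
        for (int b = a + 1; b < nd; ++b) {
          if (!mob[b] || spec[a] == spec[b]) continue;
          double rc, q;
          if (spec[a] == 1) pair_coords(x.data(), a, b, r0, box, &rc, &q);
          else pair_coords(x.data(), b, a, r0, box, &rc, &q);
          if (rc < dimer_rcom) {
            bool ok = insert_dumbbell(a) && insert_dumbbell(b);
            persist[a] = persist[b] = 0;
            ++n_dimer_splits;
            if (!ok) { insert_failed = true; }
            break;
          }
        }
        if (insert_failed) break;
      }
      if (insert_failed) break;
      Rcpp::checkUserInterrupt();
    }
  }
  if (insert_failed) stop("insertion failure: box too crowded");

  int n_ev = event_steps.size();
  NumericVector ev(n_ev);
  for (int i = 0; i < n_ev; ++i) ev[i] = event_steps[i] * P.dt;

  // final free count per species (bookkeeping invariant)
  int free_a = 0, free_b = 0;
  for (int d = L0; d < nd; ++d)
    if (mob[d]) { if (spec[d] == 1) ++free_a; else ++free_b; }

  NumericMatrix fin(2 * nd, 3);
  for (int p = 0; p < 2 * nd; ++p)
    for (int k = 0; k < 3; ++k) fin(p, k) = x[3 * p + k];
  IntegerVector fspec(nd), fmob(nd);
  for (int d = 0; d < nd; ++d) { fspec[d] = spec[d]; fmob[d] = mob[d]; }

  return List::create(
      _["event_times"] = ev, _["n_events"] = n_ev,
      _["dimer_splits"] = n_dimer_splits, _["evictions"] = n_evictions,
      _["free_a"] = free_a, _["free_b"] = free_b,
      _["final_length"] = L0 + n_ev,
      _["pos"] = fin, _["species"] = fspec, _["mobile"] = fmob);
}
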