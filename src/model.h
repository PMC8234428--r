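#ifndef DOCKLOCK_MODEL_H
#define DOCKLOCK_MODEL_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Chiral-dumbbell model: two diatomic species (A = particle types 1-2,
// B = types 3-4). Pair coordinates (rcom, q) are defined per unlike pair
// with u = COM(A) - COM(B), v = (x4 - x3) x (x2 - x1); rcom = |u| is the
// physical COM separation in Angstrom and q = u.v / (r0^2 |u|) the
// dimensionless chirality. Energies in kBT, time in s.

struct Params {
  double kb, r0;
  double eps_lj, r_lj_m;
  double eps_lj_c, r_lj_cm;    // COM-COM LJ on the COM separation (Angstrom)
  double eps_wca, r_wca_m;
  double ew, r0w, srw, q0w, sqw;   // wall
  double ec, r0c, src, q0c, sqc;   // channel
  double et, r0t, srt, q0t, sqt;   // tilt
  double beta, D_atom, dt;
  double rcom_cutoff;              // pair cutoff on COM separation (Angstrom)
  double ecap;                     // hard cap on total energy (kBT)
  int gauss_all_pairs;             // 1: Gaussians on every unlike pair
};

inline Params parse_params(const Rcpp::NumericVector& p) {
  Params P;
  P.kb = p["kb"];           P.r0 = p["r0"];
  P.eps_lj = p["eps_lj"];   P.r_lj_m = p["r_lj_m"];
  P.eps_lj_c = p["eps_lj_c"]; P.r_lj_cm = p["r_lj_cm"];
  P.eps_wca = p["eps_wca"]; P.r_wca_m = p["r_wca_m"];
  P.ew = p["ew"]; P.r0w = p["r0_w"]; P.srw = p["sr_w"];
  P.q0w = p["q0_w"]; P.sqw = p["sq_w"];
  P.ec = p["ec"]; P.r0c = p["r0_c"]; P.src = p["sr_c"];
  P.q0c = p["q0_c"]; P.sqc = p["sq_c"];
  P.et = p["et"]; P.r0t = p["r0_t"]; P.srt = p["sr_t"];
  P.q0t = p["q0_t"]; P.sqt = p["sq_t"];
  P.beta = p["beta"]; P.D_atom = p["D_atom"]; P.dt = p["dt"];
  P.rcom_cutoff = p["rcom_cutoff"]; P.ecap = p["ecap"];
  P.gauss_all_pairs = (int)p["gauss_all_pairs"];
  return P;
}

inline void min_image(double* d, double box) {
  if (box > 0.0) {
    for (int k = 0; k < 3; ++k) d[k] -= box * std::nearbyint(d[k] / box);
  }
}

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// 12-6 LJ written so the minimum (-eps) sits at r = rm.
// Returns energy; if dudr non-null adds dU/dr.
inline double lj_pair(double r, double eps, double rm, double* dudr) {
  const double sig = rm * std::pow(2.0, -1.0 / 6.0);
  if (r < 1e-2) r = 1e-2;
  double sr = sig / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  if (dudr) *dudr = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
  return 4.0 * eps * (sr12 - sr6);
}

// WCA: LJ + eps for r < rm, zero beyond.
inline double wca_pair(double r, double eps, double rm, double* dudr) {
  if (r >= rm) { if (dudr) *dudr = 0.0; return 0.0; }
  double du = 0.0;
  double u = lj_pair(r, eps, rm, dudr ? &du : nullptr) + eps;
  if (dudr) *dudr = du;
  return u;
}

// Seven-term energy breakdown.
struct EnergyTerms {
  double bond = 0, lj_atom = 0, lj_com = 0, wca = 0;
  double wall = 0, channel = 0, tilt = 0;
  bool capped = false;
  double total() const {
    return bond + lj_atom + lj_com + wca + wall + channel + tilt;
  }
};

struct Workspace {
  std::vector<double> com, bv;
  void resize(int nd) {
    if ((int)com.size() < 3 * nd) { com.resize(3 * nd); bv.resize(3 * nd); }
  }
};

// Optional restriction of the wall/channel/tilt Gaussians to "interface"
// unlike pairs: both free, free vs a terminal fibril member, or consecutive
// fibril members. role: -1 = free dumbbell, >= 0 = fibril chain position.
// (With the physical-Angstrom geometry the interior fibril sites are
// sterically shielded by the same-species WCA, so the default evaluates the
// Gaussians on every unlike pair.)
inline bool gaussian_pair(int role_a, int role_b, int role_max) {
  if (role_a < 0 && role_b < 0) return true;
  if (role_a < 0) return role_b == 0 || role_b == role_max;
  if (role_b < 0) return role_a == 0 || role_a == role_max;
  return std::abs(role_a - role_b) == 1;
}

// Core energy/force evaluation.
//  x       : 3*N coordinates, particles 2d, 2d+1 belong to dumbbell d and are
//            stored in bond order (type 1 then 2 for species A; 3 then 4 for B)
//  species : per dumbbell, 1 = A(1-2), 2 = B(3-4)
//  mobile  : per dumbbell flag; when active_only, pairs of two frozen
//            dumbbells and bonds of frozen dumbbells are skipped (their
//            contribution is a constant that exerts no force on mobile atoms)
//  role    : per dumbbell fibril-chain label (see gaussian_pair)
//  f       : 3*N force accumulator (-grad U) or nullptr
inline EnergyTerms energy_forces(const double* x, int nd, const int* species,
                                 const int* mobile, const int* role,
                                 double box, const Params& P, double* f,
                                 bool active_only, Workspace& W) {
  EnergyTerms E;
  const double r0 = P.r0, K = r0 * r0;
  int role_max = -1;
  for (int d = 0; d < nd; ++d) if (role[d] > role_max) role_max = role[d];
  W.resize(nd);
  double* com = W.com.data();
  double* bv = W.bv.data();
  for (int d = 0; d < nd; ++d) {
    double b[3];
    for (int k = 0; k < 3; ++k) b[k] = x[3 * (2 * d + 1) + k] - x[3 * 2 * d + k];
    min_image(b, box);
    for (int k = 0; k < 3; ++k) {
      bv[3 * d + k] = b[k];
      com[3 * d + k] = x[3 * 2 * d + k] + 0.5 * b[k];
    }
  }

  // bonds
  for (int d = 0; d < nd; ++d) {
    if (active_only && !mobile[d]) continue;
    const double* b = &bv[3 * d];
    double r = norm3(b);
    double dr = r - r0;
    E.bond += 0.5 * P.kb * dr * dr;
    if (f && r > 1e-12) {
      double c = P.kb * dr / r;  // dU/dr * (unit vector scale)
      for (int k = 0; k < 3; ++k) {
        f[3 * (2 * d + 1) + k] -= c * b[k];
        f[3 * 2 * d + k] += c * b[k];
      }
    }
  }

  for (int a = 0; a < nd; ++a) {
    for (int b = a + 1; b < nd; ++b) {
      if (active_only && !mobile[a] && !mobile[b]) continue;
      double u[3];
      for (int k = 0; k < 3; ++k) u[k] = com[3 * a + k] - com[3 * b + k];
      min_image(u, box);
      double ru = norm3(u);
      if (ru > P.rcom_cutoff) continue;

      if (species[a] == species[b]) {
        // WCA between atoms of same-species dumbbells (inter-molecular only)
        for (int i = 0; i < 2; ++i) {
          for (int j = 0; j < 2; ++j) {
            int pi = 2 * a + i, pj = 2 * b + j;
            double d_[3];
            for (int k = 0; k < 3; ++k) d_[k] = x[3 * pi + k] - x[3 * pj + k];
            min_image(d_, box);
            double r = norm3(d_);
            double du = 0.0;
            E.wca += wca_pair(r, P.eps_wca, P.r_wca_m, f ? &du : nullptr);
            if (f && r > 1e-12 && du != 0.0) {
              double c = du / r;
              for (int k = 0; k < 3; ++k) {
                f[3 * pi + k] -= c * d_[k];
                f[3 * pj + k] += c * d_[k];
              }
            }
          }
        }
        continue;
      }

      // unlike pair: orient so u = COM(A) - COM(B)
      int A = a, B = b;
      double sgn = 1.0;
      if (species[a] == 2) { A = b; B = a; sgn = -1.0; }
      double uAB[3];
      for (int k = 0; k < 3; ++k) uAB[k] = sgn * u[k];

      // atom-atom LJ over the four unlike-type pairs
      for (int i = 0; i < 2; ++i) {
        for (int j = 0; j < 2; ++j) {
          int pi = 2 * A + i, pj = 2 * B + j;
          double d_[3];
          for (int k = 0; k < 3; ++k) d_[k] = x[3 * pi + k] - x[3 * pj + k];
          min_image(d_, box);
          double r = norm3(d_);
          double du = 0.0;
          E.lj_atom += lj_pair(r, P.eps_lj, P.r_lj_m, f ? &du : nullptr);
          if (f && r > 1e-12) {
            double c = du / r;
            for (int k = 0; k < 3; ++k) {
              f[3 * pi + k] -= c * d_[k];
              f[3 * pj + k] += c * d_[k];
            }
          }
        }
      }

      // COM-COM LJ on the physical separation (Angstrom)
      {
        double du = 0.0;
        E.lj_com += lj_pair(ru, P.eps_lj_c, P.r_lj_cm, f ? &du : nullptr);
        if (f && ru > 1e-12) {
          // d|u|/dx = +- uhat / 2 (A atoms +, B atoms -)
          double c = du / (2.0 * ru);
          for (int k = 0; k < 3; ++k) {
            double g = c * uAB[k];
            f[3 * 2 * A + k] -= g;     f[3 * (2 * A + 1) + k] -= g;
            f[3 * 2 * B + k] += g;     f[3 * (2 * B + 1) + k] += g;
          }
        }
      }

      // Gaussian terms on (rCOM, q): interface pairs only
      if (ru > 1e-12 && (P.gauss_all_pairs ||
                         gaussian_pair(role[a], role[b], role_max))) {
        const double* bA = &bv[3 * A];
        const double* bB = &bv[3 * B];
        double v[3];
        cross3(bB, bA, v);
        double s = dot3(uAB, v);
        double q = s / (K * ru);

        double Ug = 0.0, dUdr = 0.0, dUdq = 0.0;   // dUdr wrt |u| (Angstrom)
        const double cen[3] = {P.r0w, P.r0c, P.r0t};
        const double sr_[3] = {P.srw, P.src, P.srt};
        const double cq[3] = {P.q0w, P.q0c, P.q0t};
        const double sq_[3] = {P.sqw, P.sqc, P.sqt};
        const double ee[3] = {P.ew, P.ec, P.et};
        double terms[3];
        for (int g = 0; g < 3; ++g) {
          double zr = (ru - cen[g]) / sr_[g];
          double zq = (q - cq[g]) / sq_[g];
          double val = ee[g] * std::exp(-0.5 * zr * zr) * std::exp(-0.5 * zq * zq);
          terms[g] = val;
          Ug += val;
          dUdr += -val * zr / sr_[g];
          dUdq += -val * zq / sq_[g];
        }
        E.wall += terms[0]; E.channel += terms[1]; E.tilt += terms[2];

        if (f && (dUdr != 0.0 || dUdq != 0.0)) {
          double uhat[3];
          for (int k = 0; k < 3; ++k) uhat[k] = uAB[k] / ru;
          double uxbB[3], bAxu[3];
          cross3(uAB, bB, uxbB);
          cross3(bA, uAB, bAxu);
          // ds/dx for x1,x2 (A atoms) and x3,x4 (B atoms)
          for (int k = 0; k < 3; ++k) {
            double ds1 = 0.5 * v[k] - uxbB[k];
            double ds2 = 0.5 * v[k] + uxbB[k];
            double ds3 = -0.5 * v[k] - bAxu[k];
            double ds4 = -0.5 * v[k] + bAxu[k];
            double dru1 = 0.5 * uhat[k];   // = d|u|/dx for A atoms
            double dq1 = (ds1 - q * K * dru1) / (K * ru);
            double dq2 = (ds2 - q * K * dru1) / (K * ru);
            double dq3 = (ds3 + q * K * dru1) / (K * ru);
            double dq4 = (ds4 + q * K * dru1) / (K * ru);
            double drc = dru1;             // d|u|/dx for A atoms
            f[3 * 2 * A + k]       -= dUdr * drc + dUdq * dq1;
            f[3 * (2 * A + 1) + k] -= dUdr * drc + dUdq * dq2;
            f[3 * 2 * B + k]       -= -dUdr * drc + dUdq * dq3;
            f[3 * (2 * B + 1) + k] -= -dUdr * drc + dUdq * dq4;
          }
        }
      }
    }
  }

  if (E.total() > P.ecap) E.capped = true;
  return E;
}

// Pair coordinates of an unlike pair (dumbbell dA of species A, dB of B).
inline void pair_coords(const double* x, int dA, int dB, double r0, double box,
                        double* rcom, double* q) {
  double bA[3], bB[3], comA[3], comB[3];
  for (int k = 0; k < 3; ++k) bA[k] = x[3 * (2 * dA + 1) + k] - x[3 * 2 * dA + k];
  for (int k = 0; k < 3; ++k) bB[k] = x[3 * (2 * dB + 1) + k] - x[3 * 2 * dB + k];
  min_image(bA, box); min_image(bB, box);
  for (int k = 0; k < 3; ++k) {
    comA[k] = x[3 * 2 * dA + k] + 0.5 * bA[k];
    comB[k] = x[3 * 2 * dB + k] + 0.5 * bB[k];
  }
  double u[3];
  for (int k = 0; k < 3; ++k) u[k] = comA[k] - comB[k];
  min_image(u, box);
  double ru = norm3(u);
  *rcom = ru;                      // physical COM separation, Angstrom
  if (ru < 1e-12) { *q = NA_REAL; return; }
  double v[3];
  cross3(bB, bA, v);
  *q = dot3(u, v) / (r0 * r0 * ru);
}

// One Euler-Maruyama step; f must hold current forces (-grad U, kBT/Angstrom).
// noise_scale = 1 normally, 0 disables the stochastic term (testing).
inline void em_step(double* x, int nd, const int* mobile, double box,
                    const Params& P, const double* f, double noise_scale) {
  const double drift = P.D_atom * P.beta * P.dt;
  const double sig = noise_scale * std::sqrt(2.0 * P.D_atom * P.dt);
  for (int d = 0; d < nd; ++d) {
    if (!mobile[d]) continue;
    for (int i = 0; i < 2; ++i) {
      int p = 2 * d + i;
      for (int k = 0; k < 3; ++k) {
        double xn = x[3 * p + k] + drift * f[3 * p + k];
        if (sig > 0.0) xn += sig * norm_rand();
        if (box > 0.0) xn -= box * std::floor(xn / box);
        x[3 * p + k] = xn;
      }
    }
  }
}

#endif
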