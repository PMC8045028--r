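// Compiled core of the bead-necklace model: pair energies, total energy,
// and the Metropolis Monte Carlo loop. All energies are in kT; all
// lengths in Angstrom. Distances use the minimum image convention when
// periodic; coordinates themselves are never wrapped (bond geometry stays
// continuous, which keeps rigid-body and pivot moves exact).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct System {
  int n;
  std::vector<double> x, y, z;
  std::vector<double> q, R, eps;      // eps in kT * A^6
  std::vector<int> arg, ion, poly;
  std::vector<std::pair<int, int>> bonds;
  double L;
  bool periodic;
  double lB, kappa, kbond, r0, epsArg;

  inline double mi(double d) const {
    if (periodic) d -= L * std::round(d / L);
    return d;
  }
  inline double dist(int i, int j) const {
    double dx = mi(x[i] - x[j]), dy = mi(y[i] - y[j]), dz = mi(z[i] - z[j]);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  // nonbonded pair energy: hard sphere + extended Debye-Hueckel + r^-6
  inline double pair_u(int i, int j) const {
    double r = dist(i, j);
    double sig = R[i] + R[j];
    if (r < sig) return R_PosInf;  // contact (r == sig) is allowed
    double u = 0.0;
    double qq = q[i] * q[j];
    if (qq != 0.0) {
      u += qq * lB / r * std::exp(-kappa * (r - sig)) /
           ((1.0 + kappa * R[i]) * (1.0 + kappa * R[j]));
    }
    double e;
    if (ion[i] || ion[j]) {
      bool argpoly = (arg[i] && poly[j]) || (arg[j] && poly[i]);
      e = argpoly ? epsArg : 0.0;
    } else {
      e = 0.5 * (eps[i] + eps[j]);
    }
    if (e != 0.0) {
      double r2 = r * r;
      u -= e / (r2 * r2 * r2);
    }
    return u;
  }
  inline double bond_u(size_t b) const {
    double d = dist(bonds[b].first, bonds[b].second) - r0;
    return 0.5 * kbond * d * d;
  }
  double total() const {
    double u = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double p = pair_u(i, j);
        if (p == R_PosInf) return R_PosInf;
        u += p;
      }
    for (size_t b = 0; b < bonds.size(); ++b) u += bond_u(b);
    return u;
  }
  // all energy terms touching the site set S (in-set pairs counted once)
  double set_u(const std::vector<int>& S, const std::vector<char>& inS) const {
    double u = 0.0;
    for (size_t a = 0; a < S.size(); ++a) {
      int i = S[a];
      for (int j = 0; j < n; ++j) {
        if (j == i || (inS[j] && j < i)) continue;
        double p = pair_u(i, j);
        if (p == R_PosInf) return R_PosInf;
        u += p;
      }
    }
    for (size_t b = 0; b < bonds.size(); ++b)
      if (inS[bonds[b].first] || inS[bonds[b].second]) u += bond_u(b);
    return u;
  }
};

static System make_system(const NumericMatrix& coords, const NumericVector& q,
                          const NumericVector& radius, const NumericVector& eps,
                          const IntegerVector& is_arg, const IntegerVector& is_ion,
                          const IntegerVector& is_poly, const IntegerMatrix& bonds0,
                          double box, bool periodic, double lB, double kappa,
                          double kbond, double r0, double eps_arg) {
  System s;
  s.n = coords.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = coords(i, 0); s.y[i] = coords(i, 1); s.z[i] = coords(i, 2);
  }
  s.q = as<std::vector<double>>(q);
  s.R = as<std::vector<double>>(radius);
  s.eps = as<std::vector<double>>(eps);
  s.arg = as<std::vector<int>>(is_arg);
  s.ion = as<std::vector<int>>(is_ion);
  s.poly = as<std::vector<int>>(is_poly);
  for (int b = 0; b < bonds0.nrow(); ++b)
    s.bonds.push_back(std::make_pair(bonds0(b, 0), bonds0(b, 1)));
  s.L = box; s.periodic = periodic;
  s.lB = lB; s.kappa = kappa; s.kbond = kbond; s.r0 = r0; s.epsArg = eps_arg;
  return s;
}

// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix coords, NumericVector q,
                        NumericVector radius, NumericVector eps_kT,
                        IntegerVector is_arg, IntegerVector is_ion,
                        IntegerVector is_poly, IntegerMatrix bonds0,
                        double box, bool periodic, double lB, double kappa,
                        double kbond, double r0, double eps_arg) {
  System s = make_system(coords, q, radius, eps_kT, is_arg, is_ion, is_poly,
                         bonds0, box, periodic, lB, kappa, kbond, r0, eps_arg);
  return s.total();
}

static void rand_unit(double& ux, double& uy, double& uz) {
  // Marsaglia: uniform on the sphere
  double a, b, s;
  do {
    a = 2.0 * unif_rand() - 1.0;
    b = 2.0 * unif_rand() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0 || s == 0.0);
  double f = 2.0 * std::sqrt(1.0 - s);
  ux = a * f; uy = b * f; uz = 1.0 - 2.0 * s;
}

static void rotate_about(double px, double py, double pz, double ux, double uy,
                         double uz, double theta, double& X, double& Y, double& Z) {
  // Rodrigues rotation of (X,Y,Z) about axis u through point p
  double vx = X - px, vy = Y - py, vz = Z - pz;
  double c = std::cos(theta), s = std::sin(theta);
  double dot = ux * vx + uy * vy + uz * vz;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  X = px + vx * c + cx * s + ux * dot * (1.0 - c);
  Y = py + vy * c + cy * s + uy * dot * (1.0 - c);
  Z = pz + vz * c + cz * s + uz * dot * (1.0 - c);
}

enum MoveType { SINGLE = 0, PIVOT = 1, CHAIN = 2, SLITHER = 3 };

// [[Rcpp::export]]
List run_mc_cpp(NumericMatrix coords, NumericVector q, NumericVector radius,
                NumericVector eps_kT, IntegerVector is_arg, IntegerVector is_ion,
                IntegerVector is_poly, IntegerMatrix bonds0, double box,
                bool periodic, double lB, double kappa, double kbond, double r0,
                double eps_arg, List chains0, int n_equil, int n_prod,
                int sample_interval, NumericVector weights,
                NumericVector amplitudes, bool tune, int tune_interval,
                int revalidate_interval) {
  System s = make_system(coords, q, radius, eps_kT, is_arg, is_ion, is_poly,
                         bonds0, box, periodic, lB, kappa, kbond, r0, eps_arg);
  int nchain = chains0.size();
  std::vector<std::vector<int>> chains(nchain);
  std::vector<int> pivot_ok;  // chains with >= 3 beads
  for (int c = 0; c < nchain; ++c) {
    chains[c] = as<std::vector<int>>(chains0[c]);
    if ((int)chains[c].size() >= 3) pivot_ok.push_back(c);
  }
  double w[4] = {weights[0], weights[1], weights[2], weights[3]};
  if (nchain == 0) w[PIVOT] = w[CHAIN] = w[SLITHER] = 0.0;
  if (pivot_ok.empty()) w[PIVOT] = 0.0;
  double wsum = w[0] + w[1] + w[2] + w[3];
  if (wsum <= 0) stop("no applicable Monte Carlo moves");
  double amp[3] = {amplitudes[0], amplitudes[1], amplitudes[2]};  // single, chain, pivot

  double U = s.total();
  if (U == R_PosInf)
    stop("initial configuration contains hard-sphere overlaps");

  long attempts[4] = {0, 0, 0, 0}, accepts[4] = {0, 0, 0, 0};
  long win_att[4] = {0, 0, 0, 0}, win_acc[4] = {0, 0, 0, 0};

  int n_frames = sample_interval > 0 ? n_prod / sample_interval : 0;
  List frames(n_frames);
  NumericVector energies(n_frames);
  int frame_i = 0;

  std::vector<char> mask(s.n, 0);
  std::vector<int> S;
  std::vector<double> ox, oy, oz;  // saved coordinates for the moved set

  long total_steps = (long)n_equil + (long)n_prod;
  for (long step = 0; step < total_steps; ++step) {
    bool production = step >= n_equil;
    // pick move type
    double draw = unif_rand() * wsum;
    int mt = 0;
    double acc_w = 0.0;
    for (int k = 0; k < 4; ++k) {
      acc_w += w[k];
      if (draw < acc_w) { mt = k; break; }
    }
    // build the moved set S and propose
    S.clear();
    if (mt == SINGLE) {
      int i = (int)std::floor(unif_rand() * s.n);
      if (i >= s.n) i = s.n - 1;
      S.push_back(i);
    } else if (mt == PIVOT) {
      int c = pivot_ok[(int)std::floor(unif_rand() * pivot_ok.size())];
      const std::vector<int>& ch = chains[c];
      int len = ch.size();
      int h = 1 + (int)std::floor(unif_rand() * (len - 2));  // internal hinge
      int left = h, right = len - 1 - h;
      bool use_left = left < right || (left == right && unif_rand() < 0.5);
      if (use_left) for (int k = 0; k < h; ++k) S.push_back(ch[k]);
      else for (int k = h + 1; k < len; ++k) S.push_back(ch[k]);
      // stash hinge index at the back via mask later; rotation applied below
      ox.clear(); oy.clear(); oz.clear();
      for (size_t k = 0; k < S.size(); ++k) {
        ox.push_back(s.x[S[k]]); oy.push_back(s.y[S[k]]); oz.push_back(s.z[S[k]]);
      }
      for (size_t k = 0; k < S.size(); ++k) mask[S[k]] = 1;
      double u_old = s.set_u(S, mask);
      double ux, uy, uz;
      rand_unit(ux, uy, uz);
      double theta = (2.0 * unif_rand() - 1.0) * amp[2];
      int hi = ch[h];
      for (size_t k = 0; k < S.size(); ++k)
        rotate_about(s.x[hi], s.y[hi], s.z[hi], ux, uy, uz, theta,
                     s.x[S[k]], s.y[S[k]], s.z[S[k]]);
      double u_new = s.set_u(S, mask);
      double du = u_new - u_old;
      attempts[mt]++; win_att[mt]++;
      bool acc = (du <= 0.0) ||
                 (du != R_PosInf && unif_rand() < std::exp(-du));
      if (acc) { accepts[mt]++; win_acc[mt]++; U += du; }
      else for (size_t k = 0; k < S.size(); ++k) {
        s.x[S[k]] = ox[k]; s.y[S[k]] = oy[k]; s.z[S[k]] = oz[k];
      }
      for (size_t k = 0; k < S.size(); ++k) mask[S[k]] = 0;
      goto bookkeeping;
    } else {  // CHAIN or SLITHER
      int c = (int)std::floor(unif_rand() * nchain);
      if (c >= nchain) c = nchain - 1;
      S = chains[c];
    }
    {
      ox.clear(); oy.clear(); oz.clear();
      for (size_t k = 0; k < S.size(); ++k) {
        ox.push_back(s.x[S[k]]); oy.push_back(s.y[S[k]]); oz.push_back(s.z[S[k]]);
      }
      for (size_t k = 0; k < S.size(); ++k) mask[S[k]] = 1;
      double u_old = s.set_u(S, mask);
      double slither_bias = 0.0;
      if (mt == SINGLE) {
        int i = S[0];
        s.x[i] += (2.0 * unif_rand() - 1.0) * amp[0];
        s.y[i] += (2.0 * unif_rand() - 1.0) * amp[0];
        s.z[i] += (2.0 * unif_rand() - 1.0) * amp[0];
      } else if (mt == CHAIN) {
        double dx = (2.0 * unif_rand() - 1.0) * amp[1];
        double dy = (2.0 * unif_rand() - 1.0) * amp[1];
        double dz = (2.0 * unif_rand() - 1.0) * amp[1];
        for (size_t k = 0; k < S.size(); ++k) {
          s.x[S[k]] += dx; s.y[S[k]] += dy; s.z[S[k]] += dz;
        }
      } else {  // SLITHER: reptation with bond-Boltzmann regrowth.
        // The new terminal bond vector is drawn from
        // g(b) ~ exp(-U_bond(|b|)) d^3b (length from r^2 exp(-U_bond), direction
        // uniform); the Metropolis-Hastings ratio then cancels the regrown and
        // removed bond energies, so the acceptance uses only the remaining terms.
        int len = S.size();
        double ux, uy, uz;
        rand_unit(ux, uy, uz);
        double sigma = 1.0 / std::sqrt(kbond);
        double rcap = r0 + 6.0 * sigma;
        double rb;
        do {
          rb = r0 + sigma * norm_rand();
        } while (rb <= 0.0 || rb >= rcap ||
                 unif_rand() > (rb * rb) / (rcap * rcap));
        double dnew = rb - r0;
        double rold;
        if (unif_rand() < 0.5) {
          // grow at the last bead: p_i <- p_{i+1}; bond (0,1) is removed
          double dx = ox[1] - ox[0], dy = oy[1] - oy[0], dz = oz[1] - oz[0];
          rold = std::sqrt(dx * dx + dy * dy + dz * dz);
          double nxp = ox[len - 1] + rb * ux;
          double nyp = oy[len - 1] + rb * uy;
          double nzp = oz[len - 1] + rb * uz;
          for (int k = 0; k < len - 1; ++k) {
            s.x[S[k]] = ox[k + 1]; s.y[S[k]] = oy[k + 1]; s.z[S[k]] = oz[k + 1];
          }
          s.x[S[len - 1]] = nxp; s.y[S[len - 1]] = nyp; s.z[S[len - 1]] = nzp;
        } else {
          // grow at the first bead; bond (len-2, len-1) is removed
          double dx = ox[len - 1] - ox[len - 2], dy = oy[len - 1] - oy[len - 2],
                 dz = oz[len - 1] - oz[len - 2];
          rold = std::sqrt(dx * dx + dy * dy + dz * dz);
          double nxp = ox[0] + rb * ux;
          double nyp = oy[0] + rb * uy;
          double nzp = oz[0] + rb * uz;
          for (int k = len - 1; k >= 1; --k) {
            s.x[S[k]] = ox[k - 1]; s.y[S[k]] = oy[k - 1]; s.z[S[k]] = oz[k - 1];
          }
          s.x[S[0]] = nxp; s.y[S[0]] = nyp; s.z[S[0]] = nzp;
        }
        double dold = rold - r0;
        slither_bias = 0.5 * kbond * (dnew * dnew - dold * dold);
      }
      double u_new = s.set_u(S, mask);
      double du = u_new - u_old;
      double du_acc = (du == R_PosInf) ? du : du - slither_bias;
      attempts[mt]++; win_att[mt]++;
      bool acc = (du_acc <= 0.0) ||
                 (du_acc != R_PosInf && unif_rand() < std::exp(-du_acc));
      if (acc) { accepts[mt]++; win_acc[mt]++; U += du; }
      else for (size_t k = 0; k < S.size(); ++k) {
        s.x[S[k]] = ox[k]; s.y[S[k]] = oy[k]; s.z[S[k]] = oz[k];
      }
      for (size_t k = 0; k < S.size(); ++k) mask[S[k]] = 0;
    }
  bookkeeping:
    // amplitude tuning during equilibration only (frozen for production)
    if (tune && !production && mt != SLITHER && win_att[mt] >= tune_interval) {
      double rate = (double)win_acc[mt] / (double)win_att[mt];
      int ai = (mt == SINGLE) ? 0 : (mt == CHAIN ? 1 : 2);
      if (rate < 0.30) amp[ai] *= 0.8;
      else if (rate > 0.50) amp[ai] *= 1.2;
      double cap = (ai == 2) ? M_PI : (periodic ? box / 2.0 : box);
      if (amp[ai] > cap) amp[ai] = cap;
      if (amp[ai] < 1e-3) amp[ai] = 1e-3;
      win_att[mt] = 0; win_acc[mt] = 0;
    }
    if (step == (long)n_equil - 1) {
      // production statistics start clean
      for (int k = 0; k < 4; ++k) { attempts[k] = 0; accepts[k] = 0; }
    }
    if (revalidate_interval > 0 && (step + 1) % revalidate_interval == 0) {
      double Ut = s.total();
      if (std::fabs(Ut - U) > 1e-6 * (1.0 + std::fabs(Ut)))
        stop("incremental energy drifted from full recomputation");
      U = Ut;
    }
    if (production && sample_interval > 0 &&
        ((step - n_equil + 1) % sample_interval == 0) && frame_i < n_frames) {
      NumericMatrix fr(s.n, 3);
      for (int i = 0; i < s.n; ++i) {
        fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z[i];
      }
      frames[frame_i] = fr;
      energies[frame_i] = U;
      ++frame_i;
    }
  }

  NumericMatrix final_coords(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    final_coords(i, 0) = s.x[i];
    final_coords(i, 1) = s.y[i];
    final_coords(i, 2) = s.z[i];
  }
  IntegerMatrix accmat(4, 2);
  for (int k = 0; k < 4; ++k) {
    accmat(k, 0) = accepts[k];
    accmat(k, 1) = attempts[k];
  }
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["acceptance"] = accmat,
                      _["amplitudes"] = NumericVector::create(amp[0], amp[1], amp[2]),
                      _["final_coords"] = final_coords,
                      _["final_energy"] = U);
}
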