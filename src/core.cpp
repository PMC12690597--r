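// Bead-spring force field and dynamics in reduced Lennard-Jones units.
// Energy terms: WCA excluded volume, harmonic bonds, Coulomb via classical
// Ewald summation (real + reciprocal + self).  All positions in sigma units,
// energies in epsilon, charges in e, cubic periodic box.
#include <Rcpp.h>
#include <vector>
#include <complex>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

struct EnergyTerms {
  double wca, bond, coul;
  double total() const { return wca + bond + coul; }
};

// Holds the (fixed-topology) system definition and scratch tables for the
// Ewald reciprocal sum so repeated force calls reuse allocations.
class ForceField {
public:
  int N;
  double L, lb, rc, alpha, kbond, r0;
  int nmax;
  bool shifted;         // energy-shifted WCA (continuous at cutoff)
  bool do_coulomb;
  std::vector<double> q;
  std::vector<int> b1, b2;      // bond index pairs (0-based)
  double wca_cut2;
  // tabulated real-space kernel over r^2 (integration path): index u in
  // [u0, rc^2], values of erfc(a r)/r (energy) and the force factor
  bool use_table;
  double tab_u0, tab_du_inv;
  std::vector<double> tab_e, tab_f;
  // k-vector table (half-space) and prefactors
  std::vector<int> kx, ky, kz;
  std::vector<double> Ak;

  ForceField(int N_, double L_, double lb_, double rc_, double alpha_,
             int nmax_, double kbond_, double r0_, bool shifted_,
             const std::vector<double>& q_,
             const std::vector<int>& b1_, const std::vector<int>& b2_)
    : N(N_), L(L_), lb(lb_), rc(rc_), alpha(alpha_), kbond(kbond_), r0(r0_),
      nmax(nmax_), shifted(shifted_), q(q_), b1(b1_), b2(b2_) {
    wca_cut2 = std::pow(2.0, 1.0 / 3.0);   // (2^(1/6))^2
    do_coulomb = false;
    for (int i = 0; i < N; i++) if (q[i] != 0.0) { do_coulomb = true; break; }
    if (lb <= 0.0) do_coulomb = false;
    use_table = false;
    if (do_coulomb) build_ktable();
  }

  void build_rtable(int M = 16384) {
    if (!do_coulomb) return;
    use_table = true;
    tab_u0 = 0.5;
    double umax = rc * rc;
    double du = (umax - tab_u0) / M;
    tab_du_inv = 1.0 / du;
    tab_e.resize(M + 2); tab_f.resize(M + 2);
    double sqrtpi = std::sqrt(M_PI);
    for (int m = 0; m <= M + 1; m++) {
      double u = tab_u0 + m * du;
      double r = std::sqrt(u);
      double ar = alpha * r;
      double ec = std::erfc(ar);
      tab_e[m] = ec / r;
      tab_f[m] = (ec / r + (2.0 * alpha / sqrtpi) * std::exp(-ar * ar)) / u;
    }
  }

  void build_ktable() {
    const double twopi = 2.0 * M_PI;
    double kcut = twopi * nmax / L;
    double kcut2 = kcut * kcut * 1.0000001;
    double V = L * L * L;
    for (int nx = 0; nx <= nmax; nx++) {
      int ylo = (nx == 0) ? 0 : -nmax;
      for (int ny = ylo; ny <= nmax; ny++) {
        int zlo = (nx == 0 && ny == 0) ? 1 : -nmax;
        for (int nz = zlo; nz <= nmax; nz++) {
          double k2 = twopi * twopi * (double)(nx * nx + ny * ny + nz * nz) / (L * L);
          if (k2 > kcut2) continue;
          kx.push_back(nx); ky.push_back(ny); kz.push_back(nz);
          // half-space factor 2 folded into the prefactor
          Ak.push_back(2.0 * (2.0 * M_PI * lb / V) *
                       std::exp(-k2 / (4.0 * alpha * alpha)) / k2);
        }
      }
    }
  }

  // Pairwise (WCA + real-space Coulomb) over a neighbour list given as
  // flat (i, j) pairs; adds forces, returns energies.
  void pair_terms(const std::vector<double>& x, const std::vector<int>& pi_,
                  const std::vector<int>& pj_, std::vector<double>& f,
                  EnergyTerms& E) const {
    double rc2 = rc * rc;
    double sqrtpi = std::sqrt(M_PI);
    size_t np = pi_.size();
    for (size_t p = 0; p < np; p++) {
      int i = pi_[p], j = pj_[p];
      double dx = min_image(x[3 * i] - x[3 * j], L);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double fr = 0.0;  // force/r along r_ij, positive = repulsive
      if (r2 < wca_cut2) {
        double inv2 = 1.0 / r2;
        double inv6 = inv2 * inv2 * inv2;
        double inv12 = inv6 * inv6;
        E.wca += 4.0 * (inv12 - inv6) + (shifted ? 1.0 : 0.0);
        fr += (48.0 * inv12 - 24.0 * inv6) * inv2;
      }
      double qq = q[i] * q[j];
      if (do_coulomb && qq != 0.0) {
        if (use_table && r2 >= tab_u0) {
          double t = (r2 - tab_u0) * tab_du_inv;
          int m = (int)t;
          double w = t - m;
          E.coul += lb * qq * (tab_e[m] * (1.0 - w) + tab_e[m + 1] * w);
          fr += lb * qq * (tab_f[m] * (1.0 - w) + tab_f[m + 1] * w);
        } else {
          double r = std::sqrt(r2);
          double ar = alpha * r;
          double erfc_ar = std::erfc(ar);
          E.coul += lb * qq * erfc_ar / r;
          fr += lb * qq * (erfc_ar / r + (2.0 * alpha / sqrtpi) * std::exp(-ar * ar)) / r2;
        }
      }
      if (fr != 0.0) {
        f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
        f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
        f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
      }
    }
  }

  void bond_terms(const std::vector<double>& x, std::vector<double>& f,
                  EnergyTerms& E, double* max_dev) const {
    for (size_t b = 0; b < b1.size(); b++) {
      int i = b1[b], j = b2[b];
      double dx = min_image(x[3 * i] - x[3 * j], L);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double d = r - r0;
      E.bond += 0.5 * kbond * d * d;
      if (max_dev && std::fabs(d) > *max_dev) *max_dev = std::fabs(d);
      double fr = -kbond * d / r;
      f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
      f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
      f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
    }
  }

  // scratch for the reciprocal sum (raw re/im arrays, sign-resolved tables)
  std::vector<double> exr_, exi_, eyr_, eyi_, ezr_, ezi_, qexr_, qexi_,
                      qxyr_, qxyi_, cr_, ci_;

  void recip_terms(const std::vector<double>& x, std::vector<double>& f,
                   EnergyTerms& E) {
    if (!do_coulomb) return;
    const double twopi = 2.0 * M_PI;
    int W = 2 * nmax + 1;            // signed index: n + nmax
    exr_.assign((size_t)N * (nmax + 1), 0.0);
    exi_.assign((size_t)N * (nmax + 1), 0.0);
    eyr_.assign((size_t)N * W, 0.0); eyi_.assign((size_t)N * W, 0.0);
    ezr_.assign((size_t)N * W, 0.0); ezi_.assign((size_t)N * W, 0.0);
    qexr_.resize(N); qexi_.resize(N);
    qxyr_.resize(N); qxyi_.resize(N);
    cr_.resize(N); ci_.resize(N);
    for (int i = 0; i < N; i++) {
      double cx = std::cos(twopi * x[3 * i] / L), sx = std::sin(twopi * x[3 * i] / L);
      double cy = std::cos(twopi * x[3 * i + 1] / L), sy = std::sin(twopi * x[3 * i + 1] / L);
      double cz = std::cos(twopi * x[3 * i + 2] / L), sz = std::sin(twopi * x[3 * i + 2] / L);
      size_t ox = (size_t)i * (nmax + 1);
      size_t oy = (size_t)i * W;
      exr_[ox] = 1.0; exi_[ox] = 0.0;
      for (int n = 1; n <= nmax; n++) {
        exr_[ox + n] = exr_[ox + n - 1] * cx - exi_[ox + n - 1] * sx;
        exi_[ox + n] = exr_[ox + n - 1] * sx + exi_[ox + n - 1] * cx;
      }
      eyr_[oy + nmax] = 1.0; eyi_[oy + nmax] = 0.0;
      ezr_[oy + nmax] = 1.0; ezi_[oy + nmax] = 0.0;
      for (int n = 1; n <= nmax; n++) {
        eyr_[oy + nmax + n] = eyr_[oy + nmax + n - 1] * cy - eyi_[oy + nmax + n - 1] * sy;
        eyi_[oy + nmax + n] = eyr_[oy + nmax + n - 1] * sy + eyi_[oy + nmax + n - 1] * cy;
        ezr_[oy + nmax + n] = ezr_[oy + nmax + n - 1] * cz - ezi_[oy + nmax + n - 1] * sz;
        ezi_[oy + nmax + n] = ezr_[oy + nmax + n - 1] * sz + ezi_[oy + nmax + n - 1] * cz;
        eyr_[oy + nmax - n] = eyr_[oy + nmax + n]; eyi_[oy + nmax - n] = -eyi_[oy + nmax + n];
        ezr_[oy + nmax - n] = ezr_[oy + nmax + n]; ezi_[oy + nmax - n] = -ezi_[oy + nmax + n];
      }
    }
    int last_nx = -1, last_ny = nmax + 1;
    for (size_t kk = 0; kk < kx.size(); kk++) {
      int nx = kx[kk], ny = ky[kk], nz = kz[kk];
      if (nx != last_nx) {     // cache q_i * e^{i kx x_i}
        for (int i = 0; i < N; i++) {
          size_t ox = (size_t)i * (nmax + 1);
          qexr_[i] = q[i] * exr_[ox + nx];
          qexi_[i] = q[i] * exi_[ox + nx];
        }
        last_nx = nx; last_ny = nmax + 1;
      }
      if (ny != last_ny) {     // cache q_i * e^{i(kx x + ky y)}
        for (int i = 0; i < N; i++) {
          size_t oy = (size_t)i * W + nmax + ny;
          qxyr_[i] = qexr_[i] * eyr_[oy] - qexi_[i] * eyi_[oy];
          qxyi_[i] = qexr_[i] * eyi_[oy] + qexi_[i] * eyr_[oy];
        }
        last_ny = ny;
      }
      double Sr = 0.0, Si = 0.0;
      for (int i = 0; i < N; i++) {
        size_t oz = (size_t)i * W + nmax + nz;
        double cre = qxyr_[i] * ezr_[oz] - qxyi_[i] * ezi_[oz];
        double cim = qxyr_[i] * ezi_[oz] + qxyi_[i] * ezr_[oz];
        cr_[i] = cre; ci_[i] = cim;
        Sr += cre; Si += cim;
      }
      double A = Ak[kk];
      E.coul += A * (Sr * Sr + Si * Si);
      double gx = twopi * nx / L, gy = twopi * ny / L, gz = twopi * nz / L;
      for (int i = 0; i < N; i++) {
        // Im(conj(S) * q_i e^{ik r_i}) = Sr*ci - Si*cr
        double im = 2.0 * A * (Sr * ci_[i] - Si * cr_[i]);
        f[3 * i] += im * gx;
        f[3 * i + 1] += im * gy;
        f[3 * i + 2] += im * gz;
      }
    }
    // self energy
    double q2 = 0.0;
    for (int i = 0; i < N; i++) q2 += q[i] * q[i];
    E.coul -= lb * alpha / std::sqrt(M_PI) * q2;
  }
};

// All-pairs neighbour list (i < j), within rlist.
static void build_pairs(const std::vector<double>& x, int N, double L,
                        double rlist, std::vector<int>& pi_, std::vector<int>& pj_) {
  pi_.clear(); pj_.clear();
  double rl2 = rlist * rlist;
  for (int i = 0; i < N - 1; i++) {
    for (int j = i + 1; j < N; j++) {
      double dx = min_image(x[3 * i] - x[3 * j], L);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], L);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], L);
      if (dx * dx + dy * dy + dz * dz < rl2) { pi_.push_back(i); pj_.push_back(j); }
    }
  }
}

static ForceField make_ff(NumericMatrix pos, NumericVector charge,
                          IntegerMatrix bonds, double L, double lb, double rc,
                          double alpha, int nmax, double kbond, double r0,
                          bool shifted) {
  int N = pos.nrow();
  std::vector<double> q(charge.begin(), charge.end());
  std::vector<int> b1, b2;
  for (int b = 0; b < bonds.nrow(); b++) {
    b1.push_back(bonds(b, 0)); b2.push_back(bonds(b, 1));
  }
  return ForceField(N, L, lb, rc, alpha, nmax, kbond, r0, shifted, q, b1, b2);
}

static std::vector<double> flatten(NumericMatrix pos) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; i++) {
    x[3 * i] = pos(i, 0); x[3 * i + 1] = pos(i, 1); x[3 * i + 2] = pos(i, 2);
  }
  return x;
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix pos, NumericVector charge,
                       IntegerMatrix bonds, double L, double lb, double rc,
                       double alpha, int nmax, double kbond, double r0,
                       bool shifted) {
  ForceField ff = make_ff(pos, charge, bonds, L, lb, rc, alpha, nmax,
                          kbond, r0, shifted);
  std::vector<double> x = flatten(pos);
  std::vector<double> f(3 * ff.N, 0.0);
  std::vector<int> pi_, pj_;
  build_pairs(x, ff.N, L, rc, pi_, pj_);
  EnergyTerms E = {0.0, 0.0, 0.0};
  ff.pair_terms(x, pi_, pj_, f, E);
  ff.bond_terms(x, f, E, NULL);
  ff.recip_terms(x, f, E);
  NumericMatrix forces(ff.N, 3);
  for (int i = 0; i < ff.N; i++) {
    forces(i, 0) = f[3 * i]; forces(i, 1) = f[3 * i + 1]; forces(i, 2) = f[3 * i + 2];
  }
  return List::create(_["energy"] = E.total(), _["wca"] = E.wca,
                      _["bond"] = E.bond, _["coulomb"] = E.coul,
                      _["forces"] = forces);
}

// Leapfrog integration with optional stochastic velocity-rescaling
// thermostat (Bussi et al.) and optional force capping (soft-core
// relaxation).  Uses the R RNG, so set.seed() upstream gives bitwise
// reproducibility.
// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector charge,
                IntegerMatrix bonds, double L, double lb, double rc,
                double alpha, int nmax, double kbond, double r0, bool shifted,
                double dt, int nsteps, int stride, double kT_target,
                double tau_t, double fmax, double skin, int step0) {
  RNGScope scope;
  ForceField ff = make_ff(pos, charge, bonds, L, lb, rc, alpha, nmax,
                          kbond, r0, shifted);
  ff.build_rtable();
  int N = ff.N;
  std::vector<double> x = flatten(pos);
  std::vector<double> u = x;                       // unwrapped
  std::vector<double> v(3 * N);
  for (int i = 0; i < N; i++) {
    v[3 * i] = vel(i, 0); v[3 * i + 1] = vel(i, 1); v[3 * i + 2] = vel(i, 2);
  }
  std::vector<double> f(3 * N, 0.0);
  std::vector<int> pi_, pj_;
  std::vector<double> xref(3 * N);
  double rlist = rc + skin;
  bool thermostat = (tau_t > 0.0);
  int ndf = 3 * N - 3;
  int nframes = nsteps / stride;
  NumericVector traj(Dimension(N, 3, nframes));
  NumericVector traj_u(Dimension(N, 3, nframes));
  NumericVector pe_s(nframes), ke_s(nframes);
  IntegerVector steps_s(nframes);
  double max_bond_dev = 0.0;
  double c1 = thermostat ? std::exp(-dt / tau_t) : 1.0;
  double Kbar = 0.5 * ndf * kT_target;

  build_pairs(x, N, L, rlist, pi_, pj_);
  xref = x;
  int frame = 0;

  for (int s = 0; s < nsteps; s++) {
    // neighbour-list rebuild check (displacement since last build)
    double maxd2 = 0.0;
    for (int i = 0; i < N; i++) {
      double dx = min_image(x[3 * i] - xref[3 * i], L);
      double dy = min_image(x[3 * i + 1] - xref[3 * i + 1], L);
      double dz = min_image(x[3 * i + 2] - xref[3 * i + 2], L);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (4.0 * maxd2 > skin * skin) {   // max displacement > skin/2
      build_pairs(x, N, L, rlist, pi_, pj_);
      xref = x;
    }
    std::fill(f.begin(), f.end(), 0.0);
    EnergyTerms E = {0.0, 0.0, 0.0};
    ff.pair_terms(x, pi_, pj_, f, E);
    ff.bond_terms(x, f, E, &max_bond_dev);
    ff.recip_terms(x, f, E);
    if (fmax > 0.0) {
      for (int i = 0; i < N; i++) {
        double fn = std::sqrt(f[3 * i] * f[3 * i] + f[3 * i + 1] * f[3 * i + 1] +
                              f[3 * i + 2] * f[3 * i + 2]);
        if (fn > fmax) {
          double sc = fmax / fn;
          f[3 * i] *= sc; f[3 * i + 1] *= sc; f[3 * i + 2] *= sc;
        }
      }
    }
    // leapfrog velocity update (mass = 1)
    for (int i = 0; i < 3 * N; i++) v[i] += f[i] * dt;
    double K = 0.0;
    for (int i = 0; i < 3 * N; i++) K += 0.5 * v[i] * v[i];
    if (!std::isfinite(K) || K > 1e12 * (N + 1))
      stop("integration blew up (non-finite kinetic energy) at step %d", s + step0);
    if (thermostat && K > 0.0) {
      double R1 = norm_rand();
      double chi2 = (ndf > 1) ? R::rgamma((ndf - 1) / 2.0, 2.0) : 0.0;
      double a2 = c1 + (Kbar / (ndf * K)) * (1.0 - c1) * (R1 * R1 + chi2)
                + 2.0 * R1 * std::sqrt(c1 * (1.0 - c1) * Kbar / (ndf * K));
      double sc = std::sqrt(a2 > 0.0 ? a2 : 0.0);
      for (int i = 0; i < 3 * N; i++) v[i] *= sc;
      K *= a2 > 0.0 ? a2 : 0.0;
    }
    // position update; wrap into [0, L); accumulate unwrapped displacement
    for (int i = 0; i < 3 * N; i++) {
      double dxi = v[i] * dt;
      u[i] += dxi;
      x[i] += dxi;
      x[i] -= L * std::floor(x[i] / L);
    }
    if ((s + 1) % stride == 0 && frame < nframes) {
      for (int i = 0; i < N; i++) {
        traj[i + (size_t)N * 0 + (size_t)3 * N * frame] = x[3 * i];
        traj[i + (size_t)N * 1 + (size_t)3 * N * frame] = x[3 * i + 1];
        traj[i + (size_t)N * 2 + (size_t)3 * N * frame] = x[3 * i + 2];
        traj_u[i + (size_t)N * 0 + (size_t)3 * N * frame] = u[3 * i];
        traj_u[i + (size_t)N * 1 + (size_t)3 * N * frame] = u[3 * i + 1];
        traj_u[i + (size_t)N * 2 + (size_t)3 * N * frame] = u[3 * i + 2];
      }
      pe_s[frame] = E.total();
      ke_s[frame] = K;
      steps_s[frame] = step0 + s + 1;
      frame++;
    }
  }
  NumericMatrix fpos(N, 3), fvel(N, 3);
  for (int i = 0; i < N; i++) {
    fpos(i, 0) = x[3 * i]; fpos(i, 1) = x[3 * i + 1]; fpos(i, 2) = x[3 * i + 2];
    fvel(i, 0) = v[3 * i]; fvel(i, 1) = v[3 * i + 1]; fvel(i, 2) = v[3 * i + 2];
  }
  return List::create(_["positions"] = traj, _["unwrapped"] = traj_u,
                      _["pe"] = pe_s, _["ke"] = ke_s, _["steps"] = steps_s,
                      _["final_pos"] = fpos, _["final_vel"] = fvel,
                      _["max_bond_dev"] = max_bond_dev);
}

// Steepest-descent energy minimisation with adaptive step; never accepts
// an uphill move.
// [[Rcpp::export]]
List minimize_cpp(NumericMatrix pos, NumericVector charge, IntegerMatrix bonds,
                  double L, double lb, double rc, double alpha, int nmax,
                  double kbond, double r0, bool shifted, int max_iter,
                  double ftol) {
  ForceField ff = make_ff(pos, charge, bonds, L, lb, rc, alpha, nmax,
                          kbond, r0, shifted);
  int N = ff.N;
  std::vector<double> x = flatten(pos);
  std::vector<double> f(3 * N, 0.0), xtry(3 * N);
  std::vector<int> pi_, pj_;
  double h = 0.01;
  build_pairs(x, N, L, rc, pi_, pj_);
  std::fill(f.begin(), f.end(), 0.0);
  EnergyTerms E = {0.0, 0.0, 0.0};
  ff.pair_terms(x, pi_, pj_, f, E);
  ff.bond_terms(x, f, E, NULL);
  ff.recip_terms(x, f, E);
  double e = E.total();
  int it;
  for (it = 0; it < max_iter; it++) {
    double fmaxn = 0.0;
    for (int i = 0; i < N; i++) {
      double fn2 = f[3 * i] * f[3 * i] + f[3 * i + 1] * f[3 * i + 1] +
                   f[3 * i + 2] * f[3 * i + 2];
      if (fn2 > fmaxn) fmaxn = fn2;
    }
    fmaxn = std::sqrt(fmaxn);
    if (fmaxn < ftol) break;
    double step = h / std::max(fmaxn, 1.0);
    for (int i = 0; i < 3 * N; i++) {
      xtry[i] = x[i] + step * f[i];
      xtry[i] -= L * std::floor(xtry[i] / L);
    }
    std::vector<double> ftry(3 * N, 0.0);
    build_pairs(xtry, N, L, rc, pi_, pj_);
    EnergyTerms Et = {0.0, 0.0, 0.0};
    ff.pair_terms(xtry, pi_, pj_, ftry, Et);
    ff.bond_terms(xtry, ftry, Et, NULL);
    ff.recip_terms(xtry, ftry, Et);
    if (Et.total() <= e) {
      x = xtry; f = ftry; e = Et.total();
      h = std::min(h * 1.2, 0.1);
    } else {
      h *= 0.5;
      if (h < 1e-10) break;
    }
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; i++) {
    out(i, 0) = x[3 * i]; out(i, 1) = x[3 * i + 1]; out(i, 2) = x[3 * i + 2];
  }
  return List::create(_["positions"] = out, _["energy"] = e,
                      _["iterations"] = it);
}

// Minimum-image minimum distance between every pair of chains; chains given
// by a 0-based group index per row of pos.  Returns a dense matrix.
// [[Rcpp::export]]
NumericMatrix group_min_dist_cpp(NumericMatrix pos, IntegerVector group,
                                 int ngroup, double L) {
  int N = pos.nrow();
  NumericMatrix out(ngroup, ngroup);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int g = 0; g < ngroup; g++) out(g, g) = 0.0;
  for (int i = 0; i < N - 1; i++) {
    for (int j = i + 1; j < N; j++) {
      int gi = group[i], gj = group[j];
      if (gi == gj) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), L);
      double dy = min_image(pos(i, 1) - pos(j, 1), L);
      double dz = min_image(pos(i, 2) - pos(j, 2), L);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < out(gi, gj)) { out(gi, gj) = d; out(gj, gi) = d; }
    }
  }
  return out;
}

// Per-row-of-A minimum-image minimum distance to any row of B.
// [[Rcpp::export]]
NumericVector min_dist_to_set_cpp(NumericMatrix A, NumericMatrix B, double L) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    for (int j = 0; j < m; j++) {
      double dx = min_image(A(i, 0) - B(j, 0), L);
      double dy = min_image(A(i, 1) - B(j, 1), L);
      double dz = min_image(A(i, 2) - B(j, 2), L);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each row of A: 1-based index of the nearest row of B (minimum image)
// and the distance.
// [[Rcpp::export]]
List nearest_in_set_cpp(NumericMatrix A, NumericMatrix B, double L) {
  int n = A.nrow(), m = B.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < m; j++) {
      double dx = min_image(A(i, 0) - B(j, 0), L);
      double dy = min_image(A(i, 1) - B(j, 1), L);
      double dz = min_image(A(i, 2) - B(j, 2), L);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Kirkwood sum: sum over ordered distinct pairs of 1/r_ij (minimum image).
// [[Rcpp::export]]
double inv_dist_sum_cpp(NumericMatrix pos, double L) {
  int N = pos.nrow();
  double s = 0.0;
  for (int i = 0; i < N - 1; i++) {
    for (int j = i + 1; j < N; j++) {
      double dx = min_image(pos(i, 0) - pos(j, 0), L);
      double dy = min_image(pos(i, 1) - pos(j, 1), L);
      double dz = min_image(pos(i, 2) - pos(j, 2), L);
      s += 1.0 / std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return 2.0 * s;
}

// Direct real-space lattice sum of the Coulomb energy over periodic images
// within nshell images per axis: slow reference oracle for tiny boxes.
// [[Rcpp::export]]
double direct_coulomb_sum_cpp(NumericMatrix pos, NumericVector charge,
                              double L, double lb, int nshell) {
  int N = pos.nrow();
  double e = 0.0;
  for (int nx = -nshell; nx <= nshell; nx++)
    for (int ny = -nshell; ny <= nshell; ny++)
      for (int nz = -nshell; nz <= nshell; nz++) {
        bool home = (nx == 0 && ny == 0 && nz == 0);
        for (int i = 0; i < N; i++)
          for (int j = 0; j < N; j++) {
            if (home && i == j) continue;
            double qq = charge[i] * charge[j];
            if (qq == 0.0) continue;
            double dx = pos(i, 0) - pos(j, 0) + nx * L;
            double dy = pos(i, 1) - pos(j, 1) + ny * L;
            double dz = pos(i, 2) - pos(j, 2) + nz * L;
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            e += 0.5 * lb * qq / r;
          }
      }
  return e;
}
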