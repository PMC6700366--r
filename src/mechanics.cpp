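#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-sphere discrete-element mechanics.
//
// Contact: Kelvin-Voigt normal spring-dashpot (k_n, gamma_n), tangential
// dashpot (gamma_t) capped by the Coulomb criterion |Ft| <= mu_f |Fn|.
// Adhesion: attractive spring scaled by the product of the two agent
// masses (relative to m_ref^2), ramping linearly to zero at `cutoff`.
// Drag: Stokes, 6 pi mu r (u_fluid - v), one-way coupling.
//
// Internally SI (m, kg, s, N); the R interface carries um positions.

struct MechP {
  double k_n, gamma_n, gamma_t, mu_f, k_adh, m_ref, cutoff, visc;
  double ux, uy, uz;     // uniform fluid velocity
  double Lx, Ly;         // periodic box (m); <=0 disables wrapping
};

static inline double wrapd(double d, double L) {
  if (L > 0) d -= L * std::round(d / L);
  return d;
}

// pairwise contact+adhesion forces accumulated into fc / fa (3 x n, column
// per agent); returns max overlap (m). Deterministic order; coincident
// centers get a fixed axis direction and are counted in *ncoinc.
static double pair_forces(const std::vector<double>& px, const std::vector<double>& py,
                          const std::vector<double>& pz, const std::vector<double>& r,
                          const std::vector<double>& vx, const std::vector<double>& vy,
                          const std::vector<double>& vz, const std::vector<double>& m,
                          const MechP& P, double* fc, double* fa, int* ncoinc) {
  const int n = (int)px.size();
  double maxov = 0.0;
  // uniform binning; bin size >= max diameter + cutoff
  double maxd = 0.0;
  for (int i = 0; i < n; ++i) maxd = std::max(maxd, 2.0 * r[i]);
  double bs = maxd + P.cutoff;
  if (bs <= 0) bs = 1e-6;
  double xmin = 0, ymin = 0, zmin = 1e300, zmax = -1e300;
  for (int i = 0; i < n; ++i) { zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]); }
  int nbx = P.Lx > 0 ? std::max(1, (int)std::floor(P.Lx / bs)) : 1;
  int nby = P.Ly > 0 ? std::max(1, (int)std::floor(P.Ly / bs)) : 1;
  int nbz = std::max(1, (int)std::floor((zmax - zmin) / bs) + 1);
  bool binned = (n > 64) && (nbx > 2 || nby > 2 || nbz > 2);

  std::vector<std::vector<int>> bins;
  std::vector<int> binof(n);
  if (binned) {
    bins.assign((size_t)nbx * nby * nbz, {});
    for (int i = 0; i < n; ++i) {
      int bx = P.Lx > 0 ? (int)std::floor(px[i] / P.Lx * nbx) : 0;
      int by = P.Ly > 0 ? (int)std::floor(py[i] / P.Ly * nby) : 0;
      bx = ((bx % nbx) + nbx) % nbx; by = ((by % nby) + nby) % nby;
      int bz = std::min(nbz - 1, std::max(0, (int)std::floor((pz[i] - zmin) / bs)));
      int b = bx + nbx * (by + nby * bz);
      binof[i] = b;
      bins[b].push_back(i);
    }
  }

  auto do_pair = [&](int i, int j) {
    double dx = wrapd(px[i] - px[j], P.Lx);
    double dy = wrapd(py[i] - py[j], P.Ly);
    double dz = pz[i] - pz[j];
    double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
    double sumr = r[i] + r[j];
    if (dist >= sumr + P.cutoff) return;
    double nxv, nyv, nzv;
    if (dist < 1e-15) {               // coincident centers: fixed fallback axis
      nxv = ((i + j) % 2 == 0) ? 1.0 : 0.0;
      nyv = 1.0 - nxv; nzv = 0.0;
      dist = 1e-15;
      ++(*ncoinc);
    } else {
      nxv = dx / dist; nyv = dy / dist; nzv = dz / dist;
    }
    double ov = sumr - dist;          // >0: overlap
    double fx = 0, fy = 0, fz = 0;    // force on i (j gets the negative)
    if (ov > 0) {
      if (ov > maxov) maxov = ov;
      double rvx = vx[i] - vx[j], rvy = vy[i] - vy[j], rvz = vz[i] - vz[j];
      double vn = rvx * nxv + rvy * nyv + rvz * nzv;
      double Fn = P.k_n * ov - P.gamma_n * vn;
      double tx = rvx - vn * nxv, ty = rvy - vn * nyv, tz = rvz - vn * nzv;
      double Ftx = -P.gamma_t * tx, Fty = -P.gamma_t * ty, Ftz = -P.gamma_t * tz;
      double Ftm = std::sqrt(Ftx * Ftx + Fty * Fty + Ftz * Ftz);
      double cap = P.mu_f * std::fabs(Fn);
      if (Ftm > cap && Ftm > 0) {
        double sc = cap / Ftm;
        Ftx *= sc; Fty *= sc; Ftz *= sc;
      }
      fx = Fn * nxv + Ftx; fy = Fn * nyv + Fty; fz = Fn * nzv + Ftz;
      fc[3 * i] += fx; fc[3 * i + 1] += fy; fc[3 * i + 2] += fz;
      fc[3 * j] -= fx; fc[3 * j + 1] -= fy; fc[3 * j + 2] -= fz;
    }
    double gap = -ov;                 // separation beyond touching
    if (gap < P.cutoff) {
      double ramp = 1.0 - gap / P.cutoff;
      if (ramp > 1.0) ramp = 1.0;    // full strength once in contact
      double Fad = P.k_adh * (m[i] * m[j]) / (P.m_ref * P.m_ref) * ramp;
      double ax = -Fad * nxv, ay = -Fad * nyv, az = -Fad * nzv;
      fa[3 * i] += ax; fa[3 * i + 1] += ay; fa[3 * i + 2] += az;
      fa[3 * j] -= ax; fa[3 * j + 1] -= ay; fa[3 * j + 2] -= az;
    }
  };

  if (!binned) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) do_pair(i, j);
  } else {
    for (int b = 0; b < (int)bins.size(); ++b) {
      int bx = b % nbx, by = (b / nbx) % nby, bz = b / (nbx * nby);
      const std::vector<int>& cell = bins[b];
      for (int ddz = -1; ddz <= 1; ++ddz) {
        int cz = bz + ddz;
        if (cz < 0 || cz >= nbz) continue;
        for (int ddy = -1; ddy <= 1; ++ddy) {
          int cy = ((by + ddy) % nby + nby) % nby;
          for (int ddx = -1; ddx <= 1; ++ddx) {
            int cx = ((bx + ddx) % nbx + nbx) % nbx;
            int nb = cx + nbx * (cy + nby * cz);
            if (nb < b) continue;            // visit each bin pair once
            const std::vector<int>& other = bins[nb];
            if (nb == b) {
              for (size_t a = 0; a < cell.size(); ++a)
                for (size_t c = a + 1; c < cell.size(); ++c)
                  do_pair(cell[a], cell[c]);
            } else {
              for (int i : cell) for (int j : other) do_pair(i, j);
            }
          }
        }
      }
    }
  }
  return maxov;
}

static MechP read_params(const List& params, double Lx_um, double Ly_um) {
  MechP P;
  P.k_n = as<double>(params["k_n"]);
  P.gamma_n = as<double>(params["gamma_n"]);
  P.gamma_t = as<double>(params["gamma_t"]);
  P.mu_f = as<double>(params["mu_f"]);
  P.k_adh = as<double>(params["k_adh"]);
  P.m_ref = as<double>(params["m_ref"]);
  P.cutoff = as<double>(params["cutoff_um"]) * 1e-6;
  P.visc = as<double>(params["viscosity"]);
  NumericVector u = params["flow"];
  P.ux = u[0]; P.uy = u[1]; P.uz = u[2];
  P.Lx = Lx_um > 0 ? Lx_um * 1e-6 : -1;
  P.Ly = Ly_um > 0 ? Ly_um * 1e-6 : -1;
  return P;
}

// Force breakdown for the current state: contact, adhesion and drag, N.
// Positions/radii um, velocities um/s, masses kg.
// [[Rcpp::export]]
List cpp_mech_forces(NumericVector x, NumericVector y, NumericVector z,
                     NumericVector radius, NumericVector vx, NumericVector vy,
                     NumericVector vz, NumericVector mass, List params,
                     double Lx_um, double Ly_um) {
  int n = x.size();
  MechP P = read_params(params, Lx_um, Ly_um);
  std::vector<double> px(n), py(n), pz(n), r(n), ux(n), uy(n), uz(n), m(n);
  for (int i = 0; i < n; ++i) {
    px[i] = x[i] * 1e-6; py[i] = y[i] * 1e-6; pz[i] = z[i] * 1e-6;
    r[i] = radius[i] * 1e-6;
    ux[i] = vx[i] * 1e-6; uy[i] = vy[i] * 1e-6; uz[i] = vz[i] * 1e-6;
    m[i] = mass[i];
  }
  NumericMatrix Fc(3, n), Fa(3, n), Ff(3, n);
  std::fill(Fc.begin(), Fc.end(), 0.0);
  std::fill(Fa.begin(), Fa.end(), 0.0);
  int ncoinc = 0;
  double maxov = pair_forces(px, py, pz, r, ux, uy, uz, m, P,
                             REAL(Fc), REAL(Fa), &ncoinc);
  for (int i = 0; i < n; ++i) {
    double g = 6.0 * M_PI * P.visc * r[i];
    Ff(0, i) = g * (P.ux - ux[i]);
    Ff(1, i) = g * (P.uy - uy[i]);
    Ff(2, i) = g * (P.uz - uz[i]);
  }
  return List::create(_["contact"] = Fc, _["adhesion"] = Fa, _["drag"] = Ff,
                      _["max_overlap_m"] = maxov, _["n_coincident"] = ncoinc);
}

// Damped relaxation of m dv/dt = Fc + Fa + Ff by semi-implicit Euler (the
// Stokes drag term is treated implicitly, so the strongly overdamped limit
// is unconditionally stable). Substratum is a rigid plane at z = radius;
// x/y wrap periodically. Terminates when max overlap <= tol_overlap_frac
// of the mean diameter AND max speed <= tol_speed_m_s, or at max_steps.
// [[Rcpp::export]]
List cpp_relax(NumericVector x, NumericVector y, NumericVector z,
               NumericVector radius, NumericVector mass, List params,
               double Lx_um, double Ly_um, double dt_s, int max_steps,
               double tol_overlap_frac, double tol_speed_m_s) {
  int n = x.size();
  MechP P = read_params(params, Lx_um, Ly_um);
  std::vector<double> px(n), py(n), pz(n), r(n), m(n);
  std::vector<double> vx(n, 0.0), vy(n, 0.0), vz(n, 0.0);
  double meand = 0.0;
  for (int i = 0; i < n; ++i) {
    px[i] = x[i] * 1e-6; py[i] = y[i] * 1e-6; pz[i] = z[i] * 1e-6;
    r[i] = radius[i] * 1e-6; m[i] = mass[i];
    meand += 2.0 * r[i];
  }
  meand = n > 0 ? meand / n : 1.0;

  std::vector<double> fc(3 * n), fa(3 * n);
  NumericVector ke_trace(std::min(max_steps, 1000));
  int steps = 0, ncoinc = 0;
  double maxov = 0.0, maxsp = 0.0;
  bool conv = false;

  for (int it = 0; it < max_steps; ++it) {
    std::fill(fc.begin(), fc.end(), 0.0);
    std::fill(fa.begin(), fa.end(), 0.0);
    maxov = pair_forces(px, py, pz, r, vx, vy, vz, m, P, fc.data(), fa.data(), &ncoinc);
    double ke = 0.0;
    maxsp = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = 6.0 * M_PI * P.visc * r[i];
      double ax = (fc[3 * i] + fa[3 * i]) / m[i] + g / m[i] * P.ux;
      double ay = (fc[3 * i + 1] + fa[3 * i + 1]) / m[i] + g / m[i] * P.uy;
      double az = (fc[3 * i + 2] + fa[3 * i + 2]) / m[i] + g / m[i] * P.uz;
      double den = 1.0 + g * dt_s / m[i];
      vx[i] = (vx[i] + ax * dt_s) / den;
      vy[i] = (vy[i] + ay * dt_s) / den;
      vz[i] = (vz[i] + az * dt_s) / den;
      px[i] += vx[i] * dt_s;
      py[i] += vy[i] * dt_s;
      pz[i] += vz[i] * dt_s;
      if (P.Lx > 0) px[i] -= P.Lx * std::floor(px[i] / P.Lx);
      if (P.Ly > 0) py[i] -= P.Ly * std::floor(py[i] / P.Ly);
      if (pz[i] < r[i]) { pz[i] = r[i]; if (vz[i] < 0) vz[i] = 0; }
      double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      if (sp > maxsp) maxsp = sp;
      ke += 0.5 * m[i] * sp * sp;
    }
    if (it < ke_trace.size()) ke_trace[it] = ke;
    steps = it + 1;
    bool ok_ov = maxov <= tol_overlap_frac * meand;
    bool still_ = maxsp <= tol_speed_m_s;
    if (ok_ov && still_) { conv = true; break; }
    // quasi-static stall: motion has died down in a packing held together
    // by adhesion; the residual overlap is its mechanical equilibrium
    if (still_ && it >= 100) { conv = ok_ov; break; }
  }
  NumericVector ox(n), oy(n), oz(n);
  for (int i = 0; i < n; ++i) {
    ox[i] = px[i] * 1e6; oy[i] = py[i] * 1e6; oz[i] = pz[i] * 1e6;
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["z"] = oz,
                      _["steps"] = steps, _["converged"] = conv,
                      _["max_overlap_frac"] = maxov / meand,
                      _["max_speed_m_s"] = maxsp,
                      _["ke_trace"] = ke_trace[Rcpp::Range(0, std::max(0, std::min(steps, (int)ke_trace.size()) - 1))],
                      _["n_coincident"] = ncoinc);
}
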