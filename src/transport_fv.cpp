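// Conservative finite-volume solver for axisymmetric advection-diffusion of a
// passive tracer in an annular perivascular space whose inner radius follows
// the measured cross-section area law.
//
// Geometry: annulus R_v(t) < r < R_ast, 0 < y < L, axisymmetric.  The radial
// coordinate is mapped to a fixed grid eta in [0,1] via
// r = R_v(t) + eta * (R_ast - R_v(t)); cell faces move with the mapping and
// the radial fluxes use mesh-relative face velocities, so tracer mass
// (integral of c over the deforming annulus) is conserved to machine
// precision with no-flux boundaries.
//
// Velocity field (quasi-steady Stokes, lubrication reduction):
//   axial:  u(y, r, t) = ubar(y, t) * phi(r, t)
//           ubar(y, t) = dA/dt * (L - y) / A(t)   (cross-section mean)
//           phi = annular Poiseuille shape, normalised so that the *discrete*
//           area-weighted mean over the radial cells is exactly 1
//   radial: from incompressibility, r v(r) = R_v dR_v/dt + (dA/dt / A) S(r),
//           S(r) = cumulative area integral of phi; exactly divergence-free
//           and matching the wall velocities at both walls.
//
// Time stepping: Strang splitting per step dt --
//   (1) radial diffusion + mesh-relative radial advection, Crank-Nicolson
//       over dt/2 (tridiagonal solve per axial cell; unconditionally stable,
//       so tight gaps do not throttle the step),
//   (2) axial advection-diffusion, explicit Heun (RK2) on the conserved cell
//       masses over dt (CFL-limited by the R wrapper, dt <= 5e-3 s),
//   (3) radial half-step again at the end-of-step geometry.
// Units: um, s.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct AreaLaw {
  double A_med, a_rel, period, A_smc;
  bool oscillating;
  double A(double t) const {
    if (!oscillating) return A_med - A_smc;
    return A_med * (1.0 + 0.5 * a_rel * std::cos(2.0 * M_PI * t / period)) - A_smc;
  }
  double dAdt(double t) const {
    if (!oscillating) return 0.0;
    return -A_med * 0.5 * a_rel * (2.0 * M_PI / period) * std::sin(2.0 * M_PI * t / period);
  }
};

struct Geom {
  std::vector<double> rf;     // faces, nr+1
  std::vector<double> aj;     // face-annulus areas per radian, nr
  std::vector<double> phi;    // normalised axial profile at cell centres, nr
  std::vector<double> wf;     // mesh-relative radial face velocity, nr+1
  std::vector<double> drc;    // centre-to-centre radial spacing, nr-1
  double Atot;                // (R_ast^2 - R_v^2)/2  (area per radian)
  double g;                   // dA/dt
  double Aarea;               // free cross-section area
};

void computeGeom(Geom& G, const AreaLaw& law, double t, double R_ast,
                 int nr, bool steady) {
  double Aar = steady ? law.A(0.0) : law.A(t);
  double g = steady ? 0.0 : law.dAdt(t);
  if (Aar <= 0.0) stop("annulus collapsed: A_pvs <= 0");
  double Rv2 = R_ast * R_ast - Aar / M_PI;
  if (Rv2 <= 0.0) stop("annulus collapsed: A_pvs exceeds pi*R_ast^2");
  double Rv = std::sqrt(Rv2);
  double dRv = steady ? 0.0 : (-g / (2.0 * M_PI * Rv));
  double h = R_ast - Rv;
  G.rf.resize(nr + 1); G.aj.resize(nr); G.phi.resize(nr);
  G.wf.resize(nr + 1); G.drc.resize(nr > 1 ? nr - 1 : 0);
  for (int j = 0; j <= nr; ++j) G.rf[j] = Rv + h * (double)j / nr;
  G.Atot = 0.5 * (R_ast * R_ast - Rv * Rv);
  G.g = g;
  G.Aarea = Aar;
  double lnb = std::log(R_ast / Rv);
  double dR2 = R_ast * R_ast - Rv * Rv;
  std::vector<double> rc(nr);
  for (int j = 0; j < nr; ++j) {
    G.aj[j] = 0.5 * (G.rf[j + 1] * G.rf[j + 1] - G.rf[j] * G.rf[j]);
    rc[j] = 0.5 * (G.rf[j] + G.rf[j + 1]);
    double r = rc[j];
    G.phi[j] = R_ast * R_ast - r * r - dR2 * std::log(R_ast / r) / lnb;
  }
  for (int j = 0; j + 1 < nr; ++j) G.drc[j] = rc[j + 1] - rc[j];
  double m = 0.0;
  for (int j = 0; j < nr; ++j) m += G.aj[j] * G.phi[j];
  m /= G.Atot;
  for (int j = 0; j < nr; ++j) G.phi[j] /= m;
  // radial face velocities relative to the moving mesh:
  // r v(r) = Rv*dRv + (g/A) S(r); mesh face velocity rdot = dRv*(1 - eta)
  double Sf = 0.0;
  for (int j = 0; j <= nr; ++j) {
    double rv = (j == 0) ? Rv * dRv : Rv * dRv + (g / Aar) * Sf;
    double v = rv / G.rf[j];
    double rdot = dRv * (1.0 - (double)j / nr);
    G.wf[j] = v - rdot;
    if (j < nr) Sf += G.aj[j] * G.phi[j];
  }
  G.wf[0] = 0.0; G.wf[nr] = 0.0;  // exact wall conditions
}

// axial-only dM/dt for every cell (M = V*c per radian)
// bc: 0 = closed, 1 = entrance Dirichlet c = 1, 2 = open axial ends
void axialRhs(std::vector<double>& R, const std::vector<double>& c,
              const Geom& G, int ny, int nr, double dy, double L, double D,
              int bc, double steady_U, bool steady) {
  std::fill(R.begin(), R.end(), 0.0);
  for (int f = 0; f <= ny; ++f) {
    double yf = f * dy;
    double ubar = steady ? steady_U : G.g * (L - yf) / G.Aarea;
    if (f > 0 && f < ny) {
      int iL = f - 1, iR = f;
      for (int j = 0; j < nr; ++j) {
        double u = ubar * G.phi[j];
        double cf = 0.5 * (c[iL * nr + j] + c[iR * nr + j]);
        double flux = G.aj[j] * (u * cf - D * (c[iR * nr + j] - c[iL * nr + j]) / dy);
        R[iL * nr + j] -= flux;
        R[iR * nr + j] += flux;
      }
    } else if (f == 0) {
      if (bc == 1) {
        for (int j = 0; j < nr; ++j) {
          double u = ubar * G.phi[j];
          double flux = G.aj[j] * (u * 1.0 - D * (c[j] - 1.0) / (0.5 * dy));
          R[j] += flux;
        }
      } else if (bc == 2) {
        for (int j = 0; j < nr; ++j)
          R[j] += G.aj[j] * ubar * G.phi[j] * c[j];
      }
    } else {  // f == ny (deep end); closed unless bc == 2
      if (bc == 2) {
        int iL = ny - 1;
        for (int j = 0; j < nr; ++j)
          R[iL * nr + j] -= G.aj[j] * ubar * G.phi[j] * c[iL * nr + j];
      }
    }
  }
}

// Crank-Nicolson radial half-step of duration dt2 at frozen geometry G:
// V c+ - (dt2/2) Lr(c+) = V c + (dt2/2) Lr(c), tridiagonal per axial cell.
void radialHalfStep(std::vector<double>& c, const Geom& G, int ny, int nr,
                    double dy, double D, double dt2) {
  if (nr < 2) return;
  double th = dt2 / 2.0;
  std::vector<double> alf(nr + 1, 0.0), bet(nr + 1, 0.0);
  for (int jf = 1; jf < nr; ++jf) {
    double ar = G.rf[jf] * dy;
    alf[jf] = ar * D / G.drc[jf - 1];
    bet[jf] = ar * G.wf[jf] * 0.5;
  }
  std::vector<double> sub(nr), dia(nr), sup(nr), rhs(nr), cp(nr), gam(nr);
  for (int i = 0; i < ny; ++i) {
    const double* ci = &c[i * nr];
    for (int j = 0; j < nr; ++j) {
      double V = dy * G.aj[j];
      // F_j = (bet_j + alf_j) c_{j-1} + (bet_j - alf_j) c_j  (face below)
      // L_j = F_j - F_{j+1}
      sub[j] = -th * (bet[j] + alf[j]);
      dia[j] = V - th * ((bet[j] - alf[j]) - (bet[j + 1] + alf[j + 1]));
      sup[j] = th * (bet[j + 1] - alf[j + 1]);
      double Lj = 0.0;
      if (j > 0) Lj += (bet[j] + alf[j]) * ci[j - 1] + (bet[j] - alf[j]) * ci[j];
      if (j < nr - 1) Lj -= (bet[j + 1] + alf[j + 1]) * ci[j] +
                            (bet[j + 1] - alf[j + 1]) * ci[j + 1];
      rhs[j] = V * ci[j] + th * Lj;
    }
    // Thomas algorithm
    double b0 = dia[0];
    cp[0] = rhs[0] / b0;
    for (int j = 1; j < nr; ++j) {
      gam[j] = sup[j - 1] / b0;
      b0 = dia[j] - sub[j] * gam[j];
      cp[j] = (rhs[j] - sub[j] * cp[j - 1]) / b0;
    }
    double* co = &c[i * nr];
    co[nr - 1] = cp[nr - 1];
    for (int j = nr - 2; j >= 0; --j) co[j] = cp[j] - gam[j + 1] * co[j + 1];
  }
}

double frontPosition(const std::vector<double>& cbar, int ny, double dy,
                     double level) {
  int ideep = -1;
  for (int i = ny - 1; i >= 0; --i)
    if (cbar[i] >= level) { ideep = i; break; }
  if (ideep < 0) return NA_REAL;
  double yc = (ideep + 0.5) * dy;
  if (ideep == ny - 1) return yc;
  double c0 = cbar[ideep], c1 = cbar[ideep + 1];
  if (c0 <= c1) return yc;
  return yc + dy * (c0 - level) / (c0 - c1);
}

}  // namespace

// [[Rcpp::export(name = ".transport_fv")]]
List transport_fv(int ny, int nr, double L, double R_ast,
                  double A_med, double a_rel, double period, double A_smc,
                  bool oscillating, bool steady, double steady_U,
                  double D, double dt, double T, int bc,
                  NumericVector cbar0, double front_level,
                  double front_target, double save_dt) {
  if (ny < 2 || nr < 1) stop("grid too small");
  if (cbar0.size() != ny) stop("initial profile length must equal ny");
  double dy = L / ny;
  AreaLaw law{A_med, a_rel, period, A_smc, oscillating};
  int nsteps = (int)std::ceil(T / dt - 1e-12);
  int save_every = std::max(1, (int)std::round(save_dt / dt));

  int N = ny * nr;
  std::vector<double> c(N), c1(N), M(N), M0(N), R1(N), R2(N);
  for (int i = 0; i < ny; ++i)
    for (int j = 0; j < nr; ++j) c[i * nr + j] = cbar0[i];

  Geom Gn, Gp;
  computeGeom(Gn, law, 0.0, R_ast, nr, steady);

  int nsave = nsteps / save_every + 2;
  NumericVector t_save(nsave), mass_save(nsave), mean_save(nsave),
      var_save(nsave), front_save(nsave);
  NumericMatrix cbar_save(ny, nsave);

  std::vector<double> cbar(ny);
  double cmax_all = -1e300, cmin_all = 1e300;
  double t_front = NA_REAL;
  double front_prev = NA_REAL, t_prev = 0.0;
  bool hit = false;
  int isave = 0;

  auto sectionMean = [&](const Geom& G) {
    for (int i = 0; i < ny; ++i) {
      double s = 0.0;
      for (int j = 0; j < nr; ++j) s += G.aj[j] * c[i * nr + j];
      cbar[i] = s / G.Atot;
    }
  };
  auto record = [&](double t, const Geom& G) {
    sectionMean(G);
    double m1 = 0.0, m0 = 0.0;
    for (int i = 0; i < ny; ++i) {
      double yc = (i + 0.5) * dy;
      m0 += cbar[i];
      m1 += cbar[i] * yc;
    }
    double mu = m1 / std::max(m0, 1e-300), v2 = 0.0;
    for (int i = 0; i < ny; ++i) {
      double yc = (i + 0.5) * dy;
      v2 += cbar[i] * (yc - mu) * (yc - mu);
    }
    t_save[isave] = t;
    mass_save[isave] = m0 * dy * 2.0 * M_PI * G.Atot;
    mean_save[isave] = mu;
    var_save[isave] = v2 / std::max(m0, 1e-300);
    front_save[isave] = frontPosition(cbar, ny, dy, front_level);
    for (int i = 0; i < ny; ++i) cbar_save(i, isave) = cbar[i];
    ++isave;
  };
  record(0.0, Gn);
  bool track = !ISNA(front_target) && front_target > 0;
  if (track) front_prev = front_save[0];

  double t = 0.0;
  int step;
  for (step = 1; step <= nsteps; ++step) {
    double tnp = t + dt;
    // (1) radial half-step at start-of-step geometry
    radialHalfStep(c, Gn, ny, nr, dy, D, dt / 2.0);
    // (2) axial Heun step on conserved masses, geometry Gn -> Gp
    for (int i = 0; i < ny; ++i)
      for (int j = 0; j < nr; ++j) M0[i * nr + j] = dy * Gn.aj[j] * c[i * nr + j];
    axialRhs(R1, c, Gn, ny, nr, dy, L, D, bc, steady_U, steady);
    computeGeom(Gp, law, tnp, R_ast, nr, steady);
    for (int i = 0; i < ny; ++i)
      for (int j = 0; j < nr; ++j) {
        int k = i * nr + j;
        c1[k] = (M0[k] + dt * R1[k]) / (dy * Gp.aj[j]);
      }
    axialRhs(R2, c1, Gp, ny, nr, dy, L, D, bc, steady_U, steady);
    for (int i = 0; i < ny; ++i)
      for (int j = 0; j < nr; ++j) {
        int k = i * nr + j;
        M[k] = M0[k] + 0.5 * dt * (R1[k] + R2[k]);
        c[k] = M[k] / (dy * Gp.aj[j]);
      }
    // (3) radial half-step at end-of-step geometry
    radialHalfStep(c, Gp, ny, nr, dy, D, dt / 2.0);
    for (int k = 0; k < N; ++k) {
      if (c[k] > cmax_all) cmax_all = c[k];
      if (c[k] < cmin_all) cmin_all = c[k];
    }
    t = tnp;
    Gn = Gp;

    bool saving = (step % save_every == 0);
    if (saving || track) sectionMean(Gn);
    if (track && !hit) {
      double fr = frontPosition(cbar, ny, dy, front_level);
      if (!ISNA(fr) && fr >= front_target) {
        if (!ISNA(front_prev) && fr > front_prev)
          t_front = t_prev + dt * (front_target - front_prev) / (fr - front_prev);
        else t_front = t;
        hit = true;
      }
      front_prev = fr;
      t_prev = t;
    }
    if (saving) record(t, Gn);
    else if (step == nsteps) record(t, Gn);  // always save the final state
    if (hit && bc == 1) break;  // influx question answered; stop early
  }

  if (isave < nsave) {
    t_save = t_save[Range(0, isave - 1)];
    mass_save = mass_save[Range(0, isave - 1)];
    mean_save = mean_save[Range(0, isave - 1)];
    var_save = var_save[Range(0, isave - 1)];
    front_save = front_save[Range(0, isave - 1)];
    cbar_save = cbar_save(Range(0, ny - 1), Range(0, isave - 1));
  }

  return List::create(
      _["t"] = t_save, _["cbar"] = cbar_save, _["mass"] = mass_save,
      _["mean"] = mean_save, _["variance"] = var_save,
      _["front"] = front_save, _["t_front"] = t_front,
      _["cmax"] = cmax_all, _["cmin"] = cmin_all,
      _["dt"] = dt, _["nsteps"] = std::min(step, nsteps), _["dy"] = dy);
}
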