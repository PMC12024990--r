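// BGK lattice Boltzmann kernels in lattice units (dx = dt = 1).
//
// Flow: D3Q19, cs^2 = 1/3, Guo forcing with half-force velocity shift.
// Temperature: D3Q7 advection-diffusion, rest weight 1/4, cs_T^2 = 1/4,
// diffusivity (tau_g - 1/2)/4.
// Solid voxels use halfway bounce-back (no-slip wall midway between nodes);
// optional fixed-density faces at z = 0 / z = nz-1 use non-equilibrium
// extrapolation from the adjacent interior node.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int EX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int EY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int EZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double W19[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};
static int OPP19[19];

static const int EX7[7] = {0, 1,-1, 0, 0, 0, 0};
static const int EY7[7] = {0, 0, 0, 1,-1, 0, 0};
static const int EZ7[7] = {0, 0, 0, 0, 0, 1,-1};
static const double W7[7] = {0.25, 0.125, 0.125, 0.125, 0.125, 0.125, 0.125};
static int OPP7[7];

static void init_opp() {
  for (int i = 0; i < 19; ++i)
    for (int j = 0; j < 19; ++j)
      if (EX[i] == -EX[j] && EY[i] == -EY[j] && EZ[i] == -EZ[j]) OPP19[i] = j;
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j)
      if (EX7[i] == -EX7[j] && EY7[i] == -EY7[j] && EZ7[i] == -EZ7[j]) OPP7[i] = j;
}

static inline int wrapi(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

static inline double feq19(int i, double rho, double ux, double uy, double uz) {
  double eu = EX[i] * ux + EY[i] * uy + EZ[i] * uz;
  double u2 = ux * ux + uy * uy + uz * uz;
  return W19[i] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * u2);
}

struct Grid {
  int nx, ny, nz;
  long n;
  Grid(IntegerVector dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {
    n = (long)nx * ny * nz;
  }
  inline long idx(int i, int j, int k) const {
    return i + (long)nx * (j + (long)ny * k);
  }
};

// Macroscopic moments of a flow state.  If a body force is supplied the
// velocity includes the standard half-force correction.
// [[Rcpp::export]]
List cpp_flow_moments(NumericVector f, IntegerVector occ, IntegerVector dim_,
                      Nullable<NumericVector> force_) {
  init_opp();
  Grid g(dim_);
  NumericVector rho(g.n), ux(g.n), uy(g.n), uz(g.n);
  bool hasF = force_.isNotNull();
  NumericVector F;
  bool fconst = false;
  if (hasF) {
    F = force_.get();
    fconst = (F.size() == 3);
  }
  for (long p = 0; p < g.n; ++p) {
    if (occ[p] != 0) continue;
    double r = 0, mx = 0, my = 0, mz = 0;
    for (int i = 0; i < 19; ++i) {
      double fi = f[p + g.n * i];
      r += fi;
      mx += fi * EX[i];
      my += fi * EY[i];
      mz += fi * EZ[i];
    }
    if (hasF) {
      double Fx = fconst ? F[0] : F[p];
      double Fy = fconst ? F[1] : F[p + g.n];
      double Fz = fconst ? F[2] : F[p + 2 * g.n];
      mx += 0.5 * Fx; my += 0.5 * Fy; mz += 0.5 * Fz;
    }
    rho[p] = r;
    if (r > 0) { ux[p] = mx / r; uy[p] = my / r; uz[p] = mz / r; }
  }
  return List::create(_["rho"] = rho, _["ux"] = ux, _["uy"] = uy, _["uz"] = uz);
}

static void collide_stream_flow(std::vector<double>& f, std::vector<double>& ftmp,
                                const int* occ, const Grid& g, double tau,
                                const double* F, bool fconst, int bc_z,
                                double rho_in, double rho_out) {
  const double om = 1.0 / tau;
  const double fpre = 1.0 - 0.5 / tau;
  // collide (in place) then stream into ftmp
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        long p = g.idx(i, j, k);
        if (occ[p] != 0) continue;
        double r = 0, mx = 0, my = 0, mz = 0;
        for (int q = 0; q < 19; ++q) {
          double fi = f[p + g.n * q];
          r += fi; mx += fi * EX[q]; my += fi * EY[q]; mz += fi * EZ[q];
        }
        double Fx = fconst ? F[0] : F[p];
        double Fy = fconst ? F[1] : F[p + g.n];
        double Fz = fconst ? F[2] : F[p + 2 * g.n];
        double ux = (mx + 0.5 * Fx) / r;
        double uy = (my + 0.5 * Fy) / r;
        double uz = (mz + 0.5 * Fz) / r;
        for (int q = 0; q < 19; ++q) {
          double eu = EX[q] * ux + EY[q] * uy + EZ[q] * uz;
          double u2 = ux * ux + uy * uy + uz * uz;
          double feq = W19[q] * r * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * u2);
          double Fi = fpre * W19[q] *
            (3.0 * ((EX[q] - ux) * Fx + (EY[q] - uy) * Fy + (EZ[q] - uz) * Fz) +
             9.0 * eu * (EX[q] * Fx + EY[q] * Fy + EZ[q] * Fz));
          f[p + g.n * q] += -om * (f[p + g.n * q] - feq) + Fi;
        }
      }
  // stream with halfway bounce-back at solid targets
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        long p = g.idx(i, j, k);
        if (occ[p] != 0) continue;
        for (int q = 0; q < 19; ++q) {
          int ti = wrapi(i + EX[q], g.nx);
          int tj = wrapi(j + EY[q], g.ny);
          int tk = wrapi(k + EZ[q], g.nz);
          long t = g.idx(ti, tj, tk);
          if (occ[t] != 0)
            ftmp[p + g.n * OPP19[q]] = f[p + g.n * q];
          else
            ftmp[t + g.n * q] = f[p + g.n * q];
        }
      }
  f.swap(ftmp);
  // fixed-density z faces via non-equilibrium extrapolation
  if (bc_z == 1) {
    for (int face = 0; face < 2; ++face) {
      int k = face == 0 ? 0 : g.nz - 1;
      int kn = face == 0 ? 1 : g.nz - 2;
      double rho_b = face == 0 ? rho_in : rho_out;
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          long p = g.idx(i, j, k);
          long pn = g.idx(i, j, kn);
          if (occ[p] != 0 || occ[pn] != 0) continue;
          double r = 0, mx = 0, my = 0, mz = 0;
          for (int q = 0; q < 19; ++q) {
            double fi = f[pn + g.n * q];
            r += fi; mx += fi * EX[q]; my += fi * EY[q]; mz += fi * EZ[q];
          }
          double ux = mx / r, uy = my / r, uz = mz / r;
          for (int q = 0; q < 19; ++q) {
            double fneq = f[pn + g.n * q] - feq19(q, r, ux, uy, uz);
            f[p + g.n * q] = feq19(q, rho_b, ux, uy, uz) + fneq;
          }
        }
    }
  }
}

static void collide_stream_temp(std::vector<double>& gdist, std::vector<double>& gtmp,
                                const int* occ, const Grid& g, double tau_g,
                                const double* ux, const double* uy, const double* uz,
                                const int* dirn, const double* dirT, int ndir) {
  const double om = 1.0 / tau_g;
  for (long p = 0; p < g.n; ++p) {
    if (occ[p] != 0) continue;
    double T = 0;
    for (int q = 0; q < 7; ++q) T += gdist[p + g.n * q];
    double vx = ux ? ux[p] : 0.0, vy = uy ? uy[p] : 0.0, vz = uz ? uz[p] : 0.0;
    for (int q = 0; q < 7; ++q) {
      double eu = EX7[q] * vx + EY7[q] * vy + EZ7[q] * vz;
      double geq = W7[q] * T * (1.0 + 4.0 * eu);
      gdist[p + g.n * q] += -om * (gdist[p + g.n * q] - geq);
    }
  }
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        long p = g.idx(i, j, k);
        if (occ[p] != 0) continue;
        for (int q = 0; q < 7; ++q) {
          int ti = wrapi(i + EX7[q], g.nx);
          int tj = wrapi(j + EY7[q], g.ny);
          int tk = wrapi(k + EZ7[q], g.nz);
          long t = g.idx(ti, tj, tk);
          if (occ[t] != 0)
            gtmp[p + g.n * OPP7[q]] = gdist[p + g.n * q];
          else
            gtmp[t + g.n * q] = gdist[p + g.n * q];
        }
      }
  gdist.swap(gtmp);
  // Dirichlet (fixed temperature) nodes: reset to rest equilibrium at T_fix
  for (int s = 0; s < ndir; ++s) {
    long p = dirn[s];
    for (int q = 0; q < 7; ++q) gdist[p + g.n * q] = W7[q] * dirT[s];
  }
}

// Advance the flow field `nsteps` collide-stream cycles.
// force: length 3 (uniform) or 3N field, lattice units.
// bc_z: 0 periodic, 1 fixed density rho_in/rho_out on the z faces.
// [[Rcpp::export]]
List cpp_flow_run(NumericVector f_, IntegerVector occ, IntegerVector dim_,
                  double tau, NumericVector force, int nsteps, int bc_z,
                  double rho_in, double rho_out, double max_u) {
  init_opp();
  Grid g(dim_);
  std::vector<double> f(f_.begin(), f_.end());
  std::vector<double> ftmp(f);
  bool fconst = (force.size() == 3);
  for (int s = 0; s < nsteps; ++s) {
    collide_stream_flow(f, ftmp, INTEGER(occ), g, tau, REAL(force), fconst,
                        bc_z, rho_in, rho_out);
    if ((s & 63) == 0 || s == nsteps - 1) {
      double umax2 = 0;
      bool bad = false;
      for (long p = 0; p < g.n; ++p) {
        if (occ[p] != 0) continue;
        double r = 0, mx = 0, my = 0, mz = 0;
        for (int q = 0; q < 19; ++q) {
          double fi = f[p + g.n * q];
          r += fi; mx += fi * EX[q]; my += fi * EY[q]; mz += fi * EZ[q];
        }
        if (!std::isfinite(r) || r <= 0) { bad = true; break; }
        double u2 = (mx * mx + my * my + mz * mz) / (r * r);
        if (u2 > umax2) umax2 = u2;
      }
      if (bad || std::sqrt(umax2) > max_u) {
        return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                            _["failed_step"] = s + 1,
                            _["max_u"] = std::sqrt(umax2),
                            _["ok"] = false);
      }
    }
  }
  double mass = 0;
  for (long p = 0; p < g.n; ++p)
    if (occ[p] == 0)
      for (int q = 0; q < 19; ++q) mass += f[p + g.n * q];
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["mass"] = mass, _["ok"] = true);
}

// Advance the temperature field `nsteps` cycles in a frozen velocity field.
// dirichlet_nodes: 0-based linear indices clamped to dirichlet_T each step.
// [[Rcpp::export]]
List cpp_temp_run(NumericVector g_, IntegerVector occ, IntegerVector dim_,
                  double tau_g, Nullable<List> uf_, int nsteps,
                  IntegerVector dirichlet_nodes, NumericVector dirichlet_T) {
  init_opp();
  Grid g(dim_);
  std::vector<double> gd(g_.begin(), g_.end());
  std::vector<double> gtmp(gd);
  const double *ux = nullptr, *uy = nullptr, *uz = nullptr;
  NumericVector uxv, uyv, uzv;
  if (uf_.isNotNull()) {
    List uf(uf_.get());
    uxv = as<NumericVector>(uf["ux"]);
    uyv = as<NumericVector>(uf["uy"]);
    uzv = as<NumericVector>(uf["uz"]);
    ux = REAL(uxv); uy = REAL(uyv); uz = REAL(uzv);
  }
  for (int s = 0; s < nsteps; ++s)
    collide_stream_temp(gd, gtmp, INTEGER(occ), g, tau_g, ux, uy, uz,
                        INTEGER(dirichlet_nodes), REAL(dirichlet_T),
                        dirichlet_nodes.size());
  double heat = 0;
  for (long p = 0; p < g.n; ++p)
    if (occ[p] == 0)
      for (int q = 0; q < 7; ++q) heat += gd[p + g.n * q];
  return List::create(_["g"] = NumericVector(gd.begin(), gd.end()),
                      _["heat"] = heat, _["ok"] = true);
}

// Coupled thermal flow: each cycle assembles the Boussinesq body force
// F = beta (T0 - T) rho0 gvec from the current temperature field, advances the
// flow one step, then advects-diffuses temperature in the updated velocity
// field with fixed-temperature source nodes (heated nanoparticles).
// [[Rcpp::export]]
List cpp_coupled_run(NumericVector f_, NumericVector g_, IntegerVector occ,
                     IntegerVector dim_, double tau_f, double tau_g,
                     double beta, double T0, NumericVector gvec,
                     IntegerVector dirichlet_nodes, NumericVector dirichlet_T,
                     int nsteps, double max_u) {
  init_opp();
  Grid g(dim_);
  std::vector<double> f(f_.begin(), f_.end()), ftmp(f);
  std::vector<double> gd(g_.begin(), g_.end()), gtmp(gd);
  std::vector<double> F(3 * g.n, 0.0), ux(g.n, 0.0), uy(g.n, 0.0), uz(g.n, 0.0);
  for (int s = 0; s < nsteps; ++s) {
    for (long p = 0; p < g.n; ++p) {
      if (occ[p] != 0) continue;
      double T = 0, rho = 0;
      for (int q = 0; q < 7; ++q) T += gd[p + g.n * q];
      for (int q = 0; q < 19; ++q) rho += f[p + g.n * q];
      double amp = beta * (T0 - T) * rho;
      F[p] = amp * gvec[0];
      F[p + g.n] = amp * gvec[1];
      F[p + 2 * g.n] = amp * gvec[2];
    }
    collide_stream_flow(f, ftmp, INTEGER(occ), g, tau_f, F.data(), false, 0, 1, 1);
    for (long p = 0; p < g.n; ++p) {
      if (occ[p] != 0) continue;
      double r = 0, mx = 0, my = 0, mz = 0;
      for (int q = 0; q < 19; ++q) {
        double fi = f[p + g.n * q];
        r += fi; mx += fi * EX[q]; my += fi * EY[q]; mz += fi * EZ[q];
      }
      ux[p] = (mx + 0.5 * F[p]) / r;
      uy[p] = (my + 0.5 * F[p + g.n]) / r;
      uz[p] = (mz + 0.5 * F[p + 2 * g.n]) / r;
      if (!std::isfinite(r) || std::fabs(ux[p]) > max_u ||
          std::fabs(uy[p]) > max_u || std::fabs(uz[p]) > max_u)
        return List::create(_["ok"] = false, _["failed_step"] = s + 1);
    }
    collide_stream_temp(gd, gtmp, INTEGER(occ), g, tau_g, ux.data(), uy.data(),
                        uz.data(), INTEGER(dirichlet_nodes), REAL(dirichlet_T),
                        dirichlet_nodes.size());
  }
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["g"] = NumericVector(gd.begin(), gd.end()),
                      _["ux"] = NumericVector(ux.begin(), ux.end()),
                      _["uy"] = NumericVector(uy.begin(), uy.end()),
                      _["uz"] = NumericVector(uz.begin(), uz.end()),
                      _["ok"] = true);
}

// Temperature field (zeroth moment of g).
// [[Rcpp::export]]
NumericVector cpp_temp_moments(NumericVector g_, IntegerVector dim_) {
  Grid g(dim_);
  NumericVector T(g.n);
  for (long p = 0; p < g.n; ++p) {
    double s = 0;
    for (int q = 0; q < 7; ++q) s += g_[p + g.n * q];
    T[p] = s;
  }
  return T;
}
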