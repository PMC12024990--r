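// Nanoparticle transport engine.
//
// Velocity update is the exact exponential integrator of
//   du_p/dt = (u - u_p)/tau_p + Sigma_a
// over one step, and displacement its exact time integral.  Particles then
// move either by the stochastic lattice migration rule (probability per face
// direction proportional to the continuum displacement component, opposing
// directions zero) or by direct continuous displacement.
//
// Near a solid surface the particle feels the net of van der Waals,
// electrostatic double-layer (sphere-plate, constant potential) and Lewis
// acid-base forces along the wall normal.  A rejected move into a solid voxel
// is a contact event: if the repulsive barrier of the net wall force profile
// exceeds the driving mobile forces the particle bounces, otherwise it adheres
// at a parking separation and is released only when the outward pull (Brownian
// + magnetic + drag) exceeds the bond force there.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KB = 1.380649e-23;  // J/K
static const double EPS0 = 8.8541878128e-12;  // F/m

struct Chem {
  bool on;
  double A;        // Hamaker constant, J
  double psi1;     // particle potential, V
  double psi2;     // wall potential, V
  double eps_r;    // relative permittivity
  double kappa;    // inverse Debye length, 1/m
  double d0;       // equilibrium (minimum-contact) distance, m
  double lambda;   // acid-base decay length, m
  double fab_c;    // pi*dp*dGab: acid-base force at contact, N (+ = repulsive)
  double cutoff;   // wall-interaction cutoff, m
  double d_park;   // adhered standoff separation, m
  double stick;    // attachment efficiency: P(attach | barrier-free collision)
  double dp;       // particle diameter, m
};

// outward-positive force components at separation d (surface-to-surface)
static inline double f_vdw(const Chem& c, double d) {
  double dd = std::max(d, c.d0);
  return -c.A * c.dp / (12.0 * dd * dd);
}
static inline double f_el(const Chem& c, double d) {
  double kd = c.kappa * d;
  if (kd > 500.0) return 0.0;
  if (kd < 1e-9) kd = 1e-9;
  double em = std::exp(-kd), ep = std::exp(kd);
  return M_PI * c.dp * c.kappa * c.eps_r * EPS0 *
         (2.0 * c.psi1 * c.psi2 - (c.psi1 * c.psi1 + c.psi2 * c.psi2) * em) /
         (ep - em);
}
static inline double f_ab(const Chem& c, double d) {
  return c.fab_c * std::exp((c.d0 - d) / c.lambda);
}
static inline double f_net(const Chem& c, double d) {
  return f_vdw(c, d) + f_el(c, d) + f_ab(c, d);
}

// highest repulsive (outward) value of the net wall force between contact and
// the interaction cutoff: the barrier an approaching particle must overcome
static double barrier_force(const Chem& c) {
  double best = 0.0;
  const int ng = 48;
  double l0 = std::log(c.d0), l1 = std::log(c.cutoff);
  for (int i = 0; i <= ng; ++i) {
    double d = std::exp(l0 + (l1 - l0) * i / ng);
    double f = f_net(c, d);
    if (f > best) best = f;
  }
  return best;
}

// Net wall force profile, exposed for unit tests against the plain-R
// force functions.
// [[Rcpp::export]]
List cpp_wall_profile(NumericVector d, List chem) {
  Chem c;
  c.on = true;
  c.A = chem["hamaker"]; c.psi1 = chem["psi_particle"]; c.psi2 = chem["psi_wall"];
  c.eps_r = chem["eps_r"]; c.kappa = chem["kappa"]; c.d0 = chem["d0"];
  c.lambda = chem["lambda"]; c.fab_c = chem["fab_contact"];
  c.cutoff = chem["cutoff"]; c.d_park = chem["d_park"]; c.dp = chem["dp"];
  int n = d.size();
  NumericVector vdw(n), el(n), ab(n), net(n);
  for (int i = 0; i < n; ++i) {
    vdw[i] = f_vdw(c, d[i]);
    el[i] = f_el(c, d[i]);
    ab[i] = f_ab(c, d[i]);
    net[i] = vdw[i] + el[i] + ab[i];
  }
  return List::create(_["vdw"] = vdw, _["el"] = el, _["ab"] = ab, _["net"] = net,
                      _["barrier"] = barrier_force(c));
}

static inline int wrapi(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}
static inline double wrapd(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard against floating round-up at the boundary
  return x;
}
static inline double mind(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

struct PRng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  PRng(uint64_t s) : gen(s), norm(0.0, 1.0) {}
  void unit_vec(double* v) {
    double n2 = 0;
    do {
      for (int i = 0; i < 3; ++i) v[i] = norm(gen);
      n2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    } while (n2 < 1e-12);
    double inv = 1.0 / std::sqrt(n2);
    for (int i = 0; i < 3; ++i) v[i] *= inv;
  }
  double gauss() { return norm(gen); }
  double runif() {
    return std::generate_canonical<double, 53>(gen);
  }
};

// Sample realized lattice migrations for a fixed continuum displacement:
// n trials of the per-axis Bernoulli rule; returns n x 3 realized moves (m).
// [[Rcpp::export]]
NumericMatrix cpp_sample_moves(NumericVector dxp, double dx, int n, int seed) {
  NumericMatrix out(n, 3);
  PRng rng((uint64_t)seed * 2654435761u + 12345u);
  for (int t = 0; t < n; ++t)
    for (int a = 0; a < 3; ++a) {
      double P = std::fabs(dxp[a]) / dx;
      if (P > 1.0) P = 1.0;
      if (rng.runif() < P) out(t, a) = (dxp[a] > 0 ? dx : -dx);
    }
  return out;
}

// Main ensemble driver for one replicate.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector occ, IntegerVector dim_, double dx,
                  List near_wall, NumericMatrix init_pos, List params,
                  Nullable<List> uf_, int nsteps, int record_every, int seed) {
  int dim[3] = {dim_[0], dim_[1], dim_[2]};
  long N = (long)dim[0] * dim[1] * dim[2];
  double L[3] = {dim[0] * dx, dim[1] * dx, dim[2] * dx};
  NumericVector near_dist2 = near_wall["dist2"];
  NumericVector wn_x = near_wall["nx"], wn_y = near_wall["ny"],
                wn_z = near_wall["nz"];

  const double dt = params["dt"];
  const double dp = params["dp"];
  const double rho_p = params["rho_p"];
  const double mu = params["mu"];
  const double temp = params["temperature"];
  const double msat = params["msat"];
  const double drag_pref = params["drag_pref"];  // multiplies pi*mu*dp
  const int brownian_mode = params["brownian_mode"];  // 0 fixed, 1 gaussian
  const int move_mode = params["move_mode"];          // 0 lga, 1 continuous
  const int interp_mode = params["interp_mode"];      // 0 trilinear, 1 nearest
  NumericVector gradB = params["gradB"];

  Chem c;
  c.on = as<bool>(params["chem_on"]);
  c.A = params["hamaker"]; c.psi1 = params["psi_particle"];
  c.psi2 = params["psi_wall"]; c.eps_r = params["eps_r"];
  c.kappa = params["kappa"]; c.d0 = params["d0"]; c.lambda = params["lambda"];
  c.fab_c = params["fab_contact"]; c.cutoff = params["cutoff"];
  c.d_park = params["d_park"]; c.stick = params["stick_prob"]; c.dp = dp;

  const double vol = M_PI / 6.0 * dp * dp * dp;
  const double mass = rho_p * vol;
  const double zeta = drag_pref * M_PI * mu * dp;   // drag coefficient, N s/m
  const double tau_p = mass / zeta;
  const double fb_fixed = 2.0 * KB * temp / dp;     // printed Brownian magnitude
  const double fb_gauss = std::sqrt(2.0 * zeta * KB * temp / dt);  // per comp.
  const double tau_bond_ref = params["tau_bond_ref"];  // s, bond lifetime scale
  double amag[3];
  for (int a = 0; a < 3; ++a) amag[a] = vol * msat * gradB[a] / mass;
  const double bond = c.on ? std::max(0.0, -f_net(c, c.d_park)) : 0.0;
  const double barrier = c.on ? barrier_force(c) : 0.0;

  const double *ux = nullptr, *uy = nullptr, *uz = nullptr;
  NumericVector uxv, uyv, uzv;
  if (uf_.isNotNull()) {
    List uf(uf_.get());
    uxv = as<NumericVector>(uf["ux"]); uyv = as<NumericVector>(uf["uy"]);
    uzv = as<NumericVector>(uf["uz"]);
    ux = REAL(uxv); uy = REAL(uyv); uz = REAL(uzv);
  }

  int np = init_pos.nrow();
  int nrec = nsteps / record_every + 1;
  NumericVector traj(static_cast<R_xlen_t>(nrec) * np * 3);
  LogicalVector adh_rec(static_cast<R_xlen_t>(nrec) * np);
  IntegerVector n_adhere(np), n_release(np);

  std::vector<double> pos(3 * np), unw(3 * np, 0.0), vel(3 * np, 0.0);
  std::vector<char> adhered(np, 0);
  std::vector<double> nrm(3 * np, 0.0);  // wall normal for adhered particles

  for (int p = 0; p < np; ++p)
    for (int a = 0; a < 3; ++a) pos[3 * p + a] = wrapd(init_pos(p, a), L[a]);

  auto host_of = [&](const double* x) {
    int i = wrapi((int)std::floor(x[0] / dx), dim[0]);
    int j = wrapi((int)std::floor(x[1] / dx), dim[1]);
    int k = wrapi((int)std::floor(x[2] / dx), dim[2]);
    return (long)i + dim[0] * ((long)j + dim[1] * (long)k);
  };
  auto local_u = [&](const double* x, long host, double* u) {
    u[0] = u[1] = u[2] = 0.0;
    if (!ux) return;
    if (interp_mode == 1) { u[0] = ux[host]; u[1] = uy[host]; u[2] = uz[host]; return; }
    // trilinear over the 8 surrounding node centers (periodic)
    double gx = x[0] / dx - 0.5, gy = x[1] / dx - 0.5, gz = x[2] / dx - 0.5;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          long q = (long)wrapi(i0 + di, dim[0]) +
                   dim[0] * ((long)wrapi(j0 + dj, dim[1]) +
                             dim[1] * (long)wrapi(k0 + dk, dim[2]));
          u[0] += w * ux[q]; u[1] += w * uy[q]; u[2] += w * uz[q];
        }
  };
  // separation (particle surface to solid surface) and outward normal from
  // the precomputed near-wall map (tie-averaged over equidistant nearest
  // solids); returns -1 when no wall is within the scanned range
  auto wall_gap = [&](const double* x, long host, double* n_out) {
    (void)x;
    double d2 = near_dist2[host];
    if (d2 < 0) return -1.0;
    n_out[0] = wn_x[host]; n_out[1] = wn_y[host]; n_out[2] = wn_z[host];
    if (n_out[0] == 0 && n_out[1] == 0 && n_out[2] == 0) return -1.0;
    double gap = std::sqrt(d2) * dx - 0.5 * dx - 0.5 * dp;
    return std::max(gap, c.d0);
  };

  int rec = 0;
  auto record = [&](int r) {
    for (int p = 0; p < np; ++p) {
      for (int a = 0; a < 3; ++a)
        traj[(R_xlen_t)r + (R_xlen_t)nrec * (p + (R_xlen_t)np * a)] = unw[3 * p + a];
      adh_rec[(R_xlen_t)r + (R_xlen_t)nrec * p] = (bool)adhered[p];
    }
  };
  record(rec++);

  // one independent, deterministically derived RNG stream per particle
  std::vector<PRng> pool;
  pool.reserve(np);
  for (int q = 0; q < np; ++q)
    pool.emplace_back((uint64_t)seed * 0x9E3779B97F4A7C15ull +
                      0x100000001B3ull * (q + 1));

  bool substep_overflow = false;
  for (int step = 1; step <= nsteps; ++step) {
    for (int p = 0; p < np; ++p) {
      PRng* rng = &pool[p];
      double* x = &pos[3 * p];
      double* v = &vel[3 * p];
      long host = host_of(x);
      double uL[3];
      local_u(x, host, uL);

      // Brownian force for this step
      double fb[3];
      if (brownian_mode == 0) {
        double dir[3];
        rng->unit_vec(dir);
        for (int a = 0; a < 3; ++a) fb[a] = fb_fixed * dir[a];
      } else {
        for (int a = 0; a < 3; ++a) fb[a] = fb_gauss * rng->gauss();
      }

      if (adhered[p]) {
        // detachment kinetics: the bond lifetime scales linearly with the
        // bond force (reference lifetime tau_bond_ref at a bond equal to the
        // Brownian force magnitude 2 kB T / d_p), and a deterministic
        // outward pull (magnetic force, drag) accelerates escape by the
        // Bell factor exp(F_out x_b / kB T) with activation length x_b equal
        // to the parking separation.
        double* n = &nrm[3 * p];
        double fout = mass * (amag[0] * n[0] + amag[1] * n[1] + amag[2] * n[2]) +
                      zeta * (uL[0] * n[0] + uL[1] * n[1] + uL[2] * n[2]);
        if (fout < 0) fout = 0;
        double tau_b = tau_bond_ref * bond / fb_fixed;
        double prel = bond <= 0 ? 1.0
          : dt / tau_b * std::exp(fout * c.d_park / (KB * temp));
        if (rng->runif() < prel) {
          // desorb: step one node outward along the wall normal so the
          // particle leaves the interaction layer (stays if that node is
          // solid, e.g. in a crevice)
          long host = host_of(x);
          int hi = host % dim[0], hj = (host / dim[0]) % dim[1],
              hk = host / (dim[0] * dim[1]);
          int axis = 0;
          for (int a = 1; a < 3; ++a)
            if (std::fabs(n[a]) > std::fabs(n[axis])) axis = a;
          int dir = n[axis] > 0 ? 1 : -1;
          int tn[3] = {hi, hj, hk};
          tn[axis] = wrapi(tn[axis] + dir, dim[axis]);
          long tgt = (long)tn[0] + dim[0] * ((long)tn[1] + dim[1] * (long)tn[2]);
          if (occ[tgt] == 0) {
            adhered[p] = 0;
            ++n_release[p];
            for (int a = 0; a < 3; ++a) v[a] = 0.0;
            x[axis] = (tn[axis] + 0.5) * dx;
            unw[3 * p + axis] += dir * dx;
          }
        }
        continue;
      }

      // accelerations other than drag
      double sa[3];
      for (int a = 0; a < 3; ++a) sa[a] = fb[a] / mass + amag[a];
      double n_out[3] = {0, 0, 0};
      double gap = -1.0;
      if (c.on) {
        gap = wall_gap(x, host, n_out);
        if (gap > c.d_park && gap <= c.cutoff) {
          // attractive wells produce a resolvable margination drift toward
          // the wall.  Separations at or below the parking distance are in
          // the contact regime, which the contact/adhesion rules own; and
          // repulsive barriers act at sub-voxel range and enter through the
          // contact (bounce) rule, so only the attractive part is applied
          // as a body force.
          double fw = f_net(c, gap);
          if (fw < 0)
            for (int a = 0; a < 3; ++a) sa[a] += fw * n_out[a] / mass;
        }
      }

      // exact exponential integration over dt
      double E = std::exp(-dt / tau_p);
      double dxp[3], vnew[3];
      for (int a = 0; a < 3; ++a) {
        double term = uL[a] + tau_p * sa[a];
        vnew[a] = term + (v[a] - term) * E;
        dxp[a] = term * dt + (v[a] - term) * tau_p * (1.0 - E);
      }
      for (int a = 0; a < 3; ++a) v[a] = vnew[a];

      // migration guard: sub-step so no component exceeds one lattice spacing
      double mx = std::max({std::fabs(dxp[0]), std::fabs(dxp[1]), std::fabs(dxp[2])});
      int ksub = std::max(1, (int)std::ceil(mx / dx));
      if (ksub > 64) { ksub = 64; substep_overflow = true; }

      for (int s = 0; s < ksub && !adhered[p]; ++s) {
        if (move_mode == 0) {
          // lattice migration: independent Bernoulli per axis
          int hi = host % dim[0], hj = (host / dim[0]) % dim[1],
              hk = host / (dim[0] * dim[1]);
          int hn[3] = {hi, hj, hk};
          for (int a = 0; a < 3 && !adhered[p]; ++a) {
            double P = std::fabs(dxp[a]) / (dx * ksub);
            if (P > 1.0) P = 1.0;
            if (rng->runif() >= P) continue;
            int dir = dxp[a] > 0 ? 1 : -1;
            int tn[3] = {hn[0], hn[1], hn[2]};
            tn[a] = wrapi(tn[a] + dir, dim[a]);
            long tgt = (long)tn[0] + dim[0] * ((long)tn[1] + dim[1] * (long)tn[2]);
            if (occ[tgt] != 0) {
              // contact event
              if (!c.on) { v[a] = 0.0; continue; }
              double nrm_c[3] = {0, 0, 0};
              nrm_c[a] = -dir;  // outward = opposite the attempted move
              double drive = std::sqrt(fb[0]*fb[0] + fb[1]*fb[1] + fb[2]*fb[2]);
              double fmagn = mass * (amag[0]*nrm_c[0] + amag[1]*nrm_c[1] + amag[2]*nrm_c[2]);
              if (fmagn < 0) drive += -fmagn;
              double fdragn = zeta * ((uL[0]-v[0])*nrm_c[0] + (uL[1]-v[1])*nrm_c[1] +
                                      (uL[2]-v[2])*nrm_c[2]);
              if (fdragn < 0) drive += -fdragn;
              if (barrier > drive || rng->runif() >= c.stick) {
                v[a] = 0.0;  // bounced, or collision did not attach
              } else {
                adhered[p] = 1;
                ++n_adhere[p];
                for (int b = 0; b < 3; ++b) { v[b] = 0.0; nrm[3 * p + b] = nrm_c[b]; }
              }
            } else {
              hn[a] = tn[a];
              host = tgt;
              unw[3 * p + a] += dir * dx;
              x[a] = (tn[a] + 0.5) * dx;
            }
          }
        } else {
          // continuous displacement
          double prop[3];
          for (int a = 0; a < 3; ++a) prop[a] = wrapd(x[a] + dxp[a] / ksub, L[a]);
          long tgt = host_of(prop);
          if (occ[tgt] != 0) {
            if (!c.on) {
              for (int a = 0; a < 3; ++a) v[a] = 0.0;
              continue;
            }
            double nrm_c[3];
            double g2 = wall_gap(x, host, nrm_c);
            if (g2 < 0) { nrm_c[0] = nrm_c[1] = nrm_c[2] = 0; nrm_c[0] = 1; }
            double drive = std::sqrt(fb[0]*fb[0] + fb[1]*fb[1] + fb[2]*fb[2]);
            double fmagn = mass * (amag[0]*nrm_c[0] + amag[1]*nrm_c[1] + amag[2]*nrm_c[2]);
            if (fmagn < 0) drive += -fmagn;
            double fdragn = zeta * ((uL[0]-v[0])*nrm_c[0] + (uL[1]-v[1])*nrm_c[1] +
                                    (uL[2]-v[2])*nrm_c[2]);
            if (fdragn < 0) drive += -fdragn;
            if (barrier > drive || rng->runif() >= c.stick) {
              for (int a = 0; a < 3; ++a) v[a] = 0.0;
            } else {
              adhered[p] = 1;
              ++n_adhere[p];
              for (int b = 0; b < 3; ++b) { v[b] = 0.0; nrm[3 * p + b] = nrm_c[b]; }
            }
          } else {
            for (int a = 0; a < 3; ++a) {
              unw[3 * p + a] += dxp[a] / ksub;
              x[a] = prop[a];
            }
            host = tgt;
          }
        }
      }
    }
    if (step % record_every == 0) record(rec++);
  }

  traj.attr("dim") = IntegerVector::create(nrec, np, 3);
  adh_rec.attr("dim") = IntegerVector::create(nrec, np);
  return List::create(_["traj"] = traj, _["adhered"] = adh_rec,
                      _["n_adhere"] = n_adhere, _["n_release"] = n_release,
                      _["tau_p"] = tau_p, _["bond"] = bond,
                      _["barrier"] = barrier,
                      _["substep_overflow"] = substep_overflow);
}
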