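// Voxel geometry kernels: primitive rasterisation on a periodic cubic grid,
// degradation editing, connectivity, and near-wall distance maps.
//
// Occupancy labels: 0 fluid, 1 fiber, 2 tumor cell, 3 stromal cell, 4 sphere.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

static inline double wrap_delta(double d, double L) {
  // minimum-image separation for a periodic axis of length L
  d -= L * std::round(d / L);
  return d;
}

static inline int lin(int i, int j, int k, const int* dim) {
  return i + dim[0] * (j + dim[1] * k);
}

// Rasterise straight cylindrical rods (capsules) of given radius.  Segments
// wrap periodically.  `starts` (n x 3) and `dirs` (n x 3, unit) are in voxel
// units (node-centered coordinates: node i sits at i + 0.5); `lengths` too.
// [[Rcpp::export]]
void cpp_fill_fibers(IntegerVector occ, IntegerVector dim_, NumericMatrix starts,
                     NumericMatrix dirs, NumericVector lengths, double radius,
                     int label) {
  int dim[3] = {dim_[0], dim_[1], dim_[2]};
  double L[3] = {(double)dim[0], (double)dim[1], (double)dim[2]};
  int rpad = (int)std::ceil(radius) + 1;
  for (int s = 0; s < starts.nrow(); ++s) {
    double p0[3] = {starts(s, 0), starts(s, 1), starts(s, 2)};
    double u[3] = {dirs(s, 0), dirs(s, 1), dirs(s, 2)};
    double len = lengths[s];
    // march along the axis, marking voxels near each sample; exact
    // point-to-segment distance check keeps the surface crisp
    double step = 0.5;
    int nsamp = std::max(1, (int)std::ceil(len / step));
    for (int t = 0; t <= nsamp; ++t) {
      double a = len * (double)t / nsamp;
      double c[3] = {p0[0] + a * u[0], p0[1] + a * u[1], p0[2] + a * u[2]};
      int ic[3] = {(int)std::floor(c[0]), (int)std::floor(c[1]),
                   (int)std::floor(c[2])};
      for (int dk = -rpad; dk <= rpad; ++dk)
        for (int dj = -rpad; dj <= rpad; ++dj)
          for (int di = -rpad; di <= rpad; ++di) {
            int vi = ic[0] + di, vj = ic[1] + dj, vk = ic[2] + dk;
            // node center in unwrapped coordinates
            double x[3] = {vi + 0.5, vj + 0.5, vk + 0.5};
            // distance from node center to the segment [p0, p0 + len u]
            double w[3] = {x[0] - p0[0], x[1] - p0[1], x[2] - p0[2]};
            double proj = w[0] * u[0] + w[1] * u[1] + w[2] * u[2];
            proj = std::min(std::max(proj, 0.0), len);
            double dx0 = w[0] - proj * u[0];
            double dx1 = w[1] - proj * u[1];
            double dx2 = w[2] - proj * u[2];
            double d2 = dx0 * dx0 + dx1 * dx1 + dx2 * dx2;
            if (d2 <= radius * radius) {
              int idx = lin(wrap(vi, dim[0]), wrap(vj, dim[1]), wrap(vk, dim[2]), dim);
              occ[idx] = label;
            }
          }
      (void)L;
    }
  }
}

// Rasterise axis-aligned ellipsoids (spheres are the equal-axes case) with
// periodic wrap. centers and semiaxes in voxel units; one label per body.
// [[Rcpp::export]]
void cpp_fill_ellipsoids(IntegerVector occ, IntegerVector dim_, NumericMatrix centers,
                         NumericMatrix semiaxes, IntegerVector labels) {
  int dim[3] = {dim_[0], dim_[1], dim_[2]};
  for (int s = 0; s < centers.nrow(); ++s) {
    double c[3] = {centers(s, 0), centers(s, 1), centers(s, 2)};
    double a[3] = {semiaxes(s, 0), semiaxes(s, 1), semiaxes(s, 2)};
    int pad[3];
    for (int d = 0; d < 3; ++d) pad[d] = (int)std::ceil(a[d]) + 1;
    int ic[3] = {(int)std::floor(c[0]), (int)std::floor(c[1]), (int)std::floor(c[2])};
    for (int dk = -pad[2]; dk <= pad[2]; ++dk)
      for (int dj = -pad[1]; dj <= pad[1]; ++dj)
        for (int di = -pad[0]; di <= pad[0]; ++di) {
          int vi = ic[0] + di, vj = ic[1] + dj, vk = ic[2] + dk;
          double r2 = 0.0;
          double x[3] = {vi + 0.5, vj + 0.5, vk + 0.5};
          for (int d = 0; d < 3; ++d) {
            double dd = (x[d] - c[d]) / a[d];
            r2 += dd * dd;
          }
          if (r2 <= 1.0) {
            int idx = lin(wrap(vi, dim[0]), wrap(vj, dim[1]), wrap(vk, dim[2]), dim);
            occ[idx] = labels[s];
          }
        }
  }
}

// Seeded-growth packing of cells: every voxel whose scaled (ellipsoidal)
// distance to the nearest seed is below `scale` is claimed by that seed.
// Claims are exclusive (argmin), so grown cells never overlap; at high
// packing fractions neighbouring cells truncate one another at the
// tessellation boundary, as cells do in dense tissue.
// Returns achieved solid fraction.
// [[Rcpp::export]]
double cpp_grow_cells(IntegerVector occ, IntegerVector dim_, NumericMatrix seeds,
                      NumericMatrix semiaxes, IntegerVector labels, double scale) {
  int dim[3] = {dim_[0], dim_[1], dim_[2]};
  double L[3] = {(double)dim[0], (double)dim[1], (double)dim[2]};
  int ns = seeds.nrow();
  long ntot = (long)dim[0] * dim[1] * dim[2];
  // exclusive claims: a voxel belongs to the seed with the smallest scaled
  // (ellipsoidal) distance, provided that distance is within `scale`
  std::vector<float> best(ntot, 1e30f);
  std::vector<int32_t> who(ntot, -1);
  for (int s = 0; s < ns; ++s) {
    double c[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    double a[3] = {semiaxes(s, 0) * scale, semiaxes(s, 1) * scale,
                   semiaxes(s, 2) * scale};
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = (int)std::floor(c[d] - a[d]) - 1;
      hi[d] = (int)std::ceil(c[d] + a[d]) + 1;
    }
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double x[3] = {i + 0.5, j + 0.5, k + 0.5};
          double r2 = 0.0;
          for (int d = 0; d < 3; ++d) {
            double dd = wrap_delta(x[d] - c[d], L[d]) / semiaxes(s, d);
            r2 += dd * dd;
          }
          if (r2 > scale * scale) continue;
          long idx = lin(wrap(i, dim[0]), wrap(j, dim[1]), wrap(k, dim[2]), dim);
          if ((float)r2 < best[idx]) { best[idx] = (float)r2; who[idx] = s; }
        }
  }
  long nsolid = 0;
  for (long idx = 0; idx < ntot; ++idx) {
    if (who[idx] >= 0) { occ[idx] = labels[who[idx]]; ++nsolid; }
    else occ[idx] = 0;
  }
  return (double)nsolid / (double)ntot;
}

// Convert fiber voxels within a ball of radius `rad` (voxels) around each
// given locus to fluid.  Loci are linear voxel indices (0-based).
// [[Rcpp::export]]
int cpp_degrade(IntegerVector occ, IntegerVector dim_, IntegerVector loci,
                double rad, int fiber_label) {
  int dim[3] = {dim_[0], dim_[1], dim_[2]};
  int rpad = (int)std::ceil(rad);
  int removed = 0;
  for (int p = 0; p < loci.size(); ++p) {
    int idx = loci[p];
    int i0 = idx % dim[0];
    int j0 = (idx / dim[0]) % dim[1];
    int k0 = idx / (dim[0] * dim[1]);
    for (int dk = -rpad; dk <= rpad; ++dk)
      for (int dj = -rpad; dj <= rpad; ++dj)
        for (int di = -rpad; di <= rpad; ++di) {
          if (di * di + dj * dj + dk * dk > rad * rad) continue;
          int q = lin(wrap(i0 + di, dim[0]), wrap(j0 + dj, dim[1]),
                      wrap(k0 + dk, dim[2]), dim);
          if (occ[q] == fiber_label) {
            occ[q] = 0;
            ++removed;
          }
        }
  }
  return removed;
}

// Fraction of fluid voxels belonging to the largest face-connected (6-neighbour,
// periodic) fluid component.  Errors upstream guarantee >= 1 fluid voxel.
// [[Rcpp::export]]
double cpp_largest_component(IntegerVector occ, IntegerVector dim_) {
  int dim[3] = {dim_[0], dim_[1], dim_[2]};
  long n = (long)dim[0] * dim[1] * dim[2];
  std::vector<int32_t> comp(n, -1);
  long nfluid = 0;
  for (long i = 0; i < n; ++i)
    if (occ[i] == 0) ++nfluid;
  if (nfluid == 0) return NA_REAL;
  long best = 0;
  int32_t cur = 0;
  std::vector<int32_t> stack;
  for (long s = 0; s < n; ++s) {
    if (occ[s] != 0 || comp[s] >= 0) continue;
    long size = 0;
    stack.push_back((int32_t)s);
    comp[s] = cur;
    while (!stack.empty()) {
      int32_t v = stack.back();
      stack.pop_back();
      ++size;
      int i = v % dim[0];
      int j = (v / dim[0]) % dim[1];
      int k = v / (dim[0] * dim[1]);
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int m = 0; m < 6; ++m) {
        int q = lin(wrap(i + off[m][0], dim[0]), wrap(j + off[m][1], dim[1]),
                    wrap(k + off[m][2], dim[2]), dim);
        if (occ[q] == 0 && comp[q] < 0) {
          comp[q] = cur;
          stack.push_back(q);
        }
      }
    }
    if (size > best) best = size;
    ++cur;
  }
  return (double)best / (double)nfluid;
}

// Near-wall map: for each fluid voxel, the nearest solid voxel center within
// a scan radius (periodic), as squared distance in voxel units and the linear
// index of that solid voxel.  Voxels with no solid inside the scan radius get
// dist2 = -1 (treated as "far from any wall").
// [[Rcpp::export]]
List cpp_near_wall(IntegerVector occ, IntegerVector dim_, int scan) {
  int dim[3] = {dim_[0], dim_[1], dim_[2]};
  long n = (long)dim[0] * dim[1] * dim[2];
  NumericVector dist2(n, -1.0);
  // outward direction away from the nearest solid, averaged over all
  // equidistant nearest solids so symmetric gaps produce no net pull
  NumericVector nx(n), ny(n), nz(n);
  for (int k = 0; k < dim[2]; ++k)
    for (int j = 0; j < dim[1]; ++j)
      for (int i = 0; i < dim[0]; ++i) {
        long idx = lin(i, j, k, dim);
        if (occ[idx] != 0) { dist2[idx] = 0.0; continue; }
        int best = scan * scan * 3 + 1;
        double sx = 0, sy = 0, sz = 0;
        for (int dk = -scan; dk <= scan; ++dk)
          for (int dj = -scan; dj <= scan; ++dj)
            for (int di = -scan; di <= scan; ++di) {
              int d2 = di * di + dj * dj + dk * dk;
              if (d2 > best || d2 == 0) continue;
              int q = lin(wrap(i + di, dim[0]), wrap(j + dj, dim[1]),
                          wrap(k + dk, dim[2]), dim);
              if (occ[q] == 0) continue;
              if (d2 < best) { best = d2; sx = sy = sz = 0; }
              double inv = 1.0 / std::sqrt((double)d2);
              sx -= di * inv; sy -= dj * inv; sz -= dk * inv;
            }
        if (best <= scan * scan * 3) {
          dist2[idx] = best;
          double nrm = std::sqrt(sx * sx + sy * sy + sz * sz);
          if (nrm > 1e-12) { nx[idx] = sx / nrm; ny[idx] = sy / nrm; nz[idx] = sz / nrm; }
        }
      }
  return List::create(_["dist2"] = dist2, _["nx"] = nx, _["ny"] = ny,
                      _["nz"] = nz);
}
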