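#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact incremental voxel-boundary traversal (Amanatides–Woo) shared by the
// kerma scorer and the path-length oracle.  Grid box spans
// [boxmin, boxmin + dims * spacing); arrays are column-major (x fastest).

struct GridSpec {
  double bx, by, bz;      // box min corner
  double sx, sy, sz;      // spacing
  int nx, ny, nz;
};

static inline bool ray_box(const GridSpec &g,
                           double px, double py, double pz,
                           double dx, double dy, double dz,
                           double &t0, double &t1) {
  t0 = 0.0;
  t1 = std::numeric_limits<double>::infinity();
  const double bmin[3] = {g.bx, g.by, g.bz};
  const double bmax[3] = {g.bx + g.nx * g.sx, g.by + g.ny * g.sy,
                          g.bz + g.nz * g.sz};
  const double p[3] = {px, py, pz};
  const double d[3] = {dx, dy, dz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      if (p[a] <= bmin[a] || p[a] >= bmax[a]) return false;
    } else {
      double ta = (bmin[a] - p[a]) / d[a];
      double tb = (bmax[a] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// Deposit collision kerma along primary-photon rays.
// mu, muen: nStatic x M coefficient matrices (cm2/g) for the materials
// present; muRow maps each ray to its row (rays replicated by rotation share
// a row).  matidx: per-voxel 0-based column into mu/muen.  edep and
// edepBatch are accumulated in place across calls.
// [[Rcpp::export]]
NumericVector kerma_trace_cpp(NumericMatrix pos, NumericMatrix dir,
                              NumericVector energy, IntegerVector muRow,
                              IntegerVector batch, int nBatches,
                              NumericVector boxmin, NumericVector spacing,
                              IntegerVector dims, IntegerVector matidx,
                              NumericVector density, NumericMatrix mu,
                              NumericMatrix muen, NumericVector edep,
                              NumericVector edepBatch, double tauMax) {
  GridSpec g = {boxmin[0], boxmin[1], boxmin[2],
                spacing[0], spacing[1], spacing[2],
                dims[0], dims[1], dims[2]};
  const int n = pos.nrow();
  const bool doBatch = edepBatch.size() > 0;
  double entered = 0.0, escaped = 0.0, scatter = 0.0;
  int skipped = 0;
  const long nvox = (long)g.nx * g.ny * g.nz;

  for (int i = 0; i < n; ++i) {
    const double px = pos(i, 0), py = pos(i, 1), pz = pos(i, 2);
    const double dx = dir(i, 0), dy = dir(i, 1), dz = dir(i, 2);
    double t0, t1;
    if (!ray_box(g, px, py, pz, dx, dy, dz, t0, t1) || t1 <= 0.0) {
      ++skipped;
      continue;
    }
    if (t0 < 0.0) t0 = 0.0;
    const double E = energy[i];
    entered += E;
    // entry voxel
    const double eps = 1e-12 * (t1 - t0 + 1.0);
    double t = t0 + eps;
    int ix = (int)std::floor((px + t * dx - g.bx) / g.sx);
    int iy = (int)std::floor((py + t * dy - g.by) / g.sy);
    int iz = (int)std::floor((pz + t * dz - g.bz) / g.sz);
    ix = std::min(std::max(ix, 0), g.nx - 1);
    iy = std::min(std::max(iy, 0), g.ny - 1);
    iz = std::min(std::max(iz, 0), g.nz - 1);
    const int stepx = dx > 0 ? 1 : -1;
    const int stepy = dy > 0 ? 1 : -1;
    const int stepz = dz > 0 ? 1 : -1;
    const double inf = std::numeric_limits<double>::infinity();
    const double tdx = dx != 0 ? std::fabs(g.sx / dx) : inf;
    const double tdy = dy != 0 ? std::fabs(g.sy / dy) : inf;
    const double tdz = dz != 0 ? std::fabs(g.sz / dz) : inf;
    double tmx = dx != 0
      ? (g.bx + (ix + (stepx > 0 ? 1 : 0)) * g.sx - px) / dx : inf;
    double tmy = dy != 0
      ? (g.by + (iy + (stepy > 0 ? 1 : 0)) * g.sy - py) / dy : inf;
    double tmz = dz != 0
      ? (g.bz + (iz + (stepz > 0 ? 1 : 0)) * g.sz - pz) / dz : inf;

    double tau = 0.0;
    double ET = E; // remaining (unattenuated) energy fluence on the ray
    double tcur = t0;
    const int row = muRow[i];
    const int b = doBatch ? batch[i] : 0;
    bool truncated = false;
    while (ix >= 0 && ix < g.nx && iy >= 0 && iy < g.ny &&
           iz >= 0 && iz < g.nz) {
      double tnext = std::min(tmx, std::min(tmy, tmz));
      if (tnext > t1) tnext = t1;
      const double len = tnext - tcur;
      if (len > 0.0) {
        const long v = (long)ix + (long)g.nx * ((long)iy + (long)g.ny * iz);
        const int m = matidx[v];
        const double rho = density[v];
        const double murv = mu(row, m);
        const double dtau = murv * rho * len;
        if (dtau > 0.0) {
          // q = 1 - exp(-dtau); 4th-order series below 0.05 (error < 1e-8
          // relative), exact energy split either way
          double q;
          if (dtau < 0.05) {
            q = dtau * (1.0 - 0.5 * dtau *
                (1.0 - dtau / 3.0 * (1.0 - 0.25 * dtau)));
          } else {
            q = 1.0 - std::exp(-dtau);
          }
          const double interacted = ET * q;
          const double fen = muen(row, m) / murv;
          const double dep = interacted * fen;
          edep[v] += dep;
          if (doBatch) edepBatch[v + nvox * b] += dep;
          scatter += interacted * (1.0 - fen);
          ET -= interacted;
          tau += dtau;
        }
      }
      tcur = tnext;
      if (tcur >= t1 - 1e-15) break;
      if (tau > tauMax) { truncated = true; break; }
      if (tmx <= tmy && tmx <= tmz) { ix += stepx; tmx += tdx; }
      else if (tmy <= tmz)          { iy += stepy; tmy += tdy; }
      else                          { iz += stepz; tmz += tdz; }
    }
    // transmitted (or negligible residual when optically truncated)
    escaped += ET;
    (void)truncated;
  }
  return NumericVector::create(
    _["entered"] = entered, _["escaped"] = escaped,
    _["scatter"] = scatter, _["skipped"] = (double)skipped);
}

// Voxel indices (1-based) and chord lengths of a single ray through the grid.
// [[Rcpp::export]]
List voxel_path_cpp(NumericVector p, NumericVector d, NumericVector boxmin,
                    NumericVector spacing, IntegerVector dims) {
  GridSpec g = {boxmin[0], boxmin[1], boxmin[2],
                spacing[0], spacing[1], spacing[2],
                dims[0], dims[1], dims[2]};
  std::vector<int> vix, viy, viz;
  std::vector<double> vlen;
  double t0, t1;
  if (ray_box(g, p[0], p[1], p[2], d[0], d[1], d[2], t0, t1) && t1 > 0) {
    if (t0 < 0) t0 = 0;
    const double eps = 1e-12 * (t1 - t0 + 1.0);
    double t = t0 + eps;
    int ix = (int)std::floor((p[0] + t * d[0] - g.bx) / g.sx);
    int iy = (int)std::floor((p[1] + t * d[1] - g.by) / g.sy);
    int iz = (int)std::floor((p[2] + t * d[2] - g.bz) / g.sz);
    ix = std::min(std::max(ix, 0), g.nx - 1);
    iy = std::min(std::max(iy, 0), g.ny - 1);
    iz = std::min(std::max(iz, 0), g.nz - 1);
    const int sx = d[0] > 0 ? 1 : -1, sy = d[1] > 0 ? 1 : -1,
              sz = d[2] > 0 ? 1 : -1;
    const double inf = std::numeric_limits<double>::infinity();
    const double tdx = d[0] != 0 ? std::fabs(g.sx / d[0]) : inf;
    const double tdy = d[1] != 0 ? std::fabs(g.sy / d[1]) : inf;
    const double tdz = d[2] != 0 ? std::fabs(g.sz / d[2]) : inf;
    double tmx = d[0] != 0
      ? (g.bx + (ix + (sx > 0 ? 1 : 0)) * g.sx - p[0]) / d[0] : inf;
    double tmy = d[1] != 0
      ? (g.by + (iy + (sy > 0 ? 1 : 0)) * g.sy - p[1]) / d[1] : inf;
    double tmz = d[2] != 0
      ? (g.bz + (iz + (sz > 0 ? 1 : 0)) * g.sz - p[2]) / d[2] : inf;
    double tcur = t0;
    while (ix >= 0 && ix < g.nx && iy >= 0 && iy < g.ny &&
           iz >= 0 && iz < g.nz) {
      double tnext = std::min(tmx, std::min(tmy, tmz));
      if (tnext > t1) tnext = t1;
      if (tnext > tcur) {
        vix.push_back(ix + 1); viy.push_back(iy + 1); viz.push_back(iz + 1);
        vlen.push_back(tnext - tcur);
      }
      tcur = tnext;
      if (tcur >= t1 - 1e-15) break;
      if (tmx <= tmy && tmx <= tmz) { ix += sx; tmx += tdx; }
      else if (tmy <= tmz)          { iy += sy; tmy += tdy; }
      else                          { iz += sz; tmz += tdz; }
    }
  }
  return List::create(_["ix"] = vix, _["iy"] = viy, _["iz"] = viz,
                      _["length"] = vlen);
}

// 6-connectivity component labelling of a logical 3D mask.
// [[Rcpp::export]]
IntegerVector label_components6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  int current = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++current;
    stack.push_back(s);
    lab[s] = current;
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      int ix = (int)(v % nx);
      int iy = (int)((v / nx) % ny);
      int iz = (int)(v / ((long)nx * ny));
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int jx = ix + off[k][0], jy = iy + off[k][1], jz = iz + off[k][2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        long w = (long)jx + (long)nx * ((long)jy + (long)ny * jz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = current;
  return lab;
}
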