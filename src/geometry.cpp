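#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
#include <random>

using namespace Rcpp;

// Deterministic uniforms from a self-contained Mersenne Twister stream so
// seed realizations are reproducible independently of R's RNG state.
namespace {

struct MT {
  std::mt19937 gen;
  explicit MT(uint32_t seed) : gen(seed) {}
  double runif() { return (static_cast<double>(gen()) + 0.5) / 4294967296.0; }
  // Marsaglia polar method; deterministic given the stream.
  void rnorm3(double out[3]) {
    int filled = 0;
    while (filled < 3) {
      double u = 2.0 * runif() - 1.0, v = 2.0 * runif() - 1.0;
      double s = u * u + v * v;
      if (s >= 1.0 || s == 0.0) continue;
      double f = std::sqrt(-2.0 * std::log(s) / s);
      out[filled++] = u * f;
      if (filled < 3) out[filled++] = v * f;
    }
  }
};

inline int containing_voxel(double x) { return static_cast<int>(std::lround(x)); }

} // namespace

// Poisson-disk sample restricted to the voxels carrying lungLabel.
// Coordinates are continuous, in voxel units; voxel centre of index i is i.
// [[Rcpp::export(name = ".bridsonSampleCpp")]]
NumericMatrix bridson_sample_cpp(IntegerVector mask, IntegerVector dims,
                                 int lungLabel, double r, int rngSeed,
                                 int kAttempts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto lab = [&](int x, int y, int z) -> int {
    return mask[x + nx * (y + static_cast<R_xlen_t>(ny) * z)];
  };

  std::vector<int> lungIdx;
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (mask[i] == lungLabel) lungIdx.push_back(static_cast<int>(i));
  if (lungIdx.empty()) stop("lung label %d is empty", lungLabel);

  MT rng(static_cast<uint32_t>(rngSeed));

  // Background grid: cell size r/sqrt(3) guarantees <=1 point per cell.
  const double cell = r / std::sqrt(3.0);
  const int gx = static_cast<int>(std::floor(nx / cell)) + 1;
  const int gy = static_cast<int>(std::floor(ny / cell)) + 1;
  const int gz = static_cast<int>(std::floor(nz / cell)) + 1;
  std::vector<int> grid(static_cast<size_t>(gx) * gy * gz, -1);
  auto gcell = [&](double x, double y, double z) -> size_t {
    int cx = static_cast<int>(std::floor(x / cell));
    int cy = static_cast<int>(std::floor(y / cell));
    int cz = static_cast<int>(std::floor(z / cell));
    return static_cast<size_t>(cx) + static_cast<size_t>(gx) *
           (static_cast<size_t>(cy) + static_cast<size_t>(gy) * cz);
  };

  std::vector<double> px, py, pz;
  std::vector<int> active;

  auto too_close = [&](double x, double y, double z) -> bool {
    int cx = static_cast<int>(std::floor(x / cell));
    int cy = static_cast<int>(std::floor(y / cell));
    int cz = static_cast<int>(std::floor(z / cell));
    for (int dz = -2; dz <= 2; ++dz) {
      int zz = cz + dz; if (zz < 0 || zz >= gz) continue;
      for (int dy = -2; dy <= 2; ++dy) {
        int yy = cy + dy; if (yy < 0 || yy >= gy) continue;
        for (int dx = -2; dx <= 2; ++dx) {
          int xx = cx + dx; if (xx < 0 || xx >= gx) continue;
          int pi = grid[static_cast<size_t>(xx) + static_cast<size_t>(gx) *
                        (static_cast<size_t>(yy) + static_cast<size_t>(gy) * zz)];
          if (pi >= 0) {
            double ddx = px[pi] - x, ddy = py[pi] - y, ddz = pz[pi] - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz < r * r) return true;
          }
        }
      }
    }
    return false;
  };

  auto add_point = [&](double x, double y, double z) {
    int id = static_cast<int>(px.size());
    px.push_back(x); py.push_back(y); pz.push_back(z);
    grid[gcell(x, y, z)] = id;
    active.push_back(id);
  };

  // Initial point: uniform over lung voxels, placed at the voxel centre.
  {
    int pick = lungIdx[static_cast<size_t>(rng.runif() * lungIdx.size())];
    int z0 = pick / (nx * ny), rem = pick % (nx * ny);
    int y0 = rem / nx, x0 = rem % nx;
    add_point(x0, y0, z0);
  }

  while (!active.empty()) {
    size_t ai = static_cast<size_t>(rng.runif() * active.size());
    int pi = active[ai];
    bool found = false;
    for (int k = 0; k < kAttempts; ++k) {
      // radius volume-uniform on [r, 2r); direction uniform on the sphere
      double u = rng.runif();
      double rad = r * std::cbrt(1.0 + 7.0 * u);
      double d[3];
      rng.rnorm3(d);
      double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (nrm == 0.0) continue;
      double cx = px[pi] + rad * d[0] / nrm;
      double cy = py[pi] + rad * d[1] / nrm;
      double cz = pz[pi] + rad * d[2] / nrm;
      int vx = containing_voxel(cx), vy = containing_voxel(cy),
          vz = containing_voxel(cz);
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      if (lab(vx, vy, vz) != lungLabel) continue;
      if (too_close(cx, cy, cz)) continue;
      add_point(cx, cy, cz);
      found = true;
      break;
    }
    if (!found) {
      active[ai] = active.back();
      active.pop_back();
    }
  }

  NumericMatrix out(static_cast<int>(px.size()), 3);
  for (size_t i = 0; i < px.size(); ++i) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
  }
  return out;
}

// Label each lung voxel with the 1-based index of its nearest seed
// (Euclidean, voxel units); ties broken toward the lowest seed index.
// [[Rcpp::export(name = ".voronoiAssignCpp")]]
IntegerVector voronoi_assign_cpp(IntegerVector mask, IntegerVector dims,
                                 int lungLabel, NumericMatrix seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = seeds.nrow();
  IntegerVector out(mask.size(), 0);
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (mask[idx] != lungLabel) continue;
        double best = R_PosInf;
        int bi = 0;
        for (int k = 0; k < K; ++k) {
          double dx = seeds(k, 0) - x, dy = seeds(k, 1) - y,
                 dz = seeds(k, 2) - z;
          double d = dx * dx + dy * dy + dz * dz;
          if (d < best) { best = d; bi = k + 1; }
        }
        out[idx] = bi;
      }
  out.attr("dim") = dims;
  return out;
}

// Trilinear resampling onto an isotropic grid. Voxel centre of output
// index j sits at physical position j*iso; input index = position/spacing,
// clamped to the valid range at the borders.
// [[Rcpp::export(name = ".resampleTrilinearCpp")]]
NumericVector resample_trilinear_cpp(NumericVector values, IntegerVector dims,
                                     NumericVector spacing, double iso,
                                     IntegerVector outDims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = outDims[0], oy = outDims[1], oz = outDims[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  auto val = [&](int x, int y, int z) -> double {
    return values[x + nx * (y + static_cast<R_xlen_t>(ny) * z)];
  };
  R_xlen_t o = 0;
  for (int z = 0; z < oz; ++z) {
    double fz = z * iso / spacing[2];
    if (fz < 0) fz = 0;
    if (fz > nz - 1) fz = nz - 1;
    int z0 = static_cast<int>(std::floor(fz));
    if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
    double tz = nz > 1 ? fz - z0 : 0.0;
    int z1 = nz > 1 ? z0 + 1 : 0;
    for (int y = 0; y < oy; ++y) {
      double fy = y * iso / spacing[1];
      if (fy < 0) fy = 0;
      if (fy > ny - 1) fy = ny - 1;
      int y0 = static_cast<int>(std::floor(fy));
      if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
      double ty = ny > 1 ? fy - y0 : 0.0;
      int y1 = ny > 1 ? y0 + 1 : 0;
      for (int x = 0; x < ox; ++x, ++o) {
        double fx = x * iso / spacing[0];
        if (fx < 0) fx = 0;
        if (fx > nx - 1) fx = nx - 1;
        int x0 = static_cast<int>(std::floor(fx));
        if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
        double tx = nx > 1 ? fx - x0 : 0.0;
        int x1 = nx > 1 ? x0 + 1 : 0;
        double c00 = val(x0, y0, z0) * (1 - tx) + val(x1, y0, z0) * tx;
        double c10 = val(x0, y1, z0) * (1 - tx) + val(x1, y1, z0) * tx;
        double c01 = val(x0, y0, z1) * (1 - tx) + val(x1, y0, z1) * tx;
        double c11 = val(x0, y1, z1) * (1 - tx) + val(x1, y1, z1) * tx;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[o] = c0 * (1 - tz) + c1 * tz;
      }
    }
  }
  out.attr("dim") = outDims;
  return out;
}

// Nearest-neighbour resampling for integer label maps.
// [[Rcpp::export(name = ".resampleNearestCpp")]]
IntegerVector resample_nearest_cpp(IntegerVector labels, IntegerVector dims,
                                   NumericVector spacing, double iso,
                                   IntegerVector outDims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = outDims[0], oy = outDims[1], oz = outDims[2];
  IntegerVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  auto clampi = [](long v, int lo, int hi) -> int {
    if (v < lo) return lo;
    if (v > hi) return hi;
    return static_cast<int>(v);
  };
  R_xlen_t o = 0;
  for (int z = 0; z < oz; ++z) {
    int zi = clampi(std::lround(z * iso / spacing[2]), 0, nz - 1);
    for (int y = 0; y < oy; ++y) {
      int yi = clampi(std::lround(y * iso / spacing[1]), 0, ny - 1);
      for (int x = 0; x < ox; ++x, ++o) {
        int xi = clampi(std::lround(x * iso / spacing[0]), 0, nx - 1);
        out[o] = labels[xi + nx * (yi + static_cast<R_xlen_t>(ny) * zi)];
      }
    }
  }
  out.attr("dim") = outDims;
  return out;
}
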