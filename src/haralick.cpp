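#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-voxel 3D GLCM Haralick texture maps.
//
// For every voxel a local window of Chebyshev radius `window_radius`
// (default 3x3x3), truncated at the volume border, is scanned with the 13
// canonical symmetric distance-1 offsets. Each offset yields a symmetric
// normalized GLCM (every voxel pair is accumulated in both directions); the
// 8 Haralick statistics are computed per offset and averaged over the
// offsets that produced at least one co-occurring pair.
//
// Statistic conventions (p_ij over 0-based levels i,j; mu/sigma2 the
// marginal mean/variance, identical for rows and columns by symmetry):
//   Energy              sum p^2
//   Entropy             -sum p log2 p  (0 log 0 = 0)
//   InverseDifferenceMoment  sum p / (1 + (i-j)^2)
//   Inertia             sum (i-j)^2 p
//   ClusterShade        sum (i + j - 2 mu)^3 p
//   ClusterProminence   sum (i + j - 2 mu)^4 p
//   Correlation         sum (i-mu)(j-mu) p / sigma2   (0 when sigma2 = 0)
//   HaralickCorrelation sum (i+1)(j+1) p              (1-based autocorrelation)

static const int OFFSETS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0},
  {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export]]
List cpp_haralick_maps(NumericVector vol, IntegerVector dims, int n_levels,
                       int window_radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int r = window_radius;

  // quantize to [0, n_levels) with fixed bins over [0, 1]
  std::vector<int> q(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = vol[i];
    int lev = (int)std::floor(v * n_levels);
    if (lev < 0) lev = 0;
    if (lev >= n_levels) lev = n_levels - 1;
    q[i] = lev;
  }

  const int NFEAT = 8;
  std::vector<NumericVector> maps(NFEAT);
  for (int f = 0; f < NFEAT; ++f) maps[f] = NumericVector(n);

  // dense co-occurrence buffer with touched-cell bookkeeping
  std::vector<int> glcm((size_t)n_levels * n_levels, 0);
  std::vector<int> touched; touched.reserve(128);
  const double log2inv = 1.0 / std::log(2.0);

  double feat[NFEAT];
  double acc[NFEAT];

  for (int z = 0; z < nz; ++z) {
    const int z0 = std::max(0, z - r), z1 = std::min(nz - 1, z + r);
    for (int y = 0; y < ny; ++y) {
      const int y0 = std::max(0, y - r), y1 = std::min(ny - 1, y + r);
      for (int x = 0; x < nx; ++x) {
        const int x0 = std::max(0, x - r), x1 = std::min(nx - 1, x + r);

        for (int f = 0; f < NFEAT; ++f) acc[f] = 0.0;
        int n_valid_offsets = 0;

        for (int o = 0; o < 13; ++o) {
          const int dx = OFFSETS[o][0], dy = OFFSETS[o][1], dz = OFFSETS[o][2];
          int total = 0;

          for (int cz = z0; cz <= z1; ++cz) {
            const int pz = cz + dz;
            if (pz < z0 || pz > z1) continue;
            for (int cy = y0; cy <= y1; ++cy) {
              const int py = cy + dy;
              if (py < y0 || py > y1) continue;
              const R_xlen_t rowA = ((R_xlen_t)cz * ny + cy) * nx;
              const R_xlen_t rowB = ((R_xlen_t)pz * ny + py) * nx;
              for (int cx = x0; cx <= x1; ++cx) {
                const int px = cx + dx;
                if (px < x0 || px > x1) continue;
                const int la = q[rowA + cx];
                const int lb = q[rowB + px];
                int cellA = la * n_levels + lb;
                int cellB = lb * n_levels + la;
                if (glcm[cellA] == 0) touched.push_back(cellA);
                glcm[cellA] += 1;
                if (cellB != cellA) {
                  if (glcm[cellB] == 0) touched.push_back(cellB);
                  glcm[cellB] += 1;
                } else {
                  glcm[cellB] += 1;
                }
                total += 2;
              }
            }
          }

          if (total > 0) {
            const double inv = 1.0 / total;
            // marginal mean / variance
            double mu = 0.0;
            for (size_t t = 0; t < touched.size(); ++t) {
              const int cell = touched[t];
              const double p = glcm[cell] * inv;
              mu += (cell / n_levels) * p;
            }
            double sigma2 = 0.0;
            for (size_t t = 0; t < touched.size(); ++t) {
              const int cell = touched[t];
              const double p = glcm[cell] * inv;
              const double di = cell / n_levels - mu;
              sigma2 += di * di * p;
            }
            for (int f = 0; f < NFEAT; ++f) feat[f] = 0.0;
            for (size_t t = 0; t < touched.size(); ++t) {
              const int cell = touched[t];
              const double p = glcm[cell] * inv;
              const int i = cell / n_levels, j = cell % n_levels;
              const double dij = (double)(i - j);
              const double s = i + j - 2.0 * mu;
              feat[0] += p * p;
              feat[1] -= p * std::log(p) * log2inv;
              feat[2] += p / (1.0 + dij * dij);
              feat[3] += dij * dij * p;
              feat[4] += s * s * s * p;
              feat[5] += s * s * s * s * p;
              feat[6] += (i - mu) * (j - mu) * p;
              feat[7] += (double)(i + 1) * (j + 1) * p;
            }
            feat[6] = (sigma2 > 1e-12) ? feat[6] / sigma2 : 0.0;
            for (int f = 0; f < NFEAT; ++f) acc[f] += feat[f];
            ++n_valid_offsets;
          }

          for (size_t t = 0; t < touched.size(); ++t) glcm[touched[t]] = 0;
          touched.clear();
        }

        const R_xlen_t vi = ((R_xlen_t)z * ny + y) * nx + x;
        if (n_valid_offsets > 0) {
          for (int f = 0; f < NFEAT; ++f) maps[f][vi] = acc[f] / n_valid_offsets;
        } else {
          for (int f = 0; f < NFEAT; ++f) maps[f][vi] = 0.0;
        }
      }
    }
  }

  return List::create(
    _["Energy"] = maps[0], _["Entropy"] = maps[1],
    _["InverseDifferenceMoment"] = maps[2], _["Inertia"] = maps[3],
    _["ClusterShade"] = maps[4], _["ClusterProminence"] = maps[5],
    _["Correlation"] = maps[6], _["HaralickCorrelation"] = maps[7]);
}
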