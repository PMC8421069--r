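#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Uniform-grid spatial hash over 3-D points for nearest-neighbour queries
// (tissue-grid assignment). Points and queries are n x 3 matrices in um.

namespace {

struct HashGrid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<int64_t, std::vector<int>> bins;

  int64_t key(int ix, int iy, int iz) const {
    return (static_cast<int64_t>(ix) << 42) ^ (static_cast<int64_t>(iy) << 21) ^
           static_cast<int64_t>(iz);
  }
  void build(const NumericMatrix &pts, double cell_size) {
    cell = cell_size;
    ox = oy = oz = R_PosInf;
    for (int i = 0; i < pts.nrow(); ++i) {
      ox = std::min(ox, pts(i, 0));
      oy = std::min(oy, pts(i, 1));
      oz = std::min(oz, pts(i, 2));
    }
    for (int i = 0; i < pts.nrow(); ++i) {
      int ix = static_cast<int>(std::floor((pts(i, 0) - ox) / cell));
      int iy = static_cast<int>(std::floor((pts(i, 1) - oy) / cell));
      int iz = static_cast<int>(std::floor((pts(i, 2) - oz) / cell));
      bins[key(ix, iy, iz)].push_back(i);
    }
  }
};

inline double sqdist(const NumericMatrix &a, int i, const NumericMatrix &b,
                     int j) {
  double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1), dz = a(i, 2) - b(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// [[Rcpp::export(name = ".nn_index")]]
IntegerVector nn_index(NumericMatrix points, NumericMatrix queries,
                       double cell_size) {
  HashGrid grid;
  grid.build(points, cell_size);
  int nq = queries.nrow();
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    int ix = static_cast<int>(std::floor((queries(q, 0) - grid.ox) / grid.cell));
    int iy = static_cast<int>(std::floor((queries(q, 1) - grid.oy) / grid.cell));
    int iz = static_cast<int>(std::floor((queries(q, 2) - grid.oz) / grid.cell));
    int best = -1;
    double bestd = R_PosInf;
    for (int ring = 0;; ++ring) {
      // search the cube shell of half-width `ring`
      for (int dx = -ring; dx <= ring; ++dx) {
        for (int dy = -ring; dy <= ring; ++dy) {
          for (int dz = -ring; dz <= ring; ++dz) {
            if (std::max({std::abs(dx), std::abs(dy), std::abs(dz)}) != ring)
              continue;
            auto it = grid.bins.find(grid.key(ix + dx, iy + dy, iz + dz));
            if (it == grid.bins.end()) continue;
            for (int p : it->second) {
              double d = sqdist(queries, q, points, p);
              if (d < bestd || (d == bestd && p < best)) {
                bestd = d;
                best = p;
              }
            }
          }
        }
      }
      if (best >= 0) {
        // candidates in farther shells can still be closer: continue until
        // the shell's minimum possible distance exceeds the best found
        double safe = ring * grid.cell;
        if (std::sqrt(bestd) <= safe) break;
      }
      if (ring > 4096) stop("nearest-neighbour search failed to terminate");
    }
    out[q] = best + 1; // 1-based
  }
  return out;
}
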