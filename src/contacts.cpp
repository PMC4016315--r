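#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Cell-list neighbour search: flags every query atom that lies within
// `cutoff` of at least one target atom. Cells are cubes of edge =
// cutoff, so each query atom only scans the 27 surrounding cells.
// Contract: output identical to the all-pairs scan.

static inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one key
  const int64_t B = 1 << 20;
  return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
         ((int64_t)(iz + B));
}

// [[Rcpp::export]]
LogicalVector atoms_within_cutoff(NumericVector qx, NumericVector qy,
                                  NumericVector qz, NumericVector tx,
                                  NumericVector ty, NumericVector tz,
                                  double cutoff) {
  const int nq = qx.size(), nt = tx.size();
  LogicalVector hit(nq);
  if (nq == 0 || nt == 0) return hit;
  const double c2 = cutoff * cutoff, inv = 1.0 / cutoff;

  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(nt * 2);
  for (int j = 0; j < nt; ++j) {
    int ix = (int)std::floor(tx[j] * inv);
    int iy = (int)std::floor(ty[j] * inv);
    int iz = (int)std::floor(tz[j] * inv);
    grid[cell_key(ix, iy, iz)].push_back(j);
  }

  for (int i = 0; i < nq; ++i) {
    int ix = (int)std::floor(qx[i] * inv);
    int iy = (int)std::floor(qy[i] * inv);
    int iz = (int)std::floor(qz[i] * inv);
    bool found = false;
    for (int dx = -1; dx <= 1 && !found; ++dx)
      for (int dy = -1; dy <= 1 && !found; ++dy)
        for (int dz = -1; dz <= 1 && !found; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddx = qx[i] - tx[j], ddy = qy[i] - ty[j],
                   ddz = qz[i] - tz[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
              found = true;
              break;
            }
          }
        }
    hit[i] = found;
  }
  return hit;
}
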