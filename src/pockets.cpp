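#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Protein-solvent-protein scan: a solvent voxel is a pocket candidate when at
// least `threshold` of 7 scan lines (3 axes + 4 body diagonals) through it hit
// protein on BOTH sides before leaving the lattice. Rays are unlimited within
// the lattice.
// [[Rcpp::export]]
LogicalVector cpp_psp_scan(LogicalVector protein, IntegerVector dims,
                           int threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  static const int dir[7][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1},
                                {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {-1, 1, 1}};
  LogicalVector out(protein.size(), false);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t c = i + sy * j + sz * k;
        if (protein[c]) continue;
        int enclosed = 0;
        for (int d = 0; d < 7 && enclosed < threshold; ++d) {
          bool hit_both = true;
          for (int sgn = -1; sgn <= 1 && hit_both; sgn += 2) {
            int x = i, y = j, z = k;
            bool hit = false;
            for (;;) {
              x += sgn * dir[d][0]; y += sgn * dir[d][1]; z += sgn * dir[d][2];
              if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) break;
              if (protein[x + sy * y + sz * z]) { hit = true; break; }
            }
            if (!hit) hit_both = false;
          }
          if (hit_both) ++enclosed;
        }
        if (enclosed >= threshold) out[c] = true;
      }
    }
  }
  return out;
}

// Connected-component labelling of a voxel mask (connectivity 6 or 26).
// Returns 0 for background, 1..k for components.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < mask.size(); ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t c = stack.back();
      stack.pop_back();
      const int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / sz);
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
              continue;
            const int x = i + di, y = j + dj, z = k + dk;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
            const R_xlen_t n = x + sy * y + sz * z;
            if (mask[n] && !lab[n]) { lab[n] = next; stack.push_back(n); }
          }
        }
      }
    }
  }
  return lab;
}
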