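#ifndef GOLDSAM_CELLS_H
#define GOLDSAM_CELLS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Cell-list neighbour search for slab geometry: X and Y periodic
// (minimum image), Z open.  Cells are cubic-ish with edge >= `cutoff`.

struct CellList {
  int nx, ny, nz;
  double lx, ly, zmin, czx, czy, czz;
  bool pbc;
  std::vector<std::vector<int> > cells;

  CellList(const Rcpp::NumericMatrix &pos, const std::vector<int> &idx,
           double lx_, double ly_, double cutoff, bool pbc_xy)
      : lx(lx_), ly(ly_), pbc(pbc_xy) {
    nx = std::max(1, (int)std::floor(lx / cutoff));
    ny = std::max(1, (int)std::floor(ly / cutoff));
    double zlo = R_PosInf, zhi = R_NegInf;
    for (size_t k = 0; k < idx.size(); ++k) {
      double z = pos(idx[k], 2);
      if (z < zlo) zlo = z;
      if (z > zhi) zhi = z;
    }
    zmin = zlo;
    nz = std::max(1, (int)std::floor((zhi - zlo) / cutoff));
    czx = lx / nx; czy = ly / ny; czz = (zhi - zlo) / nz + 1e-12;
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (size_t k = 0; k < idx.size(); ++k) {
      cells[cell_of(pos(idx[k], 0), pos(idx[k], 1), pos(idx[k], 2))]
          .push_back(idx[k]);
    }
  }

  int wrap(int i, int n) const { return ((i % n) + n) % n; }

  size_t cell_of(double x, double y, double z) const {
    int ix = (int)std::floor(x / czx), iy = (int)std::floor(y / czy);
    int iz = (int)std::floor((z - zmin) / czz);
    ix = wrap(ix, nx); iy = wrap(iy, ny);
    if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
    return (size_t)(iz * ny + iy) * nx + ix;
  }

  // minimum-image displacement (XY only when pbc)
  inline void mi(double &dx, double &dy) const {
    if (!pbc) return;
    dx -= lx * std::floor(dx / lx + 0.5);
    dy -= ly * std::floor(dy / ly + 0.5);
  }

  template <class F> void for_pairs(const Rcpp::NumericMatrix &pos, F fun) {
    std::vector<size_t> seen;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          const std::vector<int> &home =
              cells[(size_t)(iz * ny + iy) * nx + ix];
          if (home.empty()) continue;
          seen.clear();
          for (int dz = -1; dz <= 1; ++dz) {
            int jz = iz + dz;
            if (jz < 0 || jz >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int jy = pbc ? wrap(iy + dy, ny) : iy + dy;
              if (jy < 0 || jy >= ny) continue;
              for (int dx = -1; dx <= 1; ++dx) {
                int jx = pbc ? wrap(ix + dx, nx) : ix + dx;
                if (jx < 0 || jx >= nx) continue;
                size_t cid = (size_t)(jz * ny + jy) * nx + jx;
                // wrapped neighbours can coincide on narrow grids
                bool dup = false;
                for (size_t s = 0; s < seen.size(); ++s)
                  if (seen[s] == cid) { dup = true; break; }
                if (dup) continue;
                seen.push_back(cid);
                const std::vector<int> &other = cells[cid];
                for (size_t a = 0; a < home.size(); ++a)
                  for (size_t b = 0; b < other.size(); ++b) {
                    int i = home[a], j = other[b];
                    if (i >= j) continue;  // each pair once
                    double ddx = pos(i, 0) - pos(j, 0);
                    double ddy = pos(i, 1) - pos(j, 1);
                    double ddz = pos(i, 2) - pos(j, 2);
                    mi(ddx, ddy);
                    fun(i, j, ddx, ddy, ddz);
                  }
              }
            }
          }
        }
  }
};

#endif
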