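#include "cells.h"
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.  Each selected atom gets
// a deterministic Fibonacci lattice of `n_points` test points on its
// expanded sphere (vdw + probe); a point is accessible when it lies
// outside every neighbour's expanded sphere.  Occluders are the selected
// atoms themselves; X/Y are treated with the minimum image.  Returns the
// per-atom accessible area in nm^2 for the selected atoms.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix pos, NumericVector box,
                       IntegerVector sel, NumericVector radius_exp,
                       int n_points, bool pbc_xy) {
  const int ns = sel.size();
  NumericVector area(ns);
  if (ns == 0) return area;
  const double lx = box[0], ly = box[1];

  // Fibonacci sphere lattice (unit sphere)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    px[k] = rho * std::cos(phi);
    py[k] = rho * std::sin(phi);
    pz[k] = z;
  }

  double rmax = 0.0;
  for (int a = 0; a < ns; ++a) rmax = std::max(rmax, radius_exp[a]);

  // neighbour lists among selected atoms within r_i + r_j
  std::vector<std::vector<int> > nb(ns);
  std::vector<int> idx(ns);
  std::vector<int> which_sel(pos.nrow(), -1);
  for (int a = 0; a < ns; ++a) {
    idx[a] = sel[a] - 1;
    which_sel[idx[a]] = a;
  }
  CellList cl(pos, idx, lx, ly, 2.0 * rmax + 1e-9, pbc_xy);
  cl.for_pairs(pos, [&](int i, int j, double dx, double dy, double dz) {
    int a = which_sel[i], b = which_sel[j];
    double lim = radius_exp[a] + radius_exp[b];
    if (dx * dx + dy * dy + dz * dz < lim * lim) {
      nb[a].push_back(b);
      nb[b].push_back(a);
    }
  });

  for (int a = 0; a < ns; ++a) {
    int i = idx[a];
    double ra = radius_exp[a];
    int n_free = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = pos(i, 0) + ra * px[k];
      double qy = pos(i, 1) + ra * py[k];
      double qz = pos(i, 2) + ra * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb[a].size(); ++m) {
        int b = nb[a][m];
        int j = idx[b];
        double dx = qx - pos(j, 0);
        double dy = qy - pos(j, 1);
        double dz = qz - pos(j, 2);
        if (pbc_xy) {
          dx -= lx * std::floor(dx / lx + 0.5);
          dy -= ly * std::floor(dy / ly + 0.5);
        }
        double rb = radius_exp[b];
        if (dx * dx + dy * dy + dz * dz < rb * rb) { buried = true; break; }
      }
      if (!buried) ++n_free;
    }
    area[a] = 4.0 * M_PI * ra * ra * n_free / n_points;
  }
  return area;
}
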