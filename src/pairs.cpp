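#include "cells.h"
using namespace Rcpp;

// Rational switching term [1-(r/r0)^a]/[1-(r/r0)^b] with the analytic
// limit a/b at r = r0.
static inline double switch_term_c(double r, double r0, int a, int b) {
  double x = r / r0;
  if (std::fabs(x - 1.0) < 1e-12) return (double)a / (double)b;
  return (1.0 - std::pow(x, a)) / (1.0 - std::pow(x, b));
}

// Sum of switching terms over heavy-atom pairs belonging to different
// groups (grafted chains), truncated at rtrunc.  `group` is one integer
// per row of `pos`; rows with group < 0 are ignored.
// [[Rcpp::export]]
double cpp_switch_sum(NumericMatrix pos, NumericVector box,
                      IntegerVector group, double r0, int a_exp, int b_exp,
                      double rtrunc, bool pbc_xy) {
  std::vector<int> idx;
  for (int i = 0; i < pos.nrow(); ++i)
    if (group[i] >= 0) idx.push_back(i);
  double cut = rtrunc;
  CellList cl(pos, idx, box[0], box[1], cut, pbc_xy);
  double total = 0.0;
  cl.for_pairs(pos, [&](int i, int j, double dx, double dy, double dz) {
    if (group[i] == group[j]) return;
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut * cut) return;
    total += switch_term_c(std::sqrt(r2), r0, a_exp, b_exp);
  });
  return total;
}

// All cross pairs (a in set A, b in set B) with distance strictly below
// `cutoff`.  setmask: 1 for A, 2 for B, 0 ignore.  Returns 1-based atom
// indices and distances.
// [[Rcpp::export]]
List cpp_cross_pairs(NumericMatrix pos, NumericVector box,
                     IntegerVector setmask, double cutoff, bool pbc_xy) {
  std::vector<int> idx;
  for (int i = 0; i < pos.nrow(); ++i)
    if (setmask[i] > 0) idx.push_back(i);
  std::vector<int> ia, ib;
  std::vector<double> dist;
  if (!idx.empty()) {
    CellList cl(pos, idx, box[0], box[1], cutoff, pbc_xy);
    cl.for_pairs(pos, [&](int i, int j, double dx, double dy, double dz) {
      if (setmask[i] == setmask[j]) return;
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cutoff * cutoff) return;
      int a = (setmask[i] == 1) ? i : j;
      int b = (setmask[i] == 1) ? j : i;
      ia.push_back(a + 1);
      ib.push_back(b + 1);
      dist.push_back(std::sqrt(r2));
    });
  }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ib),
                      _["dist"] = wrap(dist));
}

// Minimum cross-set distance (any pair a in A, b in B), brute force over
// the two sets with XY minimum image; used for convergence series where
// distances beyond any cutoff still matter.
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix pos, NumericVector box,
                          IntegerVector idx_a, IntegerVector idx_b,
                          bool pbc_xy) {
  double best = R_PosInf;
  double lx = box[0], ly = box[1];
  for (int a = 0; a < idx_a.size(); ++a) {
    int i = idx_a[a] - 1;
    for (int b = 0; b < idx_b.size(); ++b) {
      int j = idx_b[b] - 1;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (pbc_xy) {
        dx -= lx * std::floor(dx / lx + 0.5);
        dy -= ly * std::floor(dy / ly + 0.5);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  }
  return std::sqrt(best);
}
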