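#include "cells.h"
using namespace Rcpp;

// Overdamped (Brownian) position-update dynamics for grafted bead chains.
//
//   x <- x + mobility * dt * F + sqrt(2 * mobility * dt * kT) * N(0,1)
//
// Forces: harmonic bonds along each chain, soft excluded volume between all
// bead pairs, a short-range attractive well between beads of *different*
// chains, and an optional constant pulling force -mass*pull_acc along Z on
// flagged beads.  Grafted anchor beads are frozen; probe beads are frozen
// (mode 0) or take a shared vertical random walk (mode 1).  Z < 0 is a
// reflecting wall standing in for the gold slab; X/Y wrap periodically.
// Gaussian noise comes from R's RNG, so runs are reproducible via set.seed.
//
// Returns saved frames as an (n_atoms x 3 x n_saved) array; frame 1 is the
// initial configuration.
// [[Rcpp::export]]
NumericVector cpp_bd(NumericMatrix pos0, NumericVector box,
                     IntegerVector chain, LogicalVector attract,
                     LogicalVector fixed,
                     LogicalVector probe, NumericVector pull_mass,
                     IntegerMatrix bonds, IntegerMatrix angles,
                     IntegerMatrix graft_pairs, double k_bond,
                     double bond_length, double k_bend, double k_align,
                     double eps_attr, double r_attr, double a_ev,
                     double r_ev, double kT, double mobility, double dt,
                     int n_steps, int save_stride, double pull_acc,
                     int probe_mode, double probe_mobility) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0);
  const int n_saved = n_steps / save_stride + 1;
  NumericVector out(Dimension(n, 3, n_saved));
  const double lx = box[0], ly = box[1];
  const double pair_cut = std::max(r_attr, r_ev);
  const double noise_sd = std::sqrt(2.0 * mobility * dt * kT);
  const double step_limit = bond_length;      // hard stability bound
  const double cap = 0.25 * bond_length;      // deterministic-step cap

  std::vector<int> all_idx(n);
  for (int i = 0; i < n; ++i) all_idx[i] = i;

  NumericMatrix force(n, 3);
  RNGScope rng;

  auto save_frame = [&](int s) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) out[(size_t)s * n * 3 + d * n + i] = pos(i, d);
  };
  save_frame(0);

  int saved = 1;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(force.begin(), force.end(), 0.0);

    // bonds
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= lx * std::floor(dx / lx + 0.5);
      dy -= ly * std::floor(dy / ly + 0.5);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double f = -k_bond * (r - bond_length) / r;
      force(i, 0) += f * dx; force(i, 1) += f * dy; force(i, 2) += f * dz;
      force(j, 0) -= f * dx; force(j, 1) -= f * dy; force(j, 2) -= f * dz;
    }

    // bending: U = k_bend * (1 + cos theta) over consecutive triplets
    // (theta the i-j-k angle; straight chain has cos theta = -1), making
    // each chain a semiflexible rod
    if (k_bend > 0.0)
      for (int t = 0; t < angles.nrow(); ++t) {
        int i = angles(t, 0) - 1, j = angles(t, 1) - 1, k = angles(t, 2) - 1;
        double ax = pos(i, 0) - pos(j, 0), ay = pos(i, 1) - pos(j, 1),
               az = pos(i, 2) - pos(j, 2);
        double bx = pos(k, 0) - pos(j, 0), by = pos(k, 1) - pos(j, 1),
               bz = pos(k, 2) - pos(j, 2);
        ax -= lx * std::floor(ax / lx + 0.5);
        ay -= ly * std::floor(ay / ly + 0.5);
        bx -= lx * std::floor(bx / lx + 0.5);
        by -= ly * std::floor(by / ly + 0.5);
        double na = std::sqrt(ax * ax + ay * ay + az * az);
        double nb = std::sqrt(bx * bx + by * by + bz * bz);
        if (na < 1e-12 || nb < 1e-12) continue;
        double ct = (ax * bx + ay * by + az * bz) / (na * nb);
        // F_i = -dU/dr_i = -k/|a| * (b_hat - cos(theta) a_hat); the
        // straight chain (theta = pi, cos = -1) is the minimum
        double fi_x = -k_bend / na * (bx / nb - ct * ax / na);
        double fi_y = -k_bend / na * (by / nb - ct * ay / na);
        double fi_z = -k_bend / na * (bz / nb - ct * az / na);
        double fk_x = -k_bend / nb * (ax / na - ct * bx / nb);
        double fk_y = -k_bend / nb * (ay / na - ct * by / nb);
        double fk_z = -k_bend / nb * (az / na - ct * bz / nb);
        force(i, 0) += fi_x; force(i, 1) += fi_y; force(i, 2) += fi_z;
        force(k, 0) += fk_x; force(k, 1) += fk_y; force(k, 2) += fk_z;
        force(j, 0) -= fi_x + fk_x;
        force(j, 1) -= fi_y + fk_y;
        force(j, 2) -= fi_z + fk_z;
      }

    // graft alignment: U = k_align * (1 - b_z/|b|) on the first bond of
    // each grafted chain, biasing it toward the surface normal (the
    // orientational order a covalent surface anchor imposes)
    if (k_align > 0.0)
      for (int g = 0; g < graft_pairs.nrow(); ++g) {
        int i = graft_pairs(g, 0) - 1, j = graft_pairs(g, 1) - 1;
        double bx = pos(j, 0) - pos(i, 0), by = pos(j, 1) - pos(i, 1),
               bz = pos(j, 2) - pos(i, 2);
        bx -= lx * std::floor(bx / lx + 0.5);
        by -= ly * std::floor(by / ly + 0.5);
        double nb = std::sqrt(bx * bx + by * by + bz * bz);
        if (nb < 1e-12) continue;
        double n3 = nb * nb * nb;
        force(j, 0) += k_align * (-bz * bx / n3);
        force(j, 1) += k_align * (-bz * by / n3);
        force(j, 2) += k_align * (1.0 / nb - bz * bz / n3);
      }

    // non-bonded: excluded volume (all pairs) + inter-chain attraction
    if (a_ev > 0.0 || eps_attr > 0.0) {
      CellList cl(pos, all_idx, lx, ly, pair_cut, true);
      cl.for_pairs(pos, [&](int i, int j, double dx, double dy, double dz) {
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= pair_cut * pair_cut || r2 < 1e-24) return;
        double r = std::sqrt(r2);
        double f = 0.0;  // force magnitude along +d on i (repulsive > 0)
        if (r < r_ev && a_ev > 0.0)
          f += 2.0 * a_ev * (1.0 - r / r_ev) / r_ev;
        if (eps_attr > 0.0 && r < r_attr && attract[i] && attract[j] &&
            chain[i] != chain[j]) {
          double u = 1.0 - r2 / (r_attr * r_attr);
          f -= 4.0 * eps_attr * r * u / (r_attr * r_attr);
        }
        if (f == 0.0) return;
        double fx = f * dx / r, fy = f * dy / r, fz = f * dz / r;
        force(i, 0) += fx; force(i, 1) += fy; force(i, 2) += fz;
        force(j, 0) -= fx; force(j, 1) -= fy; force(j, 2) -= fz;
      });
    }

    // constant pulling toward the surface on flagged beads
    if (pull_acc > 0.0)
      for (int i = 0; i < n; ++i)
        if (pull_mass[i] > 0.0) force(i, 2) -= pull_mass[i] * pull_acc;

    // shared vertical diffusion of the rigid probe: one draw per step
    double probe_dz = 0.0;
    if (probe_mode == 1) {
      probe_dz = std::sqrt(2.0 * probe_mobility * dt * kT) * R::norm_rand();
    }

    for (int i = 0; i < n; ++i) {
      if (probe[i]) {
        if (probe_mode == 1) pos(i, 2) = std::fabs(pos(i, 2) + probe_dz);
        continue;
      }
      if (fixed[i]) continue;
      double mx = mobility * dt * force(i, 0);
      double my = mobility * dt * force(i, 1);
      double mz = mobility * dt * force(i, 2);
      // cap the deterministic displacement (nve/limit-style): steep
      // excluded-volume transients during cluster collapse otherwise
      // demand a far smaller global timestep than the equilibrium
      // dynamics needs
      double dn = std::sqrt(mx * mx + my * my + mz * mz);
      if (dn > cap) { mx *= cap / dn; my *= cap / dn; mz *= cap / dn; }
      if (noise_sd > 0.0) {
        mx += noise_sd * R::norm_rand();
        my += noise_sd * R::norm_rand();
        mz += noise_sd * R::norm_rand();
      }
      if (std::fabs(mx) > step_limit || std::fabs(my) > step_limit ||
          std::fabs(mz) > step_limit) {
        stop("unstable step at t = %g ps: bead displacement exceeds the "
             "bond length; reduce timestep or forces", step * dt);
      }
      double x = pos(i, 0) + mx, y = pos(i, 1) + my, z = pos(i, 2) + mz;
      x -= lx * std::floor(x / lx);
      y -= ly * std::floor(y / ly);
      if (z < 0.0) z = -z;  // reflecting gold wall
      pos(i, 0) = x; pos(i, 1) = y; pos(i, 2) = z;
    }

    if (step % save_stride == 0) save_frame(saved++);
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Total potential energy of a configuration under the same force field
// (bonds + excluded volume + inter-chain attraction); used to check that
// zero-temperature runs relax monotonically.
// [[Rcpp::export]]
double cpp_bd_energy(NumericMatrix pos, NumericVector box,
                     IntegerVector chain, LogicalVector attract,
                     IntegerMatrix bonds,
                     IntegerMatrix angles, IntegerMatrix graft_pairs,
                     double k_bond, double bond_length, double k_bend,
                     double k_align, double eps_attr,
                     double r_attr, double a_ev, double r_ev) {
  const double lx = box[0], ly = box[1];
  double e = 0.0;
  if (k_align > 0.0)
    for (int g = 0; g < graft_pairs.nrow(); ++g) {
      int i = graft_pairs(g, 0) - 1, j = graft_pairs(g, 1) - 1;
      double bx = pos(j, 0) - pos(i, 0), by = pos(j, 1) - pos(i, 1),
             bz = pos(j, 2) - pos(i, 2);
      bx -= lx * std::floor(bx / lx + 0.5);
      by -= ly * std::floor(by / ly + 0.5);
      double nb = std::sqrt(bx * bx + by * by + bz * bz);
      if (nb > 1e-12) e += k_align * (1.0 - bz / nb);
    }
  if (k_bend > 0.0)
    for (int t = 0; t < angles.nrow(); ++t) {
      int i = angles(t, 0) - 1, j = angles(t, 1) - 1, k = angles(t, 2) - 1;
      double ax = pos(i, 0) - pos(j, 0), ay = pos(i, 1) - pos(j, 1),
             az = pos(i, 2) - pos(j, 2);
      double bx = pos(k, 0) - pos(j, 0), by = pos(k, 1) - pos(j, 1),
             bz = pos(k, 2) - pos(j, 2);
      ax -= lx * std::floor(ax / lx + 0.5);
      ay -= ly * std::floor(ay / ly + 0.5);
      bx -= lx * std::floor(bx / lx + 0.5);
      by -= ly * std::floor(by / ly + 0.5);
      double na = std::sqrt(ax * ax + ay * ay + az * az);
      double nb = std::sqrt(bx * bx + by * by + bz * bz);
      if (na < 1e-12 || nb < 1e-12) continue;
      e += k_bend * (1.0 + (ax * bx + ay * by + az * bz) / (na * nb));
    }
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    dx -= lx * std::floor(dx / lx + 0.5);
    dy -= ly * std::floor(dy / ly + 0.5);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    e += 0.5 * k_bond * (r - bond_length) * (r - bond_length);
  }
  const double pair_cut = std::max(r_attr, r_ev);
  std::vector<int> idx(pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i) idx[i] = i;
  CellList cl(pos, idx, lx, ly, pair_cut, true);
  cl.for_pairs(pos, [&](int i, int j, double dx, double dy, double dz) {
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= pair_cut * pair_cut) return;
    double r = std::sqrt(r2);
    if (r < r_ev) e += a_ev * (1.0 - r / r_ev) * (1.0 - r / r_ev);
    if (r < r_attr && attract[i] && attract[j] && chain[i] != chain[j]) {
      double u = 1.0 - r2 / (r_attr * r_attr);
      e -= eps_attr * u * u;
    }
  });
  return e;
}
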