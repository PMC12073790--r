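# Slab density profiles: the box is cut into Z slices of fixed width
# (default 0.15 nm) measured from the gold plane, and the mass of the
# selected atoms is histogrammed per slice and averaged over the analysis
# window.  1 u/nm^3 = 1.66054 kg/m^3.

.u_per_nm3_to_kg_m3 <- 1.66053906660

#' Mass-density profile along the surface normal
#'
#' Mass-weighted Z histogram of a selection, averaged over the frames in a
#' time window.  Z is measured from the gold plane (mean gold-atom Z of
#' each frame; 0 for gold-free synthetic brushes, whose reflecting floor
#' is at Z = 0).  Atoms are binned by point position.  With `group_by =
#' "moiety"` one density column per moiety present in the selection is
#' returned.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices (see [select_atoms()]); default all atoms
#'   except gold and ions.
#' @param window `(t_start, t_end)` ps, or `NULL` for all frames.
#' @param slice_width slice thickness in nm.
#' @param group_by `"none"` (one column) or `"moiety"`.
#' @return object of class `sam_density_profile`: list with `z_centers`
#'   (nm), `density` (matrix, kg/m^3, one column per group), `slice_width`,
#'   `window`, `box_xy_area` (nm^2) and `total_mass` (u, per group).
#' @export
#' @examples
#' tr <- simulate_brush(synthetic_params(n_chains = 4, n_steps = 200))
#' pr <- density_profile(tr)
#' head(as.data.frame(pr))
density_profile <- function(traj, selection = NULL, window = NULL,
                            slice_width = 0.15,
                            group_by = c("none", "moiety")) {
  group_by <- match.arg(group_by)
  top <- traj$topology
  if (is.null(selection)) {
    selection <- select_atoms(top, moiety = c("linker", "peptide", "protein"))
  }
  if (!length(selection)) stop("empty selection")
  if (slice_width <= 0) stop("slice_width must be > 0 nm")
  idx <- frames_in_window(traj, window)
  times <- frame_times(traj)[idx]

  groups <- if (group_by == "moiety") top$moiety[selection]
            else rep("all", length(selection))
  glev <- unique(groups)
  mass <- top$mass[selection]

  # common grid across frames: from the lowest referenced Z (usually 0)
  zs <- lapply(idx, function(k) {
    traj$frames[[k]]$positions[selection, 3] -
      gold_plane_z(top, traj$frames[[k]])
  })
  zmin <- min(0, floor(min(unlist(zs)) / slice_width) * slice_width)
  zmax <- max(unlist(zs)) + slice_width
  breaks <- seq(zmin, zmax + slice_width, by = slice_width)
  nb <- length(breaks) - 1L

  dens <- matrix(0, nb, length(glev), dimnames = list(NULL, glev))
  for (f in seq_along(idx)) {
    bin <- findInterval(zs[[f]], breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (g in seq_along(glev)) {
      sel_g <- groups == glev[g]
      dens[, g] <- dens[, g] +
        vapply(split(mass[sel_g], factor(bin[sel_g], levels = seq_len(nb))),
               sum, numeric(1))
    }
  }
  area <- traj$frames[[idx[1]]]$box[1] * traj$frames[[idx[1]]]$box[2]
  vol <- area * slice_width            # nm^3 per slice
  dens <- dens / (length(idx) * vol) * .u_per_nm3_to_kg_m3
  total_mass <- vapply(glev, function(g) sum(mass[groups == g]), numeric(1))
  structure(list(z_centers = breaks[-length(breaks)] + slice_width / 2,
                 density = dens, slice_width = slice_width,
                 window = range(times), box_xy_area = area,
                 total_mass = total_mass),
            class = "sam_density_profile")
}

#' @export
as.data.frame.sam_density_profile <- function(x, ...) {
  data.frame(z_center = x$z_centers, x$density, check.names = FALSE)
}

#' @export
print.sam_density_profile <- function(x, ...) {
  cat(sprintf("<sam_density_profile> %d slices of %.3g nm, window %g..%g ps\n",
              length(x$z_centers), x$slice_width, x$window[1], x$window[2]))
  cat("  groups:", paste(colnames(x$density), collapse = ", "), "\n")
  invisible(x)
}

# integrated mass (u) of a profile column, for conservation checks
profile_mass <- function(profile, group = 1) {
  sum(profile$density[, group]) * profile$slice_width *
    profile$box_xy_area / .u_per_nm3_to_kg_m3
}

#' Outermost distance at which a profile reaches a threshold density
#'
#' Scans from the solvent side toward the surface and returns the Z of the
#' outermost downward crossing of `threshold`, linearly interpolated
#' between slice centers.  This tracks the outer extent of the monolayer
#' (the corona-thickness proxy); interior dips below the threshold are
#' ignored.
#'
#' @param profile a [density_profile()].
#' @param threshold density in kg/m^3 (convergence convention: 200).
#' @param group density column to use.
#' @return distance in nm, or `NA` with a warning when the profile never
#'   reaches the threshold.
#' @export
threshold_distance <- function(profile, threshold = 200, group = 1) {
  d <- profile$density[, group]
  z <- profile$z_centers
  if (!length(d)) stop("empty profile")
  above <- which(d >= threshold)
  if (!length(above)) {
    warning("profile never reaches ", threshold, " kg/m^3")
    return(NA_real_)
  }
  k <- max(above)              # outermost slice at/above threshold
  if (k == length(d)) return(z[k])
  # interpolate between centre k (>= thr) and centre k+1 (< thr)
  z[k] + (d[k] - threshold) / (d[k] - d[k + 1]) * (z[k + 1] - z[k])
}

#' Shift of the density-weighted mean height between two profiles
#'
#' The monolayer's "average density position": the density-weighted mean Z
#' of a profile column.  The shift is `after - before`; negative values
#' mean the mass moved toward the surface (the tensile-test reading).
#'
#' @param before,after [density_profile()]s on matching slice grids.
#' @param group density column to use.
#' @return shift in nm.
#' @export
density_centroid_shift <- function(before, after, group = 1) {
  nb <- min(length(before$z_centers), length(after$z_centers))
  if (abs(before$slice_width - after$slice_width) > 1e-9 ||
      max(abs(before$z_centers[seq_len(nb)] - after$z_centers[seq_len(nb)])) >
        1e-9) {
    stop("profiles are on different slice grids")
  }
  wmean <- function(p) sum(p$z_centers * p$density[, group]) /
    sum(p$density[, group])
  wmean(after) - wmean(before)
}

#' Convergence series: mean minimum peptide-protein distance
#'
#' Identifies the qualifying peptides -- grafted chains with at least one
#' heavy side-chain atom within `qualify_cutoff` of the protein selection
#' at any time in the qualification window -- then reports, per frame, the
#' mean over qualifying peptides of their minimum side-chain-to-protein
#' heavy-atom distance.  A flat series signals an equilibrated interface.
#'
#' @param traj a [trajectory()] containing a protein moiety.
#' @param protein_sel protein atom indices; default all heavy protein
#'   atoms.
#' @param window qualification and reporting window `(t_start, t_end)` ps;
#'   default the whole trajectory.
#' @param qualify_cutoff qualification distance in nm.
#' @return data.frame with columns `time` (ps) and `mean_min_dist` (nm);
#'   zero rows (with a warning) when no peptide qualifies.
#' @export
convergence_min_distance <- function(traj, protein_sel = NULL, window = NULL,
                                     qualify_cutoff = 0.7) {
  top <- traj$topology
  if (is.null(protein_sel)) {
    protein_sel <- select_atoms(top, moiety = "protein", heavy_only = TRUE)
  }
  if (!length(protein_sel)) stop("no protein atoms in selection")
  idx <- frames_in_window(traj, window)
  times <- frame_times(traj)[idx]
  chains <- sort(unique(top$peptide_index[top$peptide_index > 0]))
  sc <- lapply(chains, function(cc) {
    select_atoms(top, peptide_index = cc, heavy_only = TRUE,
                 sidechain_only = TRUE)
  })
  keep <- lengths(sc) > 0
  chains <- chains[keep]; sc <- sc[keep]
  dmat <- matrix(NA_real_, length(idx), length(chains))
  for (f in seq_along(idx)) {
    frm <- traj$frames[[idx[f]]]
    for (c0 in seq_along(chains)) {
      dmat[f, c0] <- cpp_min_cross_dist(frm$positions, frm$box,
                                        sc[[c0]], protein_sel, TRUE)
    }
  }
  qualifying <- which(apply(dmat, 2, min) < qualify_cutoff)
  if (!length(qualifying)) {
    warning("no peptide has a heavy side-chain atom within ",
            qualify_cutoff, " nm of the protein in the window")
    return(data.frame(time = numeric(0), mean_min_dist = numeric(0)))
  }
  data.frame(time = times,
             mean_min_dist = rowMeans(dmat[, qualifying, drop = FALSE]))
}
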