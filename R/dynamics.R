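# Desk-scale Brownian dynamics of a grafted bead brush.  One bead per
# residue (peptide beads flagged is_calpha; single-bead residues double as
# their own side chain), `linker_beads` linker beads below, the first bead
# frozen at its graft site.  The integrator is overdamped:
#
#   x <- x + mobility * dt * F + sqrt(2 * mobility * dt * temperature_factor) * N(0,1)
#
# so `temperature_factor` plays the role of kT in the reduced energy unit
# of the force field.  This generates trajectories with controllable
# morphology (clustered vs grid) for exercising the analyses; it makes no
# claim to physical kinetics.

#' Parameters for a synthetic brush simulation
#'
#' @param n_chains number of grafted chains.
#' @param beads_per_chain peptide beads per chain (1 bead ~ 1 residue).
#' @param linker_beads linker beads below the peptide block.
#' @param graft_spacing anchor grid spacing in nm.
#' @param bond_length equilibrium bond length in nm.
#' @param bond_stiffness harmonic bond constant (energy nm^-2).
#' @param bending_stiffness angle stiffness (energy units) of the
#'   `k*(1 + cos theta)` term over consecutive bead triplets; makes chains
#'   semiflexible rods (0 = freely jointed).
#' @param graft_alignment strength (energy units) of the `k*(1 - cos phi)`
#'   bias of each grafted chain's first bond toward the surface normal --
#'   the orientational order a covalent surface anchor imposes (0 = free
#'   swivel).
#' @param interchain_attraction depth (energy units) of the attractive well
#'   between *peptide* beads of different chains (linker beads do not
#'   aggregate, mirroring a non-sticky PEG phase); 0 disables it.
#' @param attraction_range range of the attractive well in nm.
#' @param excluded_volume_radius soft-core repulsion radius in nm.
#' @param excluded_strength repulsion strength (energy units).
#' @param temperature_factor dimensionless kT of the noise; 0 = quenched.
#' @param mobility bead mobility (nm^2 ps^-1 energy^-1).
#' @param timestep integration step in ps.
#' @param n_steps number of steps.
#' @param save_stride save a frame every this many steps.
#' @param seed integer seed (noise is drawn from R's RNG).
#' @param pull_acceleration constant tensile acceleration (nm ps^-2) applied
#'   along -Z to every is_calpha bead, scaled by bead mass; 0 = off.  The
#'   tensile-test convention is 0.01 nm/ps^2.
#' @param probe optional [probe_spec()]: a rigid protein-sized body.
#' @param grafted freeze the first bead of each chain at its anchor
#'   (`FALSE` releases it, e.g. for free-diffusion checks).
#' @param bead_mass,linker_mass bead masses in u.
#' @param residue_labels residue names for the peptide beads; default is
#'   the 12-mer PD-L1-binder sequence when `beads_per_chain` is 12, else
#'   generic labels.
#' @return object of class `sam_synthetic_params`.
#' @export
synthetic_params <- function(n_chains = 25, beads_per_chain = 12,
                             linker_beads = 5, graft_spacing = 1.0,
                             bond_length = 0.35, bond_stiffness = 100,
                             bending_stiffness = 5, graft_alignment = 20,
                             interchain_attraction = 0,
                             attraction_range = 0.6,
                             excluded_volume_radius = 0.35,
                             excluded_strength = 15,
                             temperature_factor = 1, mobility = 0.1,
                             timestep = 0.004, n_steps = 10000,
                             save_stride = 100, seed = 1,
                             pull_acceleration = 0, probe = NULL,
                             grafted = TRUE, bead_mass = 110,
                             linker_mass = 44, residue_labels = NULL) {
  stopifnot(n_chains >= 1, beads_per_chain >= 1, linker_beads >= 0,
            timestep > 0, n_steps >= 1, save_stride >= 1,
            pull_acceleration >= 0, interchain_attraction >= 0,
            temperature_factor >= 0, mobility > 0, bond_length > 0,
            graft_spacing > 0)
  if (is.null(residue_labels)) {
    residue_labels <- if (beads_per_chain == 12) .clp002
                      else sprintf("B%02d", seq_len(beads_per_chain))
  }
  stopifnot(length(residue_labels) == beads_per_chain)
  structure(as.list(environment()), class = "sam_synthetic_params")
}

#' Rigid probe body standing in for a protein domain
#'
#' A cylinder (default: the IgV-like domain proxy, 4 nm deep and 3 nm
#' wide) discretised into beads on its bottom disc and lateral surface.
#' Residue labels are assigned by angular sector, so a label set such as
#' [active_spots()] carves the probe surface into labelled patches usable
#' in persistence maps.
#'
#' @param depth cylinder height in nm.
#' @param width cylinder diameter in nm.
#' @param bead_spacing surface bead spacing in nm.
#' @param residue_labels character vector of residue names; default
#'   `active_spots()$name`.
#' @param mode `"fixed"` (held at its pose) or `"zdiffuse"` (shared
#'   vertical random walk).
#' @param center XY centre in nm, default box centre at simulation time.
#' @param z_bottom height of the bottom face; default: lowered to touch
#'   the mean top of the monolayer's initial configuration.
#' @param mobility vertical mobility used by `"zdiffuse"`.
#' @param bead_mass bead mass in u.
#' @return object of class `sam_probe_spec`.
#' @export
probe_spec <- function(depth = 4, width = 3, bead_spacing = 0.5,
                       residue_labels = NULL, mode = c("fixed", "zdiffuse"),
                       center = NULL, z_bottom = NULL, mobility = 0.01,
                       bead_mass = 110) {
  mode <- match.arg(mode)
  stopifnot(depth > 0, width > 0, bead_spacing > 0)
  if (is.null(residue_labels)) residue_labels <- active_spots()$name
  structure(list(depth = depth, width = width, bead_spacing = bead_spacing,
                 residue_labels = residue_labels, mode = mode,
                 center = center, z_bottom = z_bottom, mobility = mobility,
                 bead_mass = bead_mass),
            class = "sam_probe_spec")
}

# bead coordinates of the probe cylinder, centred at (0,0) with bottom at 0
.probe_coords <- function(p) {
  R <- p$width / 2
  s <- p$bead_spacing
  pts <- list()
  # bottom disc: concentric rings
  radii <- seq(0, R, by = s)
  for (r in radii) {
    n <- max(1L, round(2 * pi * r / s))
    th <- 2 * pi * (seq_len(n) - 1L) / n
    pts[[length(pts) + 1L]] <- cbind(r * cos(th), r * sin(th), 0)
  }
  # lateral surface
  for (z in seq(s, p$depth, by = s)) {
    n <- max(1L, round(2 * pi * R / s))
    th <- 2 * pi * (seq_len(n) - 1L) / n
    pts[[length(pts) + 1L]] <- cbind(R * cos(th), R * sin(th), z)
  }
  do.call(rbind, pts)
}

# topology + initial positions + box for a parameter set
.brush_setup <- function(params) {
  p <- params
  nb <- p$linker_beads + p$beads_per_chain
  nxa <- ceiling(sqrt(p$n_chains))
  nya <- ceiling(p$n_chains / nxa)
  box <- c(nxa * p$graft_spacing, nya * p$graft_spacing,
           nb * p$bond_length + 6)
  grid <- expand.grid(ix = seq_len(nxa) - 1L,
                      iy = seq_len(nya) - 1L)[seq_len(p$n_chains), ]
  ax <- (grid$ix + 0.5) * p$graft_spacing
  ay <- (grid$iy + 0.5) * p$graft_spacing

  is_linker <- rep(c(rep(TRUE, p$linker_beads), rep(FALSE, p$beads_per_chain)),
                   p$n_chains)
  bead_in_chain <- rep(seq_len(nb), p$n_chains)
  chain <- rep(seq_len(p$n_chains), each = nb)
  z <- p$bond_length * bead_in_chain
  pos <- cbind(rep(ax, each = nb), rep(ay, each = nb), z)
  resname <- rep(c(rep("PEG", p$linker_beads), p$residue_labels),
                 p$n_chains)
  df <- data.frame(
    atom_name = ifelse(is_linker, "BB", "CA"),
    residue_name = resname,
    residue_index = seq_len(nb * p$n_chains),
    moiety = ifelse(is_linker, "linker", "peptide"),
    peptide_index = chain,
    mass = ifelse(is_linker, p$linker_mass, p$bead_mass),
    is_sidechain = !is_linker,  # single-bead residues are their own side chain
    is_calpha = !is_linker,
    stringsAsFactors = FALSE)
  fixed <- p$grafted & bead_in_chain == 1L
  probe_mask <- rep(FALSE, nrow(df))

  if (!is.null(p$probe)) {
    pr <- p$probe
    ctr <- if (is.null(pr$center)) box[1:2] / 2 else pr$center
    zb <- pr$z_bottom
    if (is.null(zb)) zb <- max(z)  # touch the mean initial top surface
    pc <- .probe_coords(pr)
    pc <- sweep(pc, 2, c(ctr, zb), `+`)
    sector <- (floor((atan2(pc[, 2] - ctr[2], pc[, 1] - ctr[1]) + pi) /
                       (2 * pi) * length(pr$residue_labels)) %%
                 length(pr$residue_labels)) + 1L
    pdf <- data.frame(
      atom_name = "PB",
      residue_name = pr$residue_labels[sector],
      residue_index = max(df$residue_index) + sector,
      moiety = "protein", peptide_index = -1L, mass = pr$bead_mass,
      is_sidechain = FALSE, is_calpha = FALSE, stringsAsFactors = FALSE)
    df <- rbind(df, pdf)
    pos <- rbind(pos, pc)
    fixed <- c(fixed, rep(TRUE, nrow(pdf)))
    probe_mask <- c(probe_mask, rep(TRUE, nrow(pdf)))
    chain <- c(chain, rep(0L, nrow(pdf)))
  }

  top <- topology(atom_name = df$atom_name, residue_name = df$residue_name,
                  residue_index = df$residue_index, moiety = df$moiety,
                  peptide_index = df$peptide_index, element = "C",
                  mass = df$mass, is_sidechain = df$is_sidechain,
                  is_calpha = df$is_calpha)
  n_chain_beads <- nb * p$n_chains
  bonds <- do.call(rbind, lapply(seq_len(p$n_chains), function(c0) {
    off <- (c0 - 1L) * nb
    if (nb > 1L) cbind(off + seq_len(nb - 1L), off + seq_len(nb - 1L) + 1L)
  }))
  if (is.null(bonds)) bonds <- matrix(0L, 0, 2)
  angles <- do.call(rbind, lapply(seq_len(p$n_chains), function(c0) {
    off <- (c0 - 1L) * nb
    if (nb > 2L) cbind(off + seq_len(nb - 2L), off + seq_len(nb - 2L) + 1L,
                       off + seq_len(nb - 2L) + 2L)
  }))
  if (is.null(angles)) angles <- matrix(0L, 0, 3)
  graft_pairs <- if (p$grafted && nb > 1L) {
    cbind((seq_len(p$n_chains) - 1L) * nb + 1L,
          (seq_len(p$n_chains) - 1L) * nb + 2L)
  } else matrix(0L, 0, 2)
  list(top = top, pos = pos, box = box, chain = as.integer(chain),
       attract = top$moiety == "peptide",
       fixed = fixed, probe = probe_mask, bonds = bonds, angles = angles,
       graft_pairs = graft_pairs, n_chain_beads = n_chain_beads)
}

#' Run a synthetic brush simulation
#'
#' Integrates the overdamped dynamics described in [synthetic_params()] and
#' returns the saved frames (the initial configuration plus one frame every
#' `save_stride` steps).  Runs are bitwise-reproducible for a given
#' parameter set and seed.
#'
#' @param params a [synthetic_params()].
#' @return a [trajectory()]; the parameter set is attached as attribute
#'   `"params"`.
#' @export
#' @examples
#' tr <- simulate_brush(synthetic_params(n_chains = 4, n_steps = 100))
#' length(tr$frames)
simulate_brush <- function(params) {
  stopifnot(inherits(params, "sam_synthetic_params"))
  s <- .brush_setup(params)
  pull_mass <- ifelse(s$top$is_calpha & params$pull_acceleration > 0,
                      s$top$mass, 0)
  probe_mode <- 0L
  probe_mobility <- 0
  if (!is.null(params$probe)) {
    probe_mode <- if (params$probe$mode == "zdiffuse") 1L else 0L
    probe_mobility <- params$probe$mobility
  }
  set.seed(params$seed)
  arr <- cpp_bd(s$pos, s$box, s$chain, s$attract, s$fixed, s$probe, pull_mass,
                s$bonds, s$angles, s$graft_pairs, params$bond_stiffness,
                params$bond_length, params$bending_stiffness,
                params$graft_alignment,
                params$interchain_attraction, params$attraction_range,
                params$excluded_strength, params$excluded_volume_radius,
                params$temperature_factor, params$mobility,
                params$timestep, params$n_steps, params$save_stride,
                params$pull_acceleration, probe_mode, probe_mobility)
  dims <- dim(arr)
  dt_save <- params$timestep * params$save_stride
  frames <- lapply(seq_len(dims[3]), function(k) {
    frame(matrix(arr[, , k], ncol = 3), s$box, time = (k - 1) * dt_save)
  })
  out <- trajectory(s$top, frames, frame_interval = dt_save)
  attr(out, "params") <- params
  out
}

#' Potential energy of a frame under the brush force field
#'
#' @param frm a [frame()].
#' @param params the [synthetic_params()] of the run (attached to
#'   [simulate_brush()] output as attribute `"params"`).
#' @return total potential energy (reduced units).
#' @export
brush_energy <- function(frm, params) {
  stopifnot(inherits(params, "sam_synthetic_params"))
  s <- .brush_setup(params)
  cpp_bd_energy(frm$positions, frm$box, s$chain, s$attract, s$bonds, s$angles,
                s$graft_pairs, params$bond_stiffness, params$bond_length,
                params$bending_stiffness, params$graft_alignment,
                params$interchain_attraction, params$attraction_range,
                params$excluded_strength, params$excluded_volume_radius)
}

#' Clustered vs grid morphology pair
#'
#' Two runs differing only in the inter-chain attraction: a strongly
#' attractive run that aggregates chains into clusters with bare patches
#' between them, and a weakly attractive run in which chains stay on their
#' graft grid as a uniform carpet.  This is the synthetic stand-in for the
#' contrast between a PD-L1-binding peptide monolayer (clustered, rough,
#' accessible) and its scrambled-sequence control (grid-like, compact).
#'
#' @param base a [synthetic_params()]; its `interchain_attraction` is
#'   overridden.
#' @param eps_clustered attraction (energy units) of the clustered member.
#' @param eps_grid attraction of the grid member.
#' @return list with elements `clustered` and `grid`, both trajectories.
#' @export
make_morphology_pair <- function(base = synthetic_params(),
                                 eps_clustered = 2, eps_grid = 0.2) {
  stopifnot(inherits(base, "sam_synthetic_params"),
            eps_clustered > eps_grid)
  pc <- base; pc$interchain_attraction <- eps_clustered
  pg <- base; pg$interchain_attraction <- eps_grid
  list(clustered = simulate_brush(pc), grid = simulate_brush(pg))
}
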