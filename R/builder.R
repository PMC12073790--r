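# Monolayer construction: a single hexagonally packed gold layer plus
# grafted conjugates inserted long-axis-parallel to Z, anchor sulfur
# 0.294 nm above the gold plane, extended (all-trans) conformation unless a
# head conformation is supplied.  Chains are coarse-grained: one bead per
# linker unit / one backbone bead (CA) plus one side-chain bead per amino
# acid, with residue masses so that mass-density profiles are meaningful.

#' Build specification for a grafted monolayer
#'
#' @param conjugate a [conjugate_sequence()].
#' @param n_peptides number of grafted chains.
#' @param box length-3 box (Lx, Ly, Lz) in nm.
#' @param lattice_spacing gold nearest-neighbour distance in nm (bulk gold:
#'   0.288).
#' @param s_au_distance height of the anchor sulfur above the gold plane
#'   (nm).
#' @param n_counterions monovalent counterions; default
#'   [counterion_count()] of the conjugate.
#' @param n_water solvent count, recorded as metadata only (water is
#'   implicit in all analyses here).
#' @param restraint_k gold position-restraint force constant
#'   (kJ mol^-1 nm^-2), metadata.
#' @return object of class `sam_monolayer_spec`.
#' @export
monolayer_spec <- function(conjugate, n_peptides, box,
                           lattice_spacing = 0.288, s_au_distance = 0.294,
                           n_counterions = NULL, n_water = NA_integer_,
                           restraint_k = 10000) {
  stopifnot(inherits(conjugate, "sam_conjugate"), n_peptides >= 1,
            length(box) == 3, all(box > 0), lattice_spacing > 0,
            s_au_distance > 0)
  if (is.null(n_counterions)) {
    n_counterions <- counterion_count(conjugate, n_peptides)
  }
  structure(list(conjugate = conjugate, n_peptides = as.integer(n_peptides),
                 box = as.numeric(box), lattice_spacing = lattice_spacing,
                 s_au_distance = s_au_distance,
                 n_counterions = as.integer(n_counterions),
                 n_water = n_water, restraint_k = restraint_k),
            class = "sam_monolayer_spec")
}

#' Shipped monolayer system presets
#'
#' The three simulated gold-slab systems: `NS@P-CLP` (45 P-CLP chains, box
#' 10.32 x 9.99 x 27.55 nm, 180 Cl-), `NS@P-SCLP` (45 P-SCLP chains, box
#' 10.30 x 9.97 x 27.50 nm, 180 Cl-) and `NS@C-CLP` (90 C-CLP chains, box
#' 10.31 x 9.98 x 18.17 nm, 90 Cl-).
#'
#' @param name preset name.
#' @return a [monolayer_spec()].
#' @export
monolayer_preset <- function(name = c("NS@P-CLP", "NS@P-SCLP", "NS@C-CLP")) {
  name <- match.arg(name)
  switch(name,
         "NS@P-CLP" = monolayer_spec(conjugate_preset("P-CLP"), 45,
                                     c(10.32, 9.99, 27.55), n_water = 79050L),
         "NS@P-SCLP" = monolayer_spec(conjugate_preset("P-SCLP"), 45,
                                      c(10.30, 9.97, 27.50), n_water = 78349L),
         "NS@C-CLP" = monolayer_spec(conjugate_preset("C-CLP"), 90,
                                     c(10.31, 9.98, 18.17), n_water = 50807L))
}

#' Build a single hexagonally packed gold layer
#'
#' Atoms form a planar triangular lattice: rows separated by
#' `spacing * sqrt(3)/2`, alternate rows offset by `spacing / 2`, all Z
#' equal to 0 (the gold reference plane).
#'
#' @param spacing nearest-neighbour distance in nm.
#' @param nx,ny atoms per row and number of rows.
#' @return single-frame [trajectory()] of `nx * ny` gold atoms; the box is
#'   the periodic lattice cell (`nx * spacing` by `ny * spacing*sqrt(3)/2`).
#' @export
#' @examples
#' au <- build_gold_layer(0.288, 4, 4)
#' range(au$frames[[1]]$positions[, 3])  # coplanar at Z = 0
build_gold_layer <- function(spacing = 0.288, nx, ny) {
  if (spacing <= 0 || nx < 1 || ny < 1) {
    stop("spacing must be > 0 and nx, ny >= 1")
  }
  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  x <- (ij$i + 0.5 * (ij$j %% 2)) * spacing
  y <- ij$j * spacing * sqrt(3) / 2
  pos <- cbind(x, y, 0)
  top <- topology(atom_name = "AU", residue_name = "AU",
                  residue_index = seq_len(nrow(pos)), moiety = "gold",
                  element = "AU")
  box <- c(nx * spacing, max(ny * spacing * sqrt(3) / 2, spacing), 10)
  trajectory(top, list(frame(pos, box, 0)))
}

# atoms of one conjugate grafted at (x0, y0); returns list(df, pos)
.conjugate_atoms <- function(conj, x0, y0, s_au, chain_id,
                             residue_rise = 0.35, peg_rise = 0.28,
                             side_offset = 0.15, head_conformation = NULL) {
  rows <- list(); pos <- list(); res <- 0L
  z <- s_au
  add <- function(name, elem, resname, mass, x, y, zz, side = FALSE,
                  ca = FALSE, moiety = "linker") {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = name, element = elem, residue_name = resname,
      residue_index = res, mass = mass, is_sidechain = side, is_calpha = ca,
      moiety = moiety, stringsAsFactors = FALSE)
    pos[[length(pos) + 1L]] <<- c(x, y, zz)
  }
  units <- conj$linker_units
  for (k in seq_len(nrow(units))) {
    unit <- units$unit[k]
    for (rep in seq_len(units$n[k])) {
      res <- res + 1L
      switch(unit,
             "SH-PEG" = {
               if (k == 1L && rep == 1L) {
                 add("S", "S", "PEG", 32.06, x0, y0, z)
               }
               z <- z + peg_rise
               add("BB", "C", "PEG", .linker_mass[["SH-PEG"]], x0, y0, z)
             },
             "Ac" = add("BB", "C", "ACE", .linker_mass[["Ac"]], x0 + side_offset,
                        y0, z),
             "Cys" = {
               # anchoring cysteine, written as CYX (bound thiolate)
               add("S", "S", "CYX", 32.06, x0, y0, z)
               z <- z + .linker_rise[["Cys"]]
               add("CA", "C", "CYX", .aa_mass[["CYS"]] - 32.06, x0, y0, z)
             },
             {
               z <- z + .linker_rise[[unit]]
               add("BB", "C", toupper(substr(unit, 1, 3)),
                   .linker_mass[[unit]], x0, y0, z)
             })
    }
  }
  n_before_head <- length(pos)
  attach_z <- z
  for (p in seq_along(conj$peptide_residues)) {
    aa <- conj$peptide_residues[p]
    res <- res + 1L
    z <- z + residue_rise
    add("CA", "C", aa, 56, x0, y0, z, ca = TRUE, moiety = "peptide")
    m_side <- .aa_mass[[aa]] - 56
    if (m_side > 1) {
      add("CB", "C", aa, m_side, x0 + side_offset * ifelse(p %% 2, 1, -1),
          y0, z, side = TRUE, moiety = "peptide")
    }
  }
  df <- do.call(rbind, rows)
  pm <- do.call(rbind, pos)
  if (!is.null(head_conformation)) {
    n_head <- nrow(pm) - n_before_head
    if (nrow(head_conformation) != n_head) {
      stop(sprintf("head_conformation has %d rows; peptide head has %d atoms",
                   nrow(head_conformation), n_head))
    }
    pm[(n_before_head + 1):nrow(pm), ] <-
      sweep(as.matrix(head_conformation), 2, c(x0, y0, attach_z), `+`)
  }
  df$peptide_index <- chain_id
  list(df = df, pos = pm)
}

#' Graft conjugates onto a gold layer
#'
#' Anchors are placed on a uniform grid over the box XY face with a small
#' seeded jitter; each anchor sulfur sits exactly `spec$s_au_distance`
#' above the gold plane and the chain rises parallel to Z in its extended
#' (all-trans) conformation: 0.28 nm per PEG monomer, 0.35 nm per amino
#' acid.  Counterions are scattered in the solvent region above the
#' monolayer.
#'
#' @param gold single-frame gold [trajectory()] (see [build_gold_layer()]);
#'   its lattice must cover the box XY face.
#' @param spec a [monolayer_spec()].
#' @param seed integer seed for anchor jitter and ion placement.
#' @param head_conformation optional matrix of peptide-head coordinates
#'   relative to the linker attachment point (one row per peptide atom);
#'   default is the extended conformation.
#' @param min_anchor_distance smallest allowed anchor-anchor distance (nm).
#' @return single-frame [trajectory()] of gold + chains + ions with the
#'   spec box.
#' @export
graft_conjugates <- function(gold, spec, seed = 1, head_conformation = NULL,
                             min_anchor_distance = 0.5) {
  stopifnot(inherits(spec, "sam_monolayer_spec"))
  gtop <- gold$topology
  gpos <- gold$frames[[1]]$positions
  if (!all(gtop$moiety == "gold")) stop("gold trajectory must be gold-only")
  box <- spec$box
  if (max(gpos[, 1]) < box[1] - 2 * spec$lattice_spacing ||
      max(gpos[, 2]) < box[2] - 2 * spec$lattice_spacing) {
    stop("gold layer does not cover the box XY face; build a larger layer")
  }
  n <- spec$n_peptides
  nxa <- ceiling(sqrt(n * box[1] / box[2]))
  nya <- ceiling(n / nxa)
  sx <- box[1] / nxa
  sy <- box[2] / nya
  if (min(sx, sy) < min_anchor_distance) {
    stop(sprintf(paste0("cannot place %d anchors at >= %.2f nm separation; ",
                        "at most %d chains fit this box"),
                 n, min_anchor_distance,
                 floor(box[1] / min_anchor_distance) *
                   floor(box[2] / min_anchor_distance)))
  }
  grid <- expand.grid(ix = seq_len(nxa) - 1L, iy = seq_len(nya) - 1L)[seq_len(n), ]
  set.seed(seed)
  jitter_amp <- pmax(0, pmin(0.1 * c(sx, sy),
                             (c(sx, sy) - min_anchor_distance) / 2))
  ax <- (grid$ix + 0.5) * sx + runif(n, -jitter_amp[1], jitter_amp[1])
  ay <- (grid$iy + 0.5) * sy + runif(n, -jitter_amp[2], jitter_amp[2])
  ax <- ax %% box[1]
  ay <- ay %% box[2]

  parts <- lapply(seq_len(n), function(i) {
    .conjugate_atoms(spec$conjugate, ax[i], ay[i], spec$s_au_distance, i,
                     head_conformation = head_conformation)
  })
  cdf <- do.call(rbind, lapply(parts, `[[`, "df"))
  cpos <- do.call(rbind, lapply(parts, `[[`, "pos"))
  # renumber residues consecutively per chain block
  cdf$residue_index <- cumsum(c(TRUE, diff(as.integer(
    factor(paste(cdf$peptide_index, cdf$residue_index)))) != 0))

  top_z <- max(cpos[, 3])
  n_ion <- spec$n_counterions
  idf <- NULL; ipos <- NULL
  if (n_ion > 0) {
    ipos <- cbind(runif(n_ion, 0, box[1]), runif(n_ion, 0, box[2]),
                  runif(n_ion, min(top_z + 0.5, box[3] - 0.5), box[3]))
    idf <- data.frame(atom_name = "CL", element = "CL", residue_name = "CL",
                      residue_index = max(cdf$residue_index) + seq_len(n_ion),
                      mass = 35.45, is_sidechain = FALSE, is_calpha = FALSE,
                      moiety = "ion", peptide_index = -1L,
                      stringsAsFactors = FALSE)
  }
  gdf <- data.frame(atom_name = "AU", element = "AU", residue_name = "AU",
                    residue_index = seq_len(nrow(gpos)), mass = 196.967,
                    is_sidechain = FALSE, is_calpha = FALSE, moiety = "gold",
                    peptide_index = -1L, stringsAsFactors = FALSE)
  all_df <- rbind(gdf, cdf[names(gdf)], if (!is.null(idf)) idf[names(gdf)])
  all_pos <- rbind(gpos, cpos, ipos)
  top <- topology(atom_name = all_df$atom_name,
                  residue_name = all_df$residue_name,
                  residue_index = all_df$residue_index,
                  moiety = all_df$moiety,
                  peptide_index = all_df$peptide_index,
                  element = all_df$element, mass = all_df$mass,
                  is_sidechain = all_df$is_sidechain,
                  is_calpha = all_df$is_calpha)
  trajectory(top, list(frame(all_pos, box, 0)))
}
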