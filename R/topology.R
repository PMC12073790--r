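# Topology: a data.frame with one row per atom and a fixed column set.
# peptide_index is -1 for atoms that are not part of a grafted conjugate
# (gold, ions, protein); grafted chains are numbered from 1.

.topology_cols <- c("atom_index", "atom_name", "element", "residue_name",
                    "residue_index", "peptide_index", "moiety", "mass",
                    "vdw_radius", "is_heavy", "is_sidechain", "is_calpha")

.moieties <- c("gold", "linker", "peptide", "protein", "ion")

#' Assemble and validate an atom topology
#'
#' Builds the per-atom table used throughout the package.  Omitted columns
#' are filled with sensible defaults: element from the first letter of
#' `atom_name`, mass and van der Waals radius from the element tables,
#' `is_heavy` from the element, selection flags `FALSE`.
#'
#' @param atom_name character, atom names.
#' @param residue_name character, 3-letter residue names.
#' @param residue_index integer, residue numbers.
#' @param moiety character, one of "gold", "linker", "peptide", "protein", "ion".
#' @param peptide_index integer, grafted-chain number (>= 1) or -1.
#' @param element,mass,vdw_radius,is_heavy,is_sidechain,is_calpha optional
#'   per-atom overrides.
#' @return a `data.frame` of class `sam_topology`.
#' @export
topology <- function(atom_name, residue_name, residue_index, moiety,
                     peptide_index = -1L, element = NULL, mass = NULL,
                     vdw_radius = NULL, is_heavy = NULL,
                     is_sidechain = FALSE, is_calpha = FALSE) {
  lens <- c(length(atom_name), length(residue_name), length(residue_index),
            length(moiety), length(peptide_index))
  n <- max(lens)
  if (any(lens != 1L & lens != n)) {
    stop("topology fields must have length 1 or the atom count (", n, ")")
  }
  atom_name <- rep_len(as.character(atom_name), n)
  residue_name <- rep_len(residue_name, n)
  residue_index <- rep_len(residue_index, n)
  if (is.null(element)) element <- toupper(substr(atom_name, 1L, 1L))
  element <- rep_len(element, n)
  element <- toupper(element)
  if (is.null(mass)) {
    mass <- .element_mass[element]
    mass[is.na(mass)] <- .element_mass[["X"]]
    mass <- unname(mass)
  }
  if (is.null(vdw_radius)) vdw_radius <- goldsam::vdw_radius(element)
  if (is.null(is_heavy)) is_heavy <- element != "H"
  top <- data.frame(
    atom_index = seq_len(n),
    atom_name = as.character(atom_name),
    element = element,
    residue_name = as.character(residue_name),
    residue_index = as.integer(residue_index),
    peptide_index = as.integer(rep_len(peptide_index, n)),
    moiety = as.character(rep_len(moiety, n)),
    mass = as.numeric(rep_len(mass, n)),
    vdw_radius = as.numeric(rep_len(vdw_radius, n)),
    is_heavy = as.logical(rep_len(is_heavy, n)),
    is_sidechain = as.logical(rep_len(is_sidechain, n)),
    is_calpha = as.logical(rep_len(is_calpha, n)),
    stringsAsFactors = FALSE
  )
  validate_topology(top)
}

#' @rdname topology
#' @param top a candidate topology data.frame.
#' @export
validate_topology <- function(top) {
  stopifnot(is.data.frame(top))
  missing <- setdiff(.topology_cols, names(top))
  if (length(missing)) {
    stop("topology is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(top$moiety), .moieties)
  if (length(bad)) stop("unknown moiety label(s): ", paste(bad, collapse = ", "))
  if (any(top$mass <= 0)) stop("all atom masses must be > 0")
  if (any(top$vdw_radius <= 0)) stop("all vdW radii must be > 0")
  grafted <- top$moiety %in% c("linker", "peptide")
  if (any(grafted & top$peptide_index < 0L)) {
    stop("linker/peptide atoms must carry a peptide_index >= 0")
  }
  if (any(top$is_calpha & !top$moiety %in% c("peptide", "protein"))) {
    stop("is_calpha atoms must belong to peptide or protein moieties")
  }
  class(top) <- c("sam_topology", "data.frame")
  top
}

#' Relabel moieties of a topology
#'
#' @param top a topology.
#' @param residue_names residues to relabel.
#' @param moiety new moiety label for those residues.
#' @return the modified topology.
#' @export
set_moiety <- function(top, residue_names, moiety) {
  top$moiety[top$residue_name %in% residue_names] <- moiety
  if (moiety %in% c("gold", "protein", "ion")) {
    top$peptide_index[top$residue_name %in% residue_names] <- -1L
  }
  validate_topology(top)
}

#' Select atoms from a topology
#'
#' Returns the indices of atoms satisfying the conjunction of the given
#' criteria, in increasing atom order.  This is the single selection
#' interface used by all analyses (e.g. "heavy side-chain atoms of the
#' grafted peptides", "all protein atoms").
#'
#' @param top a topology.
#' @param moiety optional character vector of moiety labels to keep.
#' @param peptide_index optional integer vector of grafted-chain numbers.
#' @param heavy_only if `TRUE`, drop hydrogens.
#' @param sidechain_only if `TRUE`, keep only side-chain atoms.
#' @param calpha_only if `TRUE`, keep only C-alpha atoms.
#' @param residue_list optional character vector of residue names; an error
#'   is raised if any named residue is absent from the topology.
#' @return sorted integer vector of atom indices (possibly empty).
#' @export
#' @examples
#' top <- topology(c("AU", "CA", "CB"), c("AU", "TRP", "TRP"),
#'                 c(1, 2, 2), c("gold", "peptide", "peptide"),
#'                 peptide_index = c(-1L, 1L, 1L),
#'                 is_calpha = c(FALSE, TRUE, FALSE))
#' select_atoms(top, moiety = "peptide")
select_atoms <- function(top, moiety = NULL, peptide_index = NULL,
                         heavy_only = FALSE, sidechain_only = FALSE,
                         calpha_only = FALSE, residue_list = NULL) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(moiety)) keep <- keep & top$moiety %in% moiety
  if (!is.null(peptide_index)) keep <- keep & top$peptide_index %in% peptide_index
  if (heavy_only) keep <- keep & top$is_heavy
  if (sidechain_only) keep <- keep & top$is_sidechain
  if (calpha_only) keep <- keep & top$is_calpha
  if (!is.null(residue_list)) {
    absent <- setdiff(residue_list, top$residue_name)
    if (length(absent)) {
      stop("residue(s) not present in topology: ",
           paste(absent, collapse = ", "))
    }
    keep <- keep & top$residue_name %in% residue_list
  }
  sort(top$atom_index[keep])
}

# Assign peptide_index to linker/peptide atoms read from a file, where the
# chain bookkeeping is not stored.  A new chain starts when the residue
# index does not increase, or when a linker residue follows a peptide
# residue (chains are written linker-first, bottom-up).
infer_chains <- function(top) {
  grafted <- which(top$moiety %in% c("linker", "peptide"))
  if (!length(grafted)) return(top)
  chain <- 0L
  prev_res <- -Inf
  prev_moiety <- ""
  for (i in grafted) {
    new_chain <- top$residue_index[i] < prev_res ||
      (prev_moiety == "peptide" && top$moiety[i] == "linker") ||
      chain == 0L
    if (new_chain && top$residue_index[i] != prev_res) chain <- chain + 1L
    top$peptide_index[i] <- chain
    prev_res <- top$residue_index[i]
    prev_moiety <- top$moiety[i]
  }
  top
}
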