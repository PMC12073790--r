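# Reference tables: residue -> moiety mapping, element radii/masses and
# amino-acid properties used when building topologies.  All overridable by
# the caller; the shipped values target united-atom style models in which
# hydrogens are mostly implicit.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# monoisotopic-ish average residue masses (u), i.e. amino acid minus water
.aa_mass <- c(ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09,
              CYS = 103.14, GLN = 128.13, GLU = 129.12, GLY = 57.05,
              HIS = 137.14, ILE = 113.16, LEU = 113.16, LYS = 128.17,
              MET = 131.19, PHE = 147.18, PRO = 97.12, SER = 87.08,
              THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13)

# side-chain formal charge at neutral pH; thiol/thiolate Cys treated neutral
.aa_charge <- c(ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0,
                GLU = -1, GLY = 0, HIS = 0, ILE = 0, LEU = 0, LYS = 1,
                MET = 0, PHE = 0, PRO = 0, SER = 0, THR = 0, TRP = 0,
                TYR = 0, VAL = 0)

# van der Waals radii (nm) by element; CG beads get a generic 0.25 nm
.element_vdw <- c(H = 0.110, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                  P = 0.180, AU = 0.166, CL = 0.175, `NA` = 0.227,
                  X = 0.250)

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, AU = 196.967, CL = 35.45,
                   `NA` = 22.990, X = 100)

#' Default residue-name to moiety mapping
#'
#' Maps residue names found in coordinate files onto the five moieties the
#' analyses distinguish: `gold`, `linker`, `peptide`, `protein` and `ion`.
#' Standard amino acids map to `peptide` by default because the package's
#' own builders write grafted chains; when reading a protein-containing
#' file, pass an amended map (e.g. `c(default_moiety_map(), TRP = "protein")`
#' or relabel via [set_moiety()]).
#'
#' @return named character vector, names are residue names, values moieties.
#' @export
#' @examples
#' default_moiety_map()[["AU"]]
default_moiety_map <- function() {
  m <- setNames(rep("peptide", length(.aa3)), .aa3)
  # B01..B30: generic coarse-grained peptide bead labels
  beads <- setNames(rep("peptide", 30), sprintf("B%02d", 1:30))
  c(m, beads,
    AU = "gold",
    PEG = "linker", O2O = "linker", O2C = "linker", ACE = "linker",
    EO = "linker", LNK = "linker",
    CYX = "linker",  # surface-bound (thiolate) cysteine anchor
    CL = "ion", `CL-` = "ion", NA. = "ion", `NA+` = "ion", ION = "ion")
}

#' Look up van der Waals radii for elements
#'
#' @param element character vector of element symbols ("C", "AU", ...);
#'   unknown elements get the generic coarse-bead radius 0.25 nm.
#' @return numeric vector of radii in nm.
#' @export
vdw_radius <- function(element) {
  r <- .element_vdw[toupper(element)]
  r[is.na(r)] <- .element_vdw[["X"]]
  unname(r)
}

#' Residue masses of the twenty standard amino acids
#'
#' Average residue masses (amino acid minus water) in atomic mass units,
#' used to assign bead masses in coarse-grained conjugates.
#'
#' @return named numeric vector (3-letter codes).
#' @export
residue_masses <- function() .aa_mass

#' Side-chain formal charges at neutral pH
#'
#' Fixed charge-state rules: Arg and Lys +1, Asp and Glu -1, His neutral,
#' Cys (thiol or gold-bound thiolate) neutral, all others 0.
#'
#' @return named integer-valued numeric vector (3-letter codes).
#' @export
residue_charges <- function() .aa_charge

#' Convert 1-letter amino-acid codes to 3-letter codes
#' @param x character vector of 1-letter codes or a single string.
#' @return character vector of 3-letter codes.
#' @export
aa_three <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  out <- .aa1to3[toupper(x)]
  if (anyNA(out)) {
    stop("unknown amino-acid code(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}
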