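# Linker-peptide conjugates.  A conjugate is an ordered linker (anchoring
# chemistry first) followed by a peptide head; the shipped presets are the
# three conjugates used to functionalise SERS gold nanostructures:
#   P-CLP  = HS-PEG3000-Lys3-Gly2-CLP002-NH2
#   P-SCLP = HS-PEG3000-Lys3-Gly2-SCLP002-NH2
#   C-CLP  = Ac-Cys-(O2oc)2-CLP002-NH2
# CLP002 is the 12-mer PD-L1 binder WHRSYYTWNLNT; SCLP002 the scrambled
# control TRWSHYNTLWYN.

.linker_units <- c("SH-PEG", "Ac", "Cys", "O2oc", "Lys", "Gly")
.linker_charge <- c(`SH-PEG` = 0, Ac = 0, Cys = 0, O2oc = 0, Lys = 1, Gly = 0)
# unit masses (u): PEG monomer 44 (C2H4O); O2oc = -NH(CH2CH2O)2CH2CO- 145
.linker_mass <- c(`SH-PEG` = 44, Ac = 42, Cys = 103.14, O2oc = 145, Gly = 57.05,
                  Lys = 128.17)
# extended-chain rise per unit along the long axis (nm)
.linker_rise <- c(`SH-PEG` = 0.28, Ac = 0.2, Cys = 0.35, O2oc = 0.7,
                  Lys = 0.35, Gly = 0.35)

.clp002 <- c("TRP", "HIS", "ARG", "SER", "TYR", "TYR", "THR", "TRP", "ASN",
             "LEU", "ASN", "THR")
.sclp002 <- c("THR", "ARG", "TRP", "SER", "HIS", "TYR", "ASN", "THR", "LEU",
              "TRP", "TYR", "ASN")

#' Define a linker-peptide conjugate
#'
#' @param name identifier.
#' @param linker_units data.frame with columns `unit` (one of "SH-PEG",
#'   "Ac", "Cys", "O2oc", "Lys", "Gly") and `n` (repeat count); order is
#'   anchor-first.
#' @param peptide_residues character vector of amino acids (1- or 3-letter).
#' @param cterm "amide" (capped, neutral) or "free" (-1).
#' @param nterm_blocked is the peptide N-terminus blocked (by the linker or
#'   an acetyl cap)?  Grafted conjugates always are.
#' @return object of class `sam_conjugate`.
#' @export
#' @examples
#' formal_charge(conjugate_preset("P-CLP"))  # 3 linker Lys + 1 Arg = +4
conjugate_sequence <- function(name, linker_units, peptide_residues,
                               cterm = c("amide", "free"),
                               nterm_blocked = TRUE) {
  cterm <- match.arg(cterm)
  stopifnot(is.data.frame(linker_units),
            all(c("unit", "n") %in% names(linker_units)))
  bad <- setdiff(linker_units$unit, .linker_units)
  if (length(bad)) stop("unknown linker unit(s): ", paste(bad, collapse = ", "))
  if (any(linker_units$n < 1)) stop("linker unit counts must be >= 1")
  if (any(nchar(peptide_residues) == 1L)) {
    peptide_residues <- aa_three(peptide_residues)
  }
  peptide_residues <- toupper(peptide_residues)
  bad <- setdiff(peptide_residues, .aa3)
  if (length(bad)) stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, linker_units = linker_units,
                 peptide_residues = peptide_residues, cterm = cterm,
                 nterm_blocked = nterm_blocked),
            class = "sam_conjugate")
}

#' Shipped conjugate presets
#'
#' `"P-CLP"` and `"P-SCLP"` carry the long thiolated-PEG3000 linker with a
#' Lys3Gly2 cationic spacer (PEG3000 at 44 u per monomer gives 68
#' monomers); `"C-CLP"` carries the short Ac-Cys-(O2oc)2 linker.  All have
#' amidated C-termini and linker-blocked N-termini.
#'
#' @param name one of "P-CLP", "P-SCLP", "C-CLP".
#' @param peg_monomers PEG chain length for the P-linker presets.
#' @return a [conjugate_sequence()].
#' @export
conjugate_preset <- function(name = c("P-CLP", "P-SCLP", "C-CLP"),
                             peg_monomers = 68) {
  name <- match.arg(name)
  p_linker <- data.frame(unit = c("SH-PEG", "Lys", "Gly"),
                         n = c(peg_monomers, 3, 2))
  c_linker <- data.frame(unit = c("Ac", "Cys", "O2oc"), n = c(1, 1, 2))
  switch(name,
         "P-CLP" = conjugate_sequence("P-CLP", p_linker, .clp002),
         "P-SCLP" = conjugate_sequence("P-SCLP", p_linker, .sclp002),
         "C-CLP" = conjugate_sequence("C-CLP", c_linker, .clp002))
}

#' Formal charge of a conjugate at neutral pH
#'
#' Fixed charge-state rules: Arg/Lys +1 (including spacer Lys), Asp/Glu -1,
#' His neutral, Cys neutral (thiol or gold-bound thiolate), PEG/O2oc/acetyl
#' neutral; an amidated C-terminus and a blocked N-terminus contribute 0,
#' free termini -1/+1.
#'
#' @param conjugate a [conjugate_sequence()].
#' @return integer net charge.
#' @export
formal_charge <- function(conjugate) {
  stopifnot(inherits(conjugate, "sam_conjugate"))
  q_link <- sum(.linker_charge[conjugate$linker_units$unit] *
                  conjugate$linker_units$n)
  q_pep <- sum(.aa_charge[conjugate$peptide_residues])
  q_term <- (conjugate$cterm == "free") * -1 + (!conjugate$nterm_blocked) * 1
  as.integer(q_link + q_pep + q_term)
}

#' Counterions needed to neutralise a grafted monolayer
#'
#' Number of monovalent counterions (chloride for cationic conjugates)
#' required for electroneutrality: `n_peptides * formal_charge(conjugate)`.
#'
#' @param conjugate a [conjugate_sequence()].
#' @param n_peptides number of grafted conjugates.
#' @return integer ion count.
#' @export
#' @examples
#' counterion_count(conjugate_preset("P-CLP"), 45)  # 180 chloride
counterion_count <- function(conjugate, n_peptides) {
  q <- formal_charge(conjugate)
  if (q < 0) {
    stop("anionic conjugates (net charge ", q,
         ") are not supported; only chloride counterions are handled")
  }
  as.integer(n_peptides * q)
}
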