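# PDB coordinate files.  Reading is delegated to bio3d (multi-model aware);
# coordinates are converted from Angstrom to nm at this boundary.  The
# writer emits a minimal multi-model PDB with a CRYST1 record so that the
# box survives a round trip (bio3d's writer does not emit box records).

read_pdb_traj <- function(path, moiety_map = default_moiety_map(),
                          frame_interval = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  resname <- trimws(at$resid)
  atomname <- trimws(at$elety)
  element <- guess_element(atomname)
  moiety <- moiety_map[resname]
  if (anyNA(moiety)) {
    stop("no moiety mapping for residue(s): ",
         paste(unique(resname[is.na(moiety)]), collapse = ", "),
         " (extend the moiety_map argument)")
  }
  top <- topology(atom_name = atomname, residue_name = resname,
                  residue_index = at$resno, moiety = unname(moiety),
                  peptide_index = ifelse(moiety %in% c("linker", "peptide"),
                                         0L, -1L),
                  element = element,
                  is_sidechain = atomname %in% c("CB", "SC"),
                  is_calpha = atomname == "CA" &
                    moiety %in% c("peptide", "protein"))
  top <- validate_topology(infer_chains(top))
  # box from CRYST1 (Angstrom -> nm); fall back to the coordinate extent
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (length(cryst)) {
    box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                        substr(cryst[1], 25, 33))) / 10
  } else {
    box <- apply(matrix(xyz[1, ], ncol = 3, byrow = TRUE), 2,
                 function(v) diff(range(v))) / 10 + 1
  }
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    pos <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    frame(pos, box, time = (i - 1) * frame_interval)
  })
  trajectory(top, frames, frame_interval = frame_interval)
}

write_pdb_traj <- function(traj, path) {
  top <- traj$topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  b <- traj$frames[[1]]$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  serial <- top$atom_index %% 100000L
  multi <- length(traj$frames) > 1L
  for (i in seq_along(traj$frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    p <- traj$frames[[i]]$positions * 10
    writeLines(sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       serial, substr(top$atom_name, 1L, 4L),
                       substr(top$residue_name, 1L, 4L),
                       top$residue_index %% 10000L,
                       p[, 1], p[, 2], p[, 3],
                       substr(top$element, 1L, 2L)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a coordinate/trajectory file
#'
#' Reads GRO (fixed-width, nm, possibly concatenated frames) or PDB
#' (multi-model, Angstrom) files into a [trajectory()].  PDB coordinates
#' are divided by 10 so that everything downstream works in nm.  Moieties
#' are inferred from residue names via `moiety_map`; grafted-chain numbers
#' are inferred from residue ordering (chains are stored linker-first).
#'
#' @param path file to read.
#' @param format "gro", "pdb" or "auto" (from the file extension).
#' @param moiety_map named residue -> moiety vector, see
#'   [default_moiety_map()].
#' @param frame_interval time between PDB models in ps (GRO frames carry
#'   their own time stamps).
#' @return a [trajectory()].
#' @export
read_coordinates <- function(path, format = c("auto", "gro", "pdb"),
                             moiety_map = default_moiety_map(),
                             frame_interval = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         gro = read_gro(path, moiety_map),
         pdb = read_pdb_traj(path, moiety_map, frame_interval))
}

#' Write a trajectory to a coordinate file
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format "gro", "pdb" or "auto" (from the file extension).
#' @return the path, invisibly.
#' @export
write_coordinates <- function(traj, path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  if (!length(traj$frames)) stop("refusing to write an empty trajectory")
  switch(format,
         gro = write_gro(traj, path),
         pdb = write_pdb_traj(traj, path))
  invisible(path)
}
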