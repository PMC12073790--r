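# GRO (GROMACS) fixed-width coordinate files, possibly with several
# concatenated frames.  Columns: resnr(5) resname(5) atomname(5) atomnr(5)
# then x, y, z in nm with 3 decimals.  Atom and residue numbers wrap at
# 100000 (the GROMACS convention), so field widths never overflow; the
# parser therefore never trusts the printed numbers for bookkeeping beyond
# residue grouping.

guess_element <- function(atom_name) {
  nm <- toupper(gsub("[0-9]", "", atom_name))
  ifelse(nm %in% c("AU", "CL", "NA"), nm, substr(nm, 1L, 1L))
}

.parse_gro_time <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m)) as.numeric(sub("t=\\s*", "", m)) else NA_real_
}

read_gro <- function(path, moiety_map = default_moiety_map()) {
  lines <- readLines(path)
  frames <- list()
  top <- NULL
  i <- 1L
  n_frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L) {
      stop(sprintf("GRO parse error at line %d: bad atom count '%s'",
                   i + 1L, trimws(lines[i + 1L])))
    }
    if (i + 1L + natoms + 1L > length(lines)) {
      stop(sprintf("GRO structure error: frame starting at line %d expects %d atoms but file ends",
                   i, natoms))
    }
    at <- lines[(i + 2L):(i + 1L + natoms)]
    resnr <- suppressWarnings(as.integer(substr(at, 1L, 5L)))
    resname <- trimws(substr(at, 6L, 10L))
    atomname <- trimws(substr(at, 11L, 15L))
    x <- suppressWarnings(as.numeric(substr(at, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(at, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(at, 37L, 44L)))
    bad <- which(is.na(resnr) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad)) {
      stop(sprintf("GRO parse error at line %d: '%s'",
                   i + 1L + bad[1], at[bad[1]]))
    }
    boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + natoms]),
                                                   "\\s+")[[1]]))
    if (length(boxline) < 3L || anyNA(boxline[1:3])) {
      stop(sprintf("GRO parse error at line %d: bad box line", i + 2L + natoms))
    }
    n_frame <- n_frame + 1L
    if (is.null(top)) {
      element <- guess_element(atomname)
      moiety <- moiety_map[resname]
      if (anyNA(moiety)) {
        unknown <- unique(resname[is.na(moiety)])
        stop("no moiety mapping for residue(s): ",
             paste(unknown, collapse = ", "),
             " (extend the moiety_map argument)")
      }
      top <- topology(atom_name = atomname, residue_name = resname,
                      residue_index = resnr, moiety = unname(moiety),
                      peptide_index = ifelse(moiety %in% c("linker", "peptide"),
                                             0L, -1L),
                      element = element,
                      is_sidechain = atomname %in% c("CB", "SC"),
                      is_calpha = atomname == "CA" &
                        moiety %in% c("peptide", "protein"))
      top <- infer_chains(top)
      top <- validate_topology(top)
      n_ref <- natoms
    } else if (natoms != n_ref) {
      stop(sprintf("GRO structure error: frame %d has %d atoms, frame 1 had %d",
                   n_frame, natoms, n_ref))
    }
    tm <- .parse_gro_time(title)
    if (is.na(tm)) tm <- n_frame - 1
    frames[[n_frame]] <- frame(cbind(x, y, z), boxline[1:3], time = tm)
    i <- i + 3L + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (is.null(top)) stop("GRO parse error: no frames found in ", path)
  trajectory(top, frames)
}

write_gro <- function(traj, path) {
  top <- traj$topology
  n <- nrow(top)
  con <- file(path, open = "wt")
  on.exit(close(con))
  resnr <- top$residue_index %% 100000L
  atomnr <- top$atom_index %% 100000L
  for (f in traj$frames) {
    writeLines(sprintf("monolayer system t= %.5f", f$time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resnr, substr(top$residue_name, 1L, 5L),
                       substr(top$atom_name, 1L, 5L), atomnr,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]),
               con)
  }
  invisible(path)
}
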