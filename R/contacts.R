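# Contact scoring.  The pairwise contact count between grafted chains uses
# the rational switching function
#
#   S = sum_i sum_j [1 - (r_ij/r0)^6] / [1 - (r_ij/r0)^14],  r0 = 0.6 nm,
#
# summed over heavy-atom pairs of *different* peptides (XY minimum image)
# and optionally normalised by n(n-1)/2 for n peptides.  Close contacts
# and persistence maps use a strict distance cutoff (< 0.5 nm by
# convention).  Hydrogens are excluded by default: united-atom style
# topologies carry few or none.

#' Switching-function parameters
#'
#' @param r0 reference distance in nm.
#' @param num_exp,den_exp numerator and denominator exponents (the
#'   denominator exponent must be larger, keeping the function smooth and
#'   strictly decreasing).
#' @return object of class `sam_switch_params`.
#' @export
switch_params <- function(r0 = 0.6, num_exp = 6L, den_exp = 14L) {
  stopifnot(r0 > 0, num_exp > 0, den_exp > num_exp)
  structure(list(r0 = r0, num_exp = as.integer(num_exp),
                 den_exp = as.integer(den_exp)),
            class = "sam_switch_params")
}

#' Rational switching term
#'
#' `[1 - (r/r0)^a] / [1 - (r/r0)^b]`, with the analytic limit `a/b` at
#' `r = r0` (both numerator and denominator vanish there).  Continuous and
#' strictly decreasing on `r >= 0`; equals 1 at `r = 0` and decays as
#' `(r0/r)^(b-a)` at long range.
#'
#' @param r distances in nm (vectorised).
#' @param p a [switch_params()].
#' @return values in (0, 1].
#' @export
#' @examples
#' switch_term(c(0, 0.3, 0.6))  # 1, (1-0.5^6)/(1-0.5^14), 6/14
switch_term <- function(r, p = switch_params()) {
  stopifnot(all(r >= 0))
  x <- r / p$r0
  out <- ifelse(abs(x - 1) < 1e-12,
                p$num_exp / p$den_exp,
                (1 - x^p$num_exp) / (1 - x^p$den_exp))
  as.numeric(out)
}

#' Inter-peptide contact score (S function)
#'
#' Sum of [switch_term()] over all heavy-atom pairs belonging to different
#' grafted peptides, with the XY minimum image.  Terms beyond `truncation`
#' are dropped; at the default `5 * r0` a dropped term is below 3e-6, far
#' under the per-pair scores of interest.  With `normalize = TRUE` the sum
#' is divided by `n(n-1)/2` (n = number of peptides), the per-peptide-pair
#' convention used when comparing systems of different grafting counts.
#'
#' Applied to a trajectory, returns the per-frame score over a window.
#'
#' @param x a [frame()] or [trajectory()].
#' @param topology the topology (taken from `x` when it is a trajectory).
#' @param p a [switch_params()].
#' @param normalize divide by the number of peptide pairs?
#' @param include_hydrogens include hydrogen atoms?
#' @param truncation cutoff radius in nm (`Inf` disables truncation).
#' @param window time window for the trajectory method.
#' @return numeric score (frame) or vector of per-frame scores named by
#'   time (trajectory).
#' @export
s_function <- function(x, topology = NULL, p = switch_params(),
                       normalize = TRUE, include_hydrogens = FALSE,
                       truncation = 5 * p$r0, window = NULL) {
  if (inherits(x, "sam_trajectory")) {
    idx <- frames_in_window(x, window)
    out <- vapply(idx, function(k) {
      s_function(x$frames[[k]], x$topology, p, normalize,
                 include_hydrogens, truncation)
    }, numeric(1))
    return(setNames(out, frame_times(x)[idx]))
  }
  stopifnot(inherits(x, "sam_frame"), !is.null(topology))
  group <- topology$peptide_index
  group[topology$moiety != "peptide"] <- -1L
  if (!include_hydrogens) group[!topology$is_heavy] <- -1L
  n_pep <- length(unique(group[group > 0]))
  if (n_pep < 2) stop("S function needs at least two peptides")
  s <- cpp_switch_sum(x$positions, x$box, group, p$r0, p$num_exp,
                      p$den_exp, min(truncation, max(x$box) * 10), TRUE)
  if (normalize) s <- s / (n_pep * (n_pep - 1) / 2)
  s
}

# shared cross-pair machinery: strict `dist < cutoff`, XY minimum image
.cross_pairs_frame <- function(frm, set_a, set_b, cutoff) {
  mask <- integer(nrow(frm$positions))
  mask[set_a] <- 1L
  mask[set_b] <- 2L
  cpp_cross_pairs(frm$positions, frm$box, mask, cutoff, TRUE)
}

#' Close contacts between two atom sets
#'
#' Number of atom pairs (one atom from each set) at XY-minimum-image
#' distance strictly below `cutoff`, per frame, with a mean and standard
#' deviation over the window.  The convention for protein-monolayer
#' contacts is `cutoff = 0.5` nm over the last 20 ns.
#'
#' @param traj a [trajectory()].
#' @param set_a,set_b disjoint atom index sets.
#' @param cutoff contact distance in nm (strict `<`).
#' @param window time window, `NULL` for all frames.
#' @return list with `counts` (per-frame, named by time), `mean`, `sd`,
#'   `n_frames`, of class `sam_close_contacts`.
#' @export
close_contacts <- function(traj, set_a, set_b, cutoff = 0.5, window = NULL) {
  if (length(intersect(set_a, set_b))) {
    stop("set_a and set_b overlap; close contacts need disjoint selections")
  }
  if (!length(set_a) || !length(set_b)) stop("empty selection")
  idx <- frames_in_window(traj, window)
  counts <- vapply(idx, function(k) {
    length(.cross_pairs_frame(traj$frames[[k]], set_a, set_b, cutoff)$i)
  }, numeric(1))
  structure(list(counts = setNames(counts, frame_times(traj)[idx]),
                 mean = mean(counts),
                 sd = if (length(counts) > 1) sd(counts) else 0,
                 n_frames = length(counts), cutoff = cutoff),
            class = "sam_close_contacts")
}

#' @export
print.sam_close_contacts <- function(x, ...) {
  cat(sprintf("<sam_close_contacts> %.1f +/- %.1f pairs < %.2g nm over %d frames\n",
              x$mean, x$sd, x$cutoff, x$n_frames))
  invisible(x)
}

#' The PD-L1 active-spot residue set
#'
#' The 12 residues of the PD-L1 IgV-like domain at its PD-1 contact
#' surface, the standard reference set for persistence maps: Phe19, Asp26,
#' Ile54, Tyr56, Gln66, Arg113, Met115, Ala121, Asp122, Tyr123, Lys124,
#' Arg125 (numbering of the 3BIK crystal structure).
#'
#' @param offset added to the residue numbers for topologies with shifted
#'   numbering.
#' @return data.frame with columns `name`, `resid` and `index`.
#' @export
active_spots <- function(offset = 0L) {
  resid <- c("PHE", "ASP", "ILE", "TYR", "GLN", "ARG", "MET", "ALA",
             "ASP", "TYR", "LYS", "ARG")
  index <- c(19L, 26L, 54L, 56L, 66L, 113L, 115L, 121L, 122L, 123L,
             124L, 125L) + as.integer(offset)
  data.frame(name = paste0(resid, index), resid = resid, index = index,
             stringsAsFactors = FALSE)
}

#' Contact persistence map between peptide residues and active spots
#'
#' For each (peptide residue, active spot) pair, the persistence time is
#' the number of window frames in which *any* heavy-atom pair between the
#' two residues is closer than `cutoff`, times the frame interval, in ns.
#' Rows are peptide residue positions (pooled over all grafted chains);
#' columns are the spot labels.  Spots are matched on the protein moiety
#' by residue name (synthetic probes label beads with spot names) or by
#' residue number when `spots` carries plain indices.
#'
#' @param traj a [trajectory()] with peptide and protein moieties.
#' @param spots an [active_spots()]-style data.frame (columns `name` and
#'   either `resid`+`index` or just `name` matching protein residue
#'   names).
#' @param cutoff contact distance in nm (strict `<`).
#' @param window analysis window; the equilibrated-tail convention is the
#'   last 20 ns ([last_window()]).
#' @return object of class `sam_persistence_map`: list with `values`
#'   (rows x spots matrix, ns), `window_length` (ns), `cutoff`.
#' @export
persistence_map <- function(traj, spots = active_spots(), cutoff = 0.5,
                            window = NULL) {
  top <- traj$topology
  idx <- frames_in_window(traj, window)
  prot <- select_atoms(top, moiety = "protein", heavy_only = TRUE)
  if (!length(prot)) stop("no protein atoms in trajectory")

  # map each protein atom to a spot column (or NA)
  spot_of <- rep(NA_integer_, nrow(top))
  for (s in seq_len(nrow(spots))) {
    hit <- top$atom_index %in% prot & top$residue_name == spots$name[s]
    if (!is.null(spots$resid)) {
      hit <- hit | (top$atom_index %in% prot &
                      top$residue_name == spots$resid[s] &
                      top$residue_index == spots$index[s])
    }
    spot_of[hit] <- s
  }
  if (!any(!is.na(spot_of))) {
    stop("none of the active spots are present in the protein topology: ",
         paste(spots$name, collapse = ", "))
  }
  absent <- spots$name[!seq_len(nrow(spots)) %in% unique(spot_of[!is.na(spot_of)])]
  if (length(absent)) {
    stop("active spot(s) missing from protein topology: ",
         paste(absent, collapse = ", "))
  }

  # peptide rows: residue position within its chain
  pep <- select_atoms(top, moiety = "peptide", heavy_only = TRUE)
  pos_in_chain <- rep(NA_integer_, nrow(top))
  for (cc in unique(top$peptide_index[pep])) {
    at <- pep[top$peptide_index[pep] == cc]
    res <- top$residue_index[at]
    pos_in_chain[at] <- match(res, sort(unique(res)))
  }
  n_pos <- max(pos_in_chain, na.rm = TRUE)
  row_labels <- vapply(seq_len(n_pos), function(p) {
    nm <- unique(top$residue_name[which(pos_in_chain == p)])
    sprintf("%s%d", nm[1], p)
  }, character(1))

  spot_atoms <- which(!is.na(spot_of))
  counts <- matrix(0L, n_pos, nrow(spots),
                   dimnames = list(row_labels, spots$name))
  for (k in idx) {
    pr <- .cross_pairs_frame(traj$frames[[k]], pep, spot_atoms, cutoff)
    if (!length(pr$i)) next
    cells <- unique(cbind(pos_in_chain[pr$i], spot_of[pr$j]))
    counts[cells] <- counts[cells] + 1L
  }
  dt_ns <- traj$frame_interval / 1000
  structure(list(values = counts * dt_ns,
                 window_length = length(idx) * dt_ns,
                 cutoff = cutoff),
            class = "sam_persistence_map")
}

#' @export
print.sam_persistence_map <- function(x, ...) {
  cat(sprintf("<sam_persistence_map> %d residues x %d spots, window %.3g ns\n",
              nrow(x$values), ncol(x$values), x$window_length))
  cat(sprintf("  %d cells in contact, max persistence %.3g ns\n",
              sum(x$values > 0), max(x$values)))
  invisible(x)
}

#' Residue-pair contact counts between two selections
#'
#' Aggregates close contacts into residue-type pair counts, the input of
#' the contact-potential energy score.
#'
#' @inheritParams close_contacts
#' @return data.frame with columns `res_a`, `res_b`, `count` (pair counts
#'   summed over window frames).
#' @export
contact_pairs_by_residue <- function(traj, set_a, set_b, cutoff = 0.5,
                                     window = NULL) {
  if (length(intersect(set_a, set_b))) stop("selections must be disjoint")
  idx <- frames_in_window(traj, window)
  top <- traj$topology
  acc <- list()
  for (k in idx) {
    pr <- .cross_pairs_frame(traj$frames[[k]], set_a, set_b, cutoff)
    if (!length(pr$i)) next
    acc[[length(acc) + 1L]] <- data.frame(res_a = top$residue_name[pr$i],
                                          res_b = top$residue_name[pr$j],
                                          stringsAsFactors = FALSE)
  }
  if (!length(acc)) {
    return(data.frame(res_a = character(0), res_b = character(0),
                      count = integer(0)))
  }
  all_pairs <- do.call(rbind, acc)
  agg <- aggregate(list(count = rep(1L, nrow(all_pairs))),
                   by = all_pairs, FUN = sum)
  agg[order(agg$res_a, agg$res_b), , drop = FALSE]
}

#' Contact-potential energy score
#'
#' Knowledge-based pairwise score: the sum over contacting residue pairs
#' of a symmetric residue-type energy matrix (a Thomas-Dill style contact
#' potential).  The matrix is a required input -- no values are shipped --
#' and the result is a relative score, linear in the contact counts, not a
#' binding free energy.
#'
#' @param contacts data.frame from [contact_pairs_by_residue()] (columns
#'   `res_a`, `res_b`, `count`).
#' @param matrix symmetric numeric matrix with residue-type dimnames
#'   covering every type present in `contacts`.
#' @return total energy (matrix units).
#' @export
contact_energy <- function(contacts, matrix) {
  stopifnot(is.matrix(matrix), !is.null(dimnames(matrix)))
  if (max(abs(matrix - t(matrix))) > 1e-9) {
    stop("contact-energy matrix must be symmetric")
  }
  if (!nrow(contacts)) return(0)
  types <- union(contacts$res_a, contacts$res_b)
  missing <- setdiff(types, rownames(matrix))
  if (length(missing)) {
    stop("contact-energy matrix lacks residue type(s): ",
         paste(missing, collapse = ", "))
  }
  sum(matrix[cbind(contacts$res_a, contacts$res_b)] * contacts$count)
}
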