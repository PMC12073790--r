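# Frames and trajectories.  A frame is positions (nm) in an orthorhombic
# box; a trajectory is a constant topology plus time-ordered frames.
# Convention: Z = 0 at the mean plane of the gold atoms, increasing toward
# solvent; X and Y are periodic (minimum image), Z is not.

#' Create a coordinate frame
#'
#' @param positions numeric n x 3 matrix of coordinates in nm.
#' @param box length-3 numeric, box edges (Lx, Ly, Lz) in nm.
#' @param time time stamp in ps (>= 0).
#' @return object of class `sam_frame`.
#' @export
frame <- function(positions, box, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  storage.mode(positions) <- "double"
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) {
    stop("box must be three strictly positive edge lengths (nm)")
  }
  if (time < 0) stop("frame time must be >= 0 ps")
  structure(list(positions = positions, box = box, time = as.numeric(time)),
            class = "sam_frame")
}

#' Create a trajectory
#'
#' @param topology a [topology()].
#' @param frames list of [frame()]s with strictly increasing times and a
#'   constant atom count equal to the topology size.
#' @param frame_interval spacing between saved frames in ps (> 0); kept
#'   explicit because persistence analyses convert frame counts to times.
#' @return object of class `sam_trajectory`.
#' @export
trajectory <- function(topology, frames, frame_interval = NULL) {
  topology <- validate_topology(topology)
  if (!length(frames)) stop("a trajectory needs at least one frame")
  n <- nrow(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "sam_frame")) stop("frames must be sam_frame objects")
    if (nrow(f$positions) != n) {
      stop(sprintf("frame %d has %d atoms; topology has %d",
                   i, nrow(f$positions), n))
    }
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(frame_interval)) {
    frame_interval <- if (length(times) > 1L) diff(times)[1] else 1
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0 ps")
  structure(list(topology = topology, frames = frames,
                 frame_interval = as.numeric(frame_interval)),
            class = "sam_trajectory")
}

#' @export
print.sam_trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat(sprintf("<sam_trajectory> %d atoms, %d frame(s), t = %g..%g ps\n",
              nrow(x$topology), length(x$frames), min(times), max(times)))
  cat("  moieties:",
      paste(sprintf("%s (%d)", names(table(x$topology$moiety)),
                    table(x$topology$moiety)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sam_frame <- function(x, ...) {
  cat(sprintf("<sam_frame> %d atoms, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Frame time stamps of a trajectory
#' @param traj a trajectory.
#' @return numeric vector of times in ps.
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, `[[`, numeric(1), "time")
}

#' Indices of frames falling in a time window
#'
#' @param traj a trajectory.
#' @param window length-2 numeric `(t_start, t_end)` in ps, inclusive, or
#'   `NULL` for all frames.
#' @return integer vector of frame indices.
#' @export
frames_in_window <- function(traj, window = NULL) {
  times <- frame_times(traj)
  if (is.null(window)) return(seq_along(times))
  if (length(window) != 2L || window[2] < window[1]) {
    stop("window must be (t_start, t_end) with t_end >= t_start")
  }
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx)) {
    stop(sprintf("no frames in window [%g, %g] ps (trajectory spans %g..%g)",
                 window[1], window[2], min(times), max(times)))
  }
  idx
}

#' The last stretch of a trajectory as a window
#'
#' Convenience for "the last `length_ns` ns of the run", the standard
#' equilibrated analysis window.
#'
#' @param traj a trajectory.
#' @param length_ns window length in ns.
#' @return numeric `(t_start, t_end)` in ps.
#' @export
last_window <- function(traj, length_ns) {
  t_end <- max(frame_times(traj))
  c(max(0, t_end - 1000 * length_ns), t_end)
}

# Z of the gold reference plane for a frame (mean gold-atom Z), or 0 when
# the system has no gold (synthetic brushes use the reflecting floor at 0).
gold_plane_z <- function(top, frm) {
  gold <- top$moiety == "gold"
  if (any(gold)) mean(frm$positions[gold, 3]) else 0
}
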