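# Monolayer surface morphology: a gridded top-surface map (max atom Z +
# vdW radius per XY cell) and pocket detection.  Pockets are connected
# components of cells lying more than a depth threshold below the 90th
# percentile of the surface; their width is the diameter of the largest
# inscribed disc.  The quantitative anchor is whether a pocket can
# accommodate an immunoglobulin-domain-sized probe (4 nm deep, 3 nm wide).

#' Height map of a monolayer surface
#'
#' @param frm a [frame()].
#' @param topology the matching topology.
#' @param selection monolayer atoms; default heavy linker+peptide atoms.
#' @param grid_resolution XY cell edge in nm.
#' @param depth_threshold cells deeper than this below the 90th-percentile
#'   surface level are pocket candidates (nm).
#' @return object of class `sam_height_map`: list with `top_surface`
#'   (nx x ny matrix of Z in nm, measured from the gold plane), `pockets`
#'   (data.frame: `depth`, `width`, `area`, `x`, `y`), `grid_resolution`,
#'   `surface_level`.
#' @export
#' @examples
#' tr <- simulate_brush(synthetic_params(n_chains = 9, n_steps = 200))
#' hm <- height_map(tr$frames[[length(tr$frames)]], tr$topology)
#' hm$pockets
height_map <- function(frm, topology, selection = NULL,
                       grid_resolution = 0.2, depth_threshold = 1.5) {
  if (is.null(selection)) {
    selection <- select_atoms(topology, moiety = c("linker", "peptide"),
                              heavy_only = TRUE)
  }
  if (!length(selection)) stop("empty selection")
  box <- frm$box
  if (grid_resolution > min(box[1:2])) {
    stop("grid_resolution larger than the box XY face")
  }
  nx <- max(1L, floor(box[1] / grid_resolution))
  ny <- max(1L, floor(box[2] / grid_resolution))
  cx <- box[1] / nx
  cy <- box[2] / ny
  zref <- gold_plane_z(topology, frm)
  px <- frm$positions[selection, 1] %% box[1]
  py <- frm$positions[selection, 2] %% box[2]
  pz <- frm$positions[selection, 3] - zref + topology$vdw_radius[selection]
  ix <- pmin(nx - 1L, floor(px / cx)) + 1L
  iy <- pmin(ny - 1L, floor(py / cy)) + 1L

  top_surface <- matrix(NA_real_, nx, ny)
  cell <- (iy - 1L) * nx + ix
  agg <- tapply(pz, cell, max)
  top_surface[as.integer(names(agg))] <- agg

  # fill empty cells from the nearest occupied cell (periodic XY)
  if (anyNA(top_surface)) {
    filled <- which(!is.na(top_surface), arr.ind = TRUE)
    empty <- which(is.na(top_surface), arr.ind = TRUE)
    fz <- top_surface[filled]
    for (k in seq_len(nrow(empty))) {
      dx <- abs(filled[, 1] - empty[k, 1]); dx <- pmin(dx, nx - dx)
      dy <- abs(filled[, 2] - empty[k, 2]); dy <- pmin(dy, ny - dy)
      top_surface[empty[k, 1], empty[k, 2]] <- fz[which.min(dx^2 + dy^2)]
    }
  }

  level <- quantile(top_surface, 0.9, names = FALSE)
  deep <- top_surface < level - depth_threshold
  pockets <- .find_pockets(top_surface, deep, level, cx, cy)
  structure(list(top_surface = top_surface, pockets = pockets,
                 grid_resolution = grid_resolution, surface_level = level,
                 depth_threshold = depth_threshold),
            class = "sam_height_map")
}

# connected components of `deep` cells (EBImage 4-connectivity on the
# non-periodic grid), depth/width/area per component
.find_pockets <- function(surface, deep, level, cx, cy) {
  empty <- data.frame(depth = numeric(0), width = numeric(0),
                      area = numeric(0), x = numeric(0), y = numeric(0))
  if (!any(deep)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(deep * 1))
  labm <- EBImage::imageData(lab)
  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(deep * 1)))
  out <- lapply(seq_len(max(labm)), function(l) {
    cells <- which(labm == l, arr.ind = TRUE)
    depths <- level - surface[cells]
    # half-cell correction at both ends: distmap measures centre-to-centre
    data.frame(depth = max(depths),
               width = (2 * max(dist[cells]) + 1) * sqrt(cx * cy),
               area = nrow(cells) * cx * cy,
               x = mean(cells[, 1] - 0.5) * cx,
               y = mean(cells[, 2] - 0.5) * cy)
  })
  do.call(rbind, out)
}

#' @export
print.sam_height_map <- function(x, ...) {
  cat(sprintf("<sam_height_map> %d x %d cells at %.3g nm; surface level %.2f nm; %d pocket(s)\n",
              nrow(x$top_surface), ncol(x$top_surface), x$grid_resolution,
              x$surface_level, nrow(x$pockets)))
  invisible(x)
}

#' Can a pocket accommodate a probe of given size?
#'
#' `TRUE` when at least one detected pocket is at least `probe_depth` deep
#' and `probe_width` wide -- the geometric test for whether a rough
#' monolayer can host an immunoglobulin-type protein domain.
#'
#' @param map a [height_map()].
#' @param probe_depth,probe_width probe dimensions in nm (IgV-domain
#'   proxy: 4 x 3).
#' @return list with `accommodates` (logical) and `pockets` (the
#'   qualifying rows of `map$pockets`).
#' @export
accommodates_probe <- function(map, probe_depth = 4, probe_width = 3) {
  stopifnot(inherits(map, "sam_height_map"))
  ok <- map$pockets$depth >= probe_depth & map$pockets$width >= probe_width
  list(accommodates = any(ok), pockets = map$pockets[ok, , drop = FALSE])
}
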