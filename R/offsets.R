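# Offset trajectories: closed periodic cubic-spline curves displaced a
# signed distance from the attention-mask contour. Inward/outward offsets of
# the sampled polyline are trimmed (local self-intersection loops removed)
# and rejoined, then refit as periodic splines. Trajectories guide agent
# locomotion and supply tangent lookups for the observation vector.

#' Extract the closed boundary contour of a single-component mask
#'
#' Boundary pixel chain (EBImage), lightly smoothed by a circular moving
#' average, resampled and refit as a periodic cubic spline. CCW orientation
#' (positive signed area) is enforced.
#'
#' @param mask binary matrix with exactly one connected foreground component.
#' @param n_out number of contour samples returned.
#' @param smooth_window circular moving-average window (vertices).
#' @return n x 2 matrix (x, y), 0-based coordinates, closed implicitly.
#' @export
extract_contour <- function(mask, n_out = 512L, smooth_window = 7L) {
  lab <- EBImage::bwlabel(matrix(as.integer(mask > 0), nrow(mask)))
  ncomp <- max(lab)
  if (ncomp == 0) stop("empty mask")
  if (ncomp > 1) stop("mask has multiple components")
  oc <- EBImage::ocontour(lab)[[1]]
  # ocontour returns 0-based (dim1, dim2) indices; dim1 = row (y), dim2 = col (x)
  xy <- cbind(x = oc[, 2], y = oc[, 1])
  xy <- ensure_ccw(xy)
  xy <- resample_closed(xy, n_out = max(64L, round(poly_length(xy))))
  # circular moving average to suppress raster staircase
  w <- smooth_window
  ker <- rep(1 / w, w)
  pad <- function(v) c(utils::tail(v, w), v, utils::head(v, w))
  sm <- cbind(stats::filter(pad(xy[, 1]), ker, sides = 2)[(w + 1):(w + nrow(xy))],
              stats::filter(pad(xy[, 2]), ker, sides = 2)[(w + 1):(w + nrow(xy))])
  fit_periodic_spline(sm, n_out = n_out)$points
}

# Build one offset trajectory at signed level d (+ outward) from contour
# samples and tangents. Returns NULL when the offset annihilates.
offset_at_level <- function(sp, d, n_samples = 512L) {
  pts <- sp$points; tg <- sp$tangents
  # outward normal for CCW (positive shoelace) curves in (x right, y down)
  normal <- cbind(tg[, 2], -tg[, 1])
  off <- pts + d * normal
  if (d != 0) off <- trim_polyline_loops(off)
  if (is.null(off) || nrow(off) < 8) return(NULL)
  area <- abs(poly_signed_area(off))
  if (area < 4) return(NULL)                       # annihilated
  sp2 <- fit_periodic_spline(off, n_out = n_samples)
  structure(list(control_points = off, samples = sp2$points,
                 tangents = sp2$tangents, arc_length = sp2$period,
                 level = d, orientation = "CCW"),
            class = "offset_trajectory")
}

#' Align a contour with the edge map by a global normal shift
#'
#' The attention-mask boundary can sit a few pixels off the true edges
#' (threshold bias varies with contrast and speckle). Offsets are meant to
#' hug the boundary, so before the field is generated the contour is shifted
#' as a whole along its normals by the displacement that maximizes edge
#' support (fraction of contour samples within `tol` of an edge pixel). A
#' single global shift is robust against short false-edge arcs, which cannot
#' dominate the support of the full boundary.
#'
#' @param contour closed CCW polyline (n x 2).
#' @param edge_map binary matrix or `edge_map` object.
#' @param search candidate signed displacements (px, + outward).
#' @param tol support tolerance (px).
#' @return The shifted contour (same number of samples).
#' @export
align_contour_to_edges <- function(contour, edge_map,
                                   search = seq(-6, 6, by = 0.5), tol = 1.2) {
  if (inherits(edge_map, "edge_map")) edge_map <- edge_map$edges
  ep <- which(edge_map == 1L, arr.ind = TRUE)
  if (nrow(ep) == 0) return(contour)
  exy <- cbind(ep[, 2] - 1, ep[, 1] - 1)
  sp <- fit_periodic_spline(ensure_ccw(as.matrix(contour)), n_out = 256)
  normal <- cbind(sp$tangents[, 2], -sp$tangents[, 1])
  support <- vapply(search, function(d) {
    mean(min_dist_to_set(sp$points + d * normal, exy) <= tol)
  }, 0)
  d_best <- search[which.max(support)]
  sp2 <- fit_periodic_spline(ensure_ccw(as.matrix(contour)), n_out = nrow(contour))
  n2 <- cbind(sp2$tangents[, 2], -sp2$tangents[, 1])
  sp2$points + d_best * n2
}

#' Generate the offset field around a closed contour
#'
#' For levels `d in {0, +-spacing, +-2 spacing, ...}` (up to `n_levels`
#' trajectories), each spline sample is displaced along its outward normal,
#' local self-intersection loops are trimmed and rejoined, and a periodic
#' cubic spline is refit. Inward levels that annihilate (offset exceeds the
#' inradius) are dropped with a warning.
#'
#' @param contour n x 2 closed CCW polyline.
#' @param n_levels total number of levels (default 3: -1, 0, +1).
#' @param spacing level spacing in pixels (>= 1).
#' @param n_samples samples per trajectory.
#' @return An `offset_field`: list of `offset_trajectory` objects (sorted by
#'   level), `spacing`, `n_levels`, and a precomputed lookup table.
#' @export
generate_offsets <- function(contour, n_levels = 3L, spacing = 6, n_samples = 512L) {
  if (spacing < 1) stop("spacing must be >= 1 px")
  contour <- ensure_ccw(as.matrix(contour))
  sp <- fit_periodic_spline(contour, n_out = n_samples)
  half <- (n_levels - 1L) %/% 2L
  levels <- unique(sort(c(0, rep(seq_len(half + 1L), each = 2) * c(-1, 1) * spacing)))
  levels <- levels[order(abs(levels))][seq_len(n_levels)]
  trajs <- list()
  for (d in sort(levels)) {
    tr <- offset_at_level(sp, d, n_samples = n_samples)
    if (is.null(tr)) {
      warning(sprintf("offset level %+g annihilated; dropped", d))
      next
    }
    trajs[[length(trajs) + 1]] <- tr
  }
  if (length(trajs) == 0) stop("all offset levels annihilated")
  all_pts <- do.call(rbind, lapply(trajs, `[[`, "samples"))
  all_tg <- do.call(rbind, lapply(trajs, `[[`, "tangents"))
  traj_id <- rep(seq_along(trajs), vapply(trajs, function(t) nrow(t$samples), 0L))
  structure(list(trajectories = trajs, spacing = spacing, n_levels = n_levels,
                 lookup = list(points = all_pts, tangents = all_tg, id = traj_id)),
            class = "offset_field")
}

#' Tangent of the nearest offset point
#'
#' Finds the nearest point across all trajectories of the field (dense
#' sampled lookup) and returns the unit spline tangent there, oriented to the
#' querying agent's traversal sense.
#'
#' @param field an `offset_field`.
#' @param position length-2 numeric (x, y).
#' @param sense `"CCW"` (as stored) or `"CW"` (tangent negated).
#' @return `list(tangent, point, trajectory, distance)`.
#' @export
tangent_at_nearest <- function(field, position, sense = c("CCW", "CW")) {
  sense <- match.arg(sense)
  P <- field$lookup$points
  d2 <- (P[, 1] - position[1])^2 + (P[, 2] - position[2])^2
  i <- which.min(d2)
  tg <- field$lookup$tangents[i, ]
  if (sense == "CW") tg <- -tg
  list(tangent = tg, point = P[i, ], trajectory = field$lookup$id[i],
       distance = sqrt(d2[i]))
}

#' Serialize an offset field to JSON
#' @param field an `offset_field`.
#' @param path output path.
#' @export
write_offsets_json <- function(field, path) {
  obj <- list(spacing = field$spacing, n_levels = field$n_levels,
              trajectories = lapply(field$trajectories, function(tr)
                list(level = tr$level, orientation = tr$orientation,
                     arc_length = tr$arc_length,
                     control_points = unname(as.matrix(tr$control_points)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
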