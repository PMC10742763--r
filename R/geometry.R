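# Shared planar-geometry primitives for contours, offsets and metrics.
#
# Conventions (used everywhere in the package):
#  * pixel coordinates are 0-based, pixel centers at integer coordinates;
#  * a contour is an n x 2 matrix with columns (x = col, y = row), vertices
#    ordered, closed implicitly (last vertex connects back to the first);
#  * CCW means positive shoelace signed area in these coordinates.

#' Signed area of a closed polygon
#'
#' Shoelace formula. Positive area defines the CCW orientation convention
#' used throughout the package (x right, y down; stated once, used
#' everywhere).
#'
#' @param xy n x 2 matrix of vertices (x, y), closed implicitly.
#' @return Signed area (pixels^2).
#' @export
poly_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Perimeter of a closed polyline
#' @param xy n x 2 vertex matrix.
#' @return Total length in pixels.
#' @export
poly_length <- function(xy) {
  d <- xy - xy[c(2:nrow(xy), 1), ]
  sum(sqrt(rowSums(d^2)))
}

#' Orient a closed polyline counter-clockwise
#' @param xy n x 2 vertex matrix.
#' @return The same vertices, reversed if the signed area was negative.
#' @export
ensure_ccw <- function(xy) {
  if (poly_signed_area(xy) < 0) xy[nrow(xy):1, , drop = FALSE] else xy
}

#' Resample a closed polyline at uniform arc-length spacing
#'
#' Linear interpolation along the closed chain. Used to make point counts
#' proportional to contour length so that length-normalized sums (average
#' Hausdorff distance) are well-posed.
#'
#' @param xy n x 2 vertex matrix, closed implicitly.
#' @param n_out number of output points; if `NULL`, derived from `spacing`.
#' @param spacing target arc spacing in pixels (default 1).
#' @return m x 2 matrix of resampled points.
#' @export
resample_closed <- function(xy, n_out = NULL, spacing = 1) {
  xy <- as.matrix(xy)
  seg <- sqrt(rowSums((xy[c(2:nrow(xy), 1), , drop = FALSE] - xy)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate (zero-length) contour")
  if (is.null(n_out)) n_out <- max(8L, round(L / spacing))
  s <- c(0, cumsum(seg))               # arc position of each vertex, s[n+1] = L
  target <- (seq_len(n_out) - 1) * L / n_out
  idx <- findInterval(target, s, rightmost.closed = FALSE)
  idx[idx > nrow(xy)] <- nrow(xy)
  frac <- (target - s[idx]) / pmax(seg[idx], .Machine$double.eps)
  nxt <- ifelse(idx == nrow(xy), 1L, idx + 1L)
  xy[idx, , drop = FALSE] + frac * (xy[nxt, , drop = FALSE] - xy[idx, , drop = FALSE])
}

# Periodic cubic-spline fit of a closed curve, parameterized by cumulative
# chord length. Returns sampled points and unit tangents, plus the spline
# functions for later evaluation.
fit_periodic_spline <- function(xy, n_out = 512) {
  xy <- as.matrix(xy)
  # drop duplicated consecutive points (periodic splines reject ties)
  d <- sqrt(rowSums((xy - xy[c(nrow(xy), 1:(nrow(xy) - 1)), ])^2))
  keep <- d > 1e-9
  keep[1] <- TRUE
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 4) stop("too few distinct points for a periodic spline")
  seg <- sqrt(rowSums((xy[c(2:nrow(xy), 1), ] - xy)^2))
  t0 <- c(0, cumsum(seg))
  L <- t0[length(t0)]
  tx <- c(t0[-length(t0)], L)
  fx <- stats::splinefun(tx, c(xy[, 1], xy[1, 1]), method = "periodic")
  fy <- stats::splinefun(tx, c(xy[, 2], xy[1, 2]), method = "periodic")
  tt <- seq(0, L, length.out = n_out + 1)[-(n_out + 1)]
  pts <- cbind(fx(tt), fy(tt))
  tg <- cbind(fx(tt, deriv = 1), fy(tt, deriv = 1))
  nrm <- sqrt(rowSums(tg^2))
  tg <- tg / pmax(nrm, .Machine$double.eps)
  list(points = pts, tangents = tg, fx = fx, fy = fy, period = L)
}

# Proper intersection test between segments (p1,p2) and (p3,p4), vectorized
# over rows. Returns intersection parameters or NA.
segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  dp <- p3 - p1
  t <- (dp[, 1] * d2[, 2] - dp[, 2] * d2[, 1]) / denom
  u <- (dp[, 1] * d1[, 2] - dp[, 2] * d1[, 1]) / denom
  ok <- is.finite(t) & is.finite(u) & abs(denom) > eps &
    t > eps & t < 1 - eps & u > eps & u < 1 - eps
  list(ok = ok, t = t, u = u)
}

#' Find self-intersections of a closed polyline
#'
#' Brute-force test of all non-adjacent segment pairs. Used both by the
#' offset trimming step and as the simplicity check on assembled contours.
#'
#' @param xy n x 2 vertex matrix, closed implicitly.
#' @return A matrix with columns (i, j, x, y): intersecting segment indices
#'   (segment i runs from vertex i to i+1) and the crossing point; zero rows
#'   when the polyline is simple.
#' @export
self_intersections <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(matrix(numeric(0), 0, 4, dimnames = list(NULL, c("i", "j", "x", "y"))))
  nxt <- c(2:n, 1L)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  # exclude adjacent segments (share a vertex), including the wrap-around pair
  adj <- pairs[, 2] - pairs[, 1] == 1 | (pairs[, 1] == 1 & pairs[, 2] == n)
  pairs <- pairs[!adj, , drop = FALSE]
  if (nrow(pairs) == 0) return(matrix(numeric(0), 0, 4, dimnames = list(NULL, c("i", "j", "x", "y"))))
  i <- pairs[, 1]; j <- pairs[, 2]
  r <- segments_intersect(xy[i, , drop = FALSE], xy[nxt[i], , drop = FALSE],
                          xy[j, , drop = FALSE], xy[nxt[j], , drop = FALSE])
  hit <- which(r$ok)
  out <- cbind(i = i[hit], j = j[hit],
               x = xy[i[hit], 1] + r$t[hit] * (xy[nxt[i[hit]], 1] - xy[i[hit], 1]),
               y = xy[i[hit], 2] + r$t[hit] * (xy[nxt[i[hit]], 2] - xy[i[hit], 2]))
  colnames(out) <- c("i", "j", "x", "y")
  out
}

# Trim local self-intersection loops from a closed polyline: at each crossing
# remove the shorter arc between the crossing segments and insert the
# crossing point, then repeat until simple. The workhorse of the
# trim-and-join offset construction.
trim_polyline_loops <- function(xy, max_pass = 50) {
  for (pass in seq_len(max_pass)) {
    x <- self_intersections(xy)
    if (nrow(x) == 0) return(xy)
    n <- nrow(xy)
    # handle the crossing with the shortest enclosed arc first
    arc <- pmin(x[, "j"] - x[, "i"], n - (x[, "j"] - x[, "i"]))
    k <- which.min(arc)
    i <- x[k, "i"]; j <- x[k, "j"]; p <- x[k, c("x", "y")]
    inner <- (j - i)            # vertices i+1 .. j form one arc
    if (inner <= n - inner) {
      keep <- setdiff(seq_len(n), (i + 1):j)
      # insert crossing point after vertex i
      pos <- match(i, keep)
      xy <- rbind(xy[keep[seq_len(pos)], , drop = FALSE], p,
                  if (pos < length(keep)) xy[keep[(pos + 1):length(keep)], , drop = FALSE])
    } else {
      keep <- (i + 1):j         # keep the inner arc, drop the outer one
      xy <- rbind(p, xy[keep, , drop = FALSE])
    }
    if (nrow(xy) < 4) return(xy)
  }
  xy
}

#' Rasterize a closed polygon to a binary mask
#'
#' Even-odd scanline fill over pixel centers (integer coordinates).
#'
#' @param xy n x 2 vertex matrix (x, y), 0-based coordinates.
#' @param nrow,ncol mask dimensions (rows = y, cols = x).
#' @return Integer matrix (`nrow` x `ncol`) with 1 inside the polygon.
#' @export
rasterize_polygon <- function(xy, nrow, ncol) {
  mask <- matrix(0L, nrow, ncol)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (row in 0:(nrow - 1)) {
    yr <- row
    crosses <- (y <= yr & y2 > yr) | (y2 <= yr & y > yr)
    if (!any(crosses)) next
    xi <- x[crosses] + (yr - y[crosses]) / (y2[crosses] - y[crosses]) * (x2[crosses] - x[crosses])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      a <- ceiling(xi[k] - 1e-9); b <- floor(xi[k + 1] + 1e-9)
      a <- max(a, 0); b <- min(b, ncol - 1)
      if (a <= b) mask[row + 1, (a:b) + 1] <- 1L
    }
  }
  mask
}

#' Discrete curvature of a path (Menger / circumscribed circle)
#'
#' Curvature at each interior vertex equals 1/R of the circle through the
#' vertex and its two neighbors: kappa = 4 * area / (a * b * c). Collinear
#' triplets give 0.
#'
#' @param path n x 2 matrix of positions.
#' @return Numeric vector of length n - 2 of unsigned curvatures (1/px).
#' @export
menger_curvature <- function(path) {
  n <- nrow(path)
  if (n < 3) return(numeric(0))
  p1 <- path[1:(n - 2), , drop = FALSE]
  p2 <- path[2:(n - 1), , drop = FALSE]
  p3 <- path[3:n, , drop = FALSE]
  a <- sqrt(rowSums((p2 - p1)^2))
  b <- sqrt(rowSums((p3 - p2)^2))
  cc <- sqrt(rowSums((p3 - p1)^2))
  cross <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  area2 <- abs(cross)                       # 2 * triangle area
  denom <- a * b * cc
  k <- ifelse(denom > 1e-12, 2 * area2 / denom, 0)
  k
}

#' Minimum enclosing circle of a point set
#'
#' Welzl's randomized incremental algorithm (expected linear time), run on
#' the convex hull for speed. Exact for the 1/2/3-point support cases.
#'
#' @param pts n x 2 matrix of points.
#' @param seed integer seed for the random permutation (determinism).
#' @return `list(center = c(x, y), radius = r)`.
#' @export
min_enclosing_circle <- function(pts, seed = 1L) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 0) stop("empty point set")
  if (nrow(pts) == 1) return(list(center = pts[1, ], radius = 0))
  if (nrow(pts) > 3) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[h, , drop = FALSE]
  }
  ord <- withr_seed_sample(nrow(pts), seed)
  pts <- pts[ord, , drop = FALSE]
  circ2 <- function(p, q) list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: widest pair
      cands <- list(circ2(p, q), circ2(q, r), circ2(p, r))
      return(cands[[which.max(vapply(cands, `[[`, 0, "radius"))]])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) + (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) + (cx^2 + cy^2) * (bx - ax)) / d
    list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(c, p, tol = 1e-7) sqrt(sum((p - c$center)^2)) <= c$radius + tol
  n <- nrow(pts)
  circ <- list(center = pts[1, ], radius = 0)
  for (i in 2:n) {
    if (inside(circ, pts[i, ])) next
    circ <- list(center = pts[i, ], radius = 0)
    for (j in 1:(i - 1)) {
      if (inside(circ, pts[j, ])) next
      circ <- circ2(pts[i, ], pts[j, ])
      if (j > 1) for (k in 1:(j - 1)) {
        if (inside(circ, pts[k, ])) next
        circ <- circ3(pts[i, ], pts[j, ], pts[k, ])
      }
    }
  }
  circ
}

# Deterministic combination of two integer seeds, kept within R's 32-bit
# integer range.
mix_seed <- function(a, b) {
  as.integer((as.numeric(a) %% 65521) * 32749 + (as.numeric(b) %% 32749)) %% 2147483645L + 1L
}

# Seeded permutation that does not disturb the caller's RNG stream.
withr_seed_sample <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

# Smallest distance from each query point to a reference point set,
# chunked to bound memory. pts, ref: m x 2 / n x 2 matrices.
min_dist_to_set <- function(pts, ref, chunk = 2048L) {
  m <- nrow(pts)
  out <- numeric(m)
  for (s in seq(1, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    dx <- outer(pts[s:e, 1], ref[, 1], "-")
    dy <- outer(pts[s:e, 2], ref[, 2], "-")
    out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

# Rotate 2-vectors (rows) by an angle in radians.
rotate2 <- function(v, theta) {
  ct <- cos(theta); st <- sin(theta)
  if (is.null(dim(v))) v <- matrix(v, 1)
  cbind(ct * v[, 1] - st * v[, 2], st * v[, 1] + ct * v[, 2])
}

# Angle between two direction vectors, degrees in [0, 180].
angle_between <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cu))) * 180 / pi
}
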