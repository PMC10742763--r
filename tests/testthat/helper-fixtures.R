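# Shared fixtures, built in code at test time.

# Binary disk mask of given radius centered in an n x n grid.
disk_mask <- function(n = 80, cx = n / 2, cy = n / 2, radius = 30) {
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), times = n), n)
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 <= radius^2), n)
}

# Analytic circle contour (x, y), CCW in the package's convention.
circle_contour <- function(radius = 30, cx = 40, cy = 40, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ensure_ccw(cbind(x = cx + radius * cos(th), y = cy + radius * sin(th)))
}

# Memoized easy phantom so several test files can share one build.
the_fixture_env <- new.env()
easy_phantom <- function(seed = 3) {
  key <- paste0("ph", seed)
  if (is.null(the_fixture_env[[key]]))
    the_fixture_env[[key]] <- make_phantom(phantom_spec(seed = seed))
  the_fixture_env[[key]]
}

# Brute-force directed Hausdorff oracles.
brute_hausdorff <- function(X, Y) {
  dxy <- function(A, B) max(apply(A, 1, function(a)
    min(sqrt((B[, 1] - a[1])^2 + (B[, 2] - a[2])^2))))
  max(dxy(X, Y), dxy(Y, X))
}
brute_avg_hausdorff <- function(X, Y, LX = nrow(X), LY = nrow(Y)) {
  s <- function(A, B, L) sum(apply(A, 1, function(a)
    min(sqrt((B[, 1] - a[1])^2 + (B[, 2] - a[2])^2)))) / L
  max(s(X, Y, LX), s(Y, X, LY))
}

# Brute-force minimum enclosing circle over all 1/2/3-point supports.
brute_mec <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  best <- NULL
  check <- function(c0, r) {
    if (all(sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2) <= r + 1e-9)) {
      if (is.null(best) || r < best$radius) best <<- list(center = c0, radius = r)
    }
  }
  for (i in 1:n) check(pts[i, ], 0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    check((pts[i, ] + pts[j, ]) / 2, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; d <- pts[k, ]
    den <- 2 * (a[1] * (b[2] - d[2]) + b[1] * (d[2] - a[2]) + d[1] * (a[2] - b[2]))
    if (abs(den) < 1e-12) next
    ux <- (sum(a^2) * (b[2] - d[2]) + sum(b^2) * (d[2] - a[2]) + sum(d^2) * (a[2] - b[2])) / den
    uy <- (sum(a^2) * (d[1] - b[1]) + sum(b^2) * (a[1] - d[1]) + sum(d^2) * (b[1] - a[1])) / den
    check(c(ux, uy), sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
  }
  best
}
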