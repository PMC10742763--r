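# Synthetic ultrasound-like phantoms with known ground truth.
#
# The boundary is a star-shaped radial curve r(phi) = R * (1 + sum_k a_k *
# sin(k phi + phi_k)), which is guaranteed simple as long as r(phi) > 0, and
# whose lobe count/amplitude directly control the shape-complexity score
# (area deficit against the minimum enclosing circle). Edge-map pathology is
# injected explicitly: boundary arcs are removed to create gaps (total and
# maximum gap fractions are the taxonomy's two gap statistics) and distractor
# arcs are added as false edges. Speckle is emulated as multiplicative
# log-normal noise followed by a Gaussian blur; false edges are geometric
# objects, not noise.

#' Phantom construction parameters
#'
#' @param image_size side of the square image in pixels.
#' @param shape_mode one of `"simple_blob"`, `"lobulated"`, `"spiculated"`.
#' @param n_lobes number of angular lobes (defaults per shape mode).
#' @param lobe_amplitude lobe amplitude as a fraction of the base radius
#'   (defaults per shape mode).
#' @param gap_total_frac fraction in `[0, 1)` of boundary arc length removed
#'   from the edge map.
#' @param gap_max_frac fraction in `[0, 1)` for the single largest gap; must
#'   not exceed `gap_total_frac`.
#' @param n_false_edges number of distractor arcs drawn inside/outside the
#'   lesion.
#' @param noise_sigma scale of the multiplicative log-normal speckle.
#' @param seed integer seed; the phantom is a deterministic function of the
#'   spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         shape_mode = c("simple_blob", "lobulated", "spiculated"),
                         n_lobes = NULL, lobe_amplitude = NULL,
                         gap_total_frac = 0, gap_max_frac = 0,
                         n_false_edges = 0L, noise_sigma = 0.15, seed = 1L) {
  shape_mode <- match.arg(shape_mode)
  defaults <- switch(shape_mode,
    simple_blob = list(n_lobes = 2L, lobe_amplitude = 0.05),
    lobulated   = list(n_lobes = 4L, lobe_amplitude = 0.12),
    spiculated  = list(n_lobes = 7L, lobe_amplitude = 0.25))
  if (is.null(n_lobes)) n_lobes <- defaults$n_lobes
  if (is.null(lobe_amplitude)) lobe_amplitude <- defaults$lobe_amplitude
  if (gap_max_frac > gap_total_frac + 1e-12)
    stop("gap_max_frac must not exceed gap_total_frac")
  if (gap_total_frac >= 1 || gap_total_frac < 0 || gap_max_frac < 0)
    stop("gap fractions must lie in [0, 1)")
  if (gap_total_frac > 0 && gap_max_frac <= 0)
    stop("gap_max_frac must be positive when gap_total_frac > 0")
  structure(list(image_size = as.integer(image_size), shape_mode = shape_mode,
                 n_lobes = as.integer(n_lobes), lobe_amplitude = lobe_amplitude,
                 gap_total_frac = gap_total_frac, gap_max_frac = gap_max_frac,
                 n_false_edges = as.integer(n_false_edges),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Sample non-overlapping gap intervals (fractions of total arc length) on the
# unit circle of boundary parameter. The largest gap is placed first so the
# requested maximum is hit exactly; the remainder is split into gaps strictly
# smaller than the maximum.
place_gaps <- function(total, gmax, margin = 0.004, min_len = 0.025) {
  if (total <= 0) {
    out <- matrix(numeric(0), 0, 2)
    attr(out, "lens") <- numeric(0)
    return(out)
  }
  lens <- gmax
  remaining <- total - gmax
  while (remaining > 1e-9) {
    # individual gaps stay above ~min_len of the boundary so they remain
    # resolvable by the coverage tolerance of the gap statistics
    len <- max(min(min_len, gmax), stats::runif(1, 0.45, 0.95) * gmax)
    if (remaining - len < 1.2 * min_len)
      len <- if (remaining <= 0.95 * gmax) remaining else remaining / 2
    len <- min(len, remaining)
    lens <- c(lens, len)
    remaining <- remaining - len
  }
  k <- length(lens)
  free <- 1 - sum(lens) - k * margin
  if (free <= 0) stop("gap fractions too large to place on the boundary")
  # sequential layout around the circle: random phase, random spacer split
  w <- stats::runif(k)
  spacer <- margin + free * w / sum(w)
  ord <- if (k > 1) c(1, 1 + sample.int(k - 1)) else 1L
  lens_o <- lens[ord]
  phase <- stats::runif(1)
  starts <- phase + cumsum(c(0, utils::head(lens_o + spacer[ord], -1)))
  ends <- starts + lens_o
  # wrap into [0, 1), splitting intervals that cross 1
  s0 <- starts %% 1; e0 <- s0 + lens_o
  outs <- c(); oute <- c()
  for (i in seq_len(k)) {
    if (e0[i] <= 1) { outs <- c(outs, s0[i]); oute <- c(oute, e0[i]) }
    else {
      outs <- c(outs, s0[i], 0); oute <- c(oute, 1, e0[i] - 1)
    }
  }
  out <- cbind(start = outs, end = oute)
  attr(out, "lens") <- lens
  out
}

#' Generate a synthetic ultrasound-like phantom
#'
#' Deterministic for a fixed spec (including its seed). The lesion is darker
#' than the background (hypoechoic); the edge map is the rasterized
#' ground-truth boundary minus the requested gap arcs, plus distractor arcs.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom` with fields `image` (matrix in
#'   0..255), `edge_map` (binary matrix), `gt_contour` (n x 2, (x, y)),
#'   `gt_mask` (binary matrix), realized gap/shape statistics, and the spec.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) { if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()) }
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  n <- spec$image_size
  cx <- n / 2 + stats::runif(1, -2, 2)
  cy <- n / 2 + stats::runif(1, -2, 2)
  R <- stats::runif(1, 0.22, 0.28) * n
  amp <- spec$lobe_amplitude * stats::runif(1, 0.9, 1.1)
  k <- spec$n_lobes
  phi0 <- stats::runif(1, 0, 2 * pi)
  # a mild second harmonic breaks the perfect rotational symmetry
  amp2 <- if (spec$shape_mode == "simple_blob") 0 else 0.25 * amp
  phi2 <- stats::runif(1, 0, 2 * pi)
  radial <- function(phi) R * (1 + amp * sin(k * phi + phi0) + amp2 * sin((k + 2) * phi + phi2))
  phis <- seq(0, 2 * pi, length.out = 2049)[-2049]
  rr <- radial(phis)
  if (any(rr <= 1))
    stop("radial function nonpositive: boundary would not be simple")
  contour <- cbind(x = cx + rr * cos(phis), y = cy + rr * sin(phis))
  if (any(contour < 1) || any(contour > n - 2))
    stop("boundary exceeds the image; reduce radius or amplitude")
  contour <- ensure_ccw(contour)

  # ground-truth mask straight from the radial function (star-shaped test)
  xs <- matrix(rep(0:(n - 1), each = n), n)     # column index = x
  ys <- matrix(rep(0:(n - 1), times = n), n)    # row index = y
  ang <- atan2(ys - cy, xs - cx)
  gt_mask <- matrix(as.integer(sqrt((xs - cx)^2 + (ys - cy)^2) <= radial(ang)), n)

  # edge map: dense boundary samples at ~4 per pixel of arc, minus gaps
  L <- poly_length(contour)
  dense <- resample_closed(contour, n_out = max(512L, round(4 * L)))
  u <- (seq_len(nrow(dense)) - 1) / nrow(dense)      # arc-length parameter
  gaps <- place_gaps(spec$gap_total_frac, spec$gap_max_frac)
  in_gap <- rep(FALSE, length(u))
  if (nrow(gaps) > 0)
    for (g in seq_len(nrow(gaps))) in_gap <- in_gap | (u >= gaps[g, 1] & u < gaps[g, 2])
  edge_map <- matrix(0L, n, n)
  keep <- dense[!in_gap, , drop = FALSE]
  if (nrow(keep) > 0) {
    ij <- cbind(pmin(pmax(round(keep[, 2]), 0), n - 1) + 1,
                pmin(pmax(round(keep[, 1]), 0), n - 1) + 1)
    edge_map[ij] <- 1L
  }
  glens <- attr(gaps, "lens")
  realized_total <- if (length(glens) > 0) sum(glens) else 0
  realized_max <- if (length(glens) > 0) max(glens) else 0

  # false edges: short circular arcs kept clear of the true boundary
  if (spec$n_false_edges > 0) {
    for (f in seq_len(spec$n_false_edges)) {
      inside <- f %% 2 == 0
      cdist <- if (inside) stats::runif(1, 0.25, 0.5) else stats::runif(1, 1.35, 1.7)
      aphi <- stats::runif(1, 0, 2 * pi)
      ctr <- c(cx, cy) + cdist * radial(aphi) * c(cos(aphi), sin(aphi))
      rho <- stats::runif(1, 4, 10)
      a0 <- stats::runif(1, 0, 2 * pi)
      span <- stats::runif(1, pi / 3, pi)
      tt <- seq(a0, a0 + span, length.out = max(16, round(rho * span * 4)))
      arc <- cbind(ctr[1] + rho * cos(tt), ctr[2] + rho * sin(tt))
      ok <- arc[, 1] >= 0 & arc[, 1] <= n - 1 & arc[, 2] >= 0 & arc[, 2] <= n - 1
      arc <- arc[ok, , drop = FALSE]
      if (nrow(arc) == 0) next
      # keep only arc pixels at least 4 px away from the true boundary
      dmin <- min_dist_to_set(arc, dense)
      arc <- arc[dmin > 4, , drop = FALSE]
      if (nrow(arc) > 0)
        edge_map[cbind(round(arc[, 2]) + 1, round(arc[, 1]) + 1)] <- 1L
    }
  }

  # grayscale rendering: hypoechoic lesion, speckle, blur
  img <- matrix(150, n, n)
  img[gt_mask == 1] <- 60
  img <- as.matrix(EBImage::gblur(img, sigma = 1.2))
  if (spec$noise_sigma > 0) {
    z <- matrix(stats::rnorm(n * n), n)
    z <- as.matrix(EBImage::gblur(z, sigma = 0.8))   # short-range correlation
    z <- z / stats::sd(z)
    img <- img * exp(spec$noise_sigma * z - spec$noise_sigma^2 / 2)
  }
  img <- round(pmin(pmax(img, 0), 255))

  shape <- shape_score(gt_mask)
  structure(list(image = img, edge_map = edge_map,
                 gt_contour = resample_closed(contour, spacing = 1),
                 gt_mask = gt_mask,
                 realized_gap_total_frac = realized_total,
                 realized_gap_max_frac = realized_max,
                 realized_shape_score = shape,
                 spec = spec),
            class = "phantom")
}

# Category codes in the fixed curriculum order: sorted by number of tough
# letters, then by letter position (shape, max gap, total gap).
#' The eight edge-map complexity category codes
#' @return Character vector `"B|B|B" ... "T|T|T"` in curriculum order
#'   (easiest first).
#' @export
category_codes <- function() {
  c("B|B|B", "B|B|T", "B|T|B", "T|B|B", "B|T|T", "T|B|T", "T|T|B", "T|T|T")
}

#' Phantom spec for a complexity-category code
#'
#' Draws construction parameters at the category's levels. Baseline
#' total-gap sits above the tough max-gap level so that a lone large gap
#' (B|T|B) remains constructible under gap_max <= gap_total.
#'
#' @param code a category code from [category_codes()].
#' @param image_size image side in pixels.
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
category_spec <- function(code, image_size = 128L, seed = 1L) {
  parts <- strsplit(code, "|", fixed = TRUE)[[1]]
  S <- parts[1]; Cmax <- parts[2]; Ctot <- parts[3]
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) { if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()) }
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  gmax <- if (Cmax == "B") stats::runif(1, 0.028, 0.045) else stats::runif(1, 0.19, 0.23)
  gtot <- if (Ctot == "B") stats::runif(1, 0.24, 0.28) else stats::runif(1, 0.50, 0.56)
  gtot <- max(gtot, gmax)
  phantom_spec(image_size = image_size,
               shape_mode = if (S == "B") "simple_blob" else "spiculated",
               gap_total_frac = gtot, gap_max_frac = gmax,
               n_false_edges = sample(1:3, 1), noise_sigma = 0.15,
               seed = sample.int(2^30, 1))
}

#' Generate a labeled phantom corpus spanning all eight complexity codes
#'
#' @param n_per_category phantoms per code (>= 1).
#' @param seed integer master seed.
#' @param dir optional directory; when given, images/masks (PNG), contours
#'   (JSON) and a CSV manifest are written there.
#' @param image_size image side in pixels.
#' @return A list with `phantoms` (list of [make_phantom()] results),
#'   `category` (intent code per phantom) and `manifest` (data frame).
#' @export
make_corpus <- function(n_per_category, seed = 1L, dir = NULL, image_size = 128L) {
  stopifnot(n_per_category >= 1)
  codes <- category_codes()
  phantoms <- list(); category <- character(0)
  rows <- list()
  id <- 0L
  for (code in codes) {
    for (rep in seq_len(n_per_category)) {
      id <- id + 1L
      sp <- category_spec(code, image_size = image_size,
                          seed = mix_seed(seed, id))
      ph <- make_phantom(sp)
      phantoms[[id]] <- ph
      category[id] <- code
      paths <- c(image = NA_character_, mask = NA_character_, contour = NA_character_)
      if (!is.null(dir)) paths <- write_phantom(ph, dir, sprintf("phantom_%03d", id))
      rows[[id]] <- data.frame(id = id, category_code = code,
                               gap_total = ph$realized_gap_total_frac,
                               gap_max = ph$realized_gap_max_frac,
                               shape_score = ph$realized_shape_score,
                               image_path = paths[["image"]],
                               mask_path = paths[["mask"]],
                               contour_path = paths[["contour"]],
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(phantoms = phantoms, category = category, manifest = manifest)
}

#' Generate a prevalence-weighted reference corpus for threshold calibration
#'
#' Complexity thresholds are defined as mean + one standard deviation of each
#' statistic over a reference corpus; that rule presupposes a corpus in which
#' tough cases are tail events, as in clinical collections. Codes are drawn
#' with prevalence proportional to (1/3)^(#T); with the default `n = 64` the
#' composition is exact (27/9/9/9/3/3/3/1) and each letter is tough in
#' exactly 25% of phantoms.
#'
#' @param n corpus size (multiples of 64 keep the composition exact).
#' @param seed integer seed.
#' @param image_size image side in pixels.
#' @return Same structure as [make_corpus()].
#' @export
reference_corpus <- function(n = 64L, seed = 1L, image_size = 128L) {
  codes <- category_codes()
  nt <- vapply(strsplit(codes, "|", fixed = TRUE), function(p) sum(p == "T"), 0L)
  w <- (1 / 3)^nt
  counts <- round(n * w / sum(w))
  counts[1] <- counts[1] + (n - sum(counts))   # absorb rounding in B|B|B
  phantoms <- list(); category <- character(0); rows <- list()
  id <- 0L
  for (ci in seq_along(codes)) {
    for (rep in seq_len(counts[ci])) {
      id <- id + 1L
      sp <- category_spec(codes[ci], image_size = image_size,
                          seed = mix_seed(seed + 7L, id))
      ph <- make_phantom(sp)
      phantoms[[id]] <- ph
      category[id] <- codes[ci]
      rows[[id]] <- data.frame(id = id, category_code = codes[ci],
                               gap_total = ph$realized_gap_total_frac,
                               gap_max = ph$realized_gap_max_frac,
                               shape_score = ph$realized_shape_score,
                               stringsAsFactors = FALSE)
    }
  }
  list(phantoms = phantoms, category = category, manifest = do.call(rbind, rows))
}
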