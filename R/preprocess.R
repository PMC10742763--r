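# Attention-mask and edge-map construction: histogram equalization, a
# SLIC-style superpixel decomposition, a simplified neutrosophic
# (truth/indeterminacy/falsity) binarization, and a Canny-style edge
# detector. The mask restricts the agents' search space; the edge map is
# their habitat.

#' Histogram equalization of an 8-bit grayscale image
#'
#' Standard cumulative-histogram mapping `v -> round(255 * cdf(v))`.
#' A constant image is returned unchanged.
#'
#' @param img matrix with integer values in 0..255.
#' @return Equalized matrix, same dimensions.
#' @export
equalize <- function(img) {
  v <- as.integer(round(img))
  if (min(v) == max(v)) return(img)
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h) / length(v)
  map <- round(255 * cdf)
  matrix(map[v + 1L], nrow(img), ncol(img))
}

#' SLIC-style superpixel decomposition
#'
#' Localized k-means in (intensity, x, y) space: cluster centers start on a
#' regular grid with spacing `S = sqrt(N / n_segments)`; each center competes
#' for pixels in its 2S x 2S neighborhood under the distance
#' `d^2 = dI^2 + (compactness / S)^2 * (dx^2 + dy^2)`.
#'
#' @param img matrix in 0..255.
#' @param n_segments requested number of superpixels (>= 2).
#' @param compactness spatial regularization weight.
#' @param iter number of assignment/update sweeps.
#' @return Integer label matrix; labels are contiguous `1..K`, every pixel
#'   labeled.
#' @export
superpixels <- function(img, n_segments = 300L, compactness = 10, iter = 5L) {
  nr <- nrow(img); nc <- ncol(img); N <- nr * nc
  if (n_segments < 2) stop("n_segments must be >= 2")
  if (n_segments > N) stop("n_segments exceeds pixel count")
  S <- sqrt(N / n_segments)
  nx <- max(1L, ceiling(sqrt(n_segments * nc / nr)))
  ny <- max(1L, ceiling(n_segments / nx))
  gx <- (seq_len(nx) - 0.5) * nc / nx
  gy <- (seq_len(ny) - 0.5) * nr / ny
  centers <- expand.grid(x = gx, y = gy)
  K <- nrow(centers)
  cI <- img[cbind(pmin(pmax(round(centers$y), 1), nr), pmin(pmax(round(centers$x), 1), nc))]
  w2 <- (compactness / S)^2
  xs <- matrix(rep(seq_len(nc), each = nr), nr)
  ys <- matrix(rep(seq_len(nr), times = nc), nr)
  label <- matrix(0L, nr, nc)
  best <- matrix(Inf, nr, nc)
  for (it in seq_len(iter)) {
    best[] <- Inf; label[] <- 0L
    for (k in seq_len(K)) {
      x0 <- max(1, floor(centers$x[k] - S)); x1 <- min(nc, ceiling(centers$x[k] + S))
      y0 <- max(1, floor(centers$y[k] - S)); y1 <- min(nr, ceiling(centers$y[k] + S))
      sub <- img[y0:y1, x0:x1, drop = FALSE]
      dx <- xs[y0:y1, x0:x1, drop = FALSE] - centers$x[k]
      dy <- ys[y0:y1, x0:x1, drop = FALSE] - centers$y[k]
      d2 <- (sub - cI[k])^2 + w2 * (dx * dx + dy * dy)
      upd <- d2 < best[y0:y1, x0:x1]
      bsub <- best[y0:y1, x0:x1]; lsub <- label[y0:y1, x0:x1]
      bsub[upd] <- d2[upd]; lsub[upd] <- k
      best[y0:y1, x0:x1] <- bsub; label[y0:y1, x0:x1] <- lsub
    }
    # any pixel outside every center window: assign nearest center globally
    miss <- which(label == 0L)
    if (length(miss) > 0) {
      mx <- xs[miss]; my <- ys[miss]
      for (ii in seq_along(miss)) {
        d2 <- (img[miss[ii]] - cI)^2 + w2 * ((mx[ii] - centers$x)^2 + (my[ii] - centers$y)^2)
        label[miss[ii]] <- which.min(d2)
      }
    }
    # update centers
    for (k in seq_len(K)) {
      idx <- which(label == k)
      if (length(idx) == 0) next
      centers$x[k] <- mean(xs[idx]); centers$y[k] <- mean(ys[idx])
      cI[k] <- mean(img[idx])
    }
  }
  # contiguous labels
  u <- sort(unique(as.integer(label)))
  matrix(match(as.integer(label), u), nr, nc)
}

#' Neutrosophic binarization of superpixels into an attention mask
#'
#' Per superpixel, a truth membership toward the lesion class is the
#' normalized inverse distance of its mean intensity to the dark centroid of
#' a 2-means split of superpixel means; falsity is its complement;
#' indeterminacy is the normalized within-superpixel intensity standard
#' deviation. A superpixel joins the mask when truth > falsity and
#' indeterminacy < 0.5. The largest connected foreground component is kept
#' and its holes filled.
#'
#' @param img matrix in 0..255 (typically equalized).
#' @param labels label matrix from [superpixels()].
#' @param polarity `"dark"` for hypoechoic lesions (default) or `"bright"`.
#' @param open_radius radius of the morphological opening that severs thin
#'   speckle bridges before the largest component is kept (0 disables).
#' @param dilate_radius final dilation radius; the dark-class threshold
#'   under equalization biases the mask a few pixels inward on blurred
#'   boundaries, and the dilation recenters it so the level-0 offset hugs
#'   the true edge (0 disables).
#' @return `list(mask, contour)` of class `attention_mask`: binary matrix and
#'   the closed boundary polyline of the mask.
#' @export
neutrosophic_binarize <- function(img, labels, polarity = c("dark", "bright"),
                                  open_radius = 2L, dilate_radius = 3L) {
  polarity <- match.arg(polarity)
  if (polarity == "bright") img <- 255 - img
  K <- max(labels)
  mu <- vapply(seq_len(K), function(k) mean(img[labels == k]), 0)
  sdv <- vapply(seq_len(K), function(k) stats::sd(c(img[labels == k], NA), na.rm = TRUE), 0)
  sdv[is.na(sdv)] <- 0
  # deterministic 2-means on superpixel means, initialized at the extremes
  c_d <- min(mu); c_b <- max(mu)
  if (c_b - c_d < 1e-9) stop("no candidate lesion: flat intensity field")
  for (it in 1:50) {
    asg <- abs(mu - c_d) <= abs(mu - c_b)
    nd <- mean(mu[asg]); nb <- mean(mu[!asg])
    if (is.nan(nd) || is.nan(nb)) break
    if (abs(nd - c_d) + abs(nb - c_b) < 1e-9) { c_d <- nd; c_b <- nb; break }
    c_d <- nd; c_b <- nb
  }
  truth <- pmin(pmax((c_b - mu) / (c_b - c_d), 0), 1)
  falsity <- 1 - truth
  indet <- if (max(sdv) > 0) sdv / max(sdv) else sdv
  member <- truth > falsity & indet < 0.5
  if (!any(member)) stop("no candidate lesion")
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[labels %in% which(member)] <- 1L
  if (open_radius > 0) {
    br <- EBImage::makeBrush(2 * open_radius + 1, "disc")
    mask <- matrix(as.integer(as.matrix(EBImage::opening(mask, br)) > 0), nrow(img))
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  if (length(sizes) == 0 || max(sizes) == 0) stop("no candidate lesion")
  mask <- matrix(as.integer(lab == which.max(sizes)), nrow(img))
  mask <- matrix(as.integer(as.matrix(EBImage::fillHull(mask)) > 0), nrow(img))
  if (dilate_radius > 0) {
    br <- EBImage::makeBrush(2 * dilate_radius + 1, "disc")
    mask <- matrix(as.integer(as.matrix(EBImage::dilate(mask, br)) > 0), nrow(img))
  }
  structure(list(mask = mask, contour = extract_contour(mask)),
            class = "attention_mask")
}

#' Compute the attention mask of a grayscale image
#'
#' Convenience pipeline: [equalize()] then [superpixels()] then
#' [neutrosophic_binarize()].
#'
#' @param img matrix in 0..255.
#' @param n_segments,compactness superpixel parameters.
#' @param polarity lesion polarity, see [neutrosophic_binarize()].
#' @param smooth_sigma Gaussian pre-smoothing after equalization; damps
#'   speckle before clustering (0 disables; 3 keeps the mask boundary
#'   within a few pixels of the true boundary on the phantom family).
#' @return An `attention_mask` object.
#' @export
attention_mask <- function(img, n_segments = 300L, compactness = 10,
                           polarity = "dark", smooth_sigma = 3) {
  # handle polarity up front so bright-lesion masks are exactly the dark
  # masks of the inverted image
  if (polarity == "bright") { img <- 255 - img; polarity <- "dark" }
  eq <- equalize(img)
  if (smooth_sigma > 0) eq <- as.matrix(EBImage::gblur(eq, sigma = smooth_sigma))
  lab <- superpixels(eq, n_segments = n_segments, compactness = compactness)
  neutrosophic_binarize(eq, lab, polarity = polarity)
}

#' Gradient-magnitude edge detection with hysteresis (Canny-style)
#'
#' Sobel gradients, non-maximum suppression quantized to four directions,
#' then hysteresis: weak edge pixels (above `low * max|g|`) are kept only
#' when 8-connected to a strong pixel (above `high * max|g|`).
#'
#' @param img matrix in 0..255.
#' @param low,high hysteresis thresholds as fractions of the maximum gradient
#'   magnitude; `low < high` required.
#' @param sigma Gaussian pre-smoothing.
#' @return An `edge_map` object: `list(edges, source = "detected")`.
#' @export
detect_edges <- function(img, low = 0.1, high = 0.2, sigma = 1.0) {
  if (low >= high) stop("low must be < high")
  nr <- nrow(img); nc <- ncol(img)
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gxm <- as.matrix(EBImage::filter2(sm, kx))
  gym <- as.matrix(EBImage::filter2(sm, t(kx)))
  mag <- sqrt(gxm^2 + gym^2)
  mmax <- max(mag)
  if (mmax < 1e-9)
    return(structure(list(edges = matrix(0L, nr, nc), source = "detected"),
                     class = "edge_map"))
  # non-maximum suppression along the quantized gradient direction
  theta <- atan2(gym, gxm)
  sector <- (round(theta / (pi / 4)) %% 4)    # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pad <- matrix(0, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- mag
  shift <- function(dr, dc) pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  # sector gives gradient direction; compare along it. x = col, y = row.
  n1 <- mag; n2 <- mag
  s0 <- sector == 0; s1 <- sector == 1; s2 <- sector == 2; s3 <- sector == 3
  e <- shift(0, 1); w <- shift(0, -1); nn <- shift(-1, 0); ss <- shift(1, 0)
  ne <- shift(-1, 1); sw <- shift(1, -1); nw <- shift(-1, -1); se <- shift(1, 1)
  n1[s0] <- e[s0]; n2[s0] <- w[s0]
  n1[s1] <- se[s1]; n2[s1] <- nw[s1]
  n1[s2] <- ss[s2]; n2[s2] <- nn[s2]
  n1[s3] <- sw[s3]; n2[s3] <- ne[s3]
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= high * mmax
  weak <- keep & mag >= low * mmax
  if (!any(strong))
    return(structure(list(edges = matrix(0L, nr, nc), source = "detected"),
                     class = "edge_map"))
  lab <- EBImage::bwlabel(matrix(as.integer(weak), nr))
  keep_labels <- unique(as.integer(lab)[strong])
  keep_labels <- keep_labels[keep_labels > 0]
  edges <- matrix(as.integer(as.integer(lab) %in% keep_labels), nr)
  structure(list(edges = edges, source = "detected"), class = "edge_map")
}

#' Wrap a precomputed binary edge map
#'
#' Synthetic edge maps (for example a phantom's) bypass detection.
#' @param edges binary matrix.
#' @return An `edge_map` object with `source = "synthetic"`.
#' @export
synthetic_edge_map <- function(edges) {
  structure(list(edges = edges, source = "synthetic"), class = "edge_map")
}
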