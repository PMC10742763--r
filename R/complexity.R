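# Edge-map complexity taxonomy. Three statistics characterize how hard an
# edge map is to segment: the total-gap fraction L_g (missing boundary arc
# length over boundary length), the maximum-gap fraction L_g_max, and a
# shape-complexity score (area deficit of the lesion against its minimum
# enclosing circle). Each statistic is dichotomized against a
# mean-plus-one-standard-deviation threshold fitted on a reference corpus:
# below the threshold is B (baseline), at or above is T (tough). The
# three-letter code S|Cmax|C orders the letters shape, max gap, total gap.

#' Gap statistics of an edge map against a closed boundary
#'
#' The boundary is resampled at unit arc spacing; a sample is covered when
#' an edge pixel lies within `tol`. Maximal uncovered runs are the gaps;
#' each run is widened by `2 * tol` (the coverage test erodes every true gap
#' by about `tol` per side) so that reported lengths estimate the true
#' missing arc length. Totals are capped at the boundary length.
#'
#' @param edge_map binary matrix or `edge_map` object.
#' @param gt_contour closed boundary polyline (n x 2).
#' @param tol coverage tolerance in px.
#' @return `list(L_g, L_g_max)`, both fractions in `[0, 1]`.
#' @export
gap_statistics <- function(edge_map, gt_contour, tol = 2) {
  if (inherits(edge_map, "edge_map")) edge_map <- edge_map$edges
  gt_contour <- as.matrix(gt_contour)
  if (nrow(gt_contour) < 3) stop("contour must be closed (>= 3 points)")
  pts <- resample_closed(gt_contour, spacing = 1)
  n <- nrow(pts)
  ep <- which(edge_map == 1L, arr.ind = TRUE)
  if (nrow(ep) == 0) return(list(L_g = 1, L_g_max = 1))
  exy <- cbind(ep[, 2] - 1, ep[, 1] - 1)           # (x, y), 0-based
  covered <- min_dist_to_set(pts, exy) <= tol
  if (all(covered)) return(list(L_g = 0, L_g_max = 0))
  if (!any(covered)) return(list(L_g = 1, L_g_max = 1))
  # maximal uncovered runs on the circular index
  u <- !covered
  # rotate so position 1 is covered, making runs non-wrapping
  first_cov <- which(covered)[1]
  u <- u[c(first_cov:n, seq_len(first_cov - 1))]
  r <- rle(u)
  runs <- r$lengths[r$values]
  runs <- runs + 2 * tol                           # de-erode
  L <- n                                           # unit spacing: length = count
  list(L_g = min(sum(runs) / L, 1), L_g_max = min(max(runs) / L, 1))
}

#' Shape-complexity score of a lesion mask
#'
#' `1 - area(mask) / area(minimum enclosing circle)`: 0 for a disk,
#' approaching 1 for thin or highly spiculated shapes. The raw (absolute)
#' area difference is available behind `normalized = FALSE`.
#'
#' @param mask binary matrix.
#' @param normalized divide by the enclosing-circle area (default)?
#' @return Scalar score (`[0, 1]` when normalized).
#' @export
shape_score <- function(mask, normalized = TRUE) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  mec <- min_enclosing_circle(pts)
  # pixel-center count vs circle area through the same centers: a disk then
  # scores ~0 by construction
  circ_area <- pi * mec$radius^2
  if (normalized) max(0, 1 - nrow(idx) / circ_area) else circ_area - nrow(idx)
}

#' Fit complexity thresholds on a reference corpus
#'
#' Each threshold is the mean plus one population standard deviation of the
#' statistic over the corpus. A degenerate (zero-variance) statistic yields
#' threshold = mean with a warning.
#'
#' @param stats_df data frame with columns `gap_total`, `gap_max`,
#'   `shape_score` (one row per phantom/image); `>= 10` rows required.
#' @return A `threshold_set`: `L_prime`, `L_max_prime`, `S_prime`, plus the
#'   per-statistic means and standard deviations for persistence.
#' @export
fit_thresholds <- function(stats_df) {
  if (nrow(stats_df) < 10) stop("reference corpus too small (need >= 10)")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  one <- function(x, nm) {
    s <- pop_sd(x)
    if (s < 1e-12) warning("degenerate corpus for ", nm, ": threshold = mean")
    c(mean = mean(x), sd = s, threshold = mean(x) + s)
  }
  lt <- one(stats_df$gap_total, "gap_total")
  lm <- one(stats_df$gap_max, "gap_max")
  ss <- one(stats_df$shape_score, "shape_score")
  structure(list(L_prime = lt[["threshold"]], L_max_prime = lm[["threshold"]],
                 S_prime = ss[["threshold"]],
                 stats = rbind(gap_total = lt, gap_max = lm, shape_score = ss)),
            class = "threshold_set")
}

#' Categorize an image by its complexity statistics
#'
#' A letter is B (baseline) when its statistic is strictly below the fitted
#' threshold, T (tough) otherwise (values exactly at the threshold are T).
#'
#' @param L_g,L_g_max,S_score the three statistics.
#' @param thresholds a [fit_thresholds()] result.
#' @return A `complexity_label`: the statistics, the three letters and the
#'   assembled `code_string` `S|Cmax|C`.
#' @export
categorize <- function(L_g, L_g_max, S_score, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  S <- if (S_score < thresholds$S_prime) "B" else "T"
  Cm <- if (L_g_max < thresholds$L_max_prime) "B" else "T"
  Ct <- if (L_g < thresholds$L_prime) "B" else "T"
  structure(list(L_g = L_g, L_g_max = L_g_max, S_score = S_score,
                 codes = c(S = S, C_max = Cm, C = Ct),
                 code_string = paste(S, Cm, Ct, sep = "|")),
            class = "complexity_label")
}

#' Complexity statistics and label of a phantom
#'
#' Convenience wrapper measuring the statistics from the phantom's edge map,
#' ground-truth contour and mask (at inference on unlabeled images, the
#' attention-mask contour serves as a proxy).
#' @param phantom a [make_phantom()] result.
#' @param thresholds optional [fit_thresholds()] result; when given, the
#'   label is attached.
#' @param tol coverage tolerance for [gap_statistics()].
#' @export
phantom_complexity <- function(phantom, thresholds = NULL, tol = 2) {
  gs <- gap_statistics(phantom$edge_map, phantom$gt_contour, tol = tol)
  ss <- shape_score(phantom$gt_mask)
  out <- list(gap_total = gs$L_g, gap_max = gs$L_g_max, shape_score = ss)
  if (!is.null(thresholds))
    out$label <- categorize(gs$L_g, gs$L_g_max, ss, thresholds)
  out
}

#' Persist a threshold set (with corpus statistics) to JSON
#' @param thresholds a `threshold_set`; @param path output file.
#' @export
write_thresholds_json <- function(thresholds, path) {
  jsonlite::write_json(list(L_prime = thresholds$L_prime,
                            L_max_prime = thresholds$L_max_prime,
                            S_prime = thresholds$S_prime,
                            stats = as.data.frame(thresholds$stats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
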