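# Contour- and area-based segmentation quality metrics, and the
# success-ratio bookkeeping. X denotes the ground-truth contour throughout;
# the relative Hausdorff distance is normalized by the ground-truth length,
# and a segmentation counts as successful when it is at most 2%.

#' Hausdorff distance between two point sets
#'
#' Maximum of the two directed max-min Euclidean distances.
#' @param X,Y point matrices (n x 2), non-empty.
#' @return Distance in px.
#' @export
hausdorff <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty point set")
  max(max(min_dist_to_set(X, Y)), max(min_dist_to_set(Y, X)))
}

#' Average Hausdorff distance
#'
#' Maximum of the two directed mean-min distances, with the sums normalized
#' by the contour lengths `L_X`, `L_Y`. Contours resampled to unit arc
#' spacing (see [resample_closed()]) make point count and length agree, so
#' the defaults `L = nrow()` apply to raw point sets as well.
#'
#' @param X,Y point matrices.
#' @param L_X,L_Y contour lengths (default: point counts).
#' @return Distance in px.
#' @export
avg_hausdorff <- function(X, Y, L_X = nrow(X), L_Y = nrow(Y)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty point set")
  stopifnot(L_X > 0, L_Y > 0)
  max(sum(min_dist_to_set(X, Y)) / L_X, sum(min_dist_to_set(Y, X)) / L_Y)
}

#' Relative Hausdorff distance (%)
#'
#' `distH2 / L_X * 100`, normalized by the ground-truth contour length
#' (deliberately asymmetric).
#' @param distH2 average Hausdorff distance (px).
#' @param L_X ground-truth contour length (px).
#' @export
relative_hausdorff <- function(distH2, L_X) {
  stopifnot(L_X > 0)
  distH2 / L_X * 100
}

#' Pixelwise confusion counts
#' @param pred_mask,gt_mask binary matrices of identical shape.
#' @return `list(TP, FP, TN, FN)`.
#' @export
confusion <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop("shape mismatch")
  p <- pred_mask == 1L; g <- gt_mask == 1L
  list(TP = sum(p & g), FP = sum(p & !g), TN = sum(!p & !g), FN = sum(!p & g))
}

#' Area-based metrics from confusion counts (%)
#'
#' Recall, precision, accuracy, Jaccard and Dice on the percent scale.
#' Metrics with zero denominators are reported as `NA` (missing) rather
#' than 0, so corpus averages are not silently deflated.
#'
#' @param counts `list(TP, FP, TN, FN)` from [confusion()].
#' @return `list(Rec, Pre, Acc, Jac, Dice)` in percent.
#' @export
area_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den * 100
  list(Rec = sdiv(TP, TP + FN),
       Pre = sdiv(TP, TP + FP),
       Acc = sdiv(TP + TN, TP + TN + FP + FN),
       Jac = sdiv(TP, TP + FP + FN),
       Dice = sdiv(2 * TP, 2 * TP + FP + FN))
}

#' Full metrics report for one segmentation
#'
#' Contours are resampled to unit arc spacing before the Hausdorff family so
#' the length normalizations are resolution-independent; `X` is the ground
#' truth.
#'
#' @param pred_contour,gt_contour closed polylines (n x 2).
#' @param pred_mask,gt_mask binary matrices.
#' @return A `metrics_report` list: `distH1`, `distH2`, `distH3` (%),
#'   `L_X`, `L_Y`, the confusion counts, the area metrics and the `success`
#'   flag (`distH3 <= 2`).
#' @export
metrics_report <- function(pred_contour, gt_contour, pred_mask, gt_mask) {
  Xr <- resample_closed(gt_contour, spacing = 1)
  Yr <- resample_closed(pred_contour, spacing = 1)
  h1 <- hausdorff(Xr, Yr)
  h2 <- avg_hausdorff(Xr, Yr)
  h3 <- relative_hausdorff(h2, nrow(Xr))
  cf <- confusion(pred_mask, gt_mask)
  am <- area_metrics(cf)
  structure(c(list(distH1 = h1, distH2 = h2, distH3 = h3,
                   L_X = nrow(Xr), L_Y = nrow(Yr)), cf, am,
              list(success = h3 <= 2)),
            class = "metrics_report")
}

#' Success ratio over a corpus of reports
#'
#' Percent of reports satisfying the relative-Hausdorff success rule
#' (`distH3 <= 2%`, inclusive). Aggregate metrics are computed over the
#' successful subset only.
#'
#' @param reports list of [metrics_report()] results.
#' @return `list(SGratio, successful, summary)`: the percentage, the index
#'   vector of successful reports, and mean/sd of each metric over them.
#' @export
sg_ratio <- function(reports) {
  if (length(reports) == 0) stop("no reports")
  ok <- which(vapply(reports, function(r) isTRUE(r$success), TRUE))
  ratio <- 100 * length(ok) / length(reports)
  summ <- NULL
  if (length(ok) > 0) {
    nms <- c("distH1", "distH2", "distH3", "Rec", "Pre", "Acc", "Jac", "Dice")
    m <- sapply(nms, function(nm)
      vapply(reports[ok], function(r) as.numeric(r[[nm]]), 0))
    m <- matrix(m, nrow = length(ok), dimnames = list(NULL, nms))
    summ <- data.frame(metric = nms,
                       mean = colMeans(m, na.rm = TRUE),
                       sd = apply(m, 2, stats::sd, na.rm = TRUE))
  }
  list(SGratio = ratio, successful = ok, summary = summ)
}

#' Write a corpus-level metrics summary as CSV
#' @param sg result of [sg_ratio()]; @param path output file.
#' @export
write_metrics_csv <- function(sg, path) {
  df <- sg$summary
  df <- rbind(df, data.frame(metric = "SGratio", mean = sg$SGratio, sd = NA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
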