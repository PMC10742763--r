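# Neighbor message passing in the style of principal neighborhood
# aggregation: four aggregators (mean, max, min, population standard
# deviation) under three degree scalers (identity, log-degree amplification,
# its reciprocal attenuation), flattened in a fixed order.

#' Indices of an agent's neighbors
#'
#' Alive agents within a Euclidean radius of agent `i`, excluding `i`.
#'
#' @param positions n x 2 matrix of agent positions.
#' @param i querying agent index.
#' @param radius neighborhood radius (> 0).
#' @param alive logical vector (default all alive).
#' @return Integer index vector (possibly empty).
#' @export
neighbors <- function(positions, i, radius, alive = rep(TRUE, nrow(positions))) {
  stopifnot(radius > 0)
  d2 <- (positions[, 1] - positions[i, 1])^2 + (positions[, 2] - positions[i, 2])^2
  which(alive & d2 <= radius^2 & seq_len(nrow(positions)) != i)
}

#' Aggregate neighbor feature vectors
#'
#' With zero neighbors every aggregate equals the agent's own feature vector
#' and both scalers are 1. The amplification scaler is
#' `log(1 + deg) / log(1 + deg_avg)`; attenuation is its reciprocal.
#' Output order: for each scaler (identity, amplification, attenuation), the
#' four aggregates (mean, max, min, std) concatenated feature-wise.
#'
#' @param own numeric feature vector of the querying agent.
#' @param neighbor_mat matrix with one row per neighbor (same length as
#'   `own`), or `NULL`/zero rows for no neighbors.
#' @param deg_avg running average neighborhood size maintained by the
#'   trainer.
#' @return `list(features, neighbor_count)` where `features` has length
#'   `12 * length(own)`.
#' @export
aggregate_features <- function(own, neighbor_mat = NULL, deg_avg = 1) {
  f <- length(own)
  if (is.null(neighbor_mat) || NROW(neighbor_mat) == 0) {
    # no neighbors: every aggregate falls back to the agent's own features
    base <- rbind(mean = own, max = own, min = own, std = own)
    deg <- 0L
  } else {
    M <- matrix(neighbor_mat, ncol = f)
    mu <- colMeans(M)
    base <- rbind(mean = mu,
                  max = apply(M, 2, max),
                  min = apply(M, 2, min),
                  std = sqrt(pmax(colMeans(M^2) - mu^2, 0)))
    deg <- nrow(M)
  }
  if (deg == 0 || deg_avg <= 0) {
    amp <- 1; att <- 1
  } else {
    # bounded so a degenerate running average cannot explode the features
    amp <- min(max(log1p(deg) / log1p(deg_avg), 0.1), 10)
    att <- 1 / amp
  }
  feats <- c(as.numeric(t(base)),            # identity scaler
             as.numeric(t(base)) * amp,      # amplification
             as.numeric(t(base)) * att)      # attenuation
  list(features = feats, neighbor_count = deg)
}
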