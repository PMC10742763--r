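# Policy and value networks: six hidden layers (three 3x3 stride-1
# convolution layers of 32/64/128 filters, each followed by 2x2 max-pooling,
# then two dense layers of 128 rectifier units). The pooled feature maps are
# flattened and linearly projected to a 256-vector (the projection is part
# of the flattening stage; for a 24 px receptive field the raw flatten size
# is 128*3*3 = 1152), concatenated with the observation vector, the
# aggregated neighbor features and the previous reward, and fed to the dense
# stack. The policy head has 5 sigmoid outputs normalized to a categorical
# distribution; the value head is a single linear unit. Policy and value
# parameters are never shared.
#
# Everything is implemented with im2col-style matrix products so the heavy
# lifting happens in BLAS; gradients are exact backpropagation.

#' Network architecture specification
#'
#' @param r receptive-field size; must be divisible by 8 (three 2x pools).
#' @param in_channels input channels (3 frames x 3 channels = 9).
#' @param extra_dim length of the non-image input (observation vector +
#'   aggregated features + previous reward).
#' @param n_out head width (5 for the policy, 1 for the value).
#' @param conv_channels filters per convolution layer.
#' @param flat_dim width of the flattening projection.
#' @param dense_units width of the two rectifier layers.
#' @return A `net_spec` list (includes a architecture hash used to guard
#'   checkpoint loading).
#' @export
net_spec <- function(r = 24L, in_channels = 9L, extra_dim = 79L, n_out = 5L,
                     conv_channels = c(32L, 64L, 128L), flat_dim = 256L,
                     dense_units = c(128L, 128L)) {
  if (r %% 8 != 0) stop("receptive field must be divisible by 8")
  flat_raw <- conv_channels[3] * (r / 8)^2
  sp <- list(r = as.integer(r), in_channels = as.integer(in_channels),
             extra_dim = as.integer(extra_dim), n_out = as.integer(n_out),
             conv_channels = as.integer(conv_channels),
             flat_raw = as.integer(flat_raw), flat_dim = as.integer(flat_dim),
             dense_units = as.integer(dense_units))
  sp$hash <- paste(unlist(sp), collapse = "-")
  structure(sp, class = "net_spec")
}

orthogonal_init <- function(n_in, n_out) {
  a <- matrix(stats::rnorm(n_in * n_out), n_in, n_out)
  if (n_in >= n_out) qr.Q(qr(a))[, seq_len(n_out), drop = FALSE]
  else t(qr.Q(qr(t(a)))[, seq_len(n_in), drop = FALSE])
}

#' Initialize network parameters
#'
#' He-style normal initialization for convolution kernels, orthogonal for
#' the projection and dense layers, zero biases.
#'
#' @param spec a [net_spec()].
#' @param seed integer seed.
#' @return Named list of parameter arrays (class `net_params`).
#' @export
net_init <- function(spec, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) { if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()) }
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  cc <- spec$conv_channels
  cin <- c(spec$in_channels, cc[1], cc[2])
  p <- list()
  for (l in 1:3) {
    p[[paste0("Wc", l)]] <- matrix(stats::rnorm(9 * cin[l] * cc[l], sd = sqrt(2 / (9 * cin[l]))),
                                   9 * cin[l], cc[l])
    p[[paste0("bc", l)]] <- numeric(cc[l])
  }
  p$Wp <- orthogonal_init(spec$flat_raw, spec$flat_dim)
  p$bp <- numeric(spec$flat_dim)
  d1 <- spec$flat_dim + spec$extra_dim
  p$W1 <- orthogonal_init(d1, spec$dense_units[1]); p$b1 <- numeric(spec$dense_units[1])
  p$W2 <- orthogonal_init(spec$dense_units[1], spec$dense_units[2]); p$b2 <- numeric(spec$dense_units[2])
  p$W3 <- orthogonal_init(spec$dense_units[2], spec$n_out) * 0.01; p$b3 <- numeric(spec$n_out)
  attr(p, "spec") <- spec
  class(p) <- "net_params"
  p
}

# im2col for 3x3 same-padding convolution. X: [B, H, W, C] array.
# Returns [B*H*W, 9*C] matrix; column blocks ordered by kernel offset.
im2col3 <- function(X) {
  d <- dim(X); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Xp <- array(0, c(B, H + 2, W + 2, C))
  Xp[, 2:(H + 1), 2:(W + 1), ] <- X
  cols <- vector("list", 9)
  k <- 0
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1
    s <- Xp[, (2:(H + 1)) + dy, (2:(W + 1)) + dx, , drop = FALSE]
    dim(s) <- c(B * H * W, C)
    cols[[k]] <- s
  }
  do.call(cbind, cols)
}

# Scatter-add of column gradients back to the input (reverse of im2col3).
col2im3 <- function(dP, B, H, W, C) {
  dXp <- array(0, c(B, H + 2, W + 2, C))
  k <- 0
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1
    blk <- dP[, ((k - 1) * C + 1):(k * C), drop = FALSE]
    dim(blk) <- c(B, H, W, C)
    dXp[, (2:(H + 1)) + dy, (2:(W + 1)) + dx, ] <-
      dXp[, (2:(H + 1)) + dy, (2:(W + 1)) + dx, , drop = FALSE] + blk
  }
  dXp[, 2:(H + 1), 2:(W + 1), , drop = FALSE]
}

# 2x2 max pooling with argmax bookkeeping. X: [B, H, W, C].
maxpool2 <- function(X) {
  d <- dim(X); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  s1 <- X[, seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  s2 <- X[, seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  s3 <- X[, seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  s4 <- X[, seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  out <- pmax(s1, s2, s3, s4)
  # deterministic tie-break: first slice attaining the max
  m1 <- out == s1
  m2 <- !m1 & out == s2
  m3 <- !m1 & !m2 & out == s3
  arg <- 4L - 3L * m1 - 2L * m2 - m3
  list(out = out, arg = arg)
}

maxpool2_back <- function(dOut, arg, H, W) {
  d <- dim(dOut); B <- d[1]; Hp <- d[2]; Wp <- d[3]; C <- d[4]
  dX <- array(0, c(B, H, W, C))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    m <- (arg == k) * dOut
    dX[, seq(sel[[k]][1], H, 2), seq(sel[[k]][2], W, 2), ] <-
      dX[, seq(sel[[k]][1], H, 2), seq(sel[[k]][2], W, 2), , drop = FALSE] + m
  }
  dX
}

sigmoid <- function(x) 1 / (1 + exp(-x))
marlseg_sigmoid <- sigmoid

#' Forward pass through a network
#'
#' @param params a `net_params` list.
#' @param frames array `[B, r, r, in_channels]` (grid-map memory stack).
#' @param extra matrix `[B, extra_dim]` (observation, aggregated features,
#'   previous reward).
#' @param cache keep intermediates for [net_backward()]?
#' @return `list(z, probs (policy heads), cache)` where `z` is the head
#'   pre-activation `[B, n_out]` and `probs` the normalized sigmoid
#'   distribution (`NULL` for value heads of width 1).
#' @export
net_forward <- function(params, frames, extra, cache = FALSE) {
  if (any(!is.finite(frames)) || any(!is.finite(extra)))
    stop("non-finite network inputs")
  spec <- attr(params, "spec")
  B <- dim(frames)[1]
  X <- frames
  conv_cache <- list()
  H <- spec$r
  for (l in 1:3) {
    P <- im2col3(X)
    Y <- P %*% params[[paste0("Wc", l)]]
    Y <- sweep(Y, 2, params[[paste0("bc", l)]], "+")
    A <- pmax(Y, 0)
    dim(A) <- c(B, H, H, ncol(Y))
    pl <- maxpool2(A)
    if (cache) conv_cache[[l]] <- list(P = P, relu_mask = (Y > 0), arg = pl$arg,
                                       H = H, C_in = dim(X)[4])
    X <- pl$out
    H <- H / 2
  }
  Fl <- X; dim(Fl) <- c(B, spec$flat_raw)
  Fp <- sweep(Fl %*% params$Wp, 2, params$bp, "+")
  D0 <- cbind(Fp, extra)
  Z1 <- sweep(D0 %*% params$W1, 2, params$b1, "+"); A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% params$W2, 2, params$b2, "+"); A2 <- pmax(Z2, 0)
  z <- sweep(A2 %*% params$W3, 2, params$b3, "+")
  probs <- NULL
  if (spec$n_out > 1) {
    s <- sigmoid(z)
    probs <- s / rowSums(s)
  }
  out <- list(z = z, probs = probs)
  if (cache) out$cache <- list(conv = conv_cache, Fl = Fl, D0 = D0,
                               Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, B = B)
  out
}

#' Backward pass: parameter gradients from head-gradient
#'
#' @param params a `net_params`.
#' @param cache the cache returned by `net_forward(..., cache = TRUE)`.
#' @param dz gradient of the loss w.r.t. the head pre-activation `[B, n_out]`.
#' @return Named list of gradients matching `params`.
#' @export
net_backward <- function(params, cache, dz) {
  spec <- attr(params, "spec")
  B <- cache$B
  g <- list()
  g$W3 <- crossprod(cache$A2, dz); g$b3 <- colSums(dz)
  dA2 <- dz %*% t(params$W3)
  dZ2 <- dA2 * (cache$Z2 > 0)
  g$W2 <- crossprod(cache$A1, dZ2); g$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  g$W1 <- crossprod(cache$D0, dZ1); g$b1 <- colSums(dZ1)
  dD0 <- dZ1 %*% t(params$W1)
  dFp <- dD0[, seq_len(spec$flat_dim), drop = FALSE]
  g$Wp <- crossprod(cache$Fl, dFp); g$bp <- colSums(dFp)
  dFl <- dFp %*% t(params$Wp)
  H <- spec$r / 8
  dX <- dFl; dim(dX) <- c(B, H, H, spec$conv_channels[3])
  for (l in 3:1) {
    cc <- cache$conv[[l]]
    Hfull <- cc$H
    dA <- maxpool2_back(dX, cc$arg, Hfull, Hfull)
    dim(dA) <- c(B * Hfull * Hfull, dim(dX)[4])
    dY <- dA * cc$relu_mask
    g[[paste0("Wc", l)]] <- crossprod(cc$P, dY)
    g[[paste0("bc", l)]] <- colSums(dY)
    if (l > 1) {
      dP <- dY %*% t(params[[paste0("Wc", l)]])
      dX <- col2im3(dP, B, Hfull, Hfull, cc$C_in)
    }
  }
  g
}

# Gradient of log pi(a | x) w.r.t. head pre-activations for the
# sigmoid-normalized categorical head. coef: per-sample multiplier.
policy_logp_grad_z <- function(z, actions, coef) {
  s <- sigmoid(z)
  S <- rowSums(s)
  B <- nrow(z)
  dz <- -s * (1 - s) / S * coef          # -d log S / dz_j term
  idx <- cbind(seq_len(B), actions)
  dz[idx] <- dz[idx] + (1 - s[idx]) * coef
  dz
}

#' Log-probabilities of chosen actions under the policy head
#' @param probs `[B, n_out]` normalized probabilities.
#' @param actions integer vector of chosen actions.
#' @export
policy_logp <- function(probs, actions) {
  log(pmax(probs[cbind(seq_len(nrow(probs)), actions)], 1e-300))
}

#' Create an Adam optimizer state
#' @param params a `net_params`.
#' @export
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

#' One Adam update (in place on the returned copies)
#' @param params parameters; @param grads matching gradients.
#' @param state from [adam_init()]; @param lr learning rate.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @return `list(params, state)`.
#' @export
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Save / load parameter checkpoints
#'
#' Portable JSON serialization with the architecture hash embedded; loading
#' refuses a checkpoint whose hash does not match the requested spec.
#' @param params a `net_params`.
#' @param path file path.
#' @export
save_checkpoint <- function(params, path) {
  spec <- attr(params, "spec")
  obj <- list(hash = spec$hash,
              spec = unclass(spec)[setdiff(names(spec), "hash")],
              params = lapply(params, function(p)
                list(dim = if (is.matrix(p)) dim(p) else length(p),
                     data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param spec the expected [net_spec()].
#' @export
load_checkpoint <- function(path, spec) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$hash, spec$hash))
    stop("checkpoint architecture hash mismatch; refusing to load")
  p <- list()
  for (nm in names(obj$params)) {
    d <- obj$params[[nm]]$dim
    v <- obj$params[[nm]]$data
    p[[nm]] <- if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  attr(p, "spec") <- spec
  class(p) <- "net_params"
  p
}
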