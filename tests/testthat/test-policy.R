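spec_p <- net_spec(r = 8, extra_dim = 5, n_out = 5)
spec_v <- net_spec(r = 8, extra_dim = 5, n_out = 1)

test_that("policy forward yields a valid categorical distribution", {
  p <- net_init(spec_p, seed = 2)
  set.seed(1)
  fr <- array(rnorm(3 * 8 * 8 * 9), c(3, 8, 8, 9))
  ex <- matrix(rnorm(15), 3)
  fw <- net_forward(p, fr, ex)
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw$probs > 0))
  # zero inputs still give a finite valid distribution
  fw0 <- net_forward(p, array(0, c(1, 8, 8, 9)), matrix(0, 1, 5))
  expect_true(all(is.finite(fw0$probs)))
  expect_equal(sum(fw0$probs), 1, tolerance = 1e-6)
  expect_error(net_forward(p, fr * NA, ex), "non-finite")
})

test_that("value head is deterministic, separate from the policy, and robust", {
  v <- net_init(spec_v, seed = 3)
  p <- net_init(spec_p, seed = 2)
  set.seed(4)
  fr <- array(rnorm(2 * 8 * 8 * 9), c(2, 8, 8, 9)); ex <- matrix(rnorm(10), 2)
  v1 <- net_forward(v, fr, ex)$z
  expect_identical(v1, net_forward(v, fr, ex)$z)
  # perturbing policy parameters leaves the value untouched (no sharing)
  p2 <- p; p2$W1 <- p2$W1 + 1
  expect_identical(net_forward(v, fr, ex)$z, v1)
  # saturating inputs stay finite
  big <- net_forward(v, fr * 0 + 50, ex * 0 + 50)$z
  expect_true(all(is.finite(big)))
})

test_that("conv parameter counts match the closed-form architecture arithmetic", {
  p <- net_init(net_spec(r = 24, extra_dim = 79, n_out = 5), seed = 1)
  expect_equal(length(p$Wc1) + length(p$bc1), 9 * 9 * 32 + 32)        # 2624
  expect_equal(length(p$Wc2) + length(p$bc2), 9 * 32 * 64 + 64)       # 18496
  expect_equal(length(p$Wc3) + length(p$bc3), 9 * 64 * 128 + 128)     # 73856
  # 24 px with three 2x pools leaves a 3x3 map; projection is 1152 -> 256
  expect_equal(dim(p$Wp), c(128 * 3 * 3, 256))
})

test_that("backpropagation matches finite differences and reaches every layer", {
  p <- net_init(spec_p, seed = 5)
  set.seed(6)
  fr <- array(rnorm(2 * 8 * 8 * 9), c(2, 8, 8, 9)); ex <- matrix(rnorm(10), 2)
  acts <- c(2, 4)
  fw <- net_forward(p, fr, ex, cache = TRUE)
  dz <- marlseg:::policy_logp_grad_z(fw$z, acts, rep(-1 / 2, 2))
  g <- net_backward(p, fw$cache, dz)
  loss <- function(pp) -mean(policy_logp(net_forward(pp, fr, ex)$probs, acts))
  for (nm in names(g)) {
    expect_gt(sum(abs(g[[nm]])), 0)           # gradient flows to every array
    i <- which.max(abs(g[[nm]]))
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + 1e-6
    num <- (loss(pp) - loss(p)) / 1e-6
    expect_equal(g[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip and refuse mismatched architectures", {
  p <- net_init(spec_p, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(p, f)
  p2 <- load_checkpoint(f, spec_p)
  expect_equal(p2$W1, p$W1, tolerance = 1e-12)
  set.seed(8)
  fr <- array(rnorm(8 * 8 * 9), c(1, 8, 8, 9)); ex <- matrix(rnorm(5), 1)
  expect_equal(net_forward(p2, fr, ex)$probs, net_forward(p, fr, ex)$probs,
               tolerance = 1e-12)
  expect_error(load_checkpoint(f, net_spec(r = 16, extra_dim = 5, n_out = 5)),
               "hash mismatch")
})
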