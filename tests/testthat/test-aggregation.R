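test_that("neighborhoods match a brute-force distance filter", {
  set.seed(2)
  pos <- matrix(runif(40, 0, 50), 20)
  alive <- rep(TRUE, 20); alive[c(3, 7)] <- FALSE
  for (i in c(1, 5, 12)) {
    nb <- neighbors(pos, i, radius = 10, alive = alive)
    brute <- which(vapply(seq_len(20), function(j)
      j != i && alive[j] &&
        sqrt(sum((pos[j, ] - pos[i, ])^2)) <= 10, TRUE))
    expect_equal(sort(nb), sort(brute))
  }
  two <- rbind(c(0, 0), c(1, 0))
  expect_equal(neighbors(two, 1, 5), 2L)
  expect_equal(neighbors(two, 2, 5), 1L)
  expect_length(neighbors(rbind(two, c(100, 100)), 3, 5), 0)
})

test_that("aggregates match direct formulas and are permutation invariant", {
  own <- c(0.5, -1)
  nb <- rbind(c(1, 0), c(2, 1), c(3, 2))
  out <- aggregate_features(own, nb, deg_avg = 3)
  f <- length(own)
  ident <- out$features[seq_len(4 * f)]
  expect_equal(ident[1:2], c(2, 1))                      # means
  expect_equal(ident[3:4], c(3, 2))                      # max
  expect_equal(ident[5:6], c(1, 0))                      # min
  pop_sd <- sqrt(mean((c(1, 2, 3) - 2)^2))
  expect_equal(ident[7:8], c(pop_sd, pop_sd))            # population std
  perm <- aggregate_features(own, nb[c(3, 1, 2), ], deg_avg = 3)
  expect_identical(out$features, perm$features)
  expect_equal(out$neighbor_count, 3L)
  # one neighbor: std component is zero
  one <- aggregate_features(own, rbind(c(4, 4)), deg_avg = 3)
  expect_equal(one$features[7:8], c(0, 0))
})

test_that("degree scalers behave at the identity limit and with no neighbors", {
  own <- c(1, 2, 3)
  nb <- rbind(c(2, 2, 2), c(4, 4, 4))
  at_avg <- aggregate_features(own, nb, deg_avg = 2)
  f <- length(own)
  expect_equal(at_avg$features[1:(4 * f)],
               at_avg$features[(4 * f + 1):(8 * f)])     # amplification = 1
  expect_equal(at_avg$features[1:(4 * f)],
               at_avg$features[(8 * f + 1):(12 * f)])    # attenuation = 1
  none <- aggregate_features(own, NULL, deg_avg = 2)
  expect_equal(none$neighbor_count, 0L)
  expect_equal(none$features, rep(rep(own, 4), 3))
})
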