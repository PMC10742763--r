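test_that("gap statistics handle the degenerate edge maps exactly", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 2))
  full <- gap_statistics(ph$edge_map, ph$gt_contour)
  expect_equal(full$L_g, 0)
  expect_equal(full$L_g_max, 0)
  empty <- gap_statistics(matrix(0L, 128, 128), ph$gt_contour)
  expect_equal(empty$L_g, 1)
  expect_equal(empty$L_g_max, 1)
  expect_error(gap_statistics(ph$edge_map, ph$gt_contour[1:2, ]), "closed")
})

test_that("shape score separates disks from elongated and spiculated shapes", {
  expect_lte(shape_score(disk_mask(80, 40, 40, 30)), 0.02)
  bar <- matrix(0L, 120, 120); bar[58:61, 11:110] <- 1L    # 100 x 4 bar
  expect_gte(shape_score(bar), 0.9)
  expect_error(shape_score(matrix(0L, 10, 10)), "empty")
  # the enclosing circle contains every mask pixel center
  mk <- make_phantom(phantom_spec(shape_mode = "spiculated", seed = 4))$gt_mask
  idx <- which(mk == 1L, arr.ind = TRUE)
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  mec <- min_enclosing_circle(pts)
  dd <- sqrt((pts[, 1] - mec$center[1])^2 + (pts[, 2] - mec$center[2])^2)
  expect_lte(max(dd), mec$radius + 1e-6)
})

test_that("minimum enclosing circle matches brute force on small sets", {
  set.seed(21)
  for (rep in 1:30) {
    pts <- matrix(runif(2 * sample(3:12, 1), 0, 100), ncol = 2)
    got <- min_enclosing_circle(pts)
    ref <- brute_mec(pts)
    expect_equal(got$radius, ref$radius, tolerance = 1e-6)
    expect_lt(sqrt(sum((got$center - ref$center)^2)), 1e-4)
  }
})

test_that("threshold fitting is mean plus population sd, order invariant", {
  df <- data.frame(gap_total = c(rep(0.1, 9), 1.0),
                   gap_max = c(rep(0.1, 9), 1.0),
                   shape_score = c(rep(0.1, 9), 1.0))
  th <- fit_thresholds(df)
  expect_equal(th$L_prime, 0.19 + sqrt(mean((df$gap_total - 0.19)^2)))
  expect_equal(th$L_prime, 0.46, tolerance = 1e-2)
  th2 <- fit_thresholds(df[sample(10), ])
  expect_equal(th2$L_prime, th$L_prime)
  expect_warning(fit_thresholds(data.frame(gap_total = rep(0.2, 10),
                                           gap_max = runif(10),
                                           shape_score = runif(10))),
                 "degenerate")
  expect_error(fit_thresholds(df[1:5, ]), "too small")
})

test_that("categorization uses strict-below-threshold for baseline", {
  df <- data.frame(gap_total = runif(20, 0, 1), gap_max = runif(20, 0, 1),
                   shape_score = runif(20, 0, 1))
  th <- fit_thresholds(df)
  expect_equal(categorize(0, 0, 0, th)$code_string, "B|B|B")
  expect_equal(categorize(1, 1, 1, th)$code_string, "T|T|T")
  at <- categorize(th$L_prime, th$L_max_prime, th$S_prime, th)
  expect_equal(at$code_string, "T|T|T")      # exactly at threshold is tough
  # monotonicity: increasing a statistic never flips T back to B
  lab1 <- categorize(th$L_prime - 0.01, 0, 0, th)$codes[["C"]]
  lab2 <- categorize(th$L_prime + 0.01, 0, 0, th)$codes[["C"]]
  expect_true(lab1 == "B" && lab2 == "T")
})

test_that("reference-calibrated thresholds recover corpus intent labels", {
  ref <- reference_corpus(64, seed = 31)
  th <- fit_thresholds(ref$manifest)
  corpus <- make_corpus(3, seed = 32)
  got <- vapply(corpus$phantoms, function(ph)
    phantom_complexity(ph, th)$label$code_string, "")
  expect_gte(mean(got == corpus$category), 0.9)
})
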