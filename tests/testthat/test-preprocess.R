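test_that("histogram equalization follows the CDF mapping", {
  const <- matrix(120, 16, 16)
  expect_identical(equalize(const), const)
  two <- matrix(c(rep(50, 128), rep(200, 128)), 16, 16)
  out <- equalize(two)
  expect_lte(abs(sort(unique(as.vector(out)))[1] - 127.5), 1.5)
  expect_equal(sort(unique(as.vector(out)))[2], 255)
  # Kolmogorov distance to uniform never increases
  set.seed(1)
  for (rep in 1:5) {
    img <- matrix(pmin(pmax(round(rnorm(32 * 32, 120, 25)), 0), 255), 32)
    kd <- function(v) {
      cdf <- cumsum(tabulate(as.integer(v) + 1L, 256)) / length(v)
      max(abs(cdf - (1:256) / 256))
    }
    expect_lte(kd(equalize(img)), kd(img) + 1e-9)
  }
})

test_that("superpixels partition the image and split by intensity", {
  img <- matrix(0, 64, 64); img[, 33:64] <- 255
  lab <- superpixels(img, n_segments = 2, compactness = 10)
  expect_true(all(lab %in% 1:2))
  expect_equal(sort(unique(as.vector(lab))), seq_len(max(lab)))
  # oracle: 2-means on the joint (intensity, x, y) feature space
  S <- sqrt(64 * 64 / 2); w <- 10 / S
  feats <- cbind(as.vector(img),
                 w * as.vector(matrix(rep(1:64, each = 64), 64)),
                 w * as.vector(matrix(rep(1:64, times = 64), 64)))
  km <- kmeans(feats, centers = 2, nstart = 5)
  agree <- max(mean((km$cluster == 1) == (as.vector(lab) == 1)),
               mean((km$cluster == 2) == (as.vector(lab) == 1)))
  expect_gte(agree, 0.95)
  expect_error(superpixels(img, n_segments = 1), "n_segments")
  expect_error(superpixels(img, n_segments = 64 * 64 + 1), "exceeds")
})

test_that("neutrosophic binarization recovers a clean dark lesion", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 3))
  am <- attention_mask(ph$image)
  m <- area_metrics(confusion(am$mask, ph$gt_mask))
  expect_gte(m$Dice, 90)
  # polarity symmetry: inverted image with flipped flag gives the same mask
  am2 <- attention_mask(255 - ph$image, polarity = "bright")
  expect_gte(mean(am2$mask == am$mask), 0.995)
  # flat image has no candidate lesion
  expect_error(attention_mask(matrix(128, 64, 64)), "no candidate lesion")
})

test_that("attention mask is invariant to intensity shifts", {
  ph <- easy_phantom(3)
  shifted <- pmin(ph$image + 30, 255)
  m1 <- attention_mask(ph$image)$mask
  m2 <- attention_mask(shifted)$mask
  expect_gte(mean(m1 == m2), 0.98)
})

test_that("mask boundary stays near ground truth on baseline shapes", {
  for (s in c(11, 22)) {
    ph <- easy_phantom(s)
    am <- attention_mask(ph$image)
    dd <- marlseg:::min_dist_to_set(am$contour, ph$gt_contour)
    expect_lt(max(dd), 10)
  }
})

test_that("edge detection covers a clean boundary and respects passthrough", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 3))
  em <- detect_edges(ph$image)
  ep <- which(em$edges == 1L, arr.ind = TRUE)
  exy <- cbind(ep[, 2] - 1, ep[, 1] - 1)
  cov <- marlseg:::min_dist_to_set(resample_closed(ph$gt_contour, spacing = 1), exy)
  expect_gte(mean(cov <= 1.5), 0.95)
  expect_equal(sum(detect_edges(matrix(7, 32, 32))$edges), 0)
  expect_error(detect_edges(ph$image, low = 0.3, high = 0.2), "low")
  syn <- synthetic_edge_map(ph$edge_map)
  expect_identical(syn$edges, ph$edge_map)
  expect_equal(syn$source, "synthetic")
})
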