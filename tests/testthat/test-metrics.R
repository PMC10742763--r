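test_that("Hausdorff distances match brute force and simple analytic cases", {
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  X <- matrix(runif(20), 10)
  expect_equal(hausdorff(X, X), 0)
  set.seed(41)
  for (rep in 1:20) {
    A <- matrix(runif(2 * sample(3:50, 1), 0, 100), ncol = 2)
    B <- matrix(runif(2 * sample(3:50, 1), 0, 100), ncol = 2)
    expect_identical(hausdorff(A, B), brute_hausdorff(A, B))
    expect_identical(hausdorff(A, B), hausdorff(B, A))
    expect_identical(avg_hausdorff(A, B), brute_avg_hausdorff(A, B))
    expect_lte(avg_hausdorff(A, B), hausdorff(A, B) + 1e-12)
  }
  expect_error(hausdorff(matrix(numeric(0), 0, 2), X), "empty")
})

test_that("average Hausdorff of parallel segments equals their offset", {
  xs <- seq(0, 100, by = 0.5)
  A <- cbind(xs, 0); B <- cbind(xs, 3)
  expect_equal(avg_hausdorff(A, B), 3, tolerance = 1e-9)
  expect_equal(avg_hausdorff(A, A), 0)
})

test_that("relative Hausdorff is a scale-invariant percentage", {
  expect_equal(relative_hausdorff(0, 100), 0)
  expect_equal(relative_hausdorff(2, 100), 2)     # the success boundary
  ct1 <- circle_contour(20, 50, 50, 128)
  ct2 <- circle_contour(22, 50, 50, 128)
  h3 <- function(s) {
    X <- resample_closed(ct1 * s, spacing = 1)
    Y <- resample_closed(ct2 * s, spacing = 1)
    relative_hausdorff(avg_hausdorff(X, Y), nrow(X))
  }
  expect_equal(h3(1), h3(3), tolerance = 0.05)
})

test_that("confusion counts partition the image", {
  set.seed(42)
  p <- matrix(rbinom(400, 1, 0.3), 20)
  g <- matrix(rbinom(400, 1, 0.3), 20)
  cf <- confusion(p, g)
  expect_equal(cf$TP + cf$FP + cf$TN + cf$FN, 400)
  self <- confusion(g, g)
  expect_equal(self$FP + self$FN, 0)
  inv <- confusion(1 - g, g)
  expect_equal(inv$TP + inv$TN, 0)
  expect_error(confusion(p, matrix(0, 10, 10)), "shape")
})

test_that("area metrics evaluate the printed formulas on the percent scale", {
  m <- area_metrics(list(TP = 2, FP = 1, TN = 96, FN = 1))
  expect_equal(m$Jac, 50)
  expect_equal(m$Dice, 200 / 3, tolerance = 1e-10)
  expect_equal(m$Rec, 200 / 3, tolerance = 1e-10)
  expect_equal(m$Pre, 200 / 3, tolerance = 1e-10)
  expect_equal(m$Acc, 98)
  perfect <- area_metrics(list(TP = 10, FP = 0, TN = 90, FN = 0))
  expect_equal(unlist(perfect[c("Rec", "Pre", "Jac", "Dice")]),
               c(Rec = 100, Pre = 100, Jac = 100, Dice = 100))
  expect_true(is.na(area_metrics(list(TP = 0, FP = 0, TN = 1, FN = 0))$Pre))
  # Dice-Jaccard identity on random confusion tables
  set.seed(43)
  for (rep in 1:50) {
    cf <- as.list(setNames(sample(0:50, 4, replace = TRUE),
                           c("TP", "FP", "TN", "FN")))
    if (cf$TP + cf$FP + cf$FN == 0) next
    m <- area_metrics(cf)
    expect_equal(m$Dice, 2 * m$Jac / (100 + m$Jac) * 100, tolerance = 1e-9)
    expect_lte(m$Jac, m$Dice)
  }
})

test_that("success ratio uses the inclusive 2% rule over successful cases", {
  mk <- function(h3) structure(list(distH1 = h3, distH2 = h3, distH3 = h3,
                                    Rec = 90, Pre = 90, Acc = 99, Jac = 80,
                                    Dice = 89, success = h3 <= 2),
                               class = "metrics_report")
  r <- sg_ratio(list(mk(1), mk(1.5), mk(2.0), mk(2.1)))
  expect_equal(r$SGratio, 75)
  expect_equal(r$successful, 1:3)
  all_ok <- sg_ratio(list(mk(0.5), mk(0.7)))
  expect_equal(all_ok$SGratio, 100)
})

test_that("a full metrics report is internally consistent", {
  ph <- easy_phantom(3)
  noisy <- ph$gt_contour + matrix(rnorm(2 * nrow(ph$gt_contour), 0, 0.4),
                                  ncol = 2)
  rep1 <- metrics_report(noisy, ph$gt_contour,
                         rasterize_polygon(noisy, 128, 128), ph$gt_mask)
  expect_lte(rep1$distH2, rep1$distH1)
  expect_lte(rep1$Jac, rep1$Dice)
  expect_true(rep1$success)
  expect_equal(rep1$Dice, 2 * rep1$Jac / (100 + rep1$Jac) * 100,
               tolerance = 1e-9)
})
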