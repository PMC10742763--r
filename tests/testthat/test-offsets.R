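test_that("contour extraction matches a disk analytically", {
  mk <- disk_mask(80, 40, 40, 30)
  ct <- extract_contour(mk)
  expect_lt(abs(poly_length(ct) - 2 * pi * 30) / (2 * pi * 30), 0.03)
  expect_gt(poly_signed_area(ct), 0)                 # CCW convention
  rt <- rasterize_polygon(ct, 80, 80)
  dice <- 2 * sum(rt & mk) / (sum(rt) + sum(mk))
  expect_gte(dice, 0.98)
  two <- mk; two[1:4, 1:4] <- 1L
  expect_error(extract_contour(two), "multiple components")
  expect_error(extract_contour(mk * 0L), "empty")
})

test_that("circle offsets are concentric circles at the right radii", {
  ct <- circle_contour(30, 40, 40)
  fld <- generate_offsets(ct, n_levels = 3, spacing = 5)
  expect_length(fld$trajectories, 3)
  lv <- vapply(fld$trajectories, `[[`, 0, "level")
  expect_setequal(lv, c(-5, 0, 5))
  for (tr in fld$trajectories) {
    rr <- sqrt(rowSums(sweep(tr$samples, 2, c(40, 40))^2))
    expect_lt(max(abs(rr - (30 + tr$level))), 1)
    # unit tangents everywhere
    expect_lt(max(abs(sqrt(rowSums(tr$tangents^2)) - 1)), 1e-9)
  }
  # arc length monotone in level for this convex contour
  ord <- order(lv)
  al <- vapply(fld$trajectories, `[[`, 0, "arc_length")[ord]
  expect_true(all(diff(al) > 0))
})

test_that("inward offsets of a deep concavity are trimmed to simple curves", {
  # dumbbell: two disks joined by a thin neck
  t1 <- seq(0, 2 * pi, length.out = 257)[-257]
  th <- atan2(sin(t1), cos(t1))
  r <- 20 + 14 * cos(2 * t1)          # peanut-shaped closed curve
  xy <- cbind(60 + r * cos(t1), 45 + r * sin(t1))
  xy <- ensure_ccw(xy)
  fld <- generate_offsets(xy, n_levels = 3, spacing = 5)
  for (tr in fld$trajectories) {
    # brute-force pairwise segment-intersection simplicity check
    expect_equal(nrow(self_intersections(tr$control_points)), 0)
  }
  # offsetting far beyond the inradius annihilates with a warning
  expect_warning(generate_offsets(circle_contour(10), n_levels = 3,
                                  spacing = 11), "annihilated")
})

test_that("tangent lookup returns the nearest point's tangent", {
  ct <- circle_contour(30, 0, 0)
  fld <- generate_offsets(ct, n_levels = 1, spacing = 5)
  q <- tangent_at_nearest(fld, c(31, 0), sense = "CCW")
  expect_lt(max(abs(q$tangent - c(0, 1))), 0.05)
  expect_lt(max(abs(q$point - c(30, 0))), 0.2)
  q2 <- tangent_at_nearest(fld, c(31, 0), sense = "CW")
  expect_lt(max(abs(q2$tangent - c(0, -1))), 0.05)
  # random queries agree with a dense brute-force nearest-point search
  set.seed(7)
  dense <- do.call(rbind, lapply(fld$trajectories, `[[`, "samples"))
  for (rep in 1:20) {
    p <- runif(2, -45, 45)
    got <- tangent_at_nearest(fld, p)$point
    d2 <- (dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2
    expect_lt(sqrt(sum((got - dense[which.min(d2), ])^2)), 1e-6)
  }
})
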