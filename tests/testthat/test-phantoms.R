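test_that("spec invariants are enforced", {
  expect_error(phantom_spec(gap_total_frac = 0.1, gap_max_frac = 0.2),
               "gap_max_frac")
  expect_error(phantom_spec(gap_total_frac = 0.3, gap_max_frac = 0),
               "positive")
  expect_error(phantom_spec(gap_total_frac = 1.0, gap_max_frac = 0.5))
})

test_that("a clean blob phantom renders its full boundary", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, seed = 2))
  # every ground-truth boundary sample has an edge pixel within a pixel
  ep <- which(ph$edge_map == 1L, arr.ind = TRUE)
  exy <- cbind(ep[, 2] - 1, ep[, 1] - 1)
  dd <- marlseg:::min_dist_to_set(resample_closed(ph$gt_contour, spacing = 1), exy)
  expect_true(all(dd <= 1.0))
  expect_equal(ph$realized_gap_total_frac, 0)
  # contour and mask agree almost everywhere
  rast <- rasterize_polygon(ph$gt_contour, nrow(ph$gt_mask), ncol(ph$gt_mask))
  expect_gte(mean(rast == ph$gt_mask), 0.99)
})

test_that("requested gap fractions are realized within tolerance", {
  ph <- make_phantom(phantom_spec(gap_total_frac = 0.3, gap_max_frac = 0.2,
                                  seed = 5))
  expect_lt(abs(ph$realized_gap_total_frac - 0.3), 0.02)
  expect_lt(abs(ph$realized_gap_max_frac - 0.2), 0.02)
  # measured from the rendered edge map too
  gs <- gap_statistics(ph$edge_map, ph$gt_contour, tol = 2)
  expect_lt(abs(gs$L_g - 0.30), 0.02)
  expect_lt(abs(gs$L_g_max - 0.20), 0.02)
})

test_that("phantom generation is deterministic and monotone in gaps", {
  sp <- phantom_spec(gap_total_frac = 0.2, gap_max_frac = 0.1, seed = 9)
  expect_identical(make_phantom(sp), make_phantom(sp))
  # more total gap -> fewer boundary edge pixels
  counts <- vapply(c(0.1, 0.3, 0.5), function(g) {
    ph <- make_phantom(phantom_spec(gap_total_frac = g, gap_max_frac = 0.1,
                                    seed = 9))
    sum(ph$edge_map)
  }, 0)
  expect_true(all(diff(counts) < 0))
})

test_that("make_corpus spans all categories with matching manifest", {
  dir <- withr::local_tempdir()
  corpus <- make_corpus(2, seed = 4, dir = dir)
  expect_length(corpus$phantoms, 16)
  expect_equal(sort(unique(corpus$category)), sort(category_codes()))
  expect_equal(as.vector(table(corpus$category)), rep(2L, 8))
  expect_equal(nrow(corpus$manifest), 16)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(corpus$manifest$image_path)))
  # PNG/JSON round trips
  img <- read_image_png(corpus$manifest$image_path[1])
  expect_equal(dim(img), dim(corpus$phantoms[[1]]$image))
  ct <- read_contour_json(corpus$manifest$contour_path[1])
  expect_equal(ncol(ct), 2)
})
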