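make_test_env <- function(edge = NULL, n_agents = 4L, cfg = env_config(),
                          radius = 30) {
  ct <- circle_contour(radius, 40, 40)
  fld <- generate_offsets(ct, n_levels = 1, spacing = 5)
  if (is.null(edge)) {
    edge <- matrix(0L, 80, 80)
    pts <- resample_closed(ct, spacing = 0.5)
    edge[cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)] <- 1L
  }
  seg_env(matrix(128, 80, 80), edge, fld, n_agents = n_agents, cfg = cfg)
}

test_that("spawning distributes agents evenly with alternating senses", {
  e <- make_test_env(n_agents = 4L)
  ags <- e$agents
  senses <- vapply(ags, `[[`, "", "sense")
  expect_equal(sum(senses == "CW"), 2)
  expect_equal(sum(senses == "CCW"), 2)
  pos <- t(vapply(ags, `[[`, numeric(2), "position"))
  ang <- sort((atan2(pos[, 2] - 40, pos[, 1] - 40) * 180 / pi) %% 360)
  gaps <- diff(c(ang, ang[1] + 360))
  expect_true(all(abs(gaps - 90) < 3))          # ~equal arc intervals
  expect_error(spawn_agents(e$field, 1), "at least 2")
  expect_error(spawn_agents(e$field, 3), "even")
  e2 <- make_test_env(n_agents = 4L)
  expect_identical(lapply(e2$agents, `[[`, "position"),
                   lapply(ags, `[[`, "position"))
})

test_that("average curvature matches the analytic circle value", {
  line <- cbind(0:30, rep(0, 31))
  expect_equal(average_curvature(line, 21), 0)
  th <- (0:40) * (1 / 10)                       # 1 px steps on a radius-10 circle
  circ <- cbind(10 * cos(th), 10 * sin(th))
  expect_lt(abs(average_curvature(circ, 21) - 0.1), 0.005)
  # events older than the window do not affect the value
  spike <- rbind(c(0, 0), c(1, 5), c(2, -5), cbind(3:40, 0))
  expect_equal(average_curvature(spike, 10), 0)
})

test_that("observation reflects edge contact, density and windowing", {
  e <- make_test_env(n_agents = 4L)
  ob <- seg_env_observe(e)
  expect_equal(dim(ob$frames), c(4, 24, 24, 9))
  expect_equal(ncol(ob$extra), e$extra_dim)
  # agent on the rendered edge: stepping straight keeps it on-edge
  st <- seg_env_step(e, rep(3L, 4))
  a <- e$agents[[1]]
  expect_equal(a$mode, "edge")
  expect_equal(a$t_free, 0L)
  # empty edge map: free mode, zero density
  e0 <- make_test_env(edge = matrix(0L, 80, 80), n_agents = 2L)
  seg_env_step(e0, rep(3L, 2))
  expect_equal(e0$agents[[1]]$mode, "free")
  expect_equal(e0$agents[[1]]$d_i, 0)
  # half-edge window density
  half <- matrix(0L, 80, 80); half[, 1:40] <- 1L
  expect_equal(marlseg:::local_edge_density(half, c(39.5, 40), 24), 0.5)
})

test_that("step length is exact and the death rule is strict", {
  cfg <- env_config(t_live = 5)
  e <- make_test_env(edge = matrix(0L, 80, 80), n_agents = 2L, cfg = cfg)
  p0 <- e$agents[[1]]$position
  seg_env_step(e, rep(3L, 2))
  expect_equal(sqrt(sum((e$agents[[1]]$position - p0)^2)), cfg$step_length,
               tolerance = 1e-12)
  # t_free == t_live survives; t_live + 1 dies
  for (k in 2:5) seg_env_step(e, rep(3L, sum(seg_env_active(e))))
  expect_equal(e$agents[[1]]$t_free, 5L)
  expect_true(e$agents[[1]]$alive)
  seg_env_step(e, rep(3L, sum(seg_env_active(e))))
  expect_false(e$agents[[1]]$alive)
  # conservation: alive + dead constant
  expect_length(e$agents, 2L)
})

test_that("collision angles match a least-squares tangent oracle", {
  mk_agent <- function(path, sense) list(id = 1, position = path[nrow(path), ],
                                         path = path, sense = sense,
                                         alive = TRUE, closed = FALSE)
  # head-on along a line
  a1 <- mk_agent(cbind(0:5, 0), "CCW")
  a2 <- mk_agent(cbind(10:5, 0), "CW"); a2$id <- 2
  ev <- detect_collisions(list(a1, a2), collision_radius = 2)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$theta_ik, 180, tolerance = 1e-6)
  # perpendicular
  a3 <- mk_agent(cbind(rep(5, 6), 5:0), "CW"); a3$id <- 2
  ev2 <- detect_collisions(list(a1, a3), collision_radius = 2)
  expect_equal(ev2[[1]]$theta_ik, 90, tolerance = 1e-6)
  # same-sense pairs never collide
  a4 <- a2; a4$sense <- "CCW"
  expect_length(detect_collisions(list(a1, a4), 2), 0)
  # oracle: least-squares linear fits of the last 5 points
  set.seed(3)
  for (rep in 1:5) {
    th <- runif(2, 0, pi)
    # both paths end near the origin so the pair is within collision range
    p1 <- cbind(cos(th[1]) * (-4:0), sin(th[1]) * (-4:0)) + rnorm(10, 0, 0.01)
    p2 <- sweep(cbind(cos(th[2]) * (4:0), sin(th[2]) * (4:0)), 2, c(-0.3, 0))
    b1 <- mk_agent(p1, "CCW"); b2 <- mk_agent(p2, "CW"); b2$id <- 2
    ev <- detect_collisions(list(b1, b2), collision_radius = 3)
    dir_ls <- function(p, forward = TRUE) {
      t5 <- seq_len(nrow(p))
      d <- c(coef(lm(p[, 1] ~ t5))[2], coef(lm(p[, 2] ~ t5))[2])
      d / sqrt(sum(d^2))
    }
    oracle <- acos(pmin(pmax(sum(dir_ls(p1) * dir_ls(p2)), -1), 1)) * 180 / pi
    expect_equal(ev[[1]]$theta_ik, oracle, tolerance = 1.5)
  }
})

test_that("episodes are reproducible under a fixed seed and policy", {
  run_once <- function() {
    e <- make_test_env(n_agents = 4L)
    seg_env_reset(e, seed = 5)
    set.seed(5)
    for (k in 1:30) {
      act <- which(seg_env_active(e))
      if (length(act) == 0) break
      seg_env_step(e, sample(1:5, length(act), replace = TRUE))
    }
    lapply(e$agents, `[[`, "path")
  }
  expect_identical(run_once(), run_once())
})
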