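cfg <- reward_config()

test_that("indicator boundaries follow the printed inequalities exactly", {
  # curvature continuity: inclusive at s'
  expect_equal(continuity1(0, cfg), cfg$delta_r)
  expect_equal(continuity1(cfg$s_prime, cfg), cfg$delta_r)
  expect_equal(continuity1(cfg$s_prime + 1e-9, cfg), 0)
  # collision continuity: theta_min inclusive, 180 inclusive
  expect_equal(continuity2(180, cfg), cfg$delta_r)
  expect_equal(continuity2(118, cfg), cfg$delta_r)
  expect_equal(continuity2(117, cfg), 0)
  # proximity: inclusive at t_cont
  expect_equal(proximity(0, cfg), cfg$delta_r)
  expect_equal(proximity(cfg$t_cont, cfg), cfg$delta_r)
  expect_equal(proximity(cfg$t_cont + 1, cfg), 0)
  # density: strict at d'
  expect_equal(density(1, cfg), cfg$delta_r)
  expect_equal(density(cfg$d_prime, cfg), 0)
  expect_equal(density(0, cfg), 0)
})

test_that("closure fires in the departure neighborhood, once, after travel", {
  dep <- c(10, 10)
  expect_equal(closure_reward(dep, dep, cfg, traveled = 100), cfg$delta_r)
  expect_equal(closure_reward(dep + c(2 * cfg$closure_radius, 0), dep, cfg,
                              traveled = 100), 0)
  # travel guard and one-shot flag
  expect_equal(closure_reward(dep, dep, cfg, traveled = cfg$closure_radius), 0)
  expect_equal(closure_reward(dep, dep, cfg, traveled = 100,
                              already_fired = TRUE), 0)
})

test_that("the total is the exact weighted sum with the trained weights", {
  full <- list(r_cont1 = 1, r_cont2 = 1, r_prox = 1, r_closure = 1,
               r_density = 1)
  expect_equal(total_reward(full, cfg), 1.00)
  none <- lapply(full, function(x) 0)
  expect_equal(total_reward(none, cfg), 0)
  cont <- list(r_cont1 = 1, r_cont2 = 1, r_prox = 0, r_closure = 0,
               r_density = 0)
  expect_equal(total_reward(cont, cfg), 0.54)
  # weights sum to one; continuity share 54%
  expect_equal(cfg$w_c1 + cfg$w_c2 + cfg$w_pr + cfg$w_d + cfg$w_cl, 1.00)
  expect_equal(cfg$w_c1 + cfg$w_c2, 0.54)
})

test_that("total is monotone in each component", {
  base <- list(r_cont1 = 0, r_cont2 = 1, r_prox = 0, r_closure = 1,
               r_density = 0)
  t0 <- total_reward(base, cfg)
  for (nm in names(base)) {
    up <- base; up[[nm]] <- up[[nm]] + 1
    expect_gte(total_reward(up, cfg), t0)
  }
})

test_that("closure fires at most once per episode in a live environment", {
  # a tight circular edge the agent laps repeatedly
  ct <- circle_contour(12, 30, 30)
  fld <- generate_offsets(ct, n_levels = 1, spacing = 5)
  edge <- matrix(0L, 60, 60)
  pts <- resample_closed(ct, spacing = 0.5)
  edge[cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)] <- 1L
  env <- seg_env(matrix(128, 60, 60), edge, fld, n_agents = 2L)
  fired <- 0
  for (k in 1:200) {
    act <- which(seg_env_active(env))
    if (length(act) == 0) break
    st <- seg_env_step(env, rep(3L, length(act)))
    fired <- fired + sum(vapply(st$breakdowns, function(b) b$r_closure > 0, TRUE))
  }
  expect_lte(fired, length(env$agents))
  for (a in env$agents) expect_lte(as.numeric(a$closure_fired), 1)
})
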