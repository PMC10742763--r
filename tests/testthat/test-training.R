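test_that("GAE matches direct summation of the weighted TD errors", {
  set.seed(11)
  for (rep in 1:20) {
    T_ <- sample(2:20, 1)
    r <- rnorm(T_); v <- c(rnorm(T_), 0)
    g <- compute_gae(r, v, gamma = 0.99, lambda = 0.95)
    brute <- vapply(seq_len(T_), function(t)
      sum((0.99 * 0.95)^(0:(T_ - t)) * g$delta[t:T_]), 0)
    expect_lt(max(abs(g$advantage - brute)), 1e-10)
  }
  # single step: delta = A = Vhat = r when V == 0
  g1 <- compute_gae(1, c(0, 0), 0.99, 0.95)
  expect_equal(unname(unlist(g1)), c(1, 1, 1))
  # gamma = 0 removes all lookahead
  g0 <- compute_gae(c(1, 2, 3), c(5, 6, 7, 0), gamma = 0, lambda = 0.7)
  expect_equal(g0$advantage, c(1, 2, 3) - c(5, 6, 7))
  expect_error(compute_gae(1:3, 1:3, 0.9, 0.9), "bootstrap")
})

test_that("lambda = 1 telescopes to the empirical discounted return", {
  set.seed(12)
  r <- rnorm(15); v <- c(rnorm(15), 0)
  g <- compute_gae(r, v, gamma = 0.97, lambda = 1)
  ret <- vapply(1:15, function(t) sum(0.97^(0:(15 - t)) * r[t:15]), 0)
  expect_lt(max(abs(g$advantage + v[1:15] - ret)), 1e-8)
})

test_that("surrogate loss matches a termwise transcription and its identities", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(3:30, 1)
    lp_new <- rnorm(n, sd = 0.3); lp_old <- rnorm(n, sd = 0.3)
    A <- rnorm(n); eps <- 0.2
    got <- surrogate_loss(lp_new, lp_old, A, eps)
    terms <- vapply(seq_len(n), function(t) {
      rho <- exp(lp_new[t] - lp_old[t])
      min(rho * A[t], min(max(rho, 1 - eps), 1 + eps) * A[t])
    }, 0)
    expect_equal(got, mean(terms), tolerance = 1e-12)
  }
  # ratio-one identity: theta = theta_old gives mean advantage exactly
  lp <- rnorm(20); A <- rnorm(20)
  expect_identical(surrogate_loss(lp, lp, A, 0.2), mean(A))
  # clip activation: A > 0 and rho = 1 + 2 eps selects the clipped term
  expect_equal(surrogate_loss(log(1.4), log(1), 2, 0.2), 1.2 * 2)
})

test_that("value loss normalizes by trajectory count as printed", {
  expect_equal(value_loss(c(1, 2, 3), c(1, 2, 3), 2), 0)
  # two trajectories with squared-error sums 3 and 5 -> 4
  v <- c(1, 1, 1, 2, 2); vh <- c(1 + sqrt(3), 1, 1, 2 + sqrt(2), 2 + sqrt(3))
  expect_equal(value_loss(v, vh, 2), 4)
  expect_equal(value_loss(c(0, 0), c(2, 2), 1), 4 * value_loss(c(0, 0), c(1, 1), 1))
})

test_that("a short PPO run on the toy corridor is finite and reproducible", {
  run <- function() {
    env <- toy_corridor_env()
    pol <- net_init(net_spec(r = 8, extra_dim = env$extra_dim, n_out = 5), seed = 1)
    val <- net_init(net_spec(r = 8, extra_dim = env$extra_dim, n_out = 1), seed = 2)
    cfg <- ppo_config(E_pi = 2, E_phi = 2, iterations = 5,
                      collect_target = 32, seed = 3)
    ppo_train(env, pol, val, cfg)$log
  }
  log1 <- run()
  expect_equal(nrow(log1), 5)
  expect_true(all(is.finite(log1$L_theta)))
  expect_true(all(is.finite(log1$L_phi)))
  expect_identical(log1, run())               # fixed seed, single thread
})

test_that("the curriculum starts easiest and advances on plateaus", {
  expect_equal(curriculum_schedule(NULL), "B|B|B")
  expect_equal(curriculum_schedule(data.frame()), "B|B|B")
  # plateaued easiest category advances to the next code
  lb <- data.frame(category = rep("B|B|B", 40), success = rep(0.9, 40))
  expect_equal(curriculum_schedule(lb, window = 20, tol = 0.02), "B|B|T")
  # still-improving category stays
  lb2 <- data.frame(category = rep("B|B|B", 40),
                    success = seq(0.1, 0.9, length.out = 40))
  expect_equal(curriculum_schedule(lb2, window = 20, tol = 0.02), "B|B|B")
  # the full order is the lattice sorted by tough count then position
  expect_equal(category_codes(),
               c("B|B|B", "B|B|T", "B|T|B", "T|B|B",
                 "B|T|T", "T|B|T", "T|T|B", "T|T|T"))
  nt <- vapply(strsplit(category_codes(), "|", fixed = TRUE),
               function(p) sum(p == "T"), 0L)
  expect_true(all(diff(nt) >= 0))
})
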