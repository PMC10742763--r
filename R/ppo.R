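# Proximal policy optimization with generalized advantage estimation.
# An outer iteration collects per-agent trajectories until the transition
# budget T_max is exceeded, then updates the policy over E_pi epochs on the
# clipped surrogate and the value network over E_phi epochs on the squared
# return error, both with Adam. Advantages are standardized per collection
# round. Defaults follow the trained hyperparameters: T_max = 900,
# epsilon = 0.2, gamma = 0.99, lambda = 0.95, E_pi = E_phi = 40,
# lr_theta = 2e-4, lr_phi = 1e-3.

#' PPO hyperparameters
#'
#' @param T_max transition budget per collection round.
#' @param epsilon clipping threshold of the probability ratio.
#' @param gamma discount factor; @param lambda GAE smoothing factor.
#' @param E_pi,E_phi policy/value epochs per iteration.
#' @param lr_theta,lr_phi Adam learning rates (policy/value).
#' @param minibatch minibatch size in transitions.
#' @param iterations outer iteration budget.
#' @param collect_target transitions to gather per round (capped by
#'   `T_max`); lets small toy environments collect several episodes per
#'   iteration.
#' @param entropy_coef coefficient of the standard PPO entropy bonus
#'   (0 disables; small positive values counteract premature collapse into
#'   degenerate locomotion patterns).
#' @param seed master seed.
#' @export
ppo_config <- function(T_max = 900L, epsilon = 0.2, gamma = 0.99,
                       lambda = 0.95, E_pi = 40L, E_phi = 40L,
                       lr_theta = 2e-4, lr_phi = 1e-3, minibatch = 256L,
                       iterations = 100L, collect_target = NULL,
                       entropy_coef = 0, seed = 1L) {
  stopifnot(gamma > 0, gamma <= 1, lambda >= 0, lambda <= 1, epsilon > 0)
  if (is.null(collect_target)) collect_target <- T_max
  structure(list(T_max = as.integer(T_max), epsilon = epsilon, gamma = gamma,
                 lambda = lambda, E_pi = as.integer(E_pi),
                 E_phi = as.integer(E_phi), lr_theta = lr_theta,
                 lr_phi = lr_phi, minibatch = as.integer(minibatch),
                 iterations = as.integer(iterations),
                 collect_target = as.integer(min(collect_target, T_max)),
                 entropy_coef = entropy_coef, seed = as.integer(seed)),
            class = "ppo_config")
}

#' Generalized advantage estimation for one trajectory
#'
#' Temporal-difference errors
#' `delta_t = r_t + gamma V(s_{t+1}) - V(s_t)` are combined into the
#' exponentially weighted forward sum
#' `A_t = sum_{l >= 0} (gamma lambda)^l delta_{t+l}`. The return estimate
#' used as the value-regression target is the GAE-consistent
#' `Vhat_t = A_t + V(s_t)`, which at `lambda = 1` equals the discounted
#' reward-to-go plus the discounted bootstrap value.
#'
#' @param rewards length-T reward vector.
#' @param values length-(T+1) value vector including the trailing bootstrap
#'   entry (0 for terminal states).
#' @param gamma,lambda discount and smoothing factors.
#' @return `list(delta, advantage, vhat)`, each length T.
#' @export
compute_gae <- function(rewards, values, gamma, lambda) {
  T_ <- length(rewards)
  if (length(values) != T_ + 1)
    stop("values must have one trailing bootstrap entry")
  delta <- rewards + gamma * values[-1] - values[-(T_ + 1)]
  adv <- numeric(T_)
  acc <- 0
  for (t in T_:1) {
    acc <- delta[t] + gamma * lambda * acc
    adv[t] <- acc
  }
  list(delta = delta, advantage = adv, vhat = adv + values[seq_len(T_)])
}

#' Clipped surrogate objective
#'
#' `L = mean( min(rho_t A_t, clip(rho_t, 1 - eps, 1 + eps) A_t) )` with
#' `rho_t` the new/old probability ratio. This is the maximized objective;
#' the trainer minimizes its negative.
#'
#' @param logp_new,logp_old log-probabilities of the taken actions.
#' @param advantages advantage estimates.
#' @param epsilon clipping threshold.
#' @return Scalar objective value.
#' @export
surrogate_loss <- function(logp_new, logp_old, advantages, epsilon) {
  rho <- exp(logp_new - logp_old)
  if (any(!is.finite(rho))) stop("non-finite probability ratio")
  mean(pmin(rho * advantages,
            pmin(pmax(rho, 1 - epsilon), 1 + epsilon) * advantages))
}

#' Value-network squared-error loss
#'
#' `L_phi = (1/K) sum_i sum_t (V(s_i(t)) - Vhat_i(t))^2`, normalized by the
#' number of trajectories `K` (not by the number of transitions).
#'
#' @param v_pred predicted values over all transitions.
#' @param vhat regression targets.
#' @param n_traj number of trajectories K.
#' @export
value_loss <- function(v_pred, vhat, n_traj) {
  sum((v_pred - vhat)^2) / n_traj
}

#' Sample one categorical action per row of a probability matrix
#' @param probs `[B, n]` matrix of row-normalized probabilities.
#' @return Integer vector of sampled column indices.
#' @export
sample_actions <- function(probs) {
  u <- stats::runif(nrow(probs))
  cp <- t(apply(probs, 1, cumsum))
  as.integer(rowSums(u > cp) + 1L)
}

# Collect trajectories from a batch environment until the transition budget
# is reached. env interface: seg_env-style function set (see ppo_train).
collect_round <- function(env_if, policy, cfg, round_seed) {
  frames_l <- list(); extra_l <- list(); act_l <- integer(0)
  logp_l <- numeric(0); rew_l <- numeric(0)
  traj_id <- integer(0)            # trajectory key per transition
  done_l <- logical(0)
  total <- 0L
  ep <- 0L
  next_traj <- 0L
  open_traj <- integer(0)          # agent slot -> trajectory id
  while (total < cfg$collect_target && total <= cfg$T_max) {
    ep <- ep + 1L
    set.seed(mix_seed(round_seed, ep))
    env_if$reset(mix_seed(round_seed, ep))
    open_traj <- rep(NA_integer_, env_if$n_agents)
    while (TRUE) {
      ob <- env_if$observe()
      if (length(ob$idx) == 0) break
      new <- is.na(open_traj[ob$idx])
      if (any(new)) {
        open_traj[ob$idx[new]] <- next_traj + seq_len(sum(new))
        next_traj <- next_traj + sum(new)
      }
      fw <- net_forward(policy, ob$frames, ob$extra)
      acts <- sample_actions(fw$probs)
      lp <- policy_logp(fw$probs, acts)
      st <- env_if$step(acts)
      frames_l[[length(frames_l) + 1]] <- ob$frames
      extra_l[[length(extra_l) + 1]] <- ob$extra
      act_l <- c(act_l, acts)
      logp_l <- c(logp_l, lp)
      rew_l <- c(rew_l, st$rewards)
      traj_id <- c(traj_id, open_traj[ob$idx])
      done_l <- c(done_l, st$done)
      total <- total + length(acts)
      if (total > cfg$T_max) break
    }
    if (total >= cfg$collect_target) break
  }
  B <- length(act_l)
  r <- dim(frames_l[[1]])[2]; Cc <- dim(frames_l[[1]])[4]
  frames <- array(0, c(B, r, r, Cc))
  ptr <- 0L
  for (f in frames_l) {
    nb <- dim(f)[1]
    frames[ptr + seq_len(nb), , , ] <- f
    ptr <- ptr + nb
  }
  list(frames = frames, extra = do.call(rbind, extra_l), actions = act_l,
       logp_old = logp_l, rewards = rew_l, traj = traj_id, done = done_l)
}

#' Warm-start a policy by imitating the offset-guidance field
#'
#' The observation vector already contains the guiding offset tangent in the
#' agent's heading frame; the natural locomotion prior is to select the
#' heading increment closest to that tangent's angle. This routine rolls the
#' current policy out in the environment and minimizes the cross-entropy
#' between the policy head and that prior by Adam. It plays the role the
#' published model assigns to transfer-learning pre-training: without a
#' locomotion warm start, desk-scale PPO from random parameters collapses
#' into a hover-near-edges local optimum (proximity and density pay, the
#' continuity reward never becomes reachable). PPO then refines the
#' warm-started policy on the actual reward system.
#'
#' @param env_if environment interface (see [ppo_train()]), or a list of
#'   several such interfaces to cycle through (diversifies the imitation
#'   data).
#' @param policy initial `net_params`.
#' @param increments_deg the action increments (for the prior's targets).
#' @param steps number of Adam updates (the warm-up budget).
#' @param n_samples size of the demonstration dataset collected before the
#'   supervised phase.
#' @param explore_eps probability that a rollout action deviates uniformly
#'   at random from the prior; injects the off-track recovery states the
#'   policy must also master.
#' @param batch supervised minibatch size.
#' @param lr learning rate.
#' @param seed integer seed.
#' @return The warm-started policy parameters.
#' @export
pretrain_guidance <- function(env_if, policy, increments_deg = c(-45, -22.5, 0, 22.5, 45),
                              steps = 600L, n_samples = 3000L,
                              explore_eps = 0.35, batch = 128L, lr = 1e-3,
                              seed = 1L) {
  envs <- if (!is.null(env_if$observe)) list(env_if) else env_if
  set.seed(mix_seed(seed, 1L))
  ## phase 1: demonstration rollouts of the prior itself (with exploration
  ## noise), giving a fixed, well-spread state/target dataset — no feedback
  ## between the partially trained policy and the data distribution
  frames_l <- list(); extra_l <- list(); target_l <- integer(0)
  ei <- 1L
  envs[[ei]]$reset(mix_seed(seed, 1L))
  guard <- 0L
  while (length(target_l) < n_samples && guard < 100L * n_samples) {
    guard <- guard + 1L
    ob <- envs[[ei]]$observe()
    if (length(ob$idx) == 0) {
      ei <- ei %% length(envs) + 1L
      envs[[ei]]$reset(mix_seed(seed, guard + 2L))
      next
    }
    ang <- atan2(ob$extra[, 3], ob$extra[, 2]) * 180 / pi
    target <- vapply(ang, function(a) which.min(abs(increments_deg - a)), 0L)
    frames_l[[length(frames_l) + 1]] <- ob$frames
    extra_l[[length(extra_l) + 1]] <- ob$extra
    target_l <- c(target_l, target)
    acts <- target
    rnd <- stats::runif(length(acts)) < explore_eps
    acts[rnd] <- sample.int(length(increments_deg), sum(rnd), replace = TRUE)
    envs[[ei]]$step(acts)
  }
  n <- length(target_l)
  r <- dim(frames_l[[1]])[2]; Cc <- dim(frames_l[[1]])[4]
  frames <- array(0, c(n, r, r, Cc))
  ptr <- 0L
  for (f in frames_l) {
    nb <- dim(f)[1]
    frames[ptr + seq_len(nb), , , ] <- f
    ptr <- ptr + nb
  }
  extra <- do.call(rbind, extra_l)
  ## phase 2: plain supervised cross-entropy over the static dataset
  astate <- adam_init(policy)
  done <- 0L
  while (done < steps) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      mb <- ord[s:min(s + batch - 1L, n)]
      fw <- net_forward(policy, frames[mb, , , , drop = FALSE],
                        extra[mb, , drop = FALSE], cache = TRUE)
      dz <- policy_logp_grad_z(fw$z, target_l[mb], rep(-1 / length(mb), length(mb)))
      gr <- net_backward(policy, fw$cache, dz)
      up <- adam_step(policy, gr, astate, lr)
      policy <- up$params; astate <- up$state
      done <- done + 1L
      if (done >= steps) break
    }
  }
  policy
}

#' Train policy and value networks with PPO
#'
#' Generic over environments exposing the batch interface
#' `list(n_agents, reset(seed), observe(), step(actions))` where `observe()`
#' returns `list(frames, extra, idx)` and `step()` returns
#' `list(rewards, done, idx)`. [seg_env()] and [toy_corridor_env()] both
#' provide it.
#'
#' @param env_if environment interface list.
#' @param policy,value initialized `net_params` (disjoint parameter sets).
#' @param cfg a [ppo_config()].
#' @param callback optional `function(iter, info)`; returning `FALSE` stops
#'   training early (used for convergence checks).
#' @return `list(policy, value, log)`; the log has one row per iteration
#'   with the surrogate and value losses and the mean collected reward.
#' @export
ppo_train <- function(env_if, policy, value, cfg = ppo_config(),
                      callback = NULL) {
  astate <- adam_init(policy)
  vstate <- adam_init(value)
  log <- list()
  for (iter in seq_len(cfg$iterations)) {
    batch <- collect_round(env_if, policy, cfg, mix_seed(cfg$seed, iter))
    n <- length(batch$actions)
    # values with bootstrap 0 at trajectory ends
    vfw <- net_forward(value, batch$frames, batch$extra)
    v_old <- as.numeric(vfw$z)
    adv <- numeric(n); vhat <- numeric(n)
    K <- 0L
    for (tr in unique(batch$traj)) {
      sel <- which(batch$traj == tr)
      K <- K + 1L
      g <- compute_gae(batch$rewards[sel], c(v_old[sel], 0),
                       cfg$gamma, cfg$lambda)
      adv[sel] <- g$advantage
      vhat[sel] <- g$vhat
    }
    adv_std <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
    set.seed(mix_seed(cfg$seed + 5000L, iter))
    # policy epochs
    L_theta <- NA_real_
    for (ep in seq_len(cfg$E_pi)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = cfg$minibatch)) {
        mb <- ord[s:min(s + cfg$minibatch - 1, n)]
        fw <- net_forward(policy, batch$frames[mb, , , , drop = FALSE],
                          batch$extra[mb, , drop = FALSE], cache = TRUE)
        lp_new <- policy_logp(fw$probs, batch$actions[mb])
        rho <- exp(lp_new - batch$logp_old[mb])
        A <- adv_std[mb]
        # gradient of -mean(min(rho A, clip(rho) A)) wrt log pi:
        unclipped_active <- (rho * A <= pmin(pmax(rho, 1 - cfg$epsilon),
                                             1 + cfg$epsilon) * A + 1e-12) &
          (rho >= 1 - cfg$epsilon | A > 0) & (rho <= 1 + cfg$epsilon | A < 0)
        coef <- ifelse(unclipped_active, rho * A, 0) / length(mb)
        dz <- policy_logp_grad_z(fw$z, batch$actions[mb], -coef)
        if (cfg$entropy_coef > 0) {
          # entropy bonus gradient for the normalized-sigmoid head:
          # dH/dz_k = -(s_k (1 - s_k) / S) (log p_k + H)
          s <- marlseg_sigmoid(fw$z)
          Srow <- rowSums(s)
          lp <- log(pmax(fw$probs, 1e-300))
          Hent <- -rowSums(fw$probs * lp)
          dH <- -(s * (1 - s) / Srow) * (lp + Hent)
          dz <- dz - cfg$entropy_coef * dH / length(mb)
        }
        gr <- net_backward(policy, fw$cache, dz)
        up <- adam_step(policy, gr, astate, cfg$lr_theta)
        policy <- up$params; astate <- up$state
      }
      if (ep == cfg$E_pi) {
        fw <- net_forward(policy, batch$frames, batch$extra)
        L_theta <- surrogate_loss(policy_logp(fw$probs, batch$actions),
                                  batch$logp_old, adv_std, cfg$epsilon)
      }
    }
    # value epochs
    L_phi <- NA_real_
    for (ep in seq_len(cfg$E_phi)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = cfg$minibatch)) {
        mb <- ord[s:min(s + cfg$minibatch - 1, n)]
        fw <- net_forward(value, batch$frames[mb, , , , drop = FALSE],
                          batch$extra[mb, , drop = FALSE], cache = TRUE)
        resid <- as.numeric(fw$z) - vhat[mb]
        dz <- matrix(2 * resid / length(mb), ncol = 1)
        gr <- net_backward(value, fw$cache, dz)
        up <- adam_step(value, gr, vstate, cfg$lr_phi)
        value <- up$params; vstate <- up$state
      }
    }
    vfw <- net_forward(value, batch$frames, batch$extra)
    L_phi <- value_loss(as.numeric(vfw$z), vhat, K)
    if (!is.finite(L_theta) || !is.finite(L_phi))
      stop("NaN/Inf loss; aborting with diagnostics: iter ", iter)
    info <- list(iteration = iter, n_transitions = n, n_traj = K,
                 L_theta = L_theta, L_phi = L_phi,
                 mean_reward = mean(batch$rewards))
    log[[iter]] <- info
    if (!is.null(callback) && isFALSE(callback(iter, list(info = info,
                                                          policy = policy)))) break
  }
  logdf <- do.call(rbind, lapply(log, function(x)
    data.frame(iteration = x$iteration, n_transitions = x$n_transitions,
               n_traj = x$n_traj, L_theta = x$L_theta, L_phi = x$L_phi,
               mean_reward = x$mean_reward)))
  list(policy = policy, value = value, log = logdf)
}

#' A one-agent toy corridor environment
#'
#' Minimal sanity environment for the trainer: a single agent walks a
#' corridor for `episode_len` steps; exactly one action (`rewarded_action`)
#' yields reward 1, every other action yields 0. Frames are zero (there is
#' nothing to see); the extra input is a constant vector. A sound PPO
#' implementation drives the probability of the rewarded action toward 1.
#'
#' @param r receptive-field size of the attached network (small by default
#'   to keep the toy fast).
#' @param episode_len steps per episode.
#' @param rewarded_action index in 1..5.
#' @param extra_dim length of the constant non-image input.
#' @return Environment interface list for [ppo_train()].
#' @export
toy_corridor_env <- function(r = 8L, episode_len = 16L, rewarded_action = 3L,
                             extra_dim = 7L) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  extra0 <- matrix(seq(0.1, 0.7, length.out = extra_dim), 1)
  list(
    n_agents = 1L, r = r, in_channels = 9L, extra_dim = extra_dim,
    reset = function(seed) { state$t <- 0L; invisible(NULL) },
    observe = function() {
      if (state$t >= episode_len) return(list(idx = integer(0)))
      list(frames = array(0, c(1, r, r, 9)), extra = extra0, idx = 1L)
    },
    step = function(actions) {
      state$t <- state$t + 1L
      list(rewards = as.numeric(actions == rewarded_action),
           done = state$t >= episode_len, idx = 1L)
    })
}

#' Curriculum schedule over the complexity categories
#'
#' Categories are presented easiest-first in the fixed lattice order of
#' [category_codes()] (sorted by number of tough letters, then position).
#' Training advances to the next category when the moving average (window
#' `window`) of the per-iteration success statistic changes by less than
#' `tol` relative between the two most recent windows.
#'
#' @param logbook data frame with columns `category` and `success` (one row
#'   per iteration, in order).
#' @param window moving-average window (iterations).
#' @param tol relative-change threshold.
#' @return The category code to train on next.
#' @export
curriculum_schedule <- function(logbook, window = 20L, tol = 0.02) {
  codes <- category_codes()
  if (is.null(logbook) || nrow(logbook) == 0) return(codes[1])
  cur <- logbook$category[nrow(logbook)]
  ci <- match(cur, codes)
  rows <- logbook[logbook$category == cur, , drop = FALSE]
  if (nrow(rows) < 2 * window) return(cur)
  recent <- mean(utils::tail(rows$success, window))
  prev <- mean(utils::tail(rows$success, 2 * window)[seq_len(window)])
  denom <- max(abs(prev), 1e-8)
  if (abs(recent - prev) / denom < tol && ci < length(codes))
    return(codes[ci + 1])
  cur
}

#' Train the segmentation policy over a phantom corpus with a curriculum
#'
#' Builds a [seg_env()] per phantom, cycles through the phantoms of the
#' current curriculum category, and runs [ppo_train()] one iteration at a
#' time, advancing categories by [curriculum_schedule()]. Success per
#' iteration is the fraction of agents that fired their closure reward.
#'
#' @param corpus result of [make_corpus()] (or a compatible list).
#' @param env_cfg,reward_cfg,ppo_cfg configurations.
#' @param n_agents agents per episode.
#' @param categories category codes to include, in curriculum order.
#' @param window,tol curriculum advance parameters.
#' @param max_steps optional training-episode step cap; short truncated
#'   episodes concentrate experience near the informative spawn regime and
#'   restart agents on the offsets more often (`NULL` = the environment's
#'   boundary-proportional default).
#' @param pretrain_steps guidance-imitation warm-up updates before PPO
#'   (see [pretrain_guidance()]; 0 disables).
#' @param init_policy,init_value optional warm-start parameters.
#' @return `list(policy, value, log)`; the log adds `category` and `success`
#'   columns.
#' @export
train_segmenter <- function(corpus, env_cfg = env_config(),
                            reward_cfg = reward_config(),
                            ppo_cfg = ppo_config(), n_agents = 16L,
                            categories = category_codes(),
                            window = 20L, tol = 0.02, max_steps = NULL,
                            pretrain_steps = 0L,
                            init_policy = NULL, init_value = NULL) {
  # pre-build environments once per phantom
  envs <- list()
  for (i in seq_along(corpus$phantoms)) {
    if (!(corpus$category[i] %in% categories)) next
    ph <- corpus$phantoms[[i]]
    am <- try(attention_mask(ph$image), silent = TRUE)
    contour <- if (inherits(am, "try-error")) ph$gt_contour
               else align_contour_to_edges(am$contour, ph$edge_map)
    field <- generate_offsets(contour)
    envs[[length(envs) + 1]] <- list(
      category = corpus$category[i],
      env = seg_env(ph$image, ph$edge_map, field, n_agents = n_agents,
                    cfg = env_cfg, reward_cfg = reward_cfg,
                    max_steps = max_steps))
  }
  if (length(envs) == 0) stop("corpus contains no phantoms in the requested categories")
  ex_env <- envs[[1]]$env
  pspec <- net_spec(r = env_cfg$r, in_channels = 9L,
                    extra_dim = ex_env$extra_dim, n_out = 5L)
  vspec <- net_spec(r = env_cfg$r, in_channels = 9L,
                    extra_dim = ex_env$extra_dim, n_out = 1L)
  policy <- if (is.null(init_policy)) net_init(pspec, seed = ppo_cfg$seed) else init_policy
  value <- if (is.null(init_value)) net_init(vspec, seed = ppo_cfg$seed + 1L) else init_value
  if (pretrain_steps > 0) {
    wrap <- function(env0) list(n_agents = env0$n_agents,
                                reset = function(seed) seg_env_reset(env0, seed),
                                observe = function() seg_env_observe(env0),
                                step = function(a) seg_env_step(env0, a))
    pre_envs <- lapply(envs[seq_len(min(4L, length(envs)))],
                       function(x) wrap(x$env))
    policy <- pretrain_guidance(pre_envs, policy,
                                increments_deg = env_cfg$action_increments_deg,
                                steps = pretrain_steps, seed = ppo_cfg$seed)
  }
  logbook <- data.frame()
  cat_ptr <- list()                          # per-category round-robin pointer
  for (iter in seq_len(ppo_cfg$iterations)) {
    current <- curriculum_schedule(logbook, window = window, tol = tol)
    if (!(current %in% categories)) current <- categories[1]
    cands <- which(vapply(envs, function(x) x$category == current, TRUE))
    if (length(cands) == 0) cands <- seq_along(envs)
    ptr <- (cat_ptr[[current]] %||% 0L) %% length(cands) + 1L
    cat_ptr[[current]] <- ptr
    ei <- cands[ptr]
    one <- ppo_config(T_max = ppo_cfg$T_max, epsilon = ppo_cfg$epsilon,
                      gamma = ppo_cfg$gamma, lambda = ppo_cfg$lambda,
                      E_pi = ppo_cfg$E_pi, E_phi = ppo_cfg$E_phi,
                      lr_theta = ppo_cfg$lr_theta, lr_phi = ppo_cfg$lr_phi,
                      minibatch = ppo_cfg$minibatch, iterations = 1L,
                      collect_target = ppo_cfg$collect_target,
                      seed = mix_seed(ppo_cfg$seed, iter))
    env <- envs[[ei]]$env
    env_if <- list(n_agents = env$n_agents,
                   reset = function(seed) seg_env_reset(env, seed),
                   observe = function() seg_env_observe(env),
                   step = function(a) seg_env_step(env, a))
    # warm-start from the running parameters
    res <- ppo_train(env_if, policy, value, one)
    policy <- res$policy; value <- res$value
    succ <- mean(vapply(env$agents, function(a) as.numeric(a$closure_fired), 0))
    row <- cbind(res$log, category = current, success = succ)
    logbook <- rbind(logbook, row)
  }
  list(policy = policy, value = value, log = logbook)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
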