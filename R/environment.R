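# The partially observable multi-agent world. Agents live on the edge map,
# follow offset trajectories clockwise or counterclockwise, perceive an
# r x r receptive window (last three frames of edge/grayscale/occupancy
# channels), and die after spending more than t_live consecutive steps off
# the edge. Actions are discrete heading increments at fixed step length.

#' Environment configuration
#'
#' @param t2 curvature-averaging window in steps.
#' @param t_live maximum consecutive free (off-edge) steps before death
#'   (death is strict: `t_free > t_live`).
#' @param t_cont proximity reward horizon in steps.
#' @param collision_radius CW/CCW collision distance (px).
#' @param closure_radius departure-neighborhood radius for closure (px).
#' @param step_length step length per action (px).
#' @param edge_snap_tol distance within which an agent counts as on-edge
#'   (px); 1.5 covers 1-px rasterized edges with diagonal moves.
#' @param r receptive-field size (px, square window).
#' @param action_increments_deg discrete heading increments (degrees).
#' @param aggregation_radius neighbor radius for message passing (px).
#' @return An `env_config` list.
#' @export
env_config <- function(t2 = 21L, t_live = 30L, t_cont = 12L,
                       collision_radius = 2, closure_radius = 3,
                       step_length = 1, edge_snap_tol = 1.5, r = 24L,
                       action_increments_deg = c(-45, -22.5, 0, 22.5, 45),
                       aggregation_radius = 4 * 2) {
  stopifnot(t2 > 0, t_live > 0, t_cont > 0, collision_radius > 0,
            closure_radius > 0, step_length > 0, edge_snap_tol > 0, r > 0)
  structure(list(t2 = as.integer(t2), t_live = as.integer(t_live),
                 t_cont = as.integer(t_cont),
                 collision_radius = collision_radius,
                 closure_radius = closure_radius, step_length = step_length,
                 edge_snap_tol = edge_snap_tol, r = as.integer(r),
                 action_increments_deg = action_increments_deg,
                 aggregation_radius = aggregation_radius),
            class = "env_config")
}

#' Windowed average absolute curvature of a path
#'
#' Discrete curvature at each interior vertex by the circumscribed-circle
#' (Menger) formula; the mean of absolute curvature over the last `t2`
#' samples (or all available when fewer exist). Paths with fewer than 3
#' points have zero curvature.
#'
#' @param path n x 2 matrix of positions.
#' @param t2 window length in steps.
#' @return Scalar `s_iC >= 0` (1/px).
#' @export
average_curvature <- function(path, t2) {
  k <- menger_curvature(path)
  if (length(k) == 0) return(0)
  mean(utils::tail(k, t2))
}

#' Spawn agents on the offset field
#'
#' Agents are placed at equal arc-length intervals along the level-0
#' trajectory (the boundary estimate the agents are meant to trace; the
#' other levels serve as guidance structure), with alternating CCW/CW
#' traversal senses and headings set to the local offset tangent.
#'
#' @param field an `offset_field`.
#' @param n_agents even count >= 2.
#' @param seed integer seed (spawning is deterministic; the seed tags the
#'   episode).
#' @param cfg an [env_config()].
#' @return List of agent-state lists (`position`, `heading`, `sense`,
#'   `mode`, `t_free`, `departure`, `path`, `alive`, ...).
#' @export
spawn_agents <- function(field, n_agents, seed = 1L, cfg = env_config()) {
  if (n_agents < 2) stop("need at least 2 agents")
  if (n_agents %% 2 != 0) stop("n_agents must be even (CW/CCW pairs)")
  lvl0 <- which.min(vapply(field$trajectories, function(t) abs(t$level), 0))
  tr <- field$trajectories[[lvl0]]
  ns <- nrow(tr$samples)
  agents <- vector("list", n_agents)
  for (j in seq_len(n_agents)) {
    idx <- floor((j - 1) / n_agents * ns) + 1L
    sense <- if (j %% 2 == 1) "CCW" else "CW"
    heading <- tr$tangents[idx, ]
    if (sense == "CW") heading <- -heading
    pos <- tr$samples[idx, ]
    agents[[j]] <- list(id = j, position = pos, heading = heading,
                        sense = sense, mode = "free", t_free = 0L,
                        departure = pos, path = matrix(pos, 1),
                        on_edge = FALSE,           # per-vertex edge-contact flags
                        winding = 0,               # cumulative angle around the region
                        alive = TRUE, closed = FALSE, traveled = 0,
                        closure_fired = FALSE, reward_prev = 0,
                        s_iC = 0, d_i = 0, seed = seed)
  }
  agents
}

# Exact distance from a continuous position to the nearest edge pixel in a
# small neighborhood; Inf when none is close.
local_edge_distance <- function(edge, pos, tol) {
  nr <- nrow(edge); nc <- ncol(edge)
  cx <- round(pos[1]); cy <- round(pos[2])
  rad <- ceiling(tol) + 1L
  x0 <- max(0, cx - rad); x1 <- min(nc - 1, cx + rad)
  y0 <- max(0, cy - rad); y1 <- min(nr - 1, cy + rad)
  if (x0 > x1 || y0 > y1) return(Inf)
  sub <- edge[(y0:y1) + 1, (x0:x1) + 1, drop = FALSE]
  hit <- which(sub == 1L, arr.ind = TRUE)
  if (nrow(hit) == 0) return(Inf)
  ex <- x0 + hit[, 2] - 1; ey <- y0 + hit[, 1] - 1
  min(sqrt((ex - pos[1])^2 + (ey - pos[2])^2))
}

# Edge-pixel fraction of the r x r window centered at the (rounded)
# position, zero-padded at borders.
local_edge_density <- function(edge, pos, r) {
  nr <- nrow(edge); nc <- ncol(edge)
  half <- r %/% 2
  cx <- round(pos[1]); cy <- round(pos[2])
  x0 <- cx - half; y0 <- cy - half
  xs <- (x0:(x0 + r - 1)); ys <- (y0:(y0 + r - 1))
  vx <- xs >= 0 & xs <= nc - 1; vy <- ys >= 0 & ys <= nr - 1
  if (!any(vx) || !any(vy)) return(0)
  sum(edge[ys[vy] + 1, xs[vx] + 1]) / (r * r)
}

# r x r crop of a matrix centered at the rounded position, zero-padded.
crop_window <- function(mat, pos, r) {
  out <- matrix(0, r, r)
  nr <- nrow(mat); nc <- ncol(mat)
  half <- r %/% 2
  cx <- round(pos[1]); cy <- round(pos[2])
  xs <- (cx - half):(cx - half + r - 1)
  ys <- (cy - half):(cy - half + r - 1)
  vx <- which(xs >= 0 & xs <= nc - 1); vy <- which(ys >= 0 & ys <= nr - 1)
  if (length(vx) == 0 || length(vy) == 0) return(out)
  out[vy, vx] <- mat[ys[vy] + 1, xs[vx] + 1]
  out
}

# Local direction of motion from the last up-to-5 path points (principal
# axis of the centered points, sign-aligned with the displacement).
path_direction <- function(path) {
  n <- nrow(path)
  pts <- path[max(1, n - 4):n, , drop = FALSE]
  if (nrow(pts) < 2) return(c(1, 0))
  disp <- pts[nrow(pts), ] - pts[1, ]
  ctr <- sweep(pts, 2, colMeans(pts))
  cv <- crossprod(ctr)
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (sum(ev * disp) < 0) ev <- -ev
  if (sum(abs(disp)) < 1e-12) ev <- c(1, 0)
  ev / sqrt(sum(ev^2))
}

#' Detect CW/CCW collisions among agents
#'
#' Events are reported for pairs of opposite traversal sense whose positions
#' lie within `collision_radius`, at most once per pair per episode. The
#' interior meeting angle `theta` (degrees, `[0, 180]`) is the angle between
#' the two agents' local directions of motion (180 for a head-on meeting).
#'
#' @param agents list of agent states (see [spawn_agents()]).
#' @param collision_radius distance threshold (px).
#' @param seen_pairs optional 2-column matrix of already-reported pairs.
#' @return List of events `list(agents = c(i, k), point, theta_ik)`.
#' @export
detect_collisions <- function(agents, collision_radius, seen_pairs = NULL) {
  act <- which(vapply(agents, function(a) isTRUE(a$alive) && !isTRUE(a$closed), TRUE))
  events <- list()
  if (length(act) < 2) return(events)
  for (ii in seq_along(act)[-length(act)]) {
    for (kk in (ii + 1):length(act)) {
      i <- act[ii]; k <- act[kk]
      if (agents[[i]]$sense == agents[[k]]$sense) next
      if (!is.null(seen_pairs) && nrow(seen_pairs) > 0 &&
          any(seen_pairs[, 1] == min(i, k) & seen_pairs[, 2] == max(i, k))) next
      d <- sqrt(sum((agents[[i]]$position - agents[[k]]$position)^2))
      if (d > collision_radius) next
      u <- path_direction(agents[[i]]$path)
      v <- path_direction(agents[[k]]$path)
      theta <- angle_between(u, v)
      events[[length(events) + 1]] <-
        list(agents = c(i, k),
             point = (agents[[i]]$position + agents[[k]]$position) / 2,
             theta_ik = theta)
    }
  }
  events
}

#' Create a segmentation environment
#'
#' Binds an image, its edge map and an offset field into a steppable
#' multi-agent world exposing the batch interface consumed by
#' [ppo_train()]: `reset(seed)`, `active()`, `observe_batch()`,
#' `step(actions)`.
#'
#' @param image grayscale matrix in 0..255.
#' @param edge_map binary matrix (an `edge_map` object's `edges` or a plain
#'   matrix).
#' @param field an `offset_field`.
#' @param n_agents even agent count.
#' @param cfg an [env_config()].
#' @param reward_cfg a [reward_config()].
#' @param max_steps episode step cap (default 4 x level-0 arc length /
#'   step_length, matching boundary-proportional runtime).
#' @return A `seg_env` environment object.
#' @export
seg_env <- function(image, edge_map, field, n_agents = 16L,
                    cfg = env_config(), reward_cfg = reward_config(),
                    max_steps = NULL) {
  if (inherits(edge_map, "edge_map")) edge_map <- edge_map$edges
  e <- new.env(parent = emptyenv())
  e$gray <- image / 255
  e$edge <- edge_map
  e$field <- field
  e$cfg <- cfg
  e$reward_cfg <- reward_cfg
  e$n_agents <- as.integer(n_agents)
  lvl0 <- which.min(vapply(field$trajectories, function(t) abs(t$level), 0))
  L0 <- field$trajectories[[lvl0]]$arc_length
  e$max_steps <- if (is.null(max_steps)) ceiling(4 * L0 / cfg$step_length) else max_steps
  e$r <- cfg$r
  e$in_channels <- 9L
  e$obs_dim <- 6L
  e$extra_dim <- 6L + 12L * 6L + 1L      # obs + aggregated features + prev reward
  e$deg_avg <- 1
  e$centroid <- colMeans(field$trajectories[[lvl0]]$samples)
  class(e) <- c("seg_env", "environment")
  seg_env_reset(e, seed = 1L)
  e
}

#' Reset a segmentation environment
#' @param e a `seg_env`.
#' @param seed episode seed (controls stochastic policy sampling downstream;
#'   spawning itself is deterministic).
#' @export
seg_env_reset <- function(e, seed = 1L) {
  e$agents <- spawn_agents(e$field, e$n_agents, seed = seed, cfg = e$cfg)
  e$frames <- array(0, c(e$n_agents, e$r, e$r, 9L))
  e$seen_pairs <- matrix(integer(0), 0, 2)
  e$collisions <- list()
  e$step_count <- 0L
  # spawn-time average neighborhood size initializes the degree scaler
  # (floored at 1: an empty spawn neighborhood must not blow up the
  # log-degree amplification); a running average is maintained per step
  pos <- t(vapply(e$agents, `[[`, numeric(2), "position"))
  degs <- vapply(seq_len(e$n_agents), function(i)
    length(neighbors(pos, i, e$cfg$aggregation_radius)), 0L)
  e$deg_avg <- max(mean(degs), 1)
  invisible(e)
}

#' Which agents are still acting?
#' @param e a `seg_env`.
#' @return Logical vector: alive, not yet closed, step cap not reached.
#' @export
seg_env_active <- function(e) {
  if (e$step_count >= e$max_steps) return(rep(FALSE, e$n_agents))
  vapply(e$agents, function(a) a$alive && !a$closed, TRUE)
}

# Observation vector of agent i (egocentric): on-edge flag, offset tangent
# rotated into the agent's heading frame, windowed average curvature,
# normalized free time, local edge density.
agent_obs_vector <- function(e, i) {
  a <- e$agents[[i]]
  tg <- tangent_at_nearest(e$field, a$position, sense = a$sense)$tangent
  hd <- a$heading
  # rotate world tangent into heading frame: R(-phi) v, phi = atan2(hd)
  vx <- hd[1] * tg[1] + hd[2] * tg[2]
  vy <- -hd[2] * tg[1] + hd[1] * tg[2]
  c(as.numeric(a$mode == "edge"), vx, vy, a$s_iC,
    a$t_free / e$cfg$t_live, a$d_i)
}

#' Observe all active agents (batched)
#'
#' Updates each active agent's three-frame memory stack and returns the
#' network inputs: frames array, extra vector (observation, aggregated
#' neighbor features, previous reward) and the active indices.
#'
#' @param e a `seg_env`.
#' @return `list(frames = [B, r, r, 9], extra = [B, extra_dim], idx)`.
#' @export
seg_env_observe <- function(e) {
  act <- which(seg_env_active(e))
  B <- length(act)
  if (B == 0) return(list(frames = NULL, extra = NULL, idx = integer(0)))
  occ <- matrix(0, nrow(e$edge), ncol(e$edge))
  for (a in e$agents) if (a$alive && !a$closed) {
    x <- round(a$position[1]); y <- round(a$position[2])
    if (x >= 0 && y >= 0 && x < ncol(occ) && y < nrow(occ)) occ[y + 1, x + 1] <- 1
  }
  obs_mat <- matrix(0, e$n_agents, e$obs_dim)
  for (i in act) obs_mat[i, ] <- agent_obs_vector(e, i)
  pos <- t(vapply(e$agents, `[[`, numeric(2), "position"))
  alive <- vapply(e$agents, function(a) a$alive && !a$closed, TRUE)
  degs_now <- vapply(act, function(i)
    length(neighbors(pos, i, e$cfg$aggregation_radius, alive)), 0L)
  e$deg_avg <- max(0.95 * e$deg_avg + 0.05 * mean(degs_now), 1)
  frames <- array(0, c(B, e$r, e$r, 9L))
  extra <- matrix(0, B, e$extra_dim)
  for (b in seq_len(B)) {
    i <- act[b]
    a <- e$agents[[i]]
    st <- e$frames[i, , , ]
    st[, , 1:6] <- st[, , 4:9]
    st[, , 7] <- crop_window(e$edge, a$position, e$r)
    st[, , 8] <- crop_window(e$gray, a$position, e$r)
    st[, , 9] <- crop_window(occ, a$position, e$r)
    e$frames[i, , , ] <- st
    frames[b, , , ] <- st
    nb <- neighbors(pos, i, e$cfg$aggregation_radius, alive)
    agg <- aggregate_features(obs_mat[i, ],
                              if (length(nb)) obs_mat[nb, , drop = FALSE] else NULL,
                              deg_avg = e$deg_avg)
    extra[b, ] <- c(obs_mat[i, ], agg$features, a$reward_prev)
  }
  list(frames = frames, extra = extra, idx = act)
}

#' Advance one agent by one action (single-agent transition)
#'
#' Rotates the heading by the selected increment, advances `step_length`
#' pixels, updates mode/free-time/path and applies the death rule. Exposed
#' for tests and replay; [seg_env_step()] applies it to all active agents
#' and adds collisions and rewards.
#'
#' @param e a `seg_env`.
#' @param i agent index.
#' @param action integer in `1..length(action_increments_deg)`.
#' @return The updated agent state (invisibly).
#' @export
seg_env_step_agent <- function(e, i, action) {
  a <- e$agents[[i]]
  stopifnot(a$alive, !a$closed)
  inc <- e$cfg$action_increments_deg[action] * pi / 180
  a$heading <- as.numeric(rotate2(a$heading, inc))
  a$heading <- a$heading / sqrt(sum(a$heading^2))
  a$position <- a$position + e$cfg$step_length * a$heading
  nr <- nrow(e$edge); nc <- ncol(e$edge)
  if (a$position[1] < 0 || a$position[1] > nc - 1 ||
      a$position[2] < 0 || a$position[2] > nr - 1) {
    a$position <- pmin(pmax(a$position, 0), c(nc - 1, nr - 1))
    a$alive <- FALSE
  }
  prev <- a$path[nrow(a$path), ]
  a$path <- rbind(a$path, a$position)
  a$traveled <- a$traveled + e$cfg$step_length
  # winding of the position around the lesion centroid, accumulated so the
  # closure reward can demand a genuine loop rather than a tight pirouette
  d_ang <- atan2(a$position[2] - e$centroid[2], a$position[1] - e$centroid[1]) -
    atan2(prev[2] - e$centroid[2], prev[1] - e$centroid[1])
  if (d_ang > pi) d_ang <- d_ang - 2 * pi
  if (d_ang < -pi) d_ang <- d_ang + 2 * pi
  a$winding <- a$winding + d_ang
  d_edge <- local_edge_distance(e$edge, a$position, e$cfg$edge_snap_tol)
  if (d_edge <= e$cfg$edge_snap_tol) {
    a$mode <- "edge"; a$t_free <- 0L
  } else {
    a$mode <- "free"; a$t_free <- a$t_free + 1L
    if (a$t_free > e$cfg$t_live) a$alive <- FALSE
  }
  a$on_edge <- c(a$on_edge, a$mode == "edge")
  a$s_iC <- average_curvature(a$path, e$cfg$t2)
  a$d_i <- local_edge_density(e$edge, a$position, e$cfg$r)
  e$agents[[i]] <- a
  invisible(a)
}

#' Step all active agents and score rewards
#'
#' Applies [seg_env_step_agent()] to every active agent, detects new CW/CCW
#' collisions, evaluates the five Gestalt reward components and their
#' weighted total, and returns rewards and done flags aligned with the
#' active indices.
#'
#' @param e a `seg_env`.
#' @param actions integer vector aligned with `which(seg_env_active(e))`.
#' @return `list(rewards, done, idx, breakdowns)`.
#' @export
seg_env_step <- function(e, actions) {
  act <- which(seg_env_active(e))
  stopifnot(length(actions) == length(act))
  for (b in seq_along(act)) seg_env_step_agent(e, act[b], actions[b])
  e$step_count <- e$step_count + 1L
  ev <- detect_collisions(e$agents, e$cfg$collision_radius, e$seen_pairs)
  collided <- rep(0, e$n_agents)
  for (x in ev) {
    e$seen_pairs <- rbind(e$seen_pairs, sort(x$agents))
    e$collisions[[length(e$collisions) + 1]] <- x
    r2 <- continuity2(x$theta_ik, e$reward_cfg)
    collided[x$agents] <- pmax(collided[x$agents], r2)
  }
  rewards <- numeric(length(act))
  breakdowns <- vector("list", length(act))
  for (b in seq_along(act)) {
    i <- act[b]
    a <- e$agents[[i]]
    # a closing agent must have wound most of the way around the lesion;
    # without this, tight pirouettes near the departure point would count
    r_cl <- if (abs(a$winding) >= 1.7 * pi)
      closure_reward(a$position, a$departure, e$reward_cfg,
                     a$traveled, a$closure_fired) else 0
    if (r_cl > 0) {
      a$closure_fired <- TRUE
      a$closed <- TRUE                 # a closed agent has finished its job
      e$agents[[i]] <- a
    }
    bd <- list(r_cont1 = continuity1(a$s_iC, e$reward_cfg),
               r_cont2 = collided[i],
               r_prox = proximity(a$t_free, e$reward_cfg),
               r_closure = r_cl,
               r_density = density(a$d_i, e$reward_cfg))
    rewards[b] <- total_reward(bd, e$reward_cfg)
    breakdowns[[b]] <- bd
    a <- e$agents[[i]]
    a$reward_prev <- rewards[b]
    e$agents[[i]] <- a
  }
  done <- !seg_env_active(e)[act]
  list(rewards = rewards, done = done, idx = act, breakdowns = breakdowns)
}

#' Serialize an episode trace to JSON lines
#'
#' One line per agent with its path, sense and terminal flags; intended for
#' debugging and replay.
#' @param e a `seg_env` after an episode.
#' @param path output file.
#' @export
write_episode_jsonl <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in e$agents) {
    writeLines(jsonlite::toJSON(list(id = a$id, sense = a$sense,
                                     alive = a$alive, closed = a$closed,
                                     path = unname(a$path)),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
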