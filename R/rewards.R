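# Gestalt-law reward system. Each component is an indicator increment
# (0 or delta_r per step); the per-step reward is their weighted sum. The
# shipped default weights are the trained values (continuity-by-curvature
# 0.31, continuity-by-collision 0.23, proximity 0.15, density 0.19, closure
# 0.12), which sum to 1 and put 54% of a fully rewarded step on continuity.

#' Reward-system configuration
#'
#' @param w_c1,w_c2,w_pr,w_d,w_cl nonnegative component weights (continuity
#'   by curvature, continuity by collision angle, proximity, density,
#'   closure).
#' @param delta_r reward increment per satisfied criterion (only ratios
#'   matter under advantage normalization).
#' @param s_prime curvature threshold s' (1/px): continuity-1 fires when the
#'   windowed average |curvature| is at most s'.
#' @param theta_min minimum collision angle in degrees; continuity-2 fires
#'   for angles in `[theta_min, 180]`.
#' @param d_prime edge-density threshold; density fires when the receptive
#'   window's edge fraction strictly exceeds d'.
#' @param t_cont proximity horizon in steps; proximity fires while the time
#'   since last edge contact is at most t_cont.
#' @param closure_radius radius (px) of the departure neighborhood whose
#'   re-entry fires the closure reward (once per episode).
#' @return A `reward_config` list.
#' @export
reward_config <- function(w_c1 = 0.31, w_c2 = 0.23, w_pr = 0.15, w_d = 0.19,
                          w_cl = 0.12, delta_r = 1.0, s_prime = 0.15,
                          theta_min = 118, d_prime = 0.1, t_cont = 12L,
                          closure_radius = 3) {
  w <- c(w_c1, w_c2, w_pr, w_d, w_cl)
  if (any(w < 0)) stop("weights must be nonnegative")
  structure(list(w_c1 = w_c1, w_c2 = w_c2, w_pr = w_pr, w_d = w_d, w_cl = w_cl,
                 delta_r = delta_r, s_prime = s_prime, theta_min = theta_min,
                 d_prime = d_prime, t_cont = as.integer(t_cont),
                 closure_radius = closure_radius),
            class = "reward_config")
}

#' Continuity reward from trajectory curvature
#'
#' `delta_r` when the windowed average absolute curvature is at most
#' `s_prime` (inclusive), else 0.
#' @param s_iC average absolute curvature (1/px), nonnegative.
#' @param cfg a [reward_config()].
#' @export
continuity1 <- function(s_iC, cfg) {
  stopifnot(s_iC >= 0)
  ifelse(s_iC <= cfg$s_prime, cfg$delta_r, 0)
}

#' Continuity reward from a collision angle
#'
#' `delta_r` when the interior angle between the two colliding trajectories
#' lies in `[theta_min, 180]` degrees (both ends inclusive), else 0.
#' @param theta_ik angle in degrees, in `[0, 180]`.
#' @param cfg a [reward_config()].
#' @export
continuity2 <- function(theta_ik, cfg) {
  stopifnot(theta_ik >= 0, theta_ik <= 180)
  ifelse(theta_ik >= cfg$theta_min & theta_ik <= 180, cfg$delta_r, 0)
}

#' Proximity reward
#'
#' `delta_r` while the time since last edge contact is at most `t_cont`
#' (inclusive), else 0.
#' @param t_free steps since last on-edge contact (0 while on edge).
#' @param cfg a [reward_config()].
#' @export
proximity <- function(t_free, cfg) {
  stopifnot(t_free >= 0)
  ifelse(t_free <= cfg$t_cont, cfg$delta_r, 0)
}

#' Closure reward
#'
#' `delta_r` when the agent re-enters the `closure_radius` neighborhood of
#' its departure point, provided it has traveled at least
#' `4 * closure_radius` (guards against instant self-closure) and the reward
#' has not fired before in the episode.
#'
#' @param position,departure length-2 numeric (x, y).
#' @param cfg a [reward_config()].
#' @param traveled path length so far (px).
#' @param already_fired has closure fired this episode?
#' @export
closure_reward <- function(position, departure, cfg, traveled,
                           already_fired = FALSE) {
  if (already_fired || traveled < 4 * cfg$closure_radius) return(0)
  if (sqrt(sum((position - departure)^2)) <= cfg$closure_radius) cfg$delta_r else 0
}

#' Density reward
#'
#' `delta_r` when the local edge density strictly exceeds `d_prime`, else 0.
#' @param d_i edge-pixel fraction of the receptive window, in `[0, 1]`.
#' @param cfg a [reward_config()].
#' @export
density <- function(d_i, cfg) {
  stopifnot(d_i >= -1e-12, d_i <= 1 + 1e-12)
  ifelse(d_i > cfg$d_prime, cfg$delta_r, 0)
}

#' Combine reward components into the per-step scalar
#'
#' The exact weighted sum
#' `w_c1 r_cont1 + w_c2 r_cont2 + w_pr r_prox + w_d r_density + w_cl r_closure`.
#'
#' @param breakdown named list/vector with elements `r_cont1`, `r_cont2`,
#'   `r_prox`, `r_closure`, `r_density`.
#' @param cfg a [reward_config()].
#' @return The scalar total.
#' @export
total_reward <- function(breakdown, cfg) {
  b <- as.list(breakdown)
  cfg$w_c1 * b$r_cont1 + cfg$w_c2 * b$r_cont2 + cfg$w_pr * b$r_prox +
    cfg$w_d * b$r_density + cfg$w_cl * b$r_closure
}
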