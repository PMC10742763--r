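# End-to-end orchestration: run a trained policy on an image (or phantom),
# collect candidate boundary trajectories, assemble them into one closed
# contour, and report quality metrics against ground truth when available.

#' Run one policy-driven episode on an image or phantom
#'
#' Pipeline: attention mask -> offset field -> spawn -> policy-driven
#' stepping until every agent is dead/closed or the step cap (4 x boundary
#' length / step length) is reached. Candidates are the paths of agents that
#' either closed their loop or participated in a CW/CCW collision.
#'
#' @param input a `phantom` (synthetic edge map used directly) or a list
#'   `list(image, edge_map)`; edge maps may be `edge_map` objects.
#' @param policy trained policy `net_params`.
#' @param env_cfg,reward_cfg configurations (must match training).
#' @param n_agents even agent count.
#' @param seed episode seed.
#' @param deterministic take argmax actions (default) or sample.
#' @param mask_from `"image"` (attention mask, default) or `"gt"` (phantom
#'   ground truth; for diagnostics).
#' @return `list(candidates, collisions, env, field)`; candidates carry
#'   `path`, `reward`, `closed`.
#' @export
run_episode <- function(input, policy, env_cfg = env_config(),
                        reward_cfg = reward_config(), n_agents = 16L,
                        seed = 1L, deterministic = TRUE,
                        mask_from = c("image", "gt")) {
  mask_from <- match.arg(mask_from)
  if (inherits(input, "phantom")) {
    image <- input$image
    edges <- input$edge_map
  } else {
    image <- input$image
    edges <- if (!is.null(input$edge_map)) input$edge_map else detect_edges(image)
  }
  if (inherits(edges, "edge_map")) edges <- edges$edges
  contour <- if (mask_from == "gt" && inherits(input, "phantom")) {
    input$gt_contour
  } else {
    am <- attention_mask(image)       # errors propagate ("no candidate lesion")
    align_contour_to_edges(am$contour, edges)
  }
  field <- generate_offsets(contour)
  env <- seg_env(image, edges, field, n_agents = n_agents, cfg = env_cfg,
                 reward_cfg = reward_cfg)
  seg_env_reset(env, seed = seed)
  set.seed(mix_seed(seed, 17L))
  total_reward_acc <- numeric(n_agents)
  while (TRUE) {
    ob <- seg_env_observe(env)
    if (length(ob$idx) == 0) break
    fw <- net_forward(policy, ob$frames, ob$extra)
    acts <- if (deterministic) max.col(fw$probs, ties.method = "first")
            else sample_actions(fw$probs)
    st <- seg_env_step(env, acts)
    total_reward_acc[st$idx] <- total_reward_acc[st$idx] + st$rewards
  }
  in_collision <- rep(FALSE, n_agents)
  for (x in env$collisions) in_collision[x$agents] <- TRUE
  cand_idx <- which(vapply(env$agents, function(a) a$closure_fired, TRUE) | in_collision)
  candidates <- list()
  for (i in cand_idx) {
    a <- env$agents[[i]]
    if (!any(a$on_edge)) next
    # keep the boundary-tracing span (first to last edge contact), then
    # split at off-edge excursions longer than the proximity horizon: short
    # free runs are legitimate gap bridges, long ones are lost wandering
    span <- range(which(a$on_edge))
    idxs <- span[1]:span[2]
    on <- a$on_edge[idxs]
    r <- rle(on)
    ends <- cumsum(r$lengths)
    brk <- ends[!r$values & r$lengths > env$cfg$t_cont + 2]
    piece_id <- findInterval(seq_along(on) - 0.5, brk) + 1
    for (p in unique(piece_id)) {
      sel <- which(piece_id == p)
      subon <- on[sel]
      if (!any(subon)) next
      sp2 <- range(which(subon))          # this piece's edge-contact span
      sub <- a$path[idxs[sel[sp2[1]:sp2[2]]], , drop = FALSE]
      if (nrow(sub) < 8) next
      candidates[[length(candidates) + 1]] <-
        list(id = i, path = sub,
             reward = total_reward_acc[i] * nrow(sub) / nrow(a$path),
             closed = a$closure_fired)
    }
  }
  if (length(candidates) == 0)
    warning("episode produced no candidate trajectories")
  list(candidates = candidates, collisions = env$collisions, env = env,
       field = field)
}

# Link candidate paths into connected components: two candidates are linked
# when a collision event joins them or when any pair of their endpoints lies
# within the closure radius.
candidate_components <- function(candidates, collisions, closure_radius) {
  n <- length(candidates)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  ids <- vapply(candidates, `[[`, 0, "id")
  for (x in collisions) {
    i <- match(x$agents[1], ids); j <- match(x$agents[2], ids)
    if (!is.na(i) && !is.na(j)) union2(i, j)
  }
  endpoints <- lapply(candidates, function(cd)
    rbind(cd$path[1, ], cd$path[nrow(cd$path), ]))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      # link when an endpoint of one path comes within the closure radius of
      # any point of the other (paths riding the same guide overlap midway)
      d <- min(min_dist_to_set(endpoints[[i]], candidates[[j]]$path),
               min_dist_to_set(endpoints[[j]], candidates[[i]]$path))
      if (d <= closure_radius) union2(i, j)
    }
  }
  split(seq_len(n), vapply(seq_len(n), find, 0L))
}

#' Assemble candidate trajectories into the final closed contour
#'
#' Candidates are grouped into chains through collision/endpoint links; each
#' chain's points are ordered angularly around their centroid (the lesion
#' family is star-shaped), fitted with a periodic cubic spline and
#' rasterized. Among chains, the one with the highest accumulated weighted
#' reward per unit length wins; ties break deterministically by chain length
#' then lowest agent index. If the winning contour fails the
#' self-intersection simplicity check, or no multi-path chain closes, the
#' single highest-reward candidate is closed by spline interpolation across
#' its endpoint gap and flagged `low_confidence`.
#'
#' @param candidates,collisions from [run_episode()].
#' @param cfg an [env_config()] (closure radius).
#' @param dim_im image dimensions `c(nrow, ncol)` for rasterization.
#' @return A `segmentation_result`: `contour`, `mask`,
#'   `candidate_trajectories`, `low_confidence` flag.
#' @export
assemble_contour <- function(candidates, collisions, cfg, dim_im) {
  if (length(candidates) == 0) stop("no candidate trajectories to assemble")
  comps <- candidate_components(candidates, collisions, cfg$closure_radius)
  stats_of <- function(comp) {
    pts <- do.call(rbind, lapply(candidates[comp], `[[`, "path"))
    ctr <- colMeans(pts)
    rad <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
    bins <- length(unique(floor((ang + pi) / (2 * pi) * 32)))
    rew <- sum(vapply(candidates[comp], `[[`, 0, "reward"))
    list(pts = pts, bins = bins, rad_ok = mean(rad) >= 0.1 * min(dim_im),
         n = nrow(pts), score = rew / nrow(pts),
         member_closed = any(vapply(candidates[comp], `[[`, TRUE, "closed")),
         id0 = min(vapply(candidates[comp], `[[`, 0, "id")))
  }
  cs <- lapply(comps, stats_of)
  cs <- Filter(function(x) x$n >= 8, cs)
  pick_best <- function(lst) {
    best <- NULL
    for (x in lst) {
      if (is.null(best) ||
          x$score > best$score + 1e-12 ||
          (abs(x$score - best$score) <= 1e-12 &&
           (x$n > best$n || (x$n == best$n && x$id0 < best$id0))))
        best <- x
    }
    best
  }
  # a chain counts as closed when a member self-closed or its points cover
  # (nearly) the full angular range around their centroid at lesion-like
  # spatial extent (a tight cluster around a false edge covers all angles
  # trivially but has no radius)
  closed_set <- Filter(function(x) x$rad_ok && (x$member_closed || x$bins >= 29), cs)
  low_confidence <- FALSE
  if (length(closed_set) > 0) {
    best <- pick_best(closed_set)$pts
  } else {
    # no closed chain: prefer the chain with the widest angular coverage
    # (the periodic spline bridges the remaining sector); a lone short arc
    # is the last resort
    partial <- Filter(function(x) x$rad_ok && x$bins >= 16, cs)
    low_confidence <- TRUE
    if (length(partial) > 0) {
      bb <- partial[[which.max(vapply(partial, `[[`, 0, "bins"))]]
      best <- bb$pts
    } else {
      ri <- which.max(vapply(candidates, `[[`, 0, "reward"))
      best <- candidates[[ri]]$path
    }
  }
  ctr <- colMeans(best)
  ang <- atan2(best[, 2] - ctr[2], best[, 1] - ctr[1])
  ord <- order(ang)
  poly <- best[ord, , drop = FALSE]
  # robust radial smoothing: overlapping arcs from several laps and agents
  # bunch at slightly different radii; a circular running median of r(theta)
  # rejects excursion outliers while preserving the star-shaped geometry
  if (nrow(poly) >= 24) {
    rr <- sqrt(rowSums(sweep(poly, 2, ctr)^2))
    aa <- ang[ord]
    w <- 4L
    n_p <- length(rr)
    rr_pad <- c(utils::tail(rr, w), rr, utils::head(rr, w))
    rr_med <- vapply(seq_len(n_p), function(i)
      stats::median(rr_pad[i:(i + 2 * w)]), 0)
    poly <- cbind(ctr[1] + rr_med * cos(aa), ctr[2] + rr_med * sin(aa))
  }
  # thin out near-duplicate angles to stabilize the spline
  poly <- resample_closed(poly, n_out = max(64L, min(512L, nrow(poly))))
  sp <- try(fit_periodic_spline(poly, n_out = 512L), silent = TRUE)
  contour <- if (inherits(sp, "try-error")) poly else sp$points
  if (nrow(self_intersections(contour)) > 0) {
    # fallback: convex-ish smoothing via heavier resampling
    contour <- resample_closed(poly, n_out = 128L)
    low_confidence <- TRUE
  }
  mask <- rasterize_polygon(contour, dim_im[1], dim_im[2])
  structure(list(contour = contour, mask = mask,
                 candidate_trajectories = lapply(candidates, `[[`, "path"),
                 low_confidence = low_confidence),
            class = "segmentation_result")
}

#' Segment an image end-to-end
#'
#' Full pipeline around [run_episode()] and [assemble_contour()]; when
#' ground truth is supplied a [metrics_report()] is attached.
#'
#' @param input phantom or `list(image, edge_map)`; see [run_episode()].
#' @param policy trained policy parameters (or a checkpoint path plus
#'   `spec`).
#' @param env_cfg,reward_cfg configurations.
#' @param n_agents,seed,deterministic episode controls.
#' @param gt optional `list(contour, mask)`; defaults to the phantom's
#'   ground truth when `input` is a phantom.
#' @param out_dir optional directory: writes contour JSON, mask PNG and
#'   report JSON.
#' @return `list(result, report, provenance)`.
#' @export
segment_image <- function(input, policy, env_cfg = env_config(),
                          reward_cfg = reward_config(), n_agents = 16L,
                          seed = 1L, deterministic = TRUE, gt = NULL,
                          out_dir = NULL) {
  ep <- run_episode(input, policy, env_cfg, reward_cfg,
                    n_agents = n_agents, seed = seed,
                    deterministic = deterministic)
  dim_im <- dim(if (inherits(input, "phantom")) input$image else input$image)
  res <- assemble_contour(ep$candidates, ep$collisions, env_cfg, dim_im)
  report <- NULL
  if (is.null(gt) && inherits(input, "phantom"))
    gt <- list(contour = input$gt_contour, mask = input$gt_mask)
  if (!is.null(gt))
    report <- metrics_report(res$contour, gt$contour, res$mask, gt$mask)
  prov <- list(seed = seed, n_agents = n_agents,
               spec_hash = attr(policy, "spec")$hash)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_contour_json(res$contour, file.path(out_dir, "contour.json"))
    write_image_png(res$mask * 255, file.path(out_dir, "mask.png"))
    if (!is.null(report))
      jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  list(result = res, report = report, provenance = prov)
}
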