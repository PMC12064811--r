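# Vectorized forward simulation of n_agents identical softmax agents on a
# task.  Agents do not learn: full-breadth planners use the condition's
# true jump success probability inside the tree (the value a learner
# converges around), pruning planners use 1; discounted variants apply the
# root discount from the true probability.  Returns a B x n_agents matrix
# of per-mini-block points.
simulate_agents_points <- function(task, variant, depth, n_agents,
                                   beta = 3, theta = 0, kappa = 0) {
  config <- task$config
  R <- task_rewards(task)
  B <- nrow(task$blocks)
  pruning <- variant %in% c("lpp", "dlpp")
  mv <- move_to(0:5)
  jt <- config$jump_map
  nb <- ring_neighbours(jt)
  cm <- config$action_costs[["move"]]
  cj <- config$action_costs[["jump"]]
  pts <- matrix(0, B, n_agents)
  for (b in seq_len(B)) {
    true_rho <- config$noise_levels[[task$blocks$noise[b]]]
    rho_plan <- if (pruning) 1 else true_rho
    gam <- switch(variant, fb = , lpp = 1,
                  dfb = , dlpp = discount_factor(true_rho, kappa))
    lv <- q_levels(R[, b, drop = FALSE], rho_plan, config, h_max = 3L)
    # p(jump | state, step) under this depth
    pj <- matrix(NA_real_, 6L, 3L)
    for (t in 1:3) {
      h <- min(depth, 4L - t)
      pj[, t] <- stats::plogis(beta * (gam * lv$q_jump[[h]][, 1L] -
                                         lv$q_move[[h]][, 1L]) /
                                 config$point_scale + theta)
    }
    s <- rep(task$blocks$start[b], n_agents)
    r <- R[, b]
    acc <- numeric(n_agents)
    for (t in 1:3) {
      jump <- stats::runif(n_agents) < pj[s + 1L, t]
      nxt <- integer(n_agents)
      nxt[!jump] <- mv[s[!jump] + 1L]
      if (any(jump)) {
        sj <- s[jump]
        u <- stats::runif(sum(jump))
        tgt <- jt[sj + 1L]
        nj <- ifelse(u < true_rho, tgt,
                     ifelse(u < true_rho + (1 - true_rho) / 2,
                            nb[sj + 1L, 1L], nb[sj + 1L, 2L]))
        nxt[jump] <- nj
      }
      acc <- acc + ifelse(jump, cj, cm) + r[nxt + 1L]
      s <- nxt
    }
    pts[b, ] <- acc
  }
  pts
}

# Per-agent total points over the analysis blocks of each condition.
agent_condition_totals <- function(task, pts) {
  an <- task$blocks$phase == "analysis"
  lo <- an & task$blocks$noise == "low"
  hi <- an & task$blocks$noise == "high"
  cbind(low = colSums(pts[lo, , drop = FALSE]),
        high = colSums(pts[hi, , drop = FALSE]),
        overall = colSums(pts[an, , drop = FALSE]))
}

#' Reference anchors of the relative performance scale
#'
#' Simulates the two cohorts of reference agents that anchor the relative
#' performance scale: random agents (full-breadth, depth 3, `beta = 0`,
#' `theta = 0`; the 0% anchor) and optimal agents (full-breadth, depth 3,
#' `beta = 3`, `theta = 0`; the 100% anchor), per noise condition and
#' overall (analysis mini-blocks).  Also returns the below-chance exclusion
#' threshold: the random agents' average session total (initial fuel plus
#' all mini-blocks, training included).
#'
#' @param task a [generate_task()] session.
#' @param n_agents number of reference agents per cohort (default 1000).
#' @param seed optional integer seed.
#' @return Object of class `sat_perf_scale`: list with `anchors` (data
#'   frame: condition, random_mean, optimal_mean), `threshold`, and
#'   `n_agents`.
#' @export
reference_points <- function(task, n_agents = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_agents >= 1L)
  pts_rand <- simulate_agents_points(task, "fb", 3L, n_agents, beta = 0)
  pts_opt <- simulate_agents_points(task, "fb", 3L, n_agents, beta = 3)
  tr <- agent_condition_totals(task, pts_rand)
  to <- agent_condition_totals(task, pts_opt)
  anchors <- data.frame(condition = colnames(tr),
                        random_mean = colMeans(tr),
                        optimal_mean = colMeans(to), row.names = NULL)
  structure(list(anchors = anchors,
                 threshold = task$config$initial_points +
                   mean(colSums(pts_rand)),
                 n_agents = n_agents),
            class = "sat_perf_scale")
}

#' @export
print.sat_perf_scale <- function(x, ...) {
  cat("Relative performance scale (", x$n_agents, "agents per anchor )\n")
  print(x$anchors)
  cat("below-chance exclusion threshold:", round(x$threshold, 1),
      "points\n")
  invisible(x)
}

#' Relative performance on the random--optimal scale
#'
#' `100 * (points - random_mean) / (optimal_mean - random_mean)`: 0% is the
#' random-agent anchor, 100% the optimal full-breadth depth-3 anchor.
#' Values above 100% are possible under favourable jump outcomes.
#'
#' @param points total points (vectorized) over the analysis mini-blocks of
#'   the chosen condition.
#' @param scale a [reference_points()] object.
#' @param condition `"low"`, `"high"` or `"overall"`.
#' @return Relative performance in percent.
#' @export
relative_performance <- function(points, scale,
                                 condition = c("overall", "low", "high")) {
  stopifnot(inherits(scale, "sat_perf_scale"))
  condition <- match.arg(condition)
  a <- scale$anchors[scale$anchors$condition == condition, ]
  if (a$optimal_mean <= a$random_mean)
    stop("degenerate scale: optimal anchor does not exceed random anchor")
  100 * (points - a$random_mean) / (a$optimal_mean - a$random_mean)
}

#' Strategy-efficiency sweep
#'
#' Simulates cohorts of greedy-softmax agents (`beta = 3`, `theta = 0`,
#' matching the optimal-anchor convention) for every strategy x depth cell
#' (four model variants x planning depths 1--3), computes their mean
#' relative performance per noise condition and overall, and the number of
#' decision-tree branches a depth-d planner of that strategy evaluates
#' (4^d full-breadth, 2^d pruned).
#'
#' @param task a [generate_task()] session.
#' @param n_agents agents per cell (default 1000).
#' @param kappa discount parameter of the discounted variants (default 3).
#' @param beta,theta softmax settings of the sweep agents.
#' @param scale optional precomputed [reference_points()]; computed from
#'   the task when missing.
#' @param seed optional integer seed.
#' @return Data frame with columns `strategy`, `depth`, `condition`,
#'   `rel_perf_mean`, `rel_perf_se`, `branches`.
#' @export
strategy_sweep <- function(task, n_agents = 1000L, kappa = 3, beta = 3,
                           theta = 0, scale = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scale)) scale <- reference_points(task, n_agents)
  rows <- list()
  for (v in sat_variants()) {
    for (d in 1:3) {
      pts <- simulate_agents_points(task, v, d, n_agents, beta = beta,
                                    theta = theta, kappa = kappa)
      tot <- agent_condition_totals(task, pts)
      for (cc in colnames(tot)) {
        rp <- relative_performance(tot[, cc], scale, cc)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = v, depth = d, condition = cc,
          rel_perf_mean = mean(rp),
          rel_perf_se = stats::sd(rp) / sqrt(n_agents),
          branches = branch_count(if (v %in% c("lpp", "dlpp")) 2L else 4L,
                                  d))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Number of decision-tree branches
#'
#' A planner that faces `outcomes_per_step` outcome branches per action
#' step and plans `depth` steps ahead evaluates
#' `outcomes_per_step ^ depth` branches: 4^3 = 64 for a full-breadth
#' three-step plan (one move outcome + three jump outcomes), 2^3 = 8 --
#' one-eighth of the effort -- after pruning the two low-probability jump
#' branches.
#'
#' @param outcomes_per_step outcome branches per step (>= 1).
#' @param depth planning depth (>= 0).
#' @return Integer branch count.
#' @export
branch_count <- function(outcomes_per_step, depth) {
  stopifnot(outcomes_per_step >= 1L, depth >= 0L)
  as.integer(outcomes_per_step^depth)
}

#' Condition imbalance of optimal planners
#'
#' Percentage by which optimal full-breadth depth-3 agents' mean total
#' points under low noise exceed their mean total under high noise, on the
#' analysis mini-blocks of a task session.
#'
#' @inheritParams reference_points
#' @param beta softmax temperature of the optimal agents (default 3).
#' @return Percent difference `100 * (low - high) / high`.
#' @export
condition_imbalance <- function(task, n_agents = 1000L, beta = 3,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- simulate_agents_points(task, "fb", 3L, n_agents, beta = beta)
  tot <- agent_condition_totals(task, pts)
  100 * (mean(tot[, "low"]) - mean(tot[, "high"])) / mean(tot[, "high"])
}
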