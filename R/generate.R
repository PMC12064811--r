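# Compose `total` into run lengths within [lo, hi]; always feasible for
# total = 70 with runs 3-6.
compose_runs <- function(total, lo = 3L, hi = 6L) {
  lens <- integer(0)
  rem <- total
  while (rem > 0L) {
    ok <- (lo:hi)[rem - lo:hi == 0L | rem - lo:hi >= lo]
    l <- if (length(ok) == 1L) ok else sample(ok, 1L)
    lens <- c(lens, l)
    rem <- rem - l
  }
  lens
}

#' Generate a session of mini-blocks
#'
#' Builds a full task session: 140 mini-blocks by default, with the noise
#' condition alternating in pseudo-random runs of 3--6 consecutive
#' mini-blocks so that each condition occurs exactly `n_per_condition`
#' times.  Constellations draw each of the six positions' planet kinds
#' uniformly from the five kinds; starting positions are uniform.  The
#' first `n_training` mini-blocks of each condition (in presentation order)
#' are flagged as training and excluded from analysis, leaving 120 analysis
#' blocks under the defaults.
#'
#' @param n_per_condition mini-blocks per noise condition (default 70).
#' @param n_training leading mini-blocks of each condition flagged as
#'   training (default 10).
#' @param run_range length-2 integer vector: admissible noise run lengths.
#' @param config task configuration.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `sat_task`: a list with `blocks` (data frame:
#'   `index`, `noise`, `phase`, `start`), `constellations` (n x 6 integer
#'   matrix of planet kinds 0--4) and `config`.
#' @examples
#' task <- generate_task(seed = 1)
#' table(task$blocks$noise, task$blocks$phase)
#' @export
generate_task <- function(n_per_condition = 70L, n_training = 10L,
                          run_range = c(3L, 6L), config = sat_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    runs_a <- compose_runs(n_per_condition, run_range[1], run_range[2])
    runs_b <- compose_runs(n_per_condition, run_range[1], run_range[2])
    if (abs(length(runs_a) - length(runs_b)) <= 1L) break
  }
  first <- if (length(runs_a) != length(runs_b)) {
    if (length(runs_a) > length(runs_b)) "a" else "b"
  } else sample(c("a", "b"), 1L)
  conds <- sample(c("low", "high"))  # random assignment of a/b to low/high
  names(conds) <- c("a", "b")
  order_ab <- character(length(runs_a) + length(runs_b))
  order_ab[seq(1L, length(order_ab), by = 2L)] <- first
  order_ab[order_ab == ""] <- setdiff(c("a", "b"), first)
  lens <- integer(0)
  ia <- ib <- 0L
  noise <- character(0)
  for (lab in order_ab) {
    if (lab == "a") {
      ia <- ia + 1L
      lens <- runs_a[ia]
    } else {
      ib <- ib + 1L
      lens <- runs_b[ib]
    }
    noise <- c(noise, rep(conds[[lab]], lens))
  }
  n <- length(noise)
  phase <- rep("analysis", n)
  for (cc in c("low", "high")) {
    idx <- which(noise == cc)
    phase[idx[seq_len(min(n_training, length(idx)))]] <- "training"
  }
  blocks <- data.frame(index = seq_len(n), noise = noise, phase = phase,
                       start = sample(0:5, n, replace = TRUE))
  constellations <- matrix(sample(0:4, 6L * n, replace = TRUE), nrow = n,
                           ncol = 6L)
  structure(list(blocks = blocks, constellations = constellations,
                 config = config),
            class = "sat_task")
}

#' @export
print.sat_task <- function(x, ...) {
  tb <- table(x$blocks$noise, x$blocks$phase)
  cat("Planning task session:", nrow(x$blocks), "mini-blocks\n")
  print(tb)
  invisible(x)
}

# Position-order reward matrix (6 x B) for a task.
task_rewards <- function(task) {
  t(matrix(task$config$planet_rewards[task$constellations + 1L],
           nrow = nrow(task$constellations)))
}

# Extract one block as a sat_miniblock.
task_miniblock <- function(task, b) {
  sat_miniblock(task_rewards(task)[, b], task$blocks$start[b],
                task$blocks$noise[b], index = task$blocks$index[b],
                phase = task$blocks$phase[b])
}

#' Simulate one participant on a task
#'
#' Forward-simulates the generative model: at each step the Q-values are
#' computed under the participant's model variant and planning depth, the
#' jump probability follows the softmax rule, the action is sampled, the
#' transition is sampled from the true task dynamics, and (for full-breadth
#' variants) the jump success belief is updated by the TD rule.  Beliefs
#' start at the true success probabilities and evolve in presentation order
#' across the whole session, training blocks included.
#'
#' @param task a [generate_task()] session.
#' @param variant model variant, see [variant_params()].
#' @param params named list/vector with the variant's free parameters.
#' @param depth planning depth policy: a single depth in 1--3, a length-3
#'   probability vector over depths (sampled independently per mini-block),
#'   or an integer vector with one depth per mini-block.
#' @param participant_id identifier recorded in the log.
#' @param seed optional integer seed.
#' @return A choice-log data frame (one row per action step) with columns
#'   `participant_id`, `mini_block`, `phase`, `noise`, `step`, `state`,
#'   `action`, `outcome`, `jump_success`, `reward`, `cum_points`, and an
#'   attribute `"depths"` giving the realized per-mini-block depth.
#' @export
simulate_participant <- function(task, variant, params, depth = 3L,
                                 participant_id = "sim01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  variant <- match.arg(variant, sat_variants())
  p <- check_params(params, variant)
  config <- task$config
  B <- nrow(task$blocks)
  depths <- if (length(depth) == 1L) {
    rep(as.integer(depth), B)
  } else if (length(depth) == B && all(depth %in% 1:3)) {
    as.integer(depth)
  } else if (length(depth) == 3L && abs(sum(depth) - 1) < 1e-9) {
    sample(1:3, B, replace = TRUE, prob = depth)
  } else stop("depth must be a scalar, a length-3 simplex, or one value per block")
  stopifnot(all(depths %in% 1:3))
  R <- task_rewards(task)
  belief <- config$noise_levels
  rows <- vector("list", B)
  cum <- config$initial_points
  for (b in seq_len(B)) {
    noise <- task$blocks$noise[b]
    true_rho <- config$noise_levels[[noise]]
    s <- task$blocks$start[b]
    rec <- data.frame(participant_id = participant_id,
                      mini_block = task$blocks$index[b],
                      phase = task$blocks$phase[b], noise = noise,
                      step = 1:3, state = NA_integer_,
                      action = NA_character_, outcome = NA_integer_,
                      jump_success = NA, reward = NA_real_,
                      cum_points = NA_real_)
    rho_plan0 <- if (variant %in% c("lpp", "dlpp")) 1 else NA
    for (t in 1:3) {
      rho_bel <- unname(belief[[noise]])
      rho_plan <- if (variant %in% c("lpp", "dlpp")) rho_plan0 else rho_bel
      qp <- q_values(s, t, depths[b], R[, b], rho = rho_plan,
                     config = config)
      gam <- root_gamma(variant, p, rho_bel, true_rho)
      pj <- choice_probability(qp / config$point_scale, p$beta, p$theta, gam)
      act <- if (stats::runif(1L) < pj) "jump" else "move"
      tr <- sample_transition(s, act, noise, config)
      rew <- config$action_costs[[act]] + reward_of(tr$next_pos, R[, b])
      cum <- cum + rew
      rec$state[t] <- s
      rec$action[t] <- act
      rec$outcome[t] <- tr$next_pos
      rec$jump_success[t] <- tr$success
      rec$reward[t] <- rew
      rec$cum_points[t] <- cum
      if (act == "jump" && variant %in% c("fb", "dfb"))
        belief[[noise]] <- td_update(rho_bel, as.numeric(tr$success), p$alpha)
      s <- tr$next_pos
    }
    rows[[b]] <- rec
  }
  log <- do.call(rbind, rows)
  rownames(log) <- NULL
  attr(log, "depths") <- depths
  log
}

#' Specification of a simulated cohort
#'
#' @param n_participants cohort size.
#' @param variant generating model variant.
#' @param param_ranges named list of length-2 numeric ranges; each
#'   participant's parameter is drawn uniformly from its range (a degenerate
#'   range fixes the value).  Must cover the variant's free parameters.
#' @param depth_dist length-3 probability vector over planning depths 1--3;
#'   each mini-block's depth is drawn independently from it.
#' @param seed master seed; per-participant sub-seeds are derived from it.
#' @return An object of class `sat_cohort_spec`.
#' @export
cohort_spec <- function(n_participants, variant,
                        param_ranges = list(alpha = c(0.1, 0.5),
                                            beta = c(0.5, 3),
                                            theta = c(-0.5, 0.5),
                                            kappa = c(0, 30)),
                        depth_dist = rep(1 / 3, 3), seed = 1L) {
  variant <- match.arg(variant, sat_variants())
  need <- variant_params(variant)
  if (!all(need %in% names(param_ranges)))
    stop("param_ranges must cover: ", paste(need, collapse = ", "))
  stopifnot(length(depth_dist) == 3L, all(depth_dist >= 0),
            abs(sum(depth_dist) - 1) < 1e-9)
  structure(list(n_participants = as.integer(n_participants),
                 variant = variant, param_ranges = param_ranges[need],
                 depth_dist = depth_dist, seed = as.integer(seed)),
            class = "sat_cohort_spec")
}

#' Generate a simulated cohort with known ground truth
#'
#' Draws participant-level parameters from the cohort specification,
#' simulates every participant on a shared task session, and returns the
#' choice logs together with the ground-truth parameter table and the
#' per-mini-block generating depths.
#'
#' @param spec a [cohort_spec()].
#' @param task optional shared [generate_task()] session; generated from the
#'   spec's seed when missing.
#' @param config task configuration (used only when `task` is generated).
#' @return List with `logs` (list of choice-log data frames), `truth`
#'   (data frame of sampled parameters per participant), `depths`
#'   (participants x mini-blocks matrix of generating depths) and `task`.
#' @export
generate_cohort <- function(spec, task = NULL, config = sat_config()) {
  stopifnot(inherits(spec, "sat_cohort_spec"))
  set.seed(spec$seed)
  if (is.null(task)) task <- generate_task(config = config)
  n <- spec$n_participants
  sub_seeds <- sample.int(.Machine$integer.max, n + 1L)
  pars <- lapply(spec$param_ranges, function(rg)
    stats::runif(n, rg[1], rg[2]))
  truth <- data.frame(participant_id = sprintf("sim%03d", seq_len(n)),
                      variant = spec$variant, as.data.frame(pars))
  logs <- vector("list", n)
  depths <- matrix(NA_integer_, n, nrow(task$blocks))
  for (i in seq_len(n)) {
    params <- lapply(pars, `[`, i)
    logs[[i]] <- simulate_participant(task, spec$variant, params,
                                      depth = spec$depth_dist,
                                      participant_id = truth$participant_id[i],
                                      seed = sub_seeds[i])
    depths[i, ] <- attr(logs[[i]], "depths")
  }
  names(logs) <- truth$participant_id
  list(logs = logs, truth = truth, depths = depths, task = task)
}
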