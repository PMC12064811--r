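# Ring geometry helpers (positions 0-5, clockwise).
move_to <- function(pos) (pos + 1L) %% 6L

ring_neighbours <- function(pos) cbind((pos - 1L) %% 6L, (pos + 1L) %% 6L)

#' Transition distribution of an action
#'
#' Probability distribution over the next position when executing `move` or
#' `jump` from `pos`.  `move` advances one position clockwise with
#' certainty.  `jump` reaches its target (given by the configuration's jump
#' map) with probability `rho`; the remaining mass is split equally between
#' the two ring neighbours of the target.
#'
#' @param pos current position (0--5).
#' @param action `"move"` or `"jump"`.
#' @param rho jump success probability in `[0, 1]`.
#' @param config task configuration, see [sat_config()].
#' @return Named numeric vector of length 6 (names `"0"`..`"5"`) summing
#'   to 1.
#' @examples
#' transition_distribution(0, "jump", rho = 0.9)
#' @export
transition_distribution <- function(pos, action, rho,
                                    config = sat_config()) {
  stopifnot(length(pos) == 1L, pos %in% 0:5)
  action <- match.arg(action, c("move", "jump"))
  p <- numeric(6L)
  names(p) <- as.character(0:5)
  if (action == "move") {
    p[move_to(pos) + 1L] <- 1
  } else {
    stopifnot(is.numeric(rho), rho >= 0, rho <= 1)
    target <- config$jump_map[pos + 1L]
    nb <- ring_neighbours(target)
    p[target + 1L] <- rho
    p[nb[, 1L] + 1L] <- p[nb[, 1L] + 1L] + (1 - rho) / 2
    p[nb[, 2L] + 1L] <- p[nb[, 2L] + 1L] + (1 - rho) / 2
  }
  p
}

#' Sample one transition
#'
#' Draws the next position for an action under a noise condition, using the
#' condition's true jump success probability.
#'
#' @inheritParams transition_distribution
#' @param noise `"low"` or `"high"`.
#' @return List with `next_pos` (0--5) and `success` (`TRUE`/`FALSE` for
#'   jump; `NA` for move, so belief updates never trigger on moves).
#' @export
sample_transition <- function(pos, action, noise, config = sat_config()) {
  action <- match.arg(action, c("move", "jump"))
  if (action == "move")
    return(list(next_pos = move_to(pos), success = NA))
  noise <- match.arg(noise, c("low", "high"))
  rho <- config$noise_levels[[noise]]
  target <- config$jump_map[pos + 1L]
  u <- stats::runif(1L)
  if (u < rho) {
    list(next_pos = target, success = TRUE)
  } else {
    nb <- ring_neighbours(target)
    side <- if (u < rho + (1 - rho) / 2) 1L else 2L
    list(next_pos = nb[, side], success = FALSE)
  }
}

#' A single mini-block (one planning problem)
#'
#' @param rewards numeric vector of length 6: fuel reward at each position
#'   (i.e. the constellation's planet rewards in position order).
#' @param start starting position (0--5).
#' @param noise noise condition, `"low"` or `"high"`.
#' @param index mini-block index within a session.
#' @param phase `"training"` or `"analysis"`.
#' @return An object of class `sat_miniblock` with `n_steps = 3`.
#' @export
sat_miniblock <- function(rewards, start, noise = c("low", "high"),
                          index = 1L, phase = c("analysis", "training")) {
  noise <- match.arg(noise)
  phase <- match.arg(phase)
  stopifnot(length(rewards) == 6L, !anyNA(rewards),
            length(start) == 1L, start %in% 0:5)
  structure(list(rewards = as.numeric(rewards), start = as.integer(start),
                 noise = noise, index = as.integer(index), phase = phase,
                 n_steps = 3L),
            class = "sat_miniblock")
}

#' Reward at a position
#'
#' @param pos position (0--5), may be vectorized.
#' @param rewards numeric vector of length 6 (position-order rewards), or a
#'   `sat_miniblock`.
#' @return Fuel reward(s) at `pos`.
#' @export
reward_of <- function(pos, rewards) {
  if (inherits(rewards, "sat_miniblock")) rewards <- rewards$rewards
  stopifnot(all(pos %in% 0:5))
  rewards[pos + 1L]
}

#' Execute an action sequence in a mini-block
#'
#' Samples a trajectory for a given action sequence and accumulates the
#' points earned: at each step the action's cost plus the reward of the
#' planet reached.
#'
#' @param miniblock a [sat_miniblock()].
#' @param actions character vector (length at most `n_steps`) of `"move"` /
#'   `"jump"`.
#' @param config task configuration.
#' @return List with `trajectory` (data frame: step, state, action, outcome,
#'   jump_success, reward) and `points` (total points of the episode).
#' @examples
#' mb <- sat_miniblock(c(0, 10, -10, 20, -20, 0), start = 0, noise = "low")
#' set.seed(1)
#' rollout(mb, c("move", "jump", "move"))
#' @export
rollout <- function(miniblock, actions, config = sat_config()) {
  stopifnot(inherits(miniblock, "sat_miniblock"))
  if (length(actions) > miniblock$n_steps)
    stop("action sequence longer than the mini-block's remaining steps")
  actions <- vapply(actions, match.arg, "", choices = c("move", "jump"))
  s <- miniblock$start
  n <- length(actions)
  out <- data.frame(step = seq_len(n), state = integer(n),
                    action = actions, outcome = integer(n),
                    jump_success = rep(NA, n), reward = numeric(n),
                    row.names = NULL)
  for (t in seq_len(n)) {
    tr <- sample_transition(s, actions[t], miniblock$noise, config)
    out$state[t] <- s
    out$outcome[t] <- tr$next_pos
    out$jump_success[t] <- tr$success
    out$reward[t] <- config$action_costs[[actions[t]]] +
      reward_of(tr$next_pos, miniblock)
    s <- tr$next_pos
  }
  list(trajectory = out, points = sum(out$reward))
}
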