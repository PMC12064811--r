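# Model variants and their free parameters.
sat_variants <- function() c("fb", "dfb", "lpp", "dlpp")

#' Free parameters of a model variant
#'
#' The four planning models are `fb` (full-breadth), `dfb` (discounted
#' full-breadth), `lpp` (low-probability pruning) and `dlpp` (discounted
#' low-probability pruning).  Full-breadth planners learn the jump success
#' probability (learning rate `alpha`); discounted variants devalue the jump
#' action hyperbolically (parameter `kappa`).  All variants share the
#' softmax parameters `beta` (inverse decision temperature) and `theta`
#' (action bias towards jump).
#'
#' @param variant one of `"fb"`, `"dfb"`, `"lpp"`, `"dlpp"`.
#' @return Character vector of free parameter names.
#' @export
variant_params <- function(variant) {
  switch(match.arg(variant, sat_variants()),
         fb   = c("alpha", "beta", "theta"),
         dfb  = c("alpha", "beta", "theta", "kappa"),
         lpp  = c("beta", "theta"),
         dlpp = c("beta", "theta", "kappa"))
}

check_params <- function(params, variant) {
  need <- variant_params(variant)
  if (!all(need %in% names(params)))
    stop("variant '", variant, "' needs parameters: ",
         paste(need, collapse = ", "))
  p <- as.list(params)[need]
  if ("alpha" %in% need && (p$alpha < 0 || p$alpha > 1))
    stop("alpha must lie in [0, 1]")
  if (p$beta < 0) stop("beta must be non-negative")
  if ("kappa" %in% need && (p$kappa < 0 || p$kappa > 30))
    stop("kappa must lie in [0, 30]")
  p
}

#' Transition model used inside the planning tree
#'
#' Full-breadth planners evaluate the jump action with its believed success
#' probability; pruning planners drop the two low-probability branches and
#' treat the jump as deterministic (success probability 1 inside the tree).
#'
#' @param variant model variant, see [variant_params()].
#' @param belief named numeric vector `c(low = , high = )` of believed jump
#'   success probabilities.
#' @param noise current noise condition, `"low"` or `"high"`.
#' @param config task configuration.
#' @return A function `(pos, action) -> distribution over positions` (as in
#'   [transition_distribution()]), plus an attribute `"rho"` giving the
#'   success probability it uses.
#' @export
planning_transition <- function(variant, belief, noise,
                                config = sat_config()) {
  variant <- match.arg(variant, sat_variants())
  noise <- match.arg(noise, c("low", "high"))
  rho <- if (variant %in% c("lpp", "dlpp")) 1 else unname(belief[[noise]])
  f <- function(pos, action) transition_distribution(pos, action, rho, config)
  attr(f, "rho") <- rho
  f
}

# Backward-induction value tables.
#
# rewards: 6 x B matrix (position-order rewards per mini-block);
# rho: length-B believed jump success probability.  Returns, for horizons
# h = 1..h_max, 6 x B matrices of action values:
#   Q_move(h)[s, b] = c_move + r[mv(s)] + V_{h-1}[mv(s)]
#   Q_jump(h)[s, b] = c_jump + sum_o p(o) (r[o] + V_{h-1}[o])
# with V_h = max(Q_move(h), Q_jump(h)) and V_0 = 0.  The max at interior
# nodes is over undiscounted values: probability discounting applies only
# at the root comparison (see choice_probability()).
q_levels <- function(rewards, rho, config, h_max = 3L) {
  B <- ncol(rewards)
  mv <- move_to(0:5) + 1L
  jt <- config$jump_map + 1L
  nb <- ring_neighbours(config$jump_map)
  n1 <- nb[, 1L] + 1L
  n2 <- nb[, 2L] + 1L
  cm <- config$action_costs[["move"]]
  cj <- config$action_costs[["jump"]]
  rho_m <- matrix(rho, 6L, B, byrow = TRUE)
  half <- (1 - rho_m) / 2
  V <- matrix(0, 6L, B)
  Qm <- Qj <- vector("list", h_max)
  for (h in seq_len(h_max)) {
    Gm <- rewards + V                 # r(s') + V(s') for every position
    Qm[[h]] <- cm + Gm[mv, , drop = FALSE]
    Qj[[h]] <- cj + rho_m * Gm[jt, , drop = FALSE] +
      half * (Gm[n1, , drop = FALSE] + Gm[n2, , drop = FALSE])
    V <- pmax(Qm[[h]], Qj[[h]])
  }
  list(q_move = Qm, q_jump = Qj)
}

#' Action values by backward induction
#'
#' Computes the expected cumulative reward (Q-value) of `jump` and `move` at
#' a state, for a given action step and planning depth, by finite-horizon
#' value iteration.  The effective horizon is `min(depth, T - step + 1)`
#' (planning is re-done at every step from the current state, and the state
#' value beyond the horizon is 0), so any depth at least equal to the
#' remaining steps yields the full-horizon values.
#'
#' @param state current position (0--5).
#' @param step action step within the mini-block (1--3).
#' @param depth planning depth (1--3).
#' @param rewards numeric vector of length 6 (position-order rewards) or a
#'   [sat_miniblock()].
#' @param rho jump success probability used inside the tree (1 for pruning
#'   planners; the believed probability for full-breadth planners).
#' @param config task configuration.
#' @return Named numeric vector `c(jump = , move = )`.
#' @examples
#' mb <- sat_miniblock(c(0, 10, -10, 20, -20, 0), start = 0, noise = "low")
#' q_values(0, step = 1, depth = 3, mb, rho = 0.9)
#' @export
q_values <- function(state, step, depth, rewards, rho = 1,
                     config = sat_config()) {
  if (inherits(rewards, "sat_miniblock")) rewards <- rewards$rewards
  stopifnot(state %in% 0:5, step %in% 1:3)
  if (!(length(depth) == 1L && depth %in% 1:3))
    stop("depth must be 1, 2 or 3")
  h <- min(depth, 3L - step + 1L)
  lv <- q_levels(matrix(rewards, 6L, 1L), rho, config, h_max = h)
  c(jump = lv$q_jump[[h]][state + 1L, 1L],
    move = lv$q_move[[h]][state + 1L, 1L])
}

#' Hyperbolic probability discount factor
#'
#' The subjective value of an outcome obtained with probability `rho` is its
#' nominal value times `1 / (1 + kappa * q)` where `q = (1 - rho) / rho` is
#' the odds against obtaining it.  `kappa = 0` leaves values undiscounted.
#'
#' @param rho outcome probability in `(0, 1]`.
#' @param kappa discounting parameter in `[0, 30]`.
#' @return Discount factor in `(0, 1]`.
#' @examples
#' 100 * discount_factor(0.9, 16)  # 36
#' 100 * discount_factor(0.5, 3)   # 25
#' @export
discount_factor <- function(rho, kappa) {
  if (any(rho <= 0)) stop("rho must be positive (odds undefined at 0)")
  stopifnot(all(rho <= 1), all(kappa >= 0))
  1 / (1 + kappa * (1 - rho) / rho)
}

#' Softmax choice probability of the jump action
#'
#' `p(jump) = sigmoid(beta * (gamma_prob * Q_jump - Q_move) + theta)`.
#' Probability discounting (`gamma_prob`, see [discount_factor()]) is
#' applied exactly once, to the jump value at this root comparison -- never
#' recursively inside the planning tree.  The function is unit-agnostic:
#' callers that work in fuel points divide the Q-pair by the
#' configuration's `point_scale` first, so that `beta` and `theta` live on
#' the conventional model-unit scale.
#'
#' @param qpair named numeric vector `c(jump = , move = )` as returned by
#'   [q_values()].
#' @param beta inverse decision temperature (>= 0).
#' @param theta action bias (positive favours jump).
#' @param gamma_prob discount factor applied to the jump value (default 1,
#'   i.e. no discounting).
#' @return Probability of choosing jump.
#' @export
choice_probability <- function(qpair, beta, theta, gamma_prob = 1) {
  stats::plogis(beta * (gamma_prob * qpair[["jump"]] - qpair[["move"]]) +
                  theta)
}

#' Temporal-difference update of the jump success belief
#'
#' `rho' = rho + alpha * (outcome - rho)`, applied only after jump actions
#' (outcome 1 = reached the target, 0 = missed) on the belief slot of the
#' current noise condition.
#'
#' @param rho current believed success probability.
#' @param outcome observed jump outcome, 0 or 1.
#' @param alpha learning rate in `[0, 1]`.
#' @return Updated belief.
#' @export
td_update <- function(rho, outcome, alpha) {
  stopifnot(all(outcome %in% c(0, 1)), alpha >= 0, alpha <= 1)
  rho + alpha * (outcome - rho)
}

# gamma_prob at the root for one decision.
# dfb discounts by the current *learned* belief; dlpp by the condition's
# true success probability; fb/lpp do not discount.
root_gamma <- function(variant, params, belief_rho, true_rho) {
  switch(variant,
         fb = 1, lpp = 1,
         dfb = discount_factor(belief_rho, params$kappa),
         dlpp = discount_factor(true_rho, params$kappa))
}

#' Likelihood of the choices in one mini-block at a fixed planning depth
#'
#' Product over the action steps of the softmax probability of the observed
#' action, under the given model variant and planning depth.  For
#' full-breadth variants the belief about the jump success probability is
#' updated after each observed jump outcome within the block; the belief in
#' force at each step is used both inside the planning tree and (for `dfb`)
#' in the root discount factor.
#'
#' @param choices data frame with columns `step`, `state`, `action`
#'   (`"move"`/`"jump"`) and, for jump steps, `jump_success` (logical or
#'   0/1); rows in step order.
#' @param miniblock a [sat_miniblock()].
#' @param params named list/vector with the variant's free parameters.
#' @param variant model variant.
#' @param depth planning depth (1--3).
#' @param belief named vector `c(low = , high = )` of believed jump success
#'   probabilities at the start of the block (full-breadth variants).
#' @param config task configuration.
#' @return The likelihood (a probability), with attribute `"belief"` giving
#'   the updated belief after the block.
#' @export
miniblock_likelihood <- function(choices, miniblock, params, variant,
                                 depth, belief = c(low = 0.9, high = 0.5),
                                 config = sat_config()) {
  variant <- match.arg(variant, sat_variants())
  p <- check_params(params, variant)
  stopifnot(inherits(miniblock, "sat_miniblock"))
  if (nrow(choices) > miniblock$n_steps ||
      !identical(as.integer(choices$step), seq_len(nrow(choices))))
    stop("choices must cover contiguous steps 1..k of the mini-block")
  true_rho <- config$noise_levels[[miniblock$noise]]
  lik <- 1
  s <- miniblock$start
  for (i in seq_len(nrow(choices))) {
    if (choices$state[i] != s)
      stop("choice state at step ", i, " inconsistent with the mini-block")
    rho_bel <- unname(belief[[miniblock$noise]])
    rho_plan <- if (variant %in% c("lpp", "dlpp")) 1 else rho_bel
    qp <- q_values(s, choices$step[i], depth, miniblock$rewards,
                   rho = rho_plan, config = config)
    gam <- root_gamma(variant, p, rho_bel, true_rho)
    pj <- choice_probability(qp / config$point_scale, p$beta, p$theta, gam)
    lik <- lik * if (choices$action[i] == "jump") pj else 1 - pj
    if (choices$action[i] == "jump") {
      if (variant %in% c("fb", "dfb")) {
        o <- as.numeric(choices$jump_success[i])
        if (is.na(o)) stop("jump step ", i, " lacks a jump_success outcome")
        belief[[miniblock$noise]] <- td_update(rho_bel, o, p$alpha)
      }
      s <- if (isTRUE(as.logical(choices$jump_success[i])))
        config$jump_map[s + 1L] else next_state_of(choices, i)
    } else {
      s <- move_to(s)
    }
  }
  attr(lik, "belief") <- belief
  lik
}

# Observed outcome state for step i when it is recorded in the log.
next_state_of <- function(choices, i) {
  if (!is.null(choices$outcome)) return(choices$outcome[i])
  stop("failed jump at step ", i, " requires an 'outcome' column")
}

#' Depth-mixture likelihood and depth posterior for one mini-block
#'
#' Marginalizes the per-block likelihood over the planning depth:
#' `L = sum_d prior(d) * L(choices | d)`, and returns the posterior
#' `p(d | choices) = prior(d) L(d) / L`.
#'
#' @inheritParams miniblock_likelihood
#' @param prior numeric vector of length 3 on the 3-simplex (default
#'   uniform, the Dirichlet-uniform prior used throughout).
#' @return List with `likelihood` (the mixture likelihood), `posterior`
#'   (length-3 depth posterior) and `belief` (updated belief).
#' @export
depth_mixture_likelihood <- function(choices, miniblock, params, variant,
                                     prior = rep(1 / 3, 3),
                                     belief = c(low = 0.9, high = 0.5),
                                     config = sat_config()) {
  stopifnot(length(prior) == 3L, all(prior >= 0),
            abs(sum(prior) - 1) < 1e-9)
  liks <- numeric(3L)
  bel <- belief
  for (d in 1:3) {
    l <- miniblock_likelihood(choices, miniblock, params, variant, d,
                              belief, config)
    bel <- attr(l, "belief")  # identical for every d: updates are
    liks[d] <- as.numeric(l)  # outcome-driven, not depth-driven
  }
  mix <- sum(prior * liks)
  post <- if (mix > 0) prior * liks / mix else rep(NA_real_, 3L)
  list(likelihood = mix, posterior = post, belief = bel)
}
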