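test_that("backward induction matches the expectimax oracle", {
  cfg <- sat_config()
  set.seed(21)
  worst <- 0
  for (i in 1:40) {
    r <- sample(cfg$planet_rewards, 6, replace = TRUE)
    rho <- if (i %% 2 == 0) 1 else runif(1, 0.3, 1)  # pruned and believed
    for (s in 0:5) for (t in 1:3) for (d in 1:3) {
      got <- q_values(s, t, d, r, rho, cfg)
      want <- oracle_q(s, min(d, 4 - t), r, rho, cfg)
      worst <- max(worst, abs(got - want))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("planning horizon clips at the remaining steps", {
  cfg <- sat_config()
  r <- c(10, -20, 0, 20, -10, 10)
  # at step 2 only 2 steps remain: depths 2 and 3 agree
  expect_equal(q_values(0, 2, 3, r, 0.9, cfg),
               q_values(0, 2, 2, r, 0.9, cfg))
  # at step 3, all depths agree
  for (d in 2:3)
    expect_equal(q_values(4, 3, d, r, 0.5, cfg),
                 q_values(4, 3, 1, r, 0.5, cfg))
  # depth-1 values are the single-step expectation by definition
  q1 <- q_values(0, 1, 1, r, 0.5, cfg)
  expect_equal(unname(q1["move"]),
               cfg$action_costs[["move"]] + r[2])
  tgt <- cfg$jump_map[1]
  nbs <- c((tgt - 1) %% 6, (tgt + 1) %% 6)
  expect_equal(unname(q1["jump"]),
               cfg$action_costs[["jump"]] +
                 0.5 * r[tgt + 1] + 0.25 * sum(r[nbs + 1]))
  expect_error(q_values(0, 1, 4, r, 0.5, cfg), "depth")
})

test_that("hyperbolic discounting follows the odds-against form", {
  # worked examples: 100 points at the task's two probabilities
  expect_equal(100 * discount_factor(0.9, 16), 36)
  expect_equal(100 * discount_factor(0.5, 16), 100 / 17)
  expect_equal(100 * discount_factor(0.9, 3), 75)
  expect_equal(100 * discount_factor(0.5, 3), 25)
  expect_equal(discount_factor(0.7, 0), 1)  # kappa = 0: undiscounted
  expect_equal(discount_factor(1, 25), 1)   # certain outcomes keep value
  expect_error(discount_factor(0, 5), "rho")
  # strictly decreasing in kappa, increasing in rho
  ks <- seq(0, 30, by = 2.5)
  expect_true(all(diff(discount_factor(0.6, ks)) < 0))
  rhos <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(discount_factor(rhos, 4)) > 0))
})

test_that("softmax choice rule responds to beta, theta and gamma", {
  qp <- c(jump = 3.7, move = -1.2)
  expect_equal(choice_probability(qp, 0, 0), 0.5)
  expect_equal(choice_probability(c(jump = 0, move = 0), 5, -0.21),
               0.4476920904, tolerance = 1e-9)
  expect_gt(choice_probability(c(jump = 500, move = 0), 1, 0), 1 - 1e-10)
  # discounting the jump value lowers the jump probability for gains
  expect_lt(choice_probability(qp, 2, 0, gamma_prob = 0.3),
            choice_probability(qp, 2, 0, gamma_prob = 1))
})

test_that("TD belief updates implement the delta rule", {
  expect_equal(td_update(0.9, 1, 0.1), 0.91)
  expect_equal(td_update(0.37, 0, 0), 0.37)   # no learning
  expect_equal(td_update(0.5, 0, 1), 0)       # full overwrite
  # beliefs stay in [0, 1] under any outcome sequence
  rho <- 0.5
  set.seed(3)
  for (o in rbinom(200, 1, 0.7)) {
    rho <- td_update(rho, o, 0.3)
    expect_true(rho >= 0 && rho <= 1)
  }
})

test_that("planning transition prunes exactly when the variant says so", {
  cfg <- sat_config()
  bel <- c(low = 0.8, high = 0.45)
  f_lpp <- planning_transition("lpp", bel, "high", cfg)
  p <- f_lpp(2, "jump")
  expect_equal(unname(p[as.character(cfg$jump_map[3])]), 1)
  f_fb <- planning_transition("fb", bel, "high", cfg)
  expect_equal(attr(f_fb, "rho"), 0.45)  # believed, not true
  # belief 1 makes full-breadth identical to pruning
  f_fb1 <- planning_transition("fb", c(low = 1, high = 1), "high", cfg)
  for (pos in 0:5)
    expect_equal(f_fb1(pos, "jump"), f_lpp(pos, "jump"))
})

test_that("mini-block likelihoods multiply per-step softmax terms", {
  cfg <- sat_config()
  mb <- sat_miniblock(c(0, 10, -10, 20, -20, 0), start = 0, noise = "low")
  ch <- data.frame(step = 1:3, state = c(0, 1, 2),
                   action = rep("move", 3), outcome = c(1, 2, 3),
                   jump_success = rep(NA, 3))
  # beta = 0, theta = 0: three fair coin flips
  l <- miniblock_likelihood(ch, mb, list(beta = 0, theta = 0), "lpp",
                            depth = 2, config = cfg)
  expect_equal(as.numeric(l), 0.125)
  # inconsistent state rejected
  bad <- ch
  bad$state[2] <- 5
  expect_error(miniblock_likelihood(bad, mb, list(beta = 0, theta = 0),
                                    "lpp", 2, config = cfg),
               "inconsistent")
  # missing parameters rejected
  expect_error(miniblock_likelihood(ch, mb, list(beta = 1), "dlpp", 2,
                                    config = cfg), "needs parameters")
})

test_that("depth mixture agrees with per-depth likelihoods and the prior", {
  cfg <- sat_config()
  mb <- sat_miniblock(c(-20, 20, 0, 10, -10, 10), start = 3,
                      noise = "high")
  ch <- data.frame(step = 1:3, state = c(3, 0, 1),
                   action = c("jump", "move", "move"),
                   outcome = c(0, 1, 2), jump_success = c(TRUE, NA, NA))
  params <- list(beta = 1.5, theta = -0.3)
  liks <- vapply(1:3, function(d)
    as.numeric(miniblock_likelihood(ch, mb, params, "lpp", d,
                                    config = cfg)), 0)
  prior <- c(0.2, 0.4, 0.4)
  res <- depth_mixture_likelihood(ch, mb, params, "lpp", prior = prior,
                                  config = cfg)
  expect_equal(res$likelihood, sum(prior * liks))
  expect_equal(res$posterior, prior * liks / sum(prior * liks))
  expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
  # equal per-depth likelihoods (beta = 0) + uniform prior -> uniform
  res0 <- depth_mixture_likelihood(ch, mb, list(beta = 0, theta = 0),
                                   "lpp", config = cfg)
  expect_equal(res0$posterior, rep(1 / 3, 3))
  # a depth with zero prior gets zero posterior
  resz <- depth_mixture_likelihood(ch, mb, params, "lpp",
                                   prior = c(0, 0.5, 0.5), config = cfg)
  expect_equal(resz$posterior[1], 0)
})

test_that("kappa = 0 collapses discounted variants onto their parents", {
  task <- fixture_task()
  log <- fixture_log()
  p_l <- list(beta = 1.7, theta = 0.25)
  p_d <- c(p_l, kappa = 0)
  expect_equal(as.numeric(sat_loglik(log, task, p_d, "dlpp")),
               as.numeric(sat_loglik(log, task, p_l, "lpp")),
               tolerance = 1e-12)
  p_f <- list(alpha = 0.4, beta = 1.7, theta = 0.25)
  expect_equal(as.numeric(sat_loglik(log, task, c(p_f, kappa = 0), "dfb")),
               as.numeric(sat_loglik(log, task, p_f, "fb")),
               tolerance = 1e-12)
})
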