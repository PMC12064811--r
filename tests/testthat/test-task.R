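test_that("transition distributions match the task's noise structure", {
  cfg <- sat_config()
  for (pos in 0:5) {
    tgt <- cfg$jump_map[pos + 1]
    nb <- sort(c((tgt - 1) %% 6, (tgt + 1) %% 6))
    # low noise: 90% target, 5% each neighbour
    p <- transition_distribution(pos, "jump", 0.9, cfg)
    expect_equal(unname(p[as.character(tgt)]), 0.9)
    expect_equal(unname(p[as.character(nb)]), c(0.05, 0.05))
    # high noise: 50% / 25% / 25%
    p <- transition_distribution(pos, "jump", 0.5, cfg)
    expect_equal(unname(p[as.character(tgt)]), 0.5)
    expect_equal(unname(p[as.character(nb)]), c(0.25, 0.25))
    # deterministic limit and move
    p <- transition_distribution(pos, "jump", 1, cfg)
    expect_equal(unname(p[as.character(tgt)]), 1)
    p <- transition_distribution(pos, "move", 1, cfg)
    expect_equal(unname(p[as.character((pos + 1) %% 6)]), 1)
  }
  # masses always sum to 1
  for (rho in c(0, 0.17, 0.5, 0.9, 1))
    for (pos in 0:5)
      for (a in c("move", "jump"))
        expect_equal(sum(transition_distribution(pos, a, rho, cfg)), 1,
                     tolerance = 1e-12)
  expect_error(transition_distribution(0, "teleport", 0.9, cfg))
})

test_that("configuration invariants are enforced", {
  expect_error(sat_config(jump_map = c(0, 3, 4, 5, 1, 2)),
               "fixed points")
  expect_error(sat_config(jump_map = c(1, 3, 5, 0, 2, 4)),
               "neighbour")
  expect_error(sat_config(jump_map = c(3, 3, 5, 0, 1, 2)),
               "permutation")
  expect_error(sat_config(planet_rewards = c(1, 2, 3, 4, 5)),
               "losses and gains")
  expect_error(sat_config(noise_levels = c(low = 0.9, high = 0)))
  # default jump map: derangement avoiding the move edge
  cfg <- sat_config()
  expect_true(all(cfg$jump_map != 0:5))
  expect_true(all(cfg$jump_map != (0:5 + 1) %% 6))
  expect_setequal(cfg$jump_map, 0:5)
})

test_that("sampled transitions have the advertised frequencies", {
  cfg <- sat_config()
  mv <- sample_transition(2, "move", "high", cfg)
  expect_equal(mv$next_pos, 3)
  expect_true(is.na(mv$success))  # belief updates never fire on move

  set.seed(7)
  n <- 1e5
  draws <- replicate(n, sample_transition(0, "jump", "high", cfg)$success)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)

  set.seed(8)
  outs <- replicate(n, sample_transition(0, "jump", "low", cfg)$next_pos)
  tgt <- cfg$jump_map[1]
  for (nbp in c((tgt - 1) %% 6, (tgt + 1) %% 6)) {
    f <- mean(outs == nbp)
    expect_lt(abs(f - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  }
})

test_that("rewards are determined by planet kind", {
  cfg <- sat_config()
  r <- cfg$planet_rewards[c(1, 3, 3, 5, 2, 4)]  # kinds 0,2,2,4,1,3
  mb <- sat_miniblock(r, start = 0, noise = "low")
  expect_equal(reward_of(1, mb), reward_of(2, mb))  # same kind, same reward
  expect_equal(reward_of(which(r == 0)[1] - 1, mb), 0)
  expect_lt(reward_of(0, mb), 0)
})

test_that("rollout accumulates step costs plus landing rewards", {
  cfg <- sat_config()
  r <- c(0, 10, -10, 20, -20, 0)
  mb <- sat_miniblock(r, start = 0, noise = "low")
  # all-move is deterministic: identical under any rng state
  ro1 <- rollout(mb, rep("move", 3), cfg)
  set.seed(99)
  ro2 <- rollout(mb, rep("move", 3), cfg)
  expect_identical(ro1$trajectory$outcome, c(1L, 2L, 3L))
  expect_equal(ro1$points, ro2$points)
  expect_equal(ro1$points, sum(r[c(2, 3, 4)]) +
                 3 * cfg$action_costs[["move"]])
  # all-jump with certain transitions follows the jump chain exactly
  cfg1 <- sat_config(noise_levels = c(low = 1, high = 0.5))
  mb1 <- sat_miniblock(r, start = 0, noise = "low")
  ro <- rollout(mb1, rep("jump", 3), cfg1)
  chain <- Reduce(function(s, .) cfg1$jump_map[s + 1], 1:3,
                  accumulate = TRUE, init = 0)[-1]
  expect_identical(ro$trajectory$outcome, as.integer(chain))
  expect_error(rollout(mb, rep("move", 4), cfg), "longer")
})

test_that("Monte-Carlo rollout means match the enumerated expectation", {
  cfg <- sat_config()
  mb <- sat_miniblock(c(-20, 10, 0, 20, -10, 10), start = 4, noise = "high")
  acts <- rep("jump", 3)
  exact <- oracle_rollout_mean(mb, acts, cfg)
  set.seed(11)
  pts <- replicate(1e4, rollout(mb, acts, cfg)$points)
  expect_lt(abs(mean(pts) - exact), 3 * sd(pts) / sqrt(length(pts)))
})
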