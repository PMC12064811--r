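test_that("generated sessions satisfy the block-structure constraints", {
  for (seed in c(101, 202, 303)) {
    task <- generate_task(seed = seed)
    blocks <- task$blocks
    expect_equal(nrow(blocks), 140)
    expect_equal(sum(blocks$noise == "low"), 70)
    expect_equal(sum(blocks$noise == "high"), 70)
    expect_equal(sum(blocks$phase == "analysis"), 120)
    runs <- rle(blocks$noise)
    expect_true(all(runs$lengths >= 3 & runs$lengths <= 6))
    expect_true(all(runs$values[-1] != runs$values[-length(runs$values)]))
    # training flags: the first 10 of each condition in presentation order
    for (cc in c("low", "high")) {
      idx <- which(blocks$noise == cc)
      expect_equal(blocks$phase[idx], rep(c("training", "analysis"),
                                          c(10, 60)))
    }
    expect_true(all(task$constellations %in% 0:4))
    expect_true(all(blocks$start %in% 0:5))
  }
  # determinism
  expect_identical(generate_task(seed = 7), generate_task(seed = 7))
})

test_that("simulated logs are internally consistent and reproducible", {
  task <- fixture_task()
  log <- fixture_log()
  expect_equal(nrow(log), 3 * 140)
  expect_length(validate_choice_log(log, task$config), 0)
  expect_identical(log,
                   simulate_participant(task, "lpp",
                                        list(beta = 2, theta = -0.2),
                                        depth = 2, seed = 102))
  # rewards column = action cost + landing reward; cumulative sums match
  cfg <- task$config
  R <- cfg$planet_rewards[t(task$constellations) + 1]
  expect_equal(log$reward,
               unname(cfg$action_costs[log$action]) +
                 R[log$outcome + 1 + 6 * (rep(seq_len(140), each = 3) - 1)])
  expect_equal(log$cum_points, cfg$initial_points + cumsum(log$reward))
})

test_that("value-blind simulation jumps at rate sigma(theta)", {
  task <- fixture_task()
  log <- simulate_participant(task, "lpp", list(beta = 0, theta = 0.5),
                              depth = 1, seed = 55)
  n <- nrow(log)
  p <- plogis(0.5)
  expect_lt(abs(mean(log$action == "jump") - p),
            3 * sqrt(p * (1 - p) / n))
})

test_that("near-greedy pruning agents take the argmax action", {
  task <- fixture_task()
  cfg <- task$config
  log <- simulate_participant(task, "lpp", list(beta = 1e4, theta = 0),
                              depth = 3, seed = 66)
  R <- t(matrix(cfg$planet_rewards[task$constellations + 1],
                nrow = 140))
  for (i in seq_len(nrow(log))) {
    b <- log$mini_block[i]
    qp <- q_values(log$state[i], log$step[i], 3, R[, b], rho = 1,
                   config = cfg)
    dq <- qp[["jump"]] - qp[["move"]]
    if (abs(dq) > 1e-9)
      expect_identical(log$action[i], if (dq > 0) "jump" else "move")
  }
})

test_that("stronger discounting suppresses jumping", {
  task <- fixture_task()
  l0 <- simulate_participant(task, "dlpp",
                             list(beta = 2, theta = 0, kappa = 0),
                             depth = 3, seed = 31)
  l30 <- simulate_participant(task, "dlpp",
                              list(beta = 2, theta = 0, kappa = 30),
                              depth = 3, seed = 31)
  expect_lt(mean(l30$action == "jump"), mean(l0$action == "jump"))
})

test_that("cohorts are reproducible with full ground truth", {
  spec <- cohort_spec(5, "dlpp",
                      param_ranges = list(beta = c(0.5, 3),
                                          theta = c(-0.5, 0.5),
                                          kappa = c(0, 30)),
                      depth_dist = c(0.2, 0.3, 0.5), seed = 9)
  co <- generate_cohort(spec, task = fixture_task())
  expect_length(co$logs, 5)
  expect_equal(nrow(co$truth), 5)
  expect_equal(dim(co$depths), c(5, 140))
  expect_true(all(co$truth$beta >= 0.5 & co$truth$beta <= 3))
  expect_true(all(co$truth$kappa >= 0 & co$truth$kappa <= 30))
  expect_true(all(co$depths %in% 1:3))
  co2 <- generate_cohort(spec, task = fixture_task())
  expect_identical(co$logs, co2$logs)
  expect_identical(co$truth, co2$truth)
})

test_that("generating parameters beat value-blind ones in likelihood", {
  task <- fixture_task()
  spec <- cohort_spec(5, "lpp",
                      param_ranges = list(beta = c(1, 2.5),
                                          theta = c(-0.3, 0.3)),
                      depth_dist = rep(1 / 3, 3), seed = 13)
  co <- generate_cohort(spec, task = task)
  delta <- vapply(seq_len(5), function(i) {
    p_true <- list(beta = co$truth$beta[i], theta = co$truth$theta[i])
    as.numeric(sat_loglik(co$logs[[i]], task, p_true, "lpp")) -
      as.numeric(sat_loglik(co$logs[[i]], task,
                            list(beta = 0, theta = 0), "lpp"))
  }, 0)
  expect_gt(sum(delta), 0)
})
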