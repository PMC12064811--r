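# Shared fixtures, built once per test run.
.fx <- new.env(parent = emptyenv())

fixture_task <- function() {
  if (is.null(.fx$task)) .fx$task <- generate_task(seed = 101)
  .fx$task
}

# A small LPP log with known parameters, reused by fit/io tests.
fixture_log <- function() {
  if (is.null(.fx$log))
    .fx$log <- simulate_participant(fixture_task(), "lpp",
                                    list(beta = 2, theta = -0.2),
                                    depth = 2, seed = 102)
  .fx$log
}

# Parameter-recovery experiment on a DLPP cohort (n = 50, 120 analysis
# mini-blocks, beta in [0.5, 3], kappa in [0, 30]); computed once and
# shared between the acceptance and inference tests.
fixture_recovery <- function() {
  if (is.null(.fx$recovery)) {
    task <- generate_task(seed = 1)
    spec <- cohort_spec(50, "dlpp",
                        param_ranges = list(beta = c(0.5, 3),
                                            theta = c(-0.5, 0.5),
                                            kappa = c(0, 30)),
                        depth_dist = rep(1 / 3, 3), seed = 2)
    cohort <- generate_cohort(spec, task = task)
    fits <- lapply(cohort$logs, sat_fit, task = task, variant = "dlpp")
    .fx$recovery <- list(task = task, truth = cohort$truth,
                         estimates = t(vapply(fits, coef, numeric(3))))
  }
  .fx$recovery
}
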