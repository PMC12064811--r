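# Internal replay structure: per-block step arrays extracted from a choice
# log, aligned with a task session.
prepare_replay <- function(log, task) {
  B <- nrow(task$blocks)
  stopifnot(all(log$mini_block %in% task$blocks$index))
  ord <- order(match(log$mini_block, task$blocks$index), log$step)
  log <- log[ord, ]
  if (nrow(log) != 3L * B)
    stop("log must contain exactly 3 steps for each of the task's ",
         B, " mini-blocks")
  states <- matrix(as.integer(log$state), 3L, B)
  is_jump <- matrix(log$action == "jump", 3L, B)
  succ <- matrix(as.numeric(log$jump_success), 3L, B)
  if (any(is_jump & is.na(succ)))
    stop("jump steps must record a jump_success outcome")
  if (!all(states[1L, ] == task$blocks$start))
    stop("first-step states do not match the task's start positions")
  list(states = states, is_jump = is_jump, succ = succ,
       cond = ifelse(task$blocks$noise == "low", 1L, 2L),
       analysis = task$blocks$phase == "analysis",
       rewards = task_rewards(task), B = B)
}

# Learned belief (jump success probability) in force at every step, per
# condition, given learning rate alpha.  Beliefs start at rho_init and are
# updated by the TD rule after each observed jump outcome of the matching
# condition, in presentation order (training blocks included).
belief_trajectory <- function(rep, alpha, rho_init) {
  nstep <- 3L * rep$B
  cond_step <- rep(rep$cond, each = 3L)
  is_jump <- as.vector(rep$is_jump)
  o <- as.vector(rep$succ)
  bel <- matrix(NA_real_, nstep, 2L)
  for (cc in 1:2) {
    rho0 <- rho_init[cc]
    ev <- is_jump & cond_step == cc
    o_ev <- o[ev]
    if (length(o_ev) && alpha > 0) {
      rho_after <- as.numeric(stats::filter(alpha * o_ev, 1 - alpha,
                                            method = "recursive",
                                            init = rho0))
    } else {
      rho_after <- rep(rho0, length(o_ev))
    }
    n_prior <- cumsum(ev) - ev
    bel[, cc] <- c(rho0, rho_after)[n_prior + 1L]
  }
  # belief of each step's own condition, as a 3 x B matrix
  matrix(bel[cbind(seq_len(nstep), cond_step)], 3L, rep$B)
}

# Vectorized session log-likelihood.  Returns total lnL over analysis
# blocks plus per-block depth log-likelihoods and posteriors.
session_loglik <- function(rep, params, variant, config,
                           prior = rep(1 / 3, 3),
                           rho_init = NULL) {
  p <- params
  B <- rep$B
  true_rho <- config$noise_levels[rep$cond]
  if (is.null(rho_init)) rho_init <- unname(config$noise_levels)
  pruning <- variant %in% c("lpp", "dlpp")
  ps <- config$point_scale
  rho_bel <- if (pruning) NULL
  else belief_trajectory(rep, p$alpha, rho_init)
  gam <- switch(variant,
                fb = , lpp = matrix(1, 3L, B),
                dfb = discount_factor(rho_bel, p$kappa),
                dlpp = matrix(discount_factor(true_rho, p$kappa), 3L, B,
                              byrow = TRUE))
  lb <- matrix(0, 3L, B)  # depth x block log-likelihood
  cols <- seq_len(B)
  for (t in 1:3) {
    rho_t <- if (pruning) rep(1, B) else rho_bel[t, ]
    h_max <- min(3L, 4L - t)
    lv <- q_levels(rep$rewards, rho_t, config, h_max)
    idx <- cbind(rep$states[t, ] + 1L, cols)
    sgn <- ifelse(rep$is_jump[t, ], 1, -1)
    for (d in 1:3) {
      h <- min(d, 4L - t)
      x <- p$beta * (gam[t, ] * lv$q_jump[[h]][idx] -
                       lv$q_move[[h]][idx]) / ps + p$theta
      lb[d, ] <- lb[d, ] + stats::plogis(sgn * x, log.p = TRUE)
    }
  }
  la <- log(prior) + lb
  m <- apply(la, 2L, max)
  logmix <- m + log(colSums(exp(sweep(la, 2L, m))))
  posterior <- t(exp(sweep(la, 2L, logmix)))
  colnames(posterior) <- paste0("d", 1:3)
  list(logLik = sum(logmix[rep$analysis]), logmix = logmix,
       posterior = posterior, per_depth = lb)
}

#' Session log-likelihood of a choice log under a model variant
#'
#' Evaluates the planning-depth mixture log-likelihood of a full session:
#' the sum over analysis mini-blocks of
#' `log sum_d prior(d) p(choices_b | d, params)`.  Beliefs of full-breadth
#' variants evolve across the whole session in presentation order (training
#' blocks drive learning but do not enter the likelihood sum).
#'
#' @param log choice-log data frame (see [simulate_participant()] /
#'   [read_choice_log()]).
#' @param task the [generate_task()] session the log was recorded on.
#' @param params named list/vector of the variant's free parameters.
#' @param variant model variant.
#' @param depth_prior prior over planning depths 1--3 (default uniform).
#' @param rho_init initial believed jump success probabilities
#'   `c(low, high)`; defaults to the true values.
#' @return Total log-likelihood, with attributes `"depth_posterior"` (the
#'   analysis blocks' depth posteriors) and `"n_choices"`.
#' @export
sat_loglik <- function(log, task, params, variant,
                       depth_prior = rep(1 / 3, 3), rho_init = NULL) {
  variant <- match.arg(variant, sat_variants())
  p <- check_params(params, variant)
  rp <- prepare_replay(log, task)
  res <- session_loglik(rp, p, variant, task$config, depth_prior, rho_init)
  structure(res$logLik,
            depth_posterior = res$posterior[rp$analysis, , drop = FALSE],
            n_choices = 3L * sum(rp$analysis))
}

# Parameter transforms for unconstrained optimization:
# alpha: logit on [0,1]; beta: log; theta: identity; kappa: scaled logit
# on [0,30].
to_unconstrained <- function(p, names) {
  x <- numeric(length(names))
  for (i in seq_along(names)) {
    x[i] <- switch(names[i],
                   alpha = stats::qlogis(min(max(p[[names[i]]], 1e-6),
                                             1 - 1e-6)),
                   beta = log(max(p[[names[i]]], 1e-8)),
                   theta = p[[names[i]]],
                   kappa = stats::qlogis(min(max(p[[names[i]]] / 30, 1e-6),
                                             1 - 1e-6)))
  }
  x
}

to_natural <- function(x, names) {
  p <- list()
  for (i in seq_along(names)) {
    p[[names[i]]] <- switch(names[i],
                            alpha = stats::plogis(x[i]),
                            beta = exp(x[i]),
                            theta = x[i],
                            kappa = 30 * stats::plogis(x[i]))
  }
  p
}

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

#' Fit a planning model to one participant's choice log
#'
#' Maximizes the planning-depth mixture likelihood (see [sat_loglik()])
#' over the variant's free parameters by multi-start Nelder--Mead on an
#' unconstrained reparameterization (logit for `alpha`, log for `beta`,
#' identity for `theta`, scaled logit for `kappa` on `[0, 30]`).  The
#' objective is penalized maximum likelihood: independent Gaussian priors
#' with mean 0 and standard deviation `prior_sd` on the unconstrained
#' parameters act as weakly-informative regularization.  This matters
#' mostly for `beta`: softmax likelihoods have near-deterministic ridges
#' along which `beta` (and a compensating `theta`) can run away on finite
#' data, and the log-scale prior keeps estimates in the interior without
#' materially biasing moderate values.  The fit is deterministic given
#' `seed` and the settings.
#'
#' @param log choice-log data frame.
#' @param task the [generate_task()] session the log was recorded on.
#' @param variant model variant to fit (default `"dlpp"`).
#' @param depth_prior prior over planning depths (default uniform).
#' @param n_starts number of optimizer starts (first is a fixed default
#'   start; the rest are drawn reproducibly from `seed`).
#' @param seed integer seed for the random starts.
#' @param maxit,reltol Nelder--Mead control settings.
#' @param prior_sd named numeric vector: prior standard deviations of the
#'   unconstrained parameters (`alpha` on the logit scale, `beta` on the
#'   log scale, `theta` as-is, `kappa` on the logit of `kappa / 30`).
#' @param rho_init initial beliefs `c(low, high)`; defaults to the true
#'   success probabilities.
#' @return An object of class `sat_fit` with `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `plot` and `simulate` methods.  Key fields:
#'   `coefficients` (natural scale), `logLik`, `depth_posterior` (one row
#'   per analysis mini-block), `n_choices`, `convergence`, `starts`.
#' @examples
#' task <- generate_task(seed = 42)
#' log <- simulate_participant(task, "lpp", list(beta = 2, theta = -0.2),
#'                             depth = 3, seed = 7)
#' fit <- sat_fit(log, task, "lpp", n_starts = 2)
#' coef(fit)
#' @export
sat_fit <- function(log, task, variant = c("dlpp", "lpp", "fb", "dfb"),
                    depth_prior = rep(1 / 3, 3), n_starts = 5L, seed = 1L,
                    maxit = 500L, reltol = 1e-8,
                    prior_sd = c(alpha = 2, beta = 0.5, theta = 2, kappa = 3),
                    rho_init = NULL) {
  variant <- match.arg(variant)
  rp <- prepare_replay(log, task)
  if (!any(rp$analysis)) stop("log has no analysis mini-blocks")
  config <- task$config
  free <- variant_params(variant)
  w <- 0.5 / prior_sd[free]^2
  obj <- function(x) {
    p <- to_natural(x, free)
    ll <- session_loglik(rp, p, variant, config, depth_prior,
                         rho_init)$logLik
    if (!is.finite(ll)) return(1e12)
    -(ll - sum(w * x^2))
  }
  base <- list(alpha = 0.3, beta = 1, theta = 0, kappa = 2)
  starts <- list(to_unconstrained(base, free))
  if (n_starts > 1L) {
    draws <- run_with_seed(seed, replicate(n_starts - 1L, {
      s <- list(alpha = stats::runif(1, 0.05, 0.95),
                beta = exp(stats::runif(1, log(0.2), log(5))),
                theta = stats::runif(1, -1, 1),
                kappa = stats::runif(1, 0.5, 25))
      to_unconstrained(s, free)
    }, simplify = FALSE))
    starts <- c(starts, draws)
  }
  runs <- lapply(starts, function(x0)
    stats::optim(x0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol)))
  val <- vapply(runs, `[[`, 0, "value")
  nrm <- vapply(runs, function(r) sum(r$par^2), 0)
  best <- order(val, nrm)[1L]  # highest penalized lnL, then smallest norm
  fit <- runs[[best]]
  coefs <- unlist(to_natural(fit$par, free))
  res <- session_loglik(rp, as.list(coefs), variant, config, depth_prior,
                        rho_init)
  an <- rp$analysis
  structure(list(
    variant = variant,
    coefficients = coefs,
    logLik = res$logLik,
    df = length(free) + 1L,  # + the planning-depth mixture
    n_choices = 3L * sum(an),
    n_blocks = sum(an),
    depth_posterior = structure(res$posterior[an, , drop = FALSE],
                                dimnames = list(task$blocks$index[an],
                                                paste0("d", 1:3))),
    conditions = task$blocks$noise[an],
    convergence = fit$convergence,
    starts = data.frame(start = seq_along(runs), value = -val,
                        convergence = vapply(runs, `[[`, 0L,
                                             "convergence")),
    depth_prior = depth_prior,
    settings = list(n_starts = n_starts, seed = seed, maxit = maxit,
                    reltol = reltol, prior_sd = prior_sd,
                    rho_init = rho_init),
    task = task,
    call = match.call()),
    class = "sat_fit")
}

#' @export
print.sat_fit <- function(x, digits = 3, ...) {
  cat("Planning model fit (variant:", toupper(x$variant), ")\n")
  print(round(x$coefficients, digits))
  cat("log-likelihood:", format(x$logLik, digits = 6), "on", x$n_choices,
      "choices (", x$n_blocks, "mini-blocks )\n")
  cat("mean planning depth:",
      round(mean(x$depth_posterior %*% (1:3)), digits), "\n")
  invisible(x)
}

#' @export
coef.sat_fit <- function(object, ...) object$coefficients

#' @export
logLik.sat_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_choices,
            class = "logLik")
}

#' @export
summary.sat_fit <- function(object, ...) {
  ll <- object$logLik
  out <- list(variant = object$variant,
              coefficients = object$coefficients,
              logLik = ll,
              n_choices = object$n_choices,
              pseudo_rho2 = pseudo_rho2(ll, object$n_choices),
              bic = sat_bic(ll, object$df, object$n_choices),
              depth_by_condition = depth_summary(object),
              convergence = object$convergence)
  class(out) <- "summary.sat_fit"
  out
}

#' @export
print.summary.sat_fit <- function(x, digits = 3, ...) {
  cat("Planning model fit (variant:", toupper(x$variant), ")\n\n")
  print(round(x$coefficients, digits))
  cat("\nlog-likelihood:", format(x$logLik, digits = 6),
      "  pseudo-rho^2:", round(x$pseudo_rho2, digits),
      "  BIC:", round(x$bic, 2), "\n")
  cat("mean planning depth:",
      paste(names(x$depth_by_condition),
            round(x$depth_by_condition, digits), collapse = " | "), "\n")
  invisible(x)
}

#' Fitted choice probabilities
#'
#' @param object a [sat_fit()] object.
#' @param log the choice log the model was fitted to (the fit stores only
#'   the task, not the raw choices).
#' @param ... unused.
#' @return Data frame with, per analysis-block step, the fitted probability
#'   of choosing jump under each planning depth and under the depth prior
#'   mixture.
#' @export
predict.sat_fit <- function(object, log, ...) {
  stopifnot(inherits(object, "sat_fit"))
  task <- object$task
  rp <- prepare_replay(log, task)
  p <- as.list(object$coefficients)
  pj <- fitted_pjump(rp, p, object$variant, task$config)
  an <- rep(rp$analysis, each = 3L)
  out <- data.frame(mini_block = rep(task$blocks$index, each = 3L),
                    step = rep(1:3, rp$B))
  out <- cbind(out, pj)
  out$p_mix <- as.numeric(as.matrix(pj) %*% object$depth_prior)
  out[an, , drop = FALSE]
}

# p(jump) per step and depth at given parameters.
fitted_pjump <- function(rp, p, variant, config) {
  B <- rp$B
  true_rho <- config$noise_levels[rp$cond]
  pruning <- variant %in% c("lpp", "dlpp")
  rho_bel <- if (pruning) NULL
  else belief_trajectory(rp, p$alpha, unname(config$noise_levels))
  gam <- switch(variant,
                fb = , lpp = matrix(1, 3L, B),
                dfb = discount_factor(rho_bel, p$kappa),
                dlpp = matrix(discount_factor(true_rho, p$kappa), 3L, B,
                              byrow = TRUE))
  out <- matrix(NA_real_, 3L * B, 3L,
                dimnames = list(NULL, paste0("p_jump_d", 1:3)))
  cols <- seq_len(B)
  for (t in 1:3) {
    rho_t <- if (pruning) rep(1, B) else rho_bel[t, ]
    lv <- q_levels(rp$rewards, rho_t, config, min(3L, 4L - t))
    idx <- cbind(rp$states[t, ] + 1L, cols)
    for (d in 1:3) {
      h <- min(d, 4L - t)
      x <- p$beta * (gam[t, ] * lv$q_jump[[h]][idx] -
                       lv$q_move[[h]][idx]) / config$point_scale + p$theta
      out[t + 3L * (cols - 1L), d] <- stats::plogis(x)
    }
  }
  as.data.frame(out)
}

#' @export
plot.sat_fit <- function(x, ...) {
  ed <- x$depth_posterior %*% (1:3)
  means <- colMeans(x$depth_posterior)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(means, names.arg = 1:3,
                    xlab = "planning depth", ylab = "mean posterior mass",
                    main = paste("Variant", toupper(x$variant)), ...)
  graphics::boxplot(split(as.numeric(ed), x$conditions),
                    ylab = "expected depth E[d]", xlab = "noise condition")
  invisible(x)
}

#' Simulate choice logs from a fitted model
#'
#' Posterior-predictive style simulation: participants with the fitted
#' parameters are simulated on the fitted task, with per-mini-block depths
#' drawn from the depth prior.
#'
#' @param object a `sat_fit`.
#' @param nsim number of simulated participants.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` choice-log data frames.
#' @export
simulate.sat_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_participant(object$task, object$variant,
                         as.list(object$coefficients),
                         depth = object$depth_prior,
                         participant_id = sprintf("ppsim%02d", i)))
}

#' Mean inferred planning depth per noise condition
#'
#' Averages the per-mini-block expected planning depth
#' `E[d] = sum_d d * posterior(d)` over the analysis mini-blocks of each
#' noise condition.
#'
#' @param fit a [sat_fit()] object.
#' @return Named numeric vector `c(low = , high = , overall = )`.
#' @export
depth_summary <- function(fit) {
  stopifnot(inherits(fit, "sat_fit"))
  ed <- as.numeric(fit$depth_posterior %*% (1:3))
  c(low = mean(ed[fit$conditions == "low"]),
    high = mean(ed[fit$conditions == "high"]),
    overall = mean(ed))
}

#' Fit several model variants to a cohort of choice logs
#'
#' Batch driver: fits each participant's log under each requested variant,
#' capturing failures without aborting the batch.
#'
#' @param cohort a [generate_cohort()] result, or a list with elements
#'   `logs` (list of choice logs) and `task`.
#' @param variants model variants to fit.
#' @param ... further arguments passed to [sat_fit()].
#' @return List with `fits` (participants x variants nested list) and
#'   `summary` (data frame of per-fit indices: log-likelihood, k, n,
#'   pseudo-rho^2, BIC, convergence).
#' @export
cohort_fit <- function(cohort, variants = sat_variants(), ...) {
  logs <- cohort$logs
  task <- cohort$task
  ids <- names(logs)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_along(logs))
  fits <- vector("list", length(logs))
  names(fits) <- ids
  rows <- list()
  for (i in seq_along(logs)) {
    fits[[i]] <- list()
    for (v in variants) {
      f <- tryCatch(sat_fit(logs[[i]], task, v, ...),
                    error = function(e) e)
      fits[[i]][[v]] <- f
      rows[[length(rows) + 1L]] <- if (inherits(f, "error")) {
        data.frame(participant_id = ids[i], variant = v,
                   logLik = NA_real_, k = NA_integer_, n = NA_integer_,
                   pseudo_rho2 = NA_real_, bic = NA_real_,
                   convergence = NA_integer_, error = conditionMessage(f))
      } else {
        data.frame(participant_id = ids[i], variant = v, logLik = f$logLik,
                   k = f$df, n = f$n_choices,
                   pseudo_rho2 = pseudo_rho2(f$logLik, f$n_choices),
                   bic = sat_bic(f$logLik, f$df, f$n_choices),
                   convergence = f$convergence, error = NA_character_)
      }
    }
  }
  list(fits = fits, summary = do.call(rbind, rows))
}
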