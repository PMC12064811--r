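#' McFadden-style pseudo-rho-squared against the binary-chance model
#'
#' `1 - lnL / (n * ln 0.5)`: the proportional log-likelihood improvement
#' over a model that picks each of the two actions with probability 0.5.
#' 0 for chance-level fit, 1 for perfect prediction.
#'
#' @param logLik total log-likelihood of the fitted model.
#' @param n_choices number of binary choices.
#' @return Value in `(-Inf, 1]`.
#' @export
pseudo_rho2 <- function(logLik, n_choices) {
  stopifnot(n_choices >= 1)
  1 - logLik / (n_choices * log(0.5))
}

#' Bayesian Information Criterion
#'
#' `k * ln(n) - 2 * lnL`; lower is better.  The package convention counts
#' `k` as the variant's free continuous parameters plus one for the
#' planning-depth mixture (FB 4, DFB 5, LPP 3, DLPP 4) and `n` as the
#' number of choices (3 per analysis mini-block).
#'
#' @param logLik total log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations.
#' @return BIC value.
#' @export
sat_bic <- function(logLik, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * logLik
}

#' Evidence band of a pairwise BIC difference
#'
#' Labels `|BIC_a - BIC_b|` with the conventional strength-of-evidence
#' bands: `[0, 2]` "bare mention", `(2, 6]` "positive", `(6, 10]` "strong",
#' `> 10` "very strong".
#'
#' @param bic_a,bic_b BIC values of the two models.
#' @return List with `delta` (the absolute difference) and `band`.
#' @export
delta_bic_label <- function(bic_a, bic_b) {
  stopifnot(is.finite(bic_a), is.finite(bic_b))
  d <- abs(bic_a - bic_b)
  band <- if (d <= 2) "bare mention"
  else if (d <= 6) "positive"
  else if (d <= 10) "strong"
  else "very strong"
  list(delta = d, band = band)
}

#' Model comparison table for a fitted cohort
#'
#' Aggregates per-participant fit indices by variant (mean across
#' participants, the group-level convention) and labels all pairwise BIC
#' differences with evidence bands.
#'
#' @param cohort_fits a [cohort_fit()] result.
#' @return List with `by_variant` (data frame: variant, mean lnL, mean
#'   pseudo-rho^2, mean BIC, n participants) and `delta_bic` (data frame of
#'   pairwise mean-BIC differences with bands).
#' @export
comparison_table <- function(cohort_fits) {
  s <- cohort_fits$summary
  s <- s[!is.na(s$bic), ]
  agg <- do.call(rbind, lapply(split(s, s$variant), function(g)
    data.frame(variant = g$variant[1], logLik = mean(g$logLik),
               pseudo_rho2 = mean(g$pseudo_rho2), bic = mean(g$bic),
               n_participants = nrow(g))))
  rownames(agg) <- NULL
  vs <- agg$variant
  pairs <- utils::combn(seq_along(vs), 2)
  dd <- apply(pairs, 2, function(ij) {
    lab <- delta_bic_label(agg$bic[ij[1]], agg$bic[ij[2]])
    data.frame(model_a = vs[ij[1]], model_b = vs[ij[2]],
               delta_bic = lab$delta, band = lab$band)
  })
  list(by_variant = agg, delta_bic = do.call(rbind, dd))
}

#' Model-recovery confusion matrix
#'
#' Validates the model-comparison machinery on synthetic ground truth: for
#' each generating variant, simulates `n_per_variant` participants on a
#' shared task, fits all four variants to every log, and records which
#' variant attains the lowest BIC.  Entry `(g, f)` of the returned matrix
#' is the fraction of `g`-generated participants best fitted by `f`.
#'
#' @param task a [generate_task()] session shared by all cohorts.
#' @param n_per_variant participants per generating variant.
#' @param beta generating inverse temperature (fixed across participants).
#' @param theta_range,alpha_range,kappa_range uniform sampling ranges of
#'   the remaining generating parameters (kappa is only used by the
#'   discounted variants, alpha by the full-breadth variants).
#' @param depth_dist generating distribution over planning depths.
#' @param seed master seed.
#' @param ... further arguments passed to [sat_fit()] (e.g. `n_starts`).
#' @return List with `confusion` (4 x 4 matrix of winner fractions,
#'   generators in rows), `summary` (all per-fit indices) and `winners`.
#' @export
model_recovery <- function(task, n_per_variant = 20L, beta = 2,
                           theta_range = c(-0.3, 0.3),
                           alpha_range = c(0.1, 0.5),
                           kappa_range = c(5, 20),
                           depth_dist = rep(1 / 3, 3), seed = 1L, ...) {
  variants <- sat_variants()
  conf <- matrix(0, 4L, 4L, dimnames = list(generator = variants,
                                            fitted = variants))
  all_summ <- list()
  winners <- list()
  for (g in seq_along(variants)) {
    gv <- variants[g]
    spec <- cohort_spec(n_per_variant, gv,
                        param_ranges = list(alpha = alpha_range,
                                            beta = c(beta, beta),
                                            theta = theta_range,
                                            kappa = kappa_range),
                        depth_dist = depth_dist, seed = seed + g)
    cohort <- generate_cohort(spec, task = task)
    cf <- cohort_fit(cohort, variants = variants, ...)
    s <- cf$summary
    s$generator <- gv
    all_summ[[gv]] <- s
    win <- vapply(split(s, s$participant_id), function(p)
      p$variant[which.min(p$bic)], "")
    winners[[gv]] <- win
    tab <- table(factor(win, levels = variants))
    conf[g, ] <- as.numeric(tab) / n_per_variant
  }
  list(confusion = conf, summary = do.call(rbind, all_summ),
       winners = winners)
}
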