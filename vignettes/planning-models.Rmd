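---
title: "Planning strategies and probability discounting in a sequential probabilistic task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning strategies and probability discounting in a sequential probabilistic task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satplan)
```

## The task

`satplan` models behaviour in a three-step probabilistic planning task.
On each *mini-block* the agent sees a ring of six planets (a
*constellation* drawn from five planet types worth between -20 and +20
fuel points under the default configuration) and a starting position, and
has exactly three action steps.  At every step two actions are available:

* **move** — deterministic, one position clockwise;
* **jump** — to a fixed non-neighbouring target position (the package
  default is the diametrically opposite planet).  The jump succeeds with
  probability $\rho$ and otherwise lands on one of the two ring
  neighbours of the target, each with probability $(1-\rho)/2$.

Transition noise comes in two cued conditions: *low* noise
($\rho = 0.9$, misses 5% per neighbour) and *high* noise ($\rho = 0.5$,
25% per neighbour).  A session holds 140 mini-blocks; the noise condition
alternates in pseudo-random runs of 3–6 consecutive mini-blocks, 70 per
condition, and the first 10 mini-blocks of each condition are treated as
training and excluded from analysis, leaving 120 analysis mini-blocks.
Each step earns the action's fuel cost plus the reward of the planet
reached; the goal is to maximise total fuel.

## The four planning models

All models compute action values by finite-horizon value iteration
(backward induction).  With planning depth $d \in \{1,2,3\}$, step $t$
and horizon $h = \min(d, T - t + 1)$,

$$Q(s_t, a_t, d) = \sum_{s_{t+1}} p(s_{t+1}\mid s_t,a_t)
  \left[c(a_t) + r(s_{t+1}) + V(s_{t+1}, d)\right],$$

where $V$ is zero beyond the horizon and the maximum over actions
otherwise.  Temporal discounting inside the tree is fixed at 1 (it is not
jointly identifiable with planning depth).  Planning is repeated from the
current state at every step, so depth clips at the remaining steps.
Choices follow a softmax on the Q-difference:

$$p(\text{jump}) = \sigma\!\left(\beta\,
  \frac{\gamma_{prob} Q_{jump} - Q_{move}}{s} + \theta\right),$$

with inverse decision temperature $\beta \ge 0$, action bias $\theta$
(negative favours the deterministic move), and point scale $s$ (below).
The four variants differ in the transition model inside the tree and in
the root discount $\gamma_{prob}$:

| variant | tree transitions | $\gamma_{prob}$ | free parameters |
|---|---|---|---|
| `fb` (full breadth) | believed $\rho$ | 1 | $\alpha, \beta, \theta$ |
| `dfb` (discounted full breadth) | believed $\rho$ | $1/(1+\kappa q)$, learned $\rho$ | $\alpha, \beta, \theta, \kappa$ |
| `lpp` (low-probability pruning) | deterministic ($\rho \equiv 1$) | 1 | $\beta, \theta$ |
| `dlpp` (discounted pruning) | deterministic | $1/(1+\kappa q)$, true $\rho$ | $\beta, \theta, \kappa$ |

Here $q = (1-\rho)/\rho$ is the odds against a successful jump and
$\kappa \in [0, 30]$ the hyperbolic discounting parameter
(`discount_factor()`); $\kappa = 0$ recovers the undiscounted parent
model exactly, a property the test suite asserts at machine precision.
Discounting is applied once, at the root comparison of the two actions —
not recursively inside the tree, which would be a different model.
Full-breadth variants learn the jump success probability per noise
condition by the TD rule
$\rho_{t+1} = \rho_t + \alpha(o_t - \rho_t)$, applied only after jump
outcomes of the matching condition, in presentation order across the
whole session (training blocks included, since they are experienced).
Beliefs start at the true values (0.9, 0.5).

Pruning cuts the planning tree from four outcome branches per step (one
move + three jump outcomes) to two, i.e. from $4^3 = 64$ to $2^3 = 8$
branches for a three-step plan (`branch_count()`).

## Units: the point scale

Q-values are computed in fuel points, but the softmax operates on values
divided by `point_scale` (default 10 points, one planet-type step).  This
calibration makes the conventional magnitudes of $\beta$ (around 1–3),
$\theta$ (around $\pm 0.3$) and $\kappa$ (0–30) produce realistically
noisy behaviour; with raw fuel points, $\beta = 2$ would already make
choices deterministic and $\beta$, $\theta$ would be unidentifiable from
data.  The scale is part of the task configuration and all analyses are
parameterized over it.

## Likelihood and planning-depth mixture

Planning depth is modelled at the mini-block level.  For one mini-block
the likelihood under depth $d$ is the product of the softmax
probabilities of the observed actions over all three steps
(`miniblock_likelihood()`); the marginal likelihood mixes over depths
with a uniform prior (`depth_mixture_likelihood()`):

$$p(a_b \mid s_b) = \sum_{d=1}^{3} p(d_b = d)\, p(a_b \mid s_b, d_b = d).$$

The session log-likelihood (`sat_loglik()`) sums the log mixture over the
120 analysis mini-blocks; all likelihood products are accumulated in log
space.  The per-block depth posterior
$p(d \mid a_b) \propto p(d)\,p(a_b \mid s_b, d)$ is returned alongside,
and `depth_summary()` reports the expected depth averaged per noise
condition.

## Fitting: penalized maximum likelihood

`sat_fit()` maximises the mixture likelihood per participant with
multi-start Nelder–Mead (5 starts by default: one fixed, the rest drawn
reproducibly from the fit seed) on an unconstrained scale: logit for
$\alpha$, log for $\beta$, identity for $\theta$, and a scaled logit for
$\kappa$ on $[0, 30]$.  Ties between starts resolve to the highest
objective, then the smallest parameter norm.  The objective includes
independent Gaussian priors on the unconstrained parameters (sd 2 for
logit $\alpha$, 0.5 for $\log\beta$, 2 for $\theta$, 3 for the $\kappa$
logit).  The $\log\beta$ prior is the one that matters: softmax
likelihoods combined with per-block latent depths have
near-deterministic ridges along which $\beta$ (with a compensating
$\theta$) runs away on finite data, and a prior on the scale of the
plausible between-participant spread of $\log\beta$ keeps estimates
interior without materially biasing moderate values.  A hierarchical
(group-level) Bayesian backend would achieve the same shrinkage; the
per-participant penalized-ML backend was chosen for determinism and
desk-scale testability, and the package's conclusions depend on the
likelihood, not the fitting engine.

Convergence settings: relative tolerance $10^{-8}$, at most 500
iterations per start.  Belief trajectories of full-breadth variants are
reconstructed exactly from the log's recorded jump outcomes (they are
deterministic given $\alpha$), so no latent state needs to be inferred.

## Model comparison

`pseudo_rho2()` is McFadden-style improvement over the two-alternative
chance model, $1 - \ln L / (n \ln 0.5)$.  `sat_bic()` uses
$k \ln n - 2 \ln L$ with $n$ the number of choices (360 per participant:
3 per analysis mini-block) and $k$ counting the variant's free
continuous parameters plus one for the depth mixture — FB 4, DFB 5,
LPP 3, DLPP 4.  Pairwise BIC differences are labelled with the
conventional evidence bands ("bare mention" $\le 2$ < "positive" $\le 6$
< "strong" $\le 10$ < "very strong"; `delta_bic_label()`).
`model_recovery()` validates the machinery end-to-end: simulate cohorts
from each variant, fit all four to every log, and tabulate which variant
wins by BIC.

## The synthetic-data generator and what it does (not) show

`generate_task()`, `simulate_participant()` and `generate_cohort()`
emulate the study's structure: 140 mini-blocks with the 70/70 noise split
and 3–6 run lengths, constellations sampled uniformly over planet kinds,
uniform start positions, participant-level parameters drawn uniformly
from configurable ranges, and mini-block-level planning depths drawn from
a configurable distribution.  One master seed derives per-participant
sub-seeds, so cohorts are exactly reproducible.

Default configuration choices, made once:

* planet rewards $\{-20, -10, 0, 10, 20\}$ — five types spanning
  symmetric losses and gains;
* action costs: move 0, jump $-2$ fuel points.  The jump cost is
  calibrated so that a random ($\beta = 0$) agent loses roughly 400
  points over a session from 1000 initial fuel, reproducing the scale on
  which a below-chance exclusion threshold near 650 points is meaningful
  (`reference_points()` returns that threshold);
* jump target: the diametrically opposite planet, the natural
  fixed-point-free pattern that avoids the move edge.

The generator does not emulate several features of real data: response
times, motor slips, within-session fatigue or strategy switching,
hand-designed constellations (the uniform sampling occasionally produces
mini-blocks where all paths are poor), or hierarchical group structure
beyond independent per-participant draws.  Passing recovery tests
therefore show that the estimator identifies its own generative model at
realistic sizes — not that human data satisfy these assumptions.

## Performance benchmarking

`reference_points()` anchors a relative performance scale per noise
condition: 0% is the mean total of 1000 random agents
($\beta = 0, d = 3, \theta = 0$) and 100% the mean total of 1000
full-breadth optimal agents ($\beta = 3, d = 3, \theta = 0$) — softmax
with $\beta = 3$, not argmax, so individual agents can exceed 100%.
`strategy_sweep()` simulates all four strategies at depths 1–3 under the
same $\beta = 3$ convention (discounted variants at $\kappa = 3$) and
reports mean relative performance per condition next to the branch
count, reproducing the efficiency comparison: pruning at depth 3 is
near-optimal under low noise and about 89% of optimal under high noise
at one-eighth of the planning effort, and adding discounting only lowers
the pruning strategy's efficiency.  `condition_imbalance()` quantifies
the task's structural asymmetry: optimal planners earn substantially
more points under low than under high noise (tens of percent), which is
why performance is reported on the relative scale.  Both quantities
depend on the stimulus set; the imbalance ratio in particular is highly
variable across freshly sampled sessions because its denominator — mean
high-noise totals — is small.

## Numerical choices and degenerate inputs

* Backward-induction levels are computed vectorized across mini-blocks;
  the test suite checks them against a brute-force expectimax
  enumeration at $10^{-9}$.
* Log-likelihoods use `plogis(log.p = TRUE)`; probabilities never
  underflow to zero in log space.
* Depth posteriors are computed by log-sum-exp; a depth with zero prior
  mass has exactly zero posterior.
* `discount_factor()` rejects $\rho = 0$ (odds undefined); $\kappa$ is
  capped at 30, beyond which the discount saturates without adding
  information.
* Jump-success flags are *not applicable* (NA) for move actions, so TD
  updates can never fire on moves.
* Run-length compositions for the noise schedule are re-drawn until the
  two conditions' run counts differ by at most one, which strict
  alternation requires; for 70 blocks with runs of 3–6 this always
  terminates quickly.

## Problem sizes used in the shipped experiments

The packaged tests run the recovery experiments at the sizes stated
above: parameter recovery on a 50-participant discounted-pruning cohort
(120 analysis mini-blocks each), depth-distribution recovery on
10-participant cohorts, and model recovery with 20 participants per
generating variant fitted under all four variants.  Agent benchmarks use
1000 agents per cell.  These sizes give stable Monte-Carlo estimates
(correlation targets, plurality confusion-matrix wins) while keeping a
full run at desk scale.

## Known limitations

* The default configuration is a package choice in the spirit of the
  original task family, not the original stimulus files; quantities that
  depend on the stimulus distribution (the 89% and 37% figures) are
  approximate reproductions.
* Large $\kappa$ is weakly identified — the discount saturates — so
  recovery correlations for $\kappa$ hover near 0.8 when the generating
  range spans the full $[0, 30]$.
* The default backend fits participants independently; group-level
  shrinkage, posterior uncertainty and hierarchical hypotheses are out
  of scope.
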