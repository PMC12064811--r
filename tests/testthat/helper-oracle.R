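# Brute-force expectimax oracle: plain recursion over every outcome branch
# of the planning tree, independent of the package's backward-induction
# tables.  Values are exact expectations with max over actions at interior
# nodes.
oracle_q <- function(state, horizon, rewards, rho, config) {
  cm <- config$action_costs[["move"]]
  cj <- config$action_costs[["jump"]]
  v <- function(s, h) {
    if (h == 0L) return(0)
    max(q(s, h))
  }
  q <- function(s, h) {
    mv <- (s + 1L) %% 6L
    qm <- cm + rewards[mv + 1L] + v(mv, h - 1L)
    tgt <- config$jump_map[s + 1L]
    outs <- c(tgt, (tgt - 1L) %% 6L, (tgt + 1L) %% 6L)
    ps <- c(rho, (1 - rho) / 2, (1 - rho) / 2)
    qj <- 0
    for (i in 1:3)
      qj <- qj + ps[i] * (cj + rewards[outs[i] + 1L] +
                            v(outs[i], h - 1L))
    c(jump = qj, move = qm)
  }
  q(state, horizon)
}

# Exact expected total points of a fixed action sequence, by enumerating
# the full outcome tree of the episode (no policy: actions are fixed).
oracle_rollout_mean <- function(miniblock, actions, config) {
  rho <- config$noise_levels[[miniblock$noise]]
  rec <- function(s, k) {
    if (k > length(actions)) return(0)
    if (actions[k] == "move") {
      nxt <- (s + 1L) %% 6L
      return(config$action_costs[["move"]] + miniblock$rewards[nxt + 1L] +
               rec(nxt, k + 1L))
    }
    tgt <- config$jump_map[s + 1L]
    outs <- c(tgt, (tgt - 1L) %% 6L, (tgt + 1L) %% 6L)
    ps <- c(rho, (1 - rho) / 2, (1 - rho) / 2)
    tot <- 0
    for (i in 1:3)
      tot <- tot + ps[i] * (config$action_costs[["jump"]] +
                              miniblock$rewards[outs[i] + 1L] +
                              rec(outs[i], k + 1L))
    tot
  }
  rec(miniblock$start, 1L)
}
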