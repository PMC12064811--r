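#' Task configuration
#'
#' Builds the configuration of the six-planet planning task: the reward of
#' each planet type, the fuel cost of the two actions, the jump transition
#' pattern, and the jump success probability of the two noise conditions.
#'
#' Planet positions are numbered 0--5 clockwise around the ring; the `move`
#' action always advances one position clockwise, the `jump` action targets
#' `jump_map[pos + 1]` and, when it fails, lands on one of the two ring
#' neighbours of the target with equal probability.  The default jump pattern
#' sends the ship to the diametrically opposite planet, which satisfies the
#' task's constraint that the jump target is never the current planet nor its
#' clockwise neighbour.  Default rewards and costs are package defaults in
#' the spirit of the original task (five planet types spanning losses and
#' gains; the risky jump costs more fuel than the safe move); every analysis
#' in the package is parameterized over this configuration.
#'
#' @param planet_rewards numeric vector of length 5: fuel reward of planet
#'   kinds 0--4 (must contain both negative and positive values).
#' @param action_costs named numeric vector with elements `move` and `jump`
#'   (fuel cost of executing each action, typically negative).
#' @param jump_map integer vector of length 6: jump target (0--5) for each
#'   starting position 0--5.  Must be a fixed-point-free permutation with no
#'   `i -> (i + 1) mod 6` edge.
#' @param noise_levels named numeric vector with elements `low` and `high`:
#'   the true jump success probability in each noise condition.
#' @param initial_points fuel points at the start of a session (used for the
#'   below-chance exclusion threshold).
#' @param point_scale fuel points per model value unit.  Q-values are
#'   computed in fuel points but enter the softmax decision variable as
#'   `beta * (gamma * Q_jump - Q_move) / point_scale + theta`; the default
#'   (10 points, one planet-type step) puts the inverse temperature,
#'   action bias and decision noise on the scale conventional for this
#'   task family.
#' @return An object of class `sat_config` (a validated list).
#' @examples
#' cfg <- sat_config()
#' cfg$jump_map
#' @export
sat_config <- function(planet_rewards = c(-20, -10, 0, 10, 20),
                       action_costs = c(move = 0, jump = -2),
                       jump_map = (0:5 + 3) %% 6,
                       noise_levels = c(low = 0.9, high = 0.5),
                       initial_points = 1000, point_scale = 10) {
  cfg <- list(
    planet_rewards = as.numeric(planet_rewards),
    action_costs = c(move = unname(action_costs["move"]),
                     jump = unname(action_costs["jump"])),
    jump_map = as.integer(jump_map),
    noise_levels = c(low = unname(noise_levels["low"]),
                     high = unname(noise_levels["high"])),
    initial_points = as.numeric(initial_points),
    point_scale = as.numeric(point_scale)
  )
  class(cfg) <- "sat_config"
  validate_config(cfg)
  cfg
}

#' Validate a task configuration
#'
#' Checks the structural invariants of a [sat_config()] object: five planet
#' kinds with both gains and losses, a jump map that is a fixed-point-free
#' permutation of 0--5 with non-neighbouring targets, and noise levels in
#' (0, 1].
#'
#' @param config a `sat_config` object.
#' @return `config`, invisibly; errors if any invariant is violated.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "sat_config"))
  r <- config$planet_rewards
  if (length(r) != 5L || anyNA(r))
    stop("planet_rewards must be 5 finite values (planet kinds 0-4)")
  if (!any(r < 0) || !any(r > 0))
    stop("planet_rewards must contain both losses and gains")
  jm <- config$jump_map
  if (length(jm) != 6L || !setequal(jm, 0:5))
    stop("jump_map must be a permutation of positions 0-5")
  pos <- 0:5
  if (any(jm == pos))
    stop("jump_map must have no fixed points")
  if (any(jm == (pos + 1L) %% 6L))
    stop("jump_map target must not be the clockwise (move) neighbour")
  nl <- config$noise_levels
  if (anyNA(nl) || any(nl <= 0) || any(nl > 1))
    stop("noise_levels must lie in (0, 1]")
  if (anyNA(config$action_costs) || length(config$action_costs) != 2L)
    stop("action_costs must contain move and jump")
  if (!is.numeric(config$point_scale) || config$point_scale <= 0)
    stop("point_scale must be a positive number")
  invisible(config)
}

#' @export
print.sat_config <- function(x, ...) {
  cat("Six-planet planning task configuration\n")
  cat("  planet rewards (kinds 0-4):", x$planet_rewards, "\n")
  cat("  action costs: move", x$action_costs["move"],
      "| jump", x$action_costs["jump"], "\n")
  cat("  jump map:", paste(0:5, "->", x$jump_map, collapse = ", "), "\n")
  cat("  jump success: low noise", x$noise_levels["low"],
      "| high noise", x$noise_levels["high"], "\n")
  cat("  initial fuel:", x$initial_points,
      "| point scale:", x$point_scale, "\n")
  invisible(x)
}

#' Write / read a task configuration as JSON
#'
#' @param config a `sat_config` object.
#' @param path file path.
#' @return `read_config_json` returns a `sat_config`; `write_config_json`
#'   returns `path` invisibly.
#' @export
write_config_json <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sat_config(planet_rewards = x$planet_rewards,
             action_costs = c(move = x$action_costs[[1]],
                              jump = x$action_costs[[2]]),
             jump_map = x$jump_map,
             noise_levels = c(low = x$noise_levels[[1]],
                              high = x$noise_levels[[2]]),
             initial_points = x$initial_points,
             point_scale = if (is.null(x$point_scale)) 10 else x$point_scale)
}
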