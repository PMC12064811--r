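# Choice-log CSV schema, in column order.
choice_log_columns <- function() {
  c("participant_id", "mini_block", "phase", "noise", "step", "state",
    "action", "outcome", "jump_success", "reward", "cum_points")
}

#' Write a choice log to CSV
#'
#' One row per action step; mini-block indices are 1-based, planet
#' positions 0-based.  `jump_success` is empty for move steps.
#'
#' @param log choice-log data frame (see [simulate_participant()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_choice_log <- function(log, path) {
  cols <- choice_log_columns()
  stopifnot(all(cols %in% names(log)))
  utils::write.csv(log[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a choice log
#'
#' Reads a choice-log CSV and validates it against a task configuration:
#' steps must be contiguous 1..3 within each mini-block, states and
#' outcomes must be positions 0--5, move outcomes must equal
#' `(state + 1) mod 6`, jump outcomes must lie in the jump action's support
#' (the target or one of its two ring neighbours), and `jump_success` must
#' be consistent with whether the target was reached.
#'
#' @param path CSV file path.
#' @param config task configuration used for transition-support checks.
#' @return The validated choice-log data frame.  Validation problems are
#'   collected and raised together as an error listing the offending rows.
#' @export
read_choice_log <- function(path, config = sat_config()) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(log) == 0L) stop("empty choice log: ", path)
  missing_cols <- setdiff(choice_log_columns(), names(log))
  if (length(missing_cols))
    stop("choice log lacks columns: ", paste(missing_cols, collapse = ", "))
  log$jump_success <- as.logical(log$jump_success)
  problems <- validate_choice_log(log, config)
  if (length(problems))
    stop("invalid choice log:\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "))
  log
}

# Returns a character vector of validation problems (empty when valid).
validate_choice_log <- function(log, config = sat_config()) {
  problems <- character(0)
  note <- function(rows, msg)
    sprintf("row %d: %s", rows, msg)
  bad <- which(!(log$state %in% 0:5) | !(log$outcome %in% 0:5))
  problems <- c(problems, note(bad, "state/outcome outside positions 0-5"))
  bad <- which(!(log$action %in% c("move", "jump")))
  problems <- c(problems, note(bad, "unknown action label"))
  bad <- which(!(log$noise %in% c("low", "high")))
  problems <- c(problems, note(bad, "unknown noise label"))
  ok <- log$action %in% c("move", "jump") & log$state %in% 0:5 &
    log$outcome %in% 0:5
  mv <- ok & log$action == "move"
  bad <- which(mv & log$outcome != (log$state + 1L) %% 6L)
  problems <- c(problems,
                note(bad, "move outcome is not the clockwise neighbour"))
  jp <- ok & log$action == "jump"
  if (any(jp)) {
    tgt <- config$jump_map[log$state + 1L]
    nb <- ring_neighbours(tgt)
    support <- log$outcome == tgt | log$outcome == nb[, 1L] |
      log$outcome == nb[, 2L]
    bad <- which(jp & !support)
    problems <- c(problems,
                  note(bad, "jump outcome outside the transition support"))
    bad <- which(jp & support & is.na(log$jump_success))
    problems <- c(problems, note(bad, "jump step lacks jump_success"))
    bad <- which(jp & support & !is.na(log$jump_success) &
                   log$jump_success != (log$outcome == tgt))
    problems <- c(problems,
                  note(bad, "jump_success inconsistent with outcome"))
  }
  for (pid in unique(log$participant_id)) {
    sub <- log[log$participant_id == pid, ]
    for (mb in unique(sub$mini_block)) {
      st <- sort(sub$step[sub$mini_block == mb])
      if (!identical(as.integer(st), seq_len(length(st))) ||
          length(st) != 3L)
        problems <- c(problems,
                      sprintf("participant %s mini-block %s: steps not contiguous 1..3",
                              pid, mb))
    }
  }
  problems
}

#' Write / read a task session as JSON
#'
#' Serializes the mini-block table, the constellations and the
#' configuration of a [generate_task()] session.
#'
#' @param task a `sat_task`.
#' @param path file path.
#' @return `read_task_json` returns a `sat_task`; `write_task_json` returns
#'   `path` invisibly.
#' @export
write_task_json <- function(task, path) {
  jsonlite::write_json(list(blocks = task$blocks,
                            constellations = task$constellations,
                            config = unclass(task$config)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_task_json
#' @export
read_task_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- sat_config(planet_rewards = x$config$planet_rewards,
                    action_costs = c(move = x$config$action_costs[[1]],
                                     jump = x$config$action_costs[[2]]),
                    jump_map = x$config$jump_map,
                    noise_levels = c(low = x$config$noise_levels[[1]],
                                     high = x$config$noise_levels[[2]]),
                    initial_points = x$config$initial_points)
  structure(list(blocks = as.data.frame(x$blocks),
                 constellations = matrix(as.integer(x$constellations),
                                         nrow = nrow(x$constellations)),
                 config = cfg),
            class = "sat_task")
}
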