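#' Timed steering command
#'
#' A runtime parameter change, addressed by structural-update iteration.
#' Commands take effect at the boundary of the iteration they name: the
#' interval simulated for that iteration already runs with the new value, and
#' parameter values recorded in the trajectory only ever change at update
#' boundaries.
#'
#' @param when structural-update iteration (>= 0) at which the command applies.
#' @param kind one of `set_nu`, `set_eta`, `set_update_interval`, `pause`,
#'   `resume`, `save_state`, `load_state`.
#' @param population target population name, or `NA` for all.
#' @param element_type target element type, or `NA` for all types on the
#'   targeted population(s).
#' @param value new parameter value (elements/ms for `set_nu`, spikes/s for
#'   `set_eta`, ms for `set_update_interval`, a path for `save_state`).
#' @return one-row data.frame of class `steering_command`.
#' @export
steering_command <- function(when, kind, population = NA_character_,
                             element_type = NA_character_, value = NA) {
  kinds <- c("set_nu", "set_eta", "set_update_interval", "pause", "resume",
             "save_state", "load_state")
  if (!kind %in% kinds) stop("unknown command kind: ", kind)
  stopifnot(when >= 0)
  cmd <- data.frame(when = as.integer(when), kind = kind,
                    population = as.character(population),
                    element_type = as.character(element_type),
                    value = if (kind == "save_state" || kind == "load_state")
                      as.character(value) else as.numeric(value),
                    stringsAsFactors = FALSE)
  class(cmd) <- c("steering_command", "data.frame")
  cmd
}

#' Assemble a command log from commands
#'
#' @param ... [steering_command()]s (or data.frames of them).
#' @return data.frame of class `command_log`, sorted by `when`.
#' @export
command_log <- function(...) {
  cmds <- list(...)
  log <- if (length(cmds)) do.call(rbind, lapply(cmds, as.data.frame))
         else empty_command_log()
  log <- log[order(log$when), , drop = FALSE]
  rownames(log) <- NULL
  class(log) <- c("command_log", "data.frame")
  log
}

empty_command_log <- function() {
  log <- data.frame(when = integer(), kind = character(),
                    population = character(), element_type = character(),
                    value = character(), applied_at = integer(),
                    stringsAsFactors = FALSE)
  class(log) <- c("command_log", "data.frame")
  log
}

#' Read / write a steering schedule as CSV
#'
#' Columns: `when` (iteration), `kind`, `population`, `element_type`, `value`.
#' @param path file path.
#' @param log a `command_log` (for writing).
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(when = "integer", kind = "character",
                                       population = "character",
                                       element_type = "character",
                                       value = "character"))
  df <- df[order(df$when), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("command_log", "data.frame")
  df
}

#' @rdname read_schedule
#' @export
write_schedule <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_bounds <- function(state, param, value) {
  b <- state$struct$param_bounds[[param]]
  if (!is.null(b) && (value < b[1] || value > b[2])) {
    stop("rejected ", param, " = ", value, ": outside configured bounds [",
         b[1], ", ", b[2], "]")
  }
}

#' Apply a steering command to a state
#'
#' Parameter changes mutate the targeted growth curves in place (element
#' counts `z` are preserved) or the update interval; the command is appended
#' to the state's command log with the iteration at which it was applied.
#'
#' @param state a `sim_state`.
#' @param cmd a [steering_command()].
#' @return the updated state.
#' @export
apply_command <- function(state, cmd) {
  stopifnot(inherits(state, "sim_state"))
  cmd <- as.data.frame(cmd)
  kind <- cmd$kind
  if (kind %in% c("set_nu", "set_eta")) {
    sel <- rep(TRUE, nrow(state$pools))
    if (!is.na(cmd$population)) {
      sel <- sel & state$pools$neuron %in% population_ids(state, cmd$population)
    }
    if (!is.na(cmd$element_type)) {
      if (!any(state$pools$element_type == cmd$element_type))
        stop("unknown element type: ", cmd$element_type)
      sel <- sel & state$pools$element_type == cmd$element_type
    }
    if (!any(sel)) stop("command targets no pools")
    value <- as.numeric(cmd$value)
    if (kind == "set_nu") {
      check_bounds(state, "nu", value)
      # steering sets the growth-rate magnitude; each pool keeps its
      # orientation (creation-below vs creation-above target)
      sgn <- ifelse(state$pools$nu[sel] < 0, -1, 1)
      state$pools$nu[sel] <- sgn * value
    } else {
      check_bounds(state, "eta", value)
      bad <- sel & state$pools$eps <= value
      if (any(bad)) stop("rejected eta = ", value,
                         ": must stay below the target rate eps")
      state$pools$eta[sel] <- value
    }
  } else if (kind == "set_update_interval") {
    value <- as.numeric(cmd$value)
    if (value <= 0) stop("rejected update interval ", value, ": must be > 0")
    check_bounds(state, "update_interval", value)
    state$struct$update_interval <- value
  } else if (kind == "pause" || kind == "resume") {
    # wall-clock control only: no effect on dynamics or RNG
  } else if (kind == "save_state") {
    save_snapshot(state, as.character(cmd$value))
  } else if (kind == "load_state") {
    stop("load_state is only supported between runs (use load_snapshot)")
  }
  applied <- as.data.frame(cmd)
  applied$value <- as.character(applied$value)
  applied$applied_at <- state$iteration + 1L  # effective from next boundary
  state$command_log <- rbind(as.data.frame(state$command_log),
                             applied[, c("when", "kind", "population",
                                         "element_type", "value",
                                         "applied_at")])
  class(state$command_log) <- c("command_log", "data.frame")
  state
}

#' Create a CSV file sink for run observables
#'
#' Returns a sink function for [run_with_schedule()] that appends one row per
#' iteration and population, identical in content to the returned trajectory.
#' @param path output CSV path.
#' @export
file_sink <- function(path) {
  cat(paste(trajectory_columns(), collapse = ","), "\n", sep = "", file = path)
  function(event) {
    df <- event_to_rows(event)
    utils::write.table(df, path, sep = ",", append = TRUE, quote = FALSE,
                       col.names = FALSE, row.names = FALSE)
  }
}

trajectory_columns <- function() {
  c("iteration", "time_ms", "population", "rate_spikes_per_s",
    "total_out_connections", "nu", "eta", "update_interval_ms")
}

event_to_rows <- function(event) {
  data.frame(iteration = event$iteration, time_ms = event$time_ms,
             population = names(event$rates),
             rate_spikes_per_s = as.numeric(event$rates),
             total_out_connections = as.integer(event$connections),
             nu = as.numeric(event$nu), eta = as.numeric(event$eta),
             update_interval_ms = event$update_interval_ms,
             stringsAsFactors = FALSE)
}

# one observation event per iteration; delivered synchronously to every sink,
# exactly once each; a sink that errors is disabled and counted, never fatal
publish_event <- function(sinks, event, sink_state) {
  for (k in seq_along(sinks)) {
    if (sink_state$disabled[k]) next
    ok <- tryCatch({ sinks[[k]](event); TRUE },
                   error = function(e) {
                     warning("observer sink ", k, " failed (", conditionMessage(e),
                             "); disabling it", call. = FALSE)
                     FALSE
                   })
    if (!ok) {
      sink_state$disabled[k] <- TRUE
      sink_state$dropped[k] <- sink_state$dropped[k] + 1L
    }
  }
  sink_state
}

# per-population axonal growth parameters for the trajectory record
active_params <- function(state) {
  nu <- eta <- rep(NA_real_, length(state$pop_names))
  for (i in seq_along(state$pop_names)) {
    ids <- population_ids(state, state$pop_names[i])
    ax <- state$pools[state$pools$neuron %in% ids &
                      grepl("^Axon", state$pools$element_type), ]
    if (nrow(ax)) {
      nu[i] <- ax$nu[1]
      eta[i] <- ax$eta[1]
    }
  }
  list(nu = nu, eta = eta)
}

#' Run a simulation under a steering schedule
#'
#' Interleaves [advance()] over one update interval, scheduled
#' [apply_command()]s, and [structural_update()], for `horizon` structural
#' iterations. Commands scheduled for iteration *k* are applied before
#' interval *k* is simulated. Returns the per-iteration trajectory (one row
#' per population): mean filtered rate, total outgoing connections, and the
#' active growth parameters.
#'
#' @param state a `sim_state` (plasticity registered).
#' @param schedule a [command_log()] (may be empty).
#' @param horizon number of structural iterations to run.
#' @param sinks list of sink functions receiving one event per iteration.
#' @param collect_spikes if `TRUE`, spikes of every interval are concatenated
#'   into the result (memory!).
#' @return list with `state`, `trajectory` (data.frame), `sink_status`, and
#'   optionally `spikes`.
#' @export
run_with_schedule <- function(state, schedule = command_log(), horizon,
                              sinks = list(), collect_spikes = FALSE) {
  stopifnot(inherits(state, "sim_state"), horizon >= 0)
  schedule <- as.data.frame(schedule)
  if (nrow(schedule) && is.unsorted(schedule$when)) {
    stop("schedule must be sorted by iteration")
  }
  traj <- vector("list", horizon)
  spikes <- if (collect_spikes) vector("list", horizon) else NULL
  sink_state <- list(disabled = rep(FALSE, length(sinks)),
                     dropped = rep(0L, length(sinks)))
  for (step in seq_len(horizon)) {
    it <- state$iteration + 1L
    due <- schedule[schedule$when == it |
                    (step == 1L & schedule$when < it), , drop = FALSE]
    for (j in seq_len(nrow(due))) {
      state <- apply_command(state, due[j, , drop = FALSE])
    }
    adv <- advance(state, state$struct$update_interval)
    state <- adv$state
    if (collect_spikes) spikes[[step]] <- adv$spikes
    state <- structural_update(state)
    ap <- active_params(state)
    event <- list(iteration = state$iteration, time_ms = state$time,
                  rates = mean_rates(state),
                  connections = outgoing_connections(state),
                  nu = ap$nu, eta = ap$eta,
                  update_interval_ms = state$struct$update_interval)
    traj[[step]] <- event_to_rows(event)
    if (length(sinks)) sink_state <- publish_event(sinks, event, sink_state)
  }
  trajectory <- if (horizon) do.call(rbind, traj) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 8)),
                    trajectory_columns())
  rownames(trajectory) <- NULL
  out <- list(state = state, trajectory = trajectory,
              sink_status = sink_state)
  if (collect_spikes) out$spikes <- do.call(rbind, spikes)
  out
}

#' Run until the connection count plateaus
#'
#' Runs structural iterations until the total connection count changes by
#' less than `tol` (relative) over `window` consecutive update intervals
#' (requiring a non-zero count), or until `max_iter`.
#'
#' @param state a `sim_state`.
#' @param schedule optional [command_log()].
#' @param tol relative change threshold (default 1%).
#' @param window number of consecutive intervals (default 10).
#' @param max_iter hard iteration cap.
#' @param min_iter minimum iterations before a plateau may be declared.
#' @return as [run_with_schedule()], plus `plateau_iteration` (`NA` if the cap
#'   was hit first).
#' @export
run_to_plateau <- function(state, schedule = command_log(), tol = 0.01,
                           window = 10, max_iter = 1000, min_iter = window) {
  counts <- numeric(0)
  trajs <- list()
  plateau <- NA_integer_
  while (state$iteration < max_iter) {
    res <- run_with_schedule(state, schedule, horizon = 1)
    state <- res$state
    trajs[[length(trajs) + 1L]] <- res$trajectory
    counts <- c(counts, nrow(state$conn))
    k <- length(counts)
    if (k >= max(min_iter, window + 1) && counts[k] > 0) {
      ref <- counts[(k - window):k]
      if ((max(ref) - min(ref)) / max(ref) < tol) {
        plateau <- state$iteration
        break
      }
    }
  }
  list(state = state, trajectory = do.call(rbind, trajs),
       plateau_iteration = plateau)
}

#' Measure per-population spike-count firing rates
#'
#' Advances the state by `duration` under frozen-in-time plasticity (the
#' structural machinery keeps running unless `freeze = TRUE`) and returns the
#' average firing rate of each population from actual spike counts.
#'
#' @param state a `sim_state`.
#' @param duration measurement window, ms.
#' @param freeze if `TRUE`, no structural updates are performed during the
#'   measurement.
#' @return list with `rates` (named, spikes/s) and `state`.
#' @export
measure_rates <- function(state, duration = 10000, freeze = FALSE) {
  interval <- state$struct$update_interval
  n_int <- ceiling(duration / interval)
  counts <- stats::setNames(numeric(length(state$pop_names)), state$pop_names)
  for (i in seq_len(n_int)) {
    adv <- advance(state, interval)
    state <- adv$state
    if (nrow(adv$spikes)) {
      tb <- tabulate(state$pop_of[adv$spikes$neuron],
                     nbins = length(state$pop_names))
      counts <- counts + tb
    }
    if (!freeze) state <- structural_update(state)
  }
  tot_ms <- n_int * interval
  sizes <- stats::setNames(state$pop_sizes, state$pop_names)
  list(rates = 1000 * counts / (sizes * tot_ms), state = state)
}

#' Publish the current observables of a state to sinks
#'
#' Emits one event (iteration, time, per-population mean rate, per-population
#' outgoing connections, active growth parameters) to each sink, exactly
#' once. [run_with_schedule()] does this automatically every iteration; this
#' function exposes the same contract for ad-hoc use. Sink errors are
#' reported as warnings, never raised.
#'
#' @param state a `sim_state`.
#' @param sinks list of sink functions (e.g. [file_sink()]).
#' @return the event, invisibly.
#' @export
publish_observables <- function(state, sinks) {
  ap <- active_params(state)
  event <- list(iteration = state$iteration, time_ms = state$time,
                rates = mean_rates(state),
                connections = outgoing_connections(state),
                nu = ap$nu, eta = ap$eta,
                update_interval_ms = state$struct$update_interval)
  publish_event(sinks, event,
                list(disabled = rep(FALSE, length(sinks)),
                     dropped = rep(0L, length(sinks))))
  invisible(event)
}
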