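SNAPSHOT_VERSION <- 1L

fmt17 <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  # deterministic full-precision formatting so snapshots diff and round-trip
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt17(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

canonical_conn <- function(conn) {
  if (!nrow(conn)) return(conn)
  o <- order(conn$source, conn$target, conn$syn_type, conn$weight)
  out <- conn[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save a network snapshot
#'
#' Serializes the full evolving-network state to a directory: a JSON header
#' (format version, time, iteration, update interval, policies, population
#' and rule definitions, command log, and the RNG state) plus CSV tables for
#' connections (canonically ordered by source, target, type), element pools
#' (with their current growth-curve parameters) and per-neuron dynamic state
#' (membrane potential, synaptic currents, refractory clock, filtered rate).
#' [load_snapshot()] reconstructs an equivalent state; with the RNG restored,
#' a resumed run continues identically to an uninterrupted one.
#'
#' @param state a `sim_state`.
#' @param path snapshot directory (created; must be empty or absent).
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(state, path) {
  stopifnot(inherits(state, "sim_state"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create snapshot directory: ", path)
  }
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  pops <- lapply(state$populations, function(p) {
    list(name = p$name, kind = p$kind, size = p$size,
         params = unclass(p$params),
         background_rate = p$background_rate,
         background_weight = p$background_weight,
         I_const = p$I_const)
  })
  rules <- lapply(state$rules, unclass)
  header <- list(
    format = "plastinet-snapshot", version = SNAPSHOT_VERSION,
    time_ms = fmt17(state$time), iteration = state$iteration,
    dt = fmt17(state$dt), tau_rate_s = fmt17(state$tau_rate),
    seed = state$seed,
    struct = list(update_interval = fmt17(state$struct$update_interval),
                  allow_autapses = state$struct$allow_autapses,
                  allow_multapses = state$struct$allow_multapses,
                  param_bounds = state$struct$param_bounds),
    populations = pops, rules = rules,
    command_log = as.data.frame(state$command_log),
    n_connections = nrow(state$conn), n_pools = nrow(state$pools),
    rng_state = rng
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_num_csv(canonical_conn(as.data.frame(state$conn)),
                file.path(path, "connections.csv"))
  pools <- state$pools[order(state$pools$neuron, state$pools$element_type), ,
                       drop = FALSE]
  write_num_csv(pools, file.path(path, "pools.csv"))
  neurons <- data.frame(neuron = seq_len(state$n), V = state$V,
                        I_ex = state$I_ex, I_in = state$I_in,
                        refr = state$refr, lambda = state$lambda)
  write_num_csv(neurons, file.path(path, "neurons.csv"))
  invisible(path)
}

#' Load a network snapshot
#'
#' Rebuilds a `sim_state` from a snapshot directory written by
#' [save_snapshot()]: growth curves are reconstructed from the stored
#' (eta, eps, nu), all connections recreated, the update interval restored,
#' and the filtered rates restored (not reset). Validation is strict - a
#' version mismatch, truncated table or inconsistent bound count raises an
#' error and returns no partial state.
#'
#' @param path snapshot directory.
#' @param restore_rng restore R's RNG state from the snapshot (default TRUE),
#'   making a resumed run bit-identical to the uninterrupted one.
#' @return a `sim_state`.
#' @export
load_snapshot <- function(path, restore_rng = TRUE) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("not a snapshot: missing ", hf)
  header <- jsonlite::read_json(hf, simplifyVector = FALSE)
  if (is.null(header$format) || header$format != "plastinet-snapshot") {
    stop("unrecognized snapshot format")
  }
  if (header$version != SNAPSHOT_VERSION) {
    stop("unsupported snapshot version: ", header$version)
  }
  pops <- lapply(header$populations, function(p) {
    pr <- p$params
    population_spec(p$name, p$kind, p$size,
                    params = neuron_params(C_m = pr$C_m, V_L = pr$V_L,
                                           V_thr = pr$V_thr, V_res = pr$V_res,
                                           tau_ref = pr$tau_ref,
                                           tau_m = pr$tau_m,
                                           tau_syn_ex = pr$tau_syn_ex,
                                           tau_syn_in = pr$tau_syn_in),
                    background_rate = p$background_rate,
                    background_weight = p$background_weight,
                    I_const = p$I_const)
  })
  conn <- utils::read.csv(file.path(path, "connections.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(source = "integer",
                                         target = "integer",
                                         syn_type = "character",
                                         weight = "numeric",
                                         plastic = "logical"))
  if (nrow(conn) != header$n_connections) {
    stop("corrupted snapshot: expected ", header$n_connections,
         " connections, found ", nrow(conn))
  }
  st <- build_network(pops, as_connection_table(conn),
                      seed = header$seed, dt = as.numeric(header$dt),
                      tau_rate = as.numeric(header$tau_rate_s))
  pools <- utils::read.csv(file.path(path, "pools.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(neuron = "integer",
                                          element_type = "character",
                                          z = "numeric", bound = "integer",
                                          eta = "numeric", eps = "numeric",
                                          nu = "numeric"))
  if (nrow(pools) != header$n_pools) {
    stop("corrupted snapshot: expected ", header$n_pools, " pools, found ",
         nrow(pools))
  }
  neurons <- utils::read.csv(file.path(path, "neurons.csv"))
  if (nrow(neurons) != st$n) {
    stop("corrupted snapshot: neuron table has ", nrow(neurons),
         " rows for a ", st$n, "-neuron network")
  }
  st$V <- neurons$V
  st$I_ex <- neurons$I_ex
  st$I_in <- neurons$I_in
  st$refr <- neurons$refr
  st$lambda <- neurons$lambda
  st$time <- as.numeric(header$time_ms)
  st$iteration <- as.integer(header$iteration)
  st$pools <- pools
  rules <- lapply(header$rules, function(r) {
    synapse_rule(r$syn_type, r$pre_element, r$post_element,
                 unlist(r$pre_populations), unlist(r$post_populations),
                 r$weight)
  })
  st$rules <- rules
  st$struct$update_interval <- as.numeric(header$struct$update_interval)
  st$struct$allow_autapses <- header$struct$allow_autapses
  st$struct$allow_multapses <- header$struct$allow_multapses
  if (!is.null(header$struct$param_bounds)) {
    st$struct$param_bounds <- lapply(header$struct$param_bounds, as.numeric)
  }
  if (length(header$command_log)) {
    jchr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
    cl <- do.call(rbind, lapply(header$command_log, function(row) {
      data.frame(when = as.integer(row$when), kind = row$kind,
                 population = jchr(row$population),
                 element_type = jchr(row$element_type),
                 value = jchr(row$value),
                 applied_at = as.integer(row$applied_at),
                 stringsAsFactors = FALSE)
    }))
    class(cl) <- c("command_log", "data.frame")
    st$command_log <- cl
  }
  validate_state(st)
  if (restore_rng && length(header$rng_state)) {
    assign(".Random.seed", as.integer(unlist(header$rng_state)),
           envir = globalenv())
  }
  st
}

#' Export a trajectory to CSV
#'
#' Stable column order and header; rates in spikes/s, times in ms (the units
#' are part of the column names).
#'
#' @param traj trajectory data.frame from [run_with_schedule()].
#' @param path output file.
#' @export
export_trajectory <- function(traj, path) {
  cols <- trajectory_columns()
  if (!nrow(traj)) {
    cat(paste(cols, collapse = ","), "\n", sep = "", file = path)
    return(invisible(path))
  }
  utils::write.csv(traj[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#' @param path file path.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
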