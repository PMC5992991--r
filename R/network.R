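#' Leaky integrate-and-fire neuron parameters
#'
#' Current-based LIF with exponential post-synaptic currents. The membrane
#' time constant can be given directly (`tau_m`) or via a leak conductance
#' (`g_m`, in nS), in which case `tau_m = C_m / g_m`.
#'
#' @param C_m membrane capacitance, nF.
#' @param V_L resting potential, mV.
#' @param V_thr spike threshold, mV.
#' @param V_res reset potential, mV.
#' @param tau_ref absolute refractory period, ms.
#' @param tau_m membrane time constant, ms (default 10; or give `g_m`).
#' @param g_m leak conductance, nS (alternative to `tau_m`).
#' @param tau_syn_ex,tau_syn_in synaptic current decay constants, ms.
#' @return object of class `neuron_params`.
#' @export
neuron_params <- function(C_m = 0.25, V_L = -65, V_thr = -50, V_res = -65,
                          tau_ref = 2, tau_m = NULL, g_m = NULL,
                          tau_syn_ex = 2, tau_syn_in = 2) {
  if (is.null(tau_m)) {
    tau_m <- if (is.null(g_m)) 10 else 1000 * C_m / g_m # nF/nS -> s; in ms
  } else if (!is.null(g_m)) {
    stop("give either tau_m or g_m, not both")
  }
  p <- list(C_m = C_m, V_L = V_L, V_thr = V_thr, V_res = V_res,
            tau_ref = tau_ref, tau_m = tau_m,
            tau_syn_ex = tau_syn_ex, tau_syn_in = tau_syn_in)
  stopifnot(p$V_res < p$V_thr, p$V_L < p$V_thr, p$tau_ref > 0,
            p$tau_m > 0, p$tau_syn_ex > 0, p$tau_syn_in > 0, p$C_m > 0)
  class(p) <- "neuron_params"
  p
}

#' Population specification
#'
#' @param name population label.
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param size number of neurons (>= 1).
#' @param params a [neuron_params()].
#' @param background_rate Poisson background input rate, kHz (per neuron,
#'   independent streams).
#' @param background_weight PSC amplitude of one background spike, pA.
#' @param I_const constant bias current, pA (mainly for tests).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(name, kind = c("excitatory", "inhibitory"),
                            size, params = neuron_params(),
                            background_rate = 0, background_weight = 0,
                            I_const = 0) {
  kind <- match.arg(kind)
  stopifnot(size >= 1, background_rate >= 0)
  structure(list(name = name, kind = kind, size = as.integer(size),
                 params = params, background_rate = background_rate,
                 background_weight = background_weight, I_const = I_const),
            class = "population_spec")
}

#' Connection table
#'
#' The explicit synapse list: one row per synapse. Excitatory synapse types
#' must have positive weight, inhibitory negative (the sign routes the PSC to
#' the excitatory or inhibitory receptor). `plastic` marks rows owned by the
#' structural-plasticity machinery.
#'
#' @param source,target neuron ids (1-based).
#' @param syn_type synapse model label.
#' @param weight PSC amplitude, pA.
#' @param plastic logical flag.
#' @return a `data.frame` with class `connection_table`.
#' @export
connection_table <- function(source = integer(), target = integer(),
                             syn_type = character(), weight = numeric(),
                             plastic = logical()) {
  df <- data.frame(source = as.integer(source), target = as.integer(target),
                   syn_type = as.character(syn_type),
                   weight = as.numeric(weight),
                   plastic = as.logical(plastic),
                   stringsAsFactors = FALSE)
  class(df) <- c("connection_table", "data.frame")
  df
}

as_connection_table <- function(df) {
  df <- df[, c("source", "target", "syn_type", "weight", "plastic")]
  class(df) <- c("connection_table", "data.frame")
  df
}

#' Build an initialized network state
#'
#' Assembles the full simulation state at `t = 0`: membrane potentials at the
#' resting potential (optionally jittered), zero synaptic currents, zero rate
#' estimates, the given connection table, and (optionally, via
#' [register_plasticity()]) synaptic-element pools.
#'
#' @param populations list of [population_spec()].
#' @param connections a [connection_table()]; defaults to empty.
#' @param seed integer seed for all randomness of the run (sets R's RNG).
#' @param dt integration step, ms.
#' @param tau_rate rate-filter time constant, s.
#' @param v_init_jitter if > 0, initial potentials drawn uniformly from
#'   `[V_L, V_L + v_init_jitter]` mV; default 0 (deterministic start at V_L).
#' @return object of class `sim_state`.
#' @examples
#' st <- build_network(list(
#'   population_spec("exc", "excitatory", 800),
#'   population_spec("inh", "inhibitory", 200)
#' ), seed = 1)
#' n_neurons(st)       # 1000
#' n_synapses(st)      # 0
#' @export
build_network <- function(populations, connections = connection_table(),
                          seed = 1, dt = 0.1, tau_rate = 10,
                          v_init_jitter = 0) {
  stopifnot(length(populations) >= 1, dt > 0, tau_rate > 0)
  sizes <- vapply(populations, function(p) p$size, integer(1))
  names <- vapply(populations, function(p) p$name, character(1))
  if (anyDuplicated(names)) stop("duplicate population names")
  n <- sum(sizes)
  offset <- cumsum(c(0L, sizes[-length(sizes)]))
  pop_of <- rep.int(seq_along(populations), sizes)

  bad <- which(connections$source < 1 | connections$source > n |
               connections$target < 1 | connections$target > n)
  if (length(bad)) {
    stop("connection row ", bad[1], " has invalid endpoint (source=",
         connections$source[bad[1]], ", target=", connections$target[bad[1]],
         ") for a ", n, "-neuron network")
  }

  set.seed(as.integer(seed))
  pull <- function(field) {
    unlist(lapply(populations, function(p) rep(p$params[[field]], p$size)),
           use.names = FALSE)
  }
  V_L <- pull("V_L")
  V <- V_L
  if (v_init_jitter > 0) V <- V_L + stats::runif(n, 0, v_init_jitter)

  st <- list(
    populations = populations,
    pop_names = names, pop_sizes = sizes, pop_offset = offset,
    pop_of = pop_of,
    n = n,
    par = list(
      C_m = pull("C_m"), V_L = V_L, V_thr = pull("V_thr"),
      V_res = pull("V_res"), tau_ref = pull("tau_ref"),
      tau_m = pull("tau_m"),
      tau_syn_ex = pull("tau_syn_ex"), tau_syn_in = pull("tau_syn_in"),
      bg_rate = unlist(lapply(populations, function(p)
        rep(p$background_rate, p$size)), use.names = FALSE),
      bg_weight = unlist(lapply(populations, function(p)
        rep(p$background_weight, p$size)), use.names = FALSE),
      I_const = unlist(lapply(populations, function(p)
        rep(p$I_const, p$size)), use.names = FALSE)
    ),
    V = V,
    I_ex = numeric(n), I_in = numeric(n),
    refr = numeric(n),
    lambda = numeric(n),
    time = 0, iteration = 0L,
    dt = dt, tau_rate = tau_rate,
    conn = as_connection_table(connections),
    pools = empty_pools(),
    rules = list(),
    struct = list(update_interval = 100, allow_autapses = FALSE,
                  allow_multapses = TRUE, param_bounds = NULL),
    command_log = empty_command_log(),
    rewiring_log = data.frame(iteration = integer(), created = integer(),
                              deleted = integer()),
    seed = as.integer(seed)
  )
  class(st) <- "sim_state"
  st
}

empty_pools <- function() {
  data.frame(neuron = integer(), element_type = character(),
             z = numeric(), bound = integer(),
             eta = numeric(), eps = numeric(), nu = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> %d neurons in %d populations, %d synapses, t = %g ms (iteration %d)\n",
              x$n, length(x$populations), nrow(x$conn), x$time, x$iteration))
  invisible(x)
}

#' Number of neurons in a state
#' @param state a `sim_state`.
#' @export
n_neurons <- function(state) state$n

#' Number of synapses (connection-table rows) in a state
#' @param state a `sim_state`.
#' @export
n_synapses <- function(state) nrow(state$conn)

#' Neuron ids of one population
#' @param state a `sim_state`.
#' @param population population name.
#' @export
population_ids <- function(state, population) {
  i <- match(population, state$pop_names)
  if (is.na(i)) stop("unknown population: ", population)
  seq.int(state$pop_offset[i] + 1L, state$pop_offset[i] + state$pop_sizes[i])
}

# compressed row (by source) view of the connection table for the C++ core
build_csr <- function(state) {
  conn <- state$conn
  n <- state$n
  if (!nrow(conn)) {
    return(list(ptr = integer(n + 1L), tgt = integer(), w = numeric()))
  }
  o <- order(conn$source)
  src <- conn$source[o]
  counts <- tabulate(src, nbins = n)
  list(ptr = as.integer(cumsum(c(0L, counts))),
       tgt = as.integer(conn$target[o]),
       w = as.numeric(conn$weight[o]))
}

#' Advance the network by a time span
#'
#' Integrates the membrane equations with the exact subthreshold propagator at
#' the state's fixed step `dt` under frozen connectivity, delivering Poisson
#' background and recurrent spikes with a one-step delay, enforcing the
#' refractory period, and updating every neuron's exponential rate filter at
#' each of its spikes.
#'
#' @param state a `sim_state`.
#' @param duration biological time to advance, ms; must be a non-negative
#'   multiple of `state$dt`.
#' @return list with elements `state` (advanced), `spikes` (data.frame
#'   `neuron`, `time_ms`) and `bg_events` (per-neuron background event count).
#' @export
advance <- function(state, duration) {
  stopifnot(inherits(state, "sim_state"), duration >= 0)
  n_steps <- round(duration / state$dt)
  if (abs(n_steps * state$dt - duration) > 1e-9) {
    stop("duration must be a multiple of the integration step dt = ", state$dt)
  }
  if (n_steps == 0) {
    return(list(state = state,
                spikes = data.frame(neuron = integer(), time_ms = numeric()),
                bg_events = numeric(state$n)))
  }
  csr <- build_csr(state)
  res <- .advance_core(state$V, state$I_ex, state$I_in, state$refr,
                       state$lambda,
                       state$par$V_L, state$par$V_thr, state$par$V_res,
                       state$par$tau_m, state$par$C_m * 1000, # nF -> pF
                       state$par$tau_ref,
                       state$par$tau_syn_ex, state$par$tau_syn_in,
                       state$par$I_const,
                       state$par$bg_rate, state$par$bg_weight,
                       csr$ptr, csr$tgt, csr$w,
                       state$time, state$dt, as.integer(n_steps),
                       state$tau_rate * 1000)
  state$V <- res$V
  state$I_ex <- res$I_ex
  state$I_in <- res$I_in
  state$refr <- res$refr
  state$lambda <- res$lambda
  state$time <- state$time + n_steps * state$dt
  list(state = state,
       spikes = data.frame(neuron = res$spike_id, time_ms = res$spike_t),
       bg_events = res$bg_count)
}

#' Per-population mean filtered firing rate
#' @param state a `sim_state`.
#' @return named numeric vector, spikes/s.
#' @export
mean_rates <- function(state) {
  r <- vapply(state$pop_names, function(p)
    mean(state$lambda[population_ids(state, p)]), numeric(1))
  names(r) <- state$pop_names
  r
}

#' Per-population total outgoing connections
#' @param state a `sim_state`.
#' @return named integer vector.
#' @export
outgoing_connections <- function(state) {
  if (!nrow(state$conn)) {
    r <- integer(length(state$pop_names))
  } else {
    r <- tabulate(state$pop_of[state$conn$source],
                  nbins = length(state$pop_names))
  }
  names(r) <- state$pop_names
  r
}

#' Export spikes as two-column CSV
#' @param spikes data.frame with `neuron`, `time_ms` (as returned by [advance()]).
#' @param path output file.
#' @export
export_spikes <- function(spikes, path) {
  utils::write.csv(spikes[, c("neuron", "time_ms")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
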