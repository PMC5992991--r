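#' Convert a peak PSP amplitude to an exponential-PSC amplitude
#'
#' For a current-based LIF with membrane time constant `tau_m` and an
#' exponential synaptic current of decay `tau_syn`, returns the PSC amplitude
#' (pA) whose post-synaptic potential peaks at `psp_mv` millivolts.
#'
#' @param psp_mv desired peak PSP, mV.
#' @param params a [neuron_params()].
#' @return PSC amplitude in pA.
#' @export
psp_to_psc <- function(psp_mv, params) {
  tm <- params$tau_m
  ts <- params$tau_syn_ex
  Cm <- params$C_m * 1000 # nF -> pF so that pA * ms / pF = mV
  if (abs(tm - ts) < 1e-12) {
    peak <- ts * exp(-1) / Cm
  } else {
    r <- ts / tm
    a <- ts / (tm - ts)
    b <- tm / (tm - ts)
    peak <- (tm * ts) / (Cm * (tm - ts)) * (r^a - r^b)
  }
  psp_mv / peak
}

#' Build the two-population structural-plasticity model
#'
#' 1,000 current-based LIF neurons (80% excitatory), no initial synapses,
#' 10 kHz independent Poisson background per neuron, and homeostatic growth
#' curves: every neuron carries one axonal and two dendritic element types;
#' each curve's target rate and growth amplitude come from the owning
#' population (5 spikes/s and 0.0001 elements/ms for excitatory neurons,
#' 20 spikes/s and 0.0004 elements/ms for inhibitory neurons - the faster
#' growth of inhibition), while the curve's orientation follows the element
#' nature: excitatory elements are created below target and deleted above
#' (positive amplitude), inhibitory elements the converse (negative
#' amplitude), so inhibition is recruited to counter overshoot. Plastic
#' synapses are formed excitatory-to-anything (`Axon_ex` + `Den_ex`) and
#' inhibitory-to-anything (`Axon_in` + `Den_in`).
#'
#' The created synapses have unit weight interpreted as a 1 mV peak PSP and
#' converted to a PSC amplitude via [psp_to_psc()]; the background weight
#' default was calibrated once so the unconnected network fires at a low
#' baseline (~3 spikes/s), well below both targets.
#'
#' @param n_total total neuron count (default 1000; proportions preserved).
#' @param exc_frac excitatory fraction (default 0.8).
#' @param seed RNG seed.
#' @param target_exc,target_inh homeostatic target rates, spikes/s.
#' @param nu_ex,nu_in growth-amplitude magnitudes (elements/ms) for the
#'   excitatory and inhibitory population's elements.
#' @param eta minimal rate of all curves, spikes/s.
#' @param bg_rate background rate, kHz.
#' @param bg_weight background PSC amplitude, pA.
#' @param syn_psp_mv magnitude of the unit synapse, mV peak PSP.
#' @param update_interval structural update interval, ms.
#' @param dt integration step, ms.
#' @return a `sim_state` with plasticity registered.
#' @export
build_two_population <- function(n_total = 1000, exc_frac = 0.8, seed = 1,
                                 target_exc = 5, target_inh = 20,
                                 nu_ex = 1e-4, nu_in = 4e-4, eta = 0,
                                 bg_rate = 10, bg_weight = 16.5,
                                 syn_psp_mv = 1,
                                 update_interval = 100, dt = 0.1) {
  n_exc <- round(n_total * exc_frac)
  n_inh <- n_total - n_exc
  par <- neuron_params(C_m = 0.25, V_L = -65, V_thr = -50, V_res = -65,
                       tau_ref = 2, tau_m = 10, tau_syn_ex = 2, tau_syn_in = 2)
  pops <- list(
    population_spec("exc", "excitatory", n_exc, par,
                    background_rate = bg_rate, background_weight = bg_weight),
    population_spec("inh", "inhibitory", n_inh, par,
                    background_rate = bg_rate, background_weight = bg_weight)
  )
  st <- build_network(pops, seed = seed, dt = dt)
  w <- psp_to_psc(syn_psp_mv, par)
  elements <- rbind(
    data.frame(population = "exc", element_type = "Axon_ex",
               eta = eta, eps = target_exc, nu = nu_ex),
    data.frame(population = "exc", element_type = "Den_ex",
               eta = eta, eps = target_exc, nu = nu_ex),
    data.frame(population = "exc", element_type = "Den_in",
               eta = eta, eps = target_exc, nu = -nu_ex),
    data.frame(population = "inh", element_type = "Axon_in",
               eta = eta, eps = target_inh, nu = -nu_in),
    data.frame(population = "inh", element_type = "Den_ex",
               eta = eta, eps = target_inh, nu = nu_in),
    data.frame(population = "inh", element_type = "Den_in",
               eta = eta, eps = target_inh, nu = -nu_in)
  )
  rules <- list(
    synapse_rule("ex", "Axon_ex", "Den_ex", "exc", c("exc", "inh"), w),
    synapse_rule("in", "Axon_in", "Den_in", "inh", c("exc", "inh"), -w)
  )
  register_plasticity(st, elements, rules,
                      update_interval = update_interval)
}

#' Build one region of the multi-region model (or an isolated region)
#'
#' One region: 160 excitatory + 40 inhibitory current-based LIF neurons with
#' the region parameter set (leak conductance expressed through
#' `tau_m = C_m/g_m`), 11.9 kHz Poisson background, static local excitatory
#' connections giving every neuron exactly 160 excitatory inputs (+1.4 pA),
#' and structural plasticity on inhibitory-to-excitatory synapses only
#' (-1.0 pA): excitatory neurons carry plastic `Den_in` elements (target
#' 3 spikes/s), inhibitory neurons plastic `Axon_in` elements (target
#' 8 spikes/s), both with negative growth amplitude so inhibition is recruited
#' when activity exceeds the target and withdrawn below it.
#'
#' Background weights were calibrated once (and frozen as defaults) following
#' the stated tuning procedure: with its static inputs, the isolated
#' excitatory population fires at ~3 spikes/s and the inhibitory population
#' slightly above 8 spikes/s (keeping the axonal element supply alive), so
#' the plastic inhibition only trims neurons whose activity strays above
#' target.
#'
#' @param n_exc,n_inh neuron counts per region.
#' @param seed RNG seed.
#' @param target_exc,target_inh homeostatic / baseline target rates, spikes/s.
#' @param nu_abs growth amplitude magnitude, elements/ms (applied as negative).
#' @param bg_rate background rate, kHz.
#' @param bg_weight_exc,bg_weight_inh background PSC amplitudes, pA.
#' @param w_exc,w_inh recurrent weights, pA.
#' @param indegree static excitatory in-degree per neuron.
#' @param update_interval structural update interval, ms.
#' @param dt integration step, ms.
#' @return a `sim_state` with plasticity registered.
#' @export
build_region <- function(n_exc = 160, n_inh = 40, seed = 1,
                         target_exc = 3, target_inh = 8,
                         nu_abs = 4e-4,
                         bg_rate = 11.9,
                         bg_weight_exc = 19.40, bg_weight_inh = 15.37,
                         w_exc = 1.4, w_inh = -1.0,
                         indegree = 160,
                         update_interval = 100, dt = 0.1) {
  st <- build_multiregion(connectome = NULL, n_regions = 1, seed = seed,
                          n_exc = n_exc, n_inh = n_inh,
                          target_exc = target_exc, target_inh = target_inh,
                          nu_abs = nu_abs, bg_rate = bg_rate,
                          bg_weight_exc = bg_weight_exc,
                          bg_weight_inh = bg_weight_inh,
                          w_exc = w_exc, w_inh = w_inh, indegree = indegree,
                          update_interval = update_interval, dt = dt)
  st
}

#' Build the multi-region model
#'
#' `n_regions` copies of the region of [build_region()], plus static
#' inter-region excitatory synapses between one representative neuron per
#' excitatory population (the region's lowest-indexed excitatory neuron):
#' region `i`'s representative projects to region `j`'s representative with
#' weight `G * C[i, j] * weight_scale` pA. The connectome `C` is a square
#' zero-diagonal non-negative matrix, conventionally scaled to a maximum
#' entry of 1 (see [synth_connectome()]); `weight_scale` sets the physical
#' strength, in pA, of a maximal (`G * C = 1`) inter-region link.
#'
#' @param connectome matrix `C`, or `NULL` for no inter-region links.
#' @param G global coupling scalar (dimensionless).
#' @param n_regions number of regions; must match `nrow(connectome)` if given.
#' @param weight_scale pA per unit of `G * C`.
#' @param seed RNG seed.
#' @inheritParams build_region
#' @return a `sim_state` with plasticity registered. Populations are named
#'   `exc_r<k>` / `inh_r<k>`.
#' @export
build_multiregion <- function(connectome = NULL, G = 1, n_regions = 8,
                              weight_scale = 1000, seed = 1,
                              n_exc = 160, n_inh = 40,
                              target_exc = 3, target_inh = 8,
                              nu_abs = 4e-4,
                              bg_rate = 11.9,
                              bg_weight_exc = 19.40, bg_weight_inh = 15.37,
                              w_exc = 1.4, w_inh = -1.0,
                              indegree = 160,
                              update_interval = 100, dt = 0.1) {
  if (!is.null(connectome)) {
    C <- as.matrix(connectome)
    if (nrow(C) != n_regions || ncol(C) != n_regions) {
      stop("connectome dimension (", nrow(C), "x", ncol(C),
           ") does not match n_regions = ", n_regions)
    }
    if (any(C < 0) || any(diag(C) != 0)) {
      stop("connectome must be non-negative with a zero diagonal")
    }
  }
  par_exc <- neuron_params(C_m = 0.5, V_L = -70, V_thr = -50, V_res = -55,
                           tau_ref = 2, g_m = 25, tau_syn_ex = 2,
                           tau_syn_in = 2)
  par_inh <- neuron_params(C_m = 0.2, V_L = -70, V_thr = -50, V_res = -55,
                           tau_ref = 1, g_m = 20, tau_syn_ex = 2,
                           tau_syn_in = 2)
  pops <- list()
  for (r in seq_len(n_regions)) {
    pops[[2 * r - 1]] <- population_spec(
      sprintf("exc_r%d", r), "excitatory", n_exc, par_exc,
      background_rate = bg_rate, background_weight = bg_weight_exc)
    pops[[2 * r]] <- population_spec(
      sprintf("inh_r%d", r), "inhibitory", n_inh, par_inh,
      background_rate = bg_rate, background_weight = bg_weight_inh)
  }
  st <- build_network(pops, seed = seed, dt = dt)

  # static local excitatory wiring: fixed in-degree per neuron, sources drawn
  # from the region's excitatory population (no autapses, multapses allowed)
  n_reg <- n_exc + n_inh
  src_all <- integer(0)
  tgt_all <- integer(0)
  for (r in seq_len(n_regions)) {
    base <- (r - 1L) * n_reg
    exc_ids <- base + seq_len(n_exc)
    reg_ids <- base + seq_len(n_reg)
    for (tgt in reg_ids) {
      pool <- setdiff(exc_ids, tgt)
      src_all <- c(src_all, sample(pool, indegree, replace = TRUE))
      tgt_all <- c(tgt_all, rep(tgt, indegree))
    }
  }
  local <- connection_table(source = src_all, target = tgt_all,
                            syn_type = "ex_static", weight = w_exc,
                            plastic = FALSE)
  inter <- connection_table()
  if (!is.null(connectome) && G > 0) {
    idx <- which(C > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      reps <- (seq_len(n_regions) - 1L) * n_reg + 1L  # lowest-indexed exc
      inter <- connection_table(source = reps[idx[, 1]],
                                target = reps[idx[, 2]],
                                syn_type = "ex_inter",
                                weight = G * C[idx] * weight_scale,
                                plastic = FALSE)
    }
  }
  st$conn <- as_connection_table(rbind(local, inter))
  rownames(st$conn) <- NULL

  elements <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
    rbind(
      data.frame(population = sprintf("exc_r%d", r), element_type = "Den_in",
                 eta = 0, eps = target_exc, nu = -nu_abs),
      data.frame(population = sprintf("inh_r%d", r), element_type = "Axon_in",
                 eta = 0, eps = target_inh, nu = -nu_abs)
    )
  }))
  rules <- list(synapse_rule("in", "Axon_in", "Den_in",
                             sprintf("inh_r%d", seq_len(n_regions)),
                             sprintf("exc_r%d", seq_len(n_regions)),
                             w_inh))
  register_plasticity(st, elements, rules, update_interval = update_interval)
}

#' Generate a synthetic connectome
#'
#' Stand-in for a diffusion-imaging structural connectivity matrix: a square,
#' zero-diagonal, non-negative matrix. Off-diagonal entries are present with
#' probability `density`, with uniform weights, then the matrix is scaled so
#' its maximum entry is 1. `hub_frac > 0` designates a fraction of regions as
#' hubs whose connection probability is multiplied by `hub_boost` (capped at
#' 1), so some regions are substantially more inter-connected than others.
#'
#' @param n_regions matrix dimension.
#' @param density expected off-diagonal occupancy in `[0, 1]`.
#' @param seed RNG seed.
#' @param symmetric if `TRUE`, the matrix is symmetrized (undirected bundle).
#' @param hub_frac fraction of regions designated hubs.
#' @param hub_boost multiplier on hub connection probability.
#' @return `n_regions x n_regions` matrix.
#' @export
synth_connectome <- function(n_regions, density = 0.3, seed = 1,
                             symmetric = FALSE, hub_frac = 0,
                             hub_boost = 3) {
  stopifnot(density >= 0, density <= 1, n_regions >= 1)
  set.seed(as.integer(seed))
  p <- matrix(density, n_regions, n_regions)
  if (hub_frac > 0) {
    hubs <- seq_len(max(1, round(hub_frac * n_regions)))
    p[hubs, ] <- pmin(1, p[hubs, ] * hub_boost)
    p[, hubs] <- pmin(1, p[, hubs] * hub_boost)
  }
  mask <- matrix(stats::runif(n_regions^2) < p, n_regions)
  w <- matrix(stats::runif(n_regions^2), n_regions) * mask
  diag(w) <- 0
  if (symmetric) w <- (w + t(w)) / 2
  m <- max(w)
  if (m > 0) w <- w / m
  w
}

#' Read / write a connectome as a whitespace-delimited dense matrix
#' @param path file path.
#' @param C matrix (for writing).
#' @export
read_connectome <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname read_connectome
#' @export
write_connectome <- function(C, path) {
  utils::write.table(format(C, digits = 17, scientific = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dynamic mean-field model parameters
#'
#' Parameters of the reduced Wong-Wang mean-field system used as the
#' region-level reference model. Values are configuration with conventional
#' defaults; the transfer function is
#' \eqn{H(x) = (ax - b)/(1 - e^{-d(ax - b)})}.
#'
#' @param a transfer gain, Hz/nA.
#' @param b transfer threshold, Hz.
#' @param d transfer curvature, s.
#' @param gamma kinetic rate (dimensionless).
#' @param tau_s gating time constant, s.
#' @param sigma noise amplitude, nA.
#' @param w local excitatory recurrence (dimensionless).
#' @param J_N synaptic coupling, nA.
#' @param I_0 effective external current, nA.
#' @return object of class `dmfm_params`.
#' @export
dmfm_params <- function(a = 270, b = 108, d = 0.154, gamma = 0.641,
                        tau_s = 0.1, sigma = 0.001, w = 0.9,
                        J_N = 0.2609, I_0 = 0.3) {
  stopifnot(tau_s > 0, d != 0)
  structure(list(a = a, b = b, d = d, gamma = gamma, tau_s = tau_s,
                 sigma = sigma, w = w, J_N = J_N, I_0 = I_0),
            class = "dmfm_params")
}

#' Mean-field transfer function
#'
#' `H(x) = (ax - b) / (1 - exp(-d (ax - b)))`, with the removable singularity
#' at `ax = b` evaluated as its limit `1/d`.
#'
#' @param x input current, nA (vectorized).
#' @param params a [dmfm_params()].
#' @return firing rate, Hz.
#' @export
dmfm_transfer <- function(x, params) {
  u <- params$a * x - params$b
  out <- numeric(length(u))
  small <- abs(params$d * u) < 1e-8
  out[small] <- 1 / params$d + u[small] / 2  # first-order expansion
  out[!small] <- u[!small] / (1 - exp(-params$d * u[!small]))
  out
}

#' Simulate the dynamic mean-field model
#'
#' Euler-Maruyama integration of the coupled gating equations
#' \eqn{\dot s = -s/\tau_s + (1 - s)\,\gamma H(x) + \sigma\nu(t)} with
#' \eqn{x = w J_N s + G J_N C s + I_0}, the gating variables clamped to
#' `[0, 1]`.
#'
#' @param params a [dmfm_params()].
#' @param connectome matrix `C` (or `NULL` for uncoupled regions).
#' @param G global coupling scalar.
#' @param n_regions number of regions (inferred from `connectome` if given).
#' @param duration simulated time, s.
#' @param dt step, s.
#' @param seed RNG seed.
#' @param s0 initial gating vector (default 0.1).
#' @param record_every store every k-th step (default 1).
#' @return list with `time` (s) and `s` (matrix, steps x regions).
#' @export
dmfm_simulate <- function(params, connectome = NULL, G = 0, n_regions = NULL,
                          duration = 10, dt = 1e-3, seed = 1, s0 = 0.1,
                          record_every = 1L) {
  stopifnot(dt > 0)
  if (!is.null(connectome)) {
    C <- as.matrix(connectome)
    n_regions <- nrow(C)
  } else {
    if (is.null(n_regions)) n_regions <- 1L
    C <- matrix(0, n_regions, n_regions)
  }
  set.seed(as.integer(seed))
  s <- rep_len(s0, n_regions)
  n_steps <- round(duration / dt)
  keep <- seq(record_every, n_steps, by = record_every)
  out <- matrix(NA_real_, length(keep), n_regions)
  ki <- 1L
  sq <- sqrt(dt)
  GC <- G * params$J_N * C
  for (k in seq_len(n_steps)) {
    x <- params$w * params$J_N * s + drop(GC %*% s) + params$I_0
    H <- dmfm_transfer(x, params)
    drift <- -s / params$tau_s + (1 - s) * params$gamma * H
    s <- s + dt * drift
    if (params$sigma > 0) s <- s + params$sigma * sq * stats::rnorm(n_regions)
    s <- pmin(1, pmax(0, s))
    if (!all(is.finite(s))) stop("non-finite gating variable at t = ", k * dt)
    if (ki <= length(keep) && k == keep[ki]) {
      out[ki, ] <- s
      ki <- ki + 1L
    }
  }
  list(time = keep * dt, s = out)
}

#' Deterministic fixed point of the single-region mean-field model
#'
#' Root of \eqn{-s/\tau_s + (1 - s)\gamma H(w J_N s + I_0)} on `[0, 1]`
#' (noise-free, uncoupled), found by bisection root search.
#'
#' @param params a [dmfm_params()].
#' @return the gating value `s*`.
#' @export
dmfm_fixed_point <- function(params) {
  f <- function(s) {
    -s / params$tau_s + (1 - s) * params$gamma *
      dmfm_transfer(params$w * params$J_N * s + params$I_0, params)
  }
  stats::uniroot(f, c(0, 1), tol = 1e-14)$root
}

#' Time for a multi-region network to stabilize after coupling is switched on
#'
#' Emulates the coupling-step protocol: the network first runs uncoupled
#' (inter-region weights suppressed) for `warmup` iterations so the rate
#' filters settle at the isolated operating point, then the inter-region
#' links are restored at their built strength `G * C * weight_scale` and the
#' run continues. Reported is the number of post-step iterations until the
#' mean filtered rate of the representative neurons (the neurons carrying
#' the inter-region input) stays within a relative band around the
#' excitatory target for `window` consecutive iterations. Stronger coupling
#' pushes the representatives further above target; once the excess drive
#' outruns what element-by-element inhibitory recruitment can absorb within
#' the horizon, the run is censored at `horizon`.
#'
#' @param state a `sim_state` from [build_multiregion()] (built with the
#'   coupling of interest).
#' @param target excitatory target rate, spikes/s.
#' @param band relative tolerance (default 0.25).
#' @param window consecutive in-band iterations required (default 10).
#' @param warmup uncoupled iterations before the coupling step (default 200).
#' @param horizon post-step iteration cap; runs that never stabilize report
#'   `horizon` (censored).
#' @return list with `time` (iterations after the step), `censored` flag,
#'   and final `state`.
#' @export
stabilization_time <- function(state, target = 3, band = 0.25, window = 10,
                               warmup = 200, horizon = 300) {
  reps <- vapply(grep("^exc", state$pop_names, value = TRUE),
                 function(p) population_ids(state, p)[1], integer(1))
  inter <- state$conn$syn_type == "ex_inter"
  w_inter <- state$conn$weight[inter]
  state$conn$weight[inter] <- 0
  for (k in seq_len(warmup)) {
    state <- advance(state, state$struct$update_interval)$state
    state <- structural_update(state)
  }
  state$conn$weight[inter] <- w_inter
  in_band_run <- 0L
  stab <- NA_integer_
  for (k in seq_len(horizon)) {
    state <- advance(state, state$struct$update_interval)$state
    state <- structural_update(state)
    dev <- abs(mean(state$lambda[reps]) - target) / target
    in_band_run <- if (dev <= band) in_band_run + 1L else 0L
    if (in_band_run >= window) {
      stab <- k - window + 1L
      break
    }
  }
  list(time = if (is.na(stab)) horizon else stab,
       censored = is.na(stab), state = state)
}
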