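#' Build a network from a hierarchical configuration file
#'
#' Reads a model definition from JSON or YAML (by file extension) and builds
#' the corresponding `sim_state`. The configuration mirrors the builder
#' arguments:
#'
#' ```yaml
#' dt: 0.1
#' populations:
#'   - {name: exc, kind: excitatory, size: 80,
#'      params: {C_m: 0.25, V_L: -65, V_thr: -50, V_res: -65,
#'               tau_ref: 2, tau_m: 10},
#'      background_rate: 10, background_weight: 16.5}
#' elements:
#'   - {population: exc, element_type: Axon_ex, eta: 0, eps: 5, nu: 1e-4}
#' rules:
#'   - {syn_type: ex, pre_element: Axon_ex, post_element: Den_ex,
#'      pre_populations: [exc], post_populations: [exc], weight: 187}
#' structural: {update_interval: 100, allow_autapses: false,
#'              allow_multapses: true}
#' ```
#'
#' `elements`, `rules` and `structural` are optional; without them the state
#' has no plasticity registered. Neuron parameters accept either `tau_m`
#' (ms) or `g_m` (nS).
#'
#' @param path configuration file (`.json`, `.yaml`/`.yml`).
#' @param seed RNG seed (overrides a `seed` entry in the file; default 1).
#' @return a `sim_state`.
#' @export
build_from_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(cfg$populations) || !length(cfg$populations)) {
    stop("config must define at least one population")
  }
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  num <- function(x, default = NULL) if (is.null(x)) default else as.numeric(x)
  pops <- lapply(cfg$populations, function(p) {
    pr <- if (is.null(p$params)) list() else p$params
    params <- neuron_params(
      C_m = num(pr$C_m, 0.25), V_L = num(pr$V_L, -65),
      V_thr = num(pr$V_thr, -50), V_res = num(pr$V_res, -65),
      tau_ref = num(pr$tau_ref, 2),
      tau_m = num(pr$tau_m), g_m = num(pr$g_m),
      tau_syn_ex = num(pr$tau_syn_ex, 2), tau_syn_in = num(pr$tau_syn_in, 2))
    population_spec(p$name, p$kind, as.integer(p$size), params,
                    background_rate = num(p$background_rate, 0),
                    background_weight = num(p$background_weight, 0),
                    I_const = num(p$I_const, 0))
  })
  st <- build_network(pops, seed = seed, dt = num(cfg$dt, 0.1),
                      tau_rate = num(cfg$tau_rate, 10))
  if (!is.null(cfg$elements)) {
    elements <- do.call(rbind, lapply(cfg$elements, function(e) {
      data.frame(population = e$population, element_type = e$element_type,
                 eta = as.numeric(e$eta), eps = as.numeric(e$eps),
                 nu = as.numeric(e$nu), stringsAsFactors = FALSE)
    }))
    rules <- lapply(cfg$rules, function(r) {
      synapse_rule(r$syn_type, r$pre_element, r$post_element,
                   unlist(r$pre_populations), unlist(r$post_populations),
                   as.numeric(r$weight))
    })
    sc <- if (is.null(cfg$structural)) list() else cfg$structural
    bounds <- if (is.null(sc$param_bounds)) NULL else
      lapply(sc$param_bounds, as.numeric)
    st <- register_plasticity(
      st, elements, rules,
      update_interval = num(sc$update_interval, 100),
      allow_autapses = isTRUE(sc$allow_autapses),
      allow_multapses = if (is.null(sc$allow_multapses)) TRUE
                        else isTRUE(sc$allow_multapses),
      param_bounds = bounds)
  }
  st
}
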