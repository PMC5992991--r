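# small builds shared across tests: scaled-down two-population model that
# keeps the 80/20 split but runs in well under a second per interval
tiny_two_pop <- function(seed = 1, n_total = 60, ...) {
  build_two_population(n_total = n_total, seed = seed, ...)
}

# a state with simple hand-set pools for rewiring unit tests:
# two populations A (2 neurons) and B (2 neurons), rule binds A-axons to
# B-dendrites with weight +1
toy_rewiring_state <- function(seed = 1, allow_autapses = FALSE,
                               allow_multapses = TRUE) {
  pops <- list(population_spec("A", "excitatory", 2),
               population_spec("B", "excitatory", 2))
  st <- build_network(pops, seed = seed)
  elements <- rbind(
    data.frame(population = "A", element_type = "Axon_ex",
               eta = 0, eps = 5, nu = 1e-4),
    data.frame(population = "B", element_type = "Den_ex",
               eta = 0, eps = 5, nu = 1e-4)
  )
  rules <- list(synapse_rule("ex", "Axon_ex", "Den_ex", "A", "B", 1))
  register_plasticity(st, elements, rules, update_interval = 100)
}

set_pool <- function(state, neuron, type, z = NULL, bound = NULL) {
  i <- which(state$pools$neuron == neuron & state$pools$element_type == type)
  stopifnot(length(i) == 1)
  if (!is.null(z)) state$pools$z[i] <- z
  if (!is.null(bound)) state$pools$bound[i] <- as.integer(bound)
  state
}
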