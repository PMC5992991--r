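test_that("two-population build matches the published construction", {
  st <- build_two_population(seed = 1)
  expect_equal(n_neurons(st), 1000)
  expect_equal(length(population_ids(st, "exc")), 800)
  expect_equal(length(population_ids(st, "inh")), 200)
  expect_equal(n_synapses(st), 0)  # no connections at the start
  expect_equal(st$struct$update_interval, 100)
  # growth curves: population targets 5 / 20, magnitudes 1e-4 / 4e-4
  p <- st$pools
  exc_ids <- population_ids(st, "exc")
  expect_true(all(p$eps[p$neuron %in% exc_ids] == 5))
  expect_true(all(p$eps[!p$neuron %in% exc_ids] == 20))
  expect_true(all(abs(p$nu[p$neuron %in% exc_ids]) == 1e-4))
  expect_true(all(abs(p$nu[!p$neuron %in% exc_ids]) == 4e-4))
  # rules: unit synapses, +/- the 1 mV PSC conversion
  w <- psp_to_psc(1, neuron_params(tau_m = 10))
  expect_equal(st$rules[[1]]$weight, w)
  expect_equal(st$rules[[2]]$weight, -w)
  validate_state(st)
})

test_that("scaled-down two-population build preserves the 80/20 split", {
  st <- build_two_population(n_total = 100, seed = 1)
  expect_equal(length(population_ids(st, "exc")), 80)
  expect_equal(length(population_ids(st, "inh")), 20)
})

test_that("PSP-to-PSC conversion peaks at the requested amplitude", {
  par <- neuron_params(tau_m = 10, tau_syn_ex = 2, C_m = 0.25)
  w <- psp_to_psc(1, par)
  # numerically integrate the PSP and check its maximum is 1 mV
  dt <- 0.001
  t <- seq(0, 60, by = dt)
  I <- w * exp(-t / 2)
  V <- 0
  peak <- 0
  for (k in seq_along(t)) {
    V <- V + dt * (-V / 10 + I[k] / 250)
    peak <- max(peak, V)
  }
  expect_equal(peak, 1, tolerance = 1e-3)
})

test_that("region build wires 160 excitatory inputs to every neuron", {
  st <- build_region(seed = 2)
  expect_equal(n_neurons(st), 200)
  indeg <- tabulate(st$conn$target, nbins = 200)
  expect_true(all(indeg == 160))
  # all static rows come from the local excitatory population
  expect_true(all(st$conn$source <= 160))
  expect_true(all(st$conn$weight == 1.4))
  expect_false(any(st$conn$plastic))
  # no autapses in the static wiring
  expect_false(any(st$conn$source == st$conn$target))
  # plastic machinery: inhibitory-to-excitatory only
  expect_equal(length(st$rules), 1)
  expect_equal(st$rules[[1]]$weight, -1.0)
  expect_true(all(st$pools$element_type %in% c("Den_in", "Axon_in")))
  validate_state(st)
})

test_that("multiregion build places representative links weighted by G*C", {
  C <- matrix(0, 3, 3)
  C[1, 2] <- 1
  C[2, 3] <- 0.5
  st <- build_multiregion(C, G = 2, n_regions = 3, weight_scale = 500,
                          seed = 1)
  expect_equal(n_neurons(st), 600)
  inter <- st$conn[st$conn$syn_type == "ex_inter", ]
  expect_equal(nrow(inter), 2)
  # representatives are the lowest-indexed excitatory neuron of each region
  expect_equal(sort(inter$source), c(1, 201))
  expect_equal(sort(inter$target), c(201, 401))
  expect_equal(sort(inter$weight), c(500, 1000))
  # G = 0 leaves regions fully decoupled
  st0 <- build_multiregion(C, G = 0, n_regions = 3, seed = 1)
  expect_equal(sum(st0$conn$syn_type == "ex_inter"), 0)
})

test_that("multiregion build rejects a mismatched connectome", {
  expect_error(build_multiregion(matrix(0, 4, 4), n_regions = 3, seed = 1),
               "dimension")
  bad <- matrix(0.5, 2, 2)  # nonzero diagonal
  expect_error(build_multiregion(bad, n_regions = 2, seed = 1), "diagonal")
})

test_that("single-region multiregion build equals the isolated region build", {
  ra <- advance(build_region(seed = 7), 500)
  rb <- advance(build_multiregion(NULL, n_regions = 1, seed = 7), 500)
  expect_identical(ra$spikes, rb$spikes)
})

test_that("synthetic connectome densities follow binomial statistics", {
  expect_true(all(synth_connectome(5, density = 0, seed = 1) == 0))
  c1 <- synth_connectome(4, density = 1, seed = 1)
  expect_equal(sum(c1 > 0), 12)  # complete digraph
  expect_true(all(diag(c1) == 0))
  expect_equal(max(c1), 1)

  n <- 68
  occ <- vapply(1:200, function(s) {
    C <- synth_connectome(n, density = 0.3, seed = s)
    sum(C > 0) / (n * (n - 1))
  }, 0)
  p <- 0.3
  sigma <- sqrt(p * (1 - p) / (n * (n - 1))) / sqrt(200)
  expect_lt(abs(mean(occ) - p), 3 * sigma)

  # symmetric mode and hubs
  cs <- synth_connectome(10, density = 0.4, seed = 3, symmetric = TRUE)
  expect_equal(cs, t(cs))
  ch <- synth_connectome(40, density = 0.1, seed = 3, hub_frac = 0.1,
                         hub_boost = 5)
  deg <- rowSums(ch > 0) + colSums(ch > 0)
  expect_gt(mean(deg[1:4]), mean(deg[5:40]))
})

test_that("connectome text round trip preserves the matrix", {
  C <- synth_connectome(6, density = 0.5, seed = 11)
  f <- tempfile()
  write_connectome(C, f)
  expect_equal(unname(read_connectome(f)), C, tolerance = 1e-15)
})

test_that("mean-field transfer handles the removable singularity", {
  p <- dmfm_params()
  x0 <- p$b / p$a  # ax - b = 0
  expect_equal(dmfm_transfer(x0, p), 1 / p$d, tolerance = 1e-9)
  # series expansion check just off the singularity
  for (du in c(1e-6, -1e-6, 1e-4, -1e-4)) {
    x <- (p$b + du) / p$a
    expect_equal(dmfm_transfer(x, p), 1 / p$d + du / 2, tolerance = 1e-6)
  }
})

test_that("noise-free mean-field trajectory settles at the root-search fixed point", {
  p <- dmfm_params(sigma = 0)
  s_star <- dmfm_fixed_point(p)
  out <- dmfm_simulate(p, n_regions = 1, duration = 20, dt = 1e-3, seed = 1,
                       s0 = s_star)
  drift <- abs(diff(out$s[, 1])) / 1e-3
  expect_lt(max(drift), 1e-8)
  # and from a displaced start it converges to the same point
  out2 <- dmfm_simulate(p, n_regions = 1, duration = 20, dt = 1e-3, seed = 1,
                        s0 = 0.5)
  expect_equal(out2$s[nrow(out2$s), 1], s_star, tolerance = 1e-6)
})

test_that("noise-free single-region trajectory matches a hundredfold finer integration", {
  p <- dmfm_params(sigma = 0)
  coarse <- dmfm_simulate(p, n_regions = 1, duration = 0.3, dt = 2e-5,
                          seed = 1, s0 = 0.4)
  fine <- dmfm_simulate(p, n_regions = 1, duration = 0.3, dt = 2e-7, seed = 1,
                        s0 = 0.4, record_every = 100L)
  expect_equal(coarse$time, fine$time, tolerance = 1e-9)
  expect_lt(max(abs(coarse$s - fine$s) / pmax(fine$s, 1e-6)), 1e-4)
})

test_that("gating variables stay inside [0, 1] under noise and coupling", {
  C <- synth_connectome(6, density = 0.6, seed = 2)
  for (sig in c(0.001, 0.01, 0.3)) {
    p <- dmfm_params(sigma = sig)
    out <- dmfm_simulate(p, C, G = 2, duration = 3, dt = 1e-3, seed = 4)
    expect_true(all(out$s >= 0 & out$s <= 1))
  }
})
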