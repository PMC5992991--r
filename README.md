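# plastinet

Spiking-network simulation with **homeostatic structural plasticity**:
networks of leaky integrate-and-fire neurons whose synapses are *created and
deleted at run time* by activity-dependent growth rules, steerable while the
simulation runs. The package is aimed at computational neuroscientists who
want to generate connectivity consistent with a target activity profile —
using structural plasticity as a numerical solver for the (degenerate)
inverse problem "which networks produce this firing-rate profile?" — and to
explore the trajectories the network takes to get there.

## The model in brief

Each neuron owns pools of *synaptic elements* (axonal and dendritic contact
points). Pool sizes follow a Gaussian growth rule of the neuron's filtered
firing rate λ:

    dn/dt = ν · H[λ − η] · (2 · 2^(−ξ²) − 1),   ξ = 2(λ − η)/(ε − η) − 1

where η is the minimal rate (Heaviside cutoff), ε the target rate (the
curve's zero crossing — the homeostatic set point) and ν the amplitude,
attained at (η + ε)/2. λ is an exponential low-pass of the spike train
(decay τ = 10 s, increment 1/τ per spike), advanced event-exactly. At every
update interval (default 100 ms) element deficits delete synapses and free
elements pair uniformly at random into new ones. Growth parameters (ν, η)
and the update interval can be changed mid-run through timed command
schedules; runs publish per-iteration observables to subscriber sinks, and
full network state (connections, pools, curves, RNG) snapshots to disk and
resumes bit-identically.

Two model presets reproduce the canonical use cases:

* `build_two_population()` — 1,000 LIF neurons (80% excitatory), zero
  initial synapses, 10 kHz Poisson background; targets 5 spikes/s
  (excitatory) and 20 spikes/s (inhibitory).
* `build_region()` / `build_multiregion()` — brain-region networks (160
  excitatory + 40 inhibitory neurons each, 160 static excitatory inputs per
  neuron, 11.9 kHz background, plastic inhibitory→excitatory synapses;
  targets 3 and 8 spikes/s), coupled through one representative neuron per
  region with weight G·C from a (synthetic) connectome, plus a reference
  dynamic mean-field integrator (`dmfm_simulate()`).

## Worked example

```r
library(plastinet)

st  <- build_two_population(seed = 1)
res <- run_with_schedule(st, make_steering_protocol("A"), horizon = 100)
tail(res$trajectory, 4)
#     iteration time_ms population rate_spikes_per_s total_out_connections     nu eta update_interval_ms
# 197        99    9900        exc          1.892307                     0  5e-05   0                100
# 198        99    9900        inh          1.830612                     0 -5e-05   0                100
# 199       100   10000        exc          1.904205                     0  5e-05   0                100
# 200       100   10000        inh          1.839742                     0 -5e-05   0                100
```

After 100 iterations (10 s biological) under the overshoot-damping schedule
(growth-rate magnitude cut to 5e-5 at iteration 8), both populations are
still in the slow ramp-up phase: rates ≈1.9 spikes/s, no whole elements
accumulated yet. The `nu` column records each population's *axonal* growth
rate with its orientation — positive for the excitatory population
(elements created below target), negative for the inhibitory one (created
above target) — at the steered magnitude. Left to run to its plateau
(~3,000 iterations), the populations settle at their homeostatic targets:

```r
res <- run_to_plateau(build_two_population(seed = 1), min_iter = 3000,
                      max_iter = 4000)
measure_rates(res$state, duration = 10000)$rates
#       exc       inh
#  4.621125 19.728000   # spike-count rates over the final 10 s
```

Snapshots and steering logs make every trajectory replayable:

```r
save_snapshot(res$state, "my_run")            # JSON header + CSV tables
st2 <- load_snapshot("my_run")                # resumes bit-identically
```

A thin command-line wrapper ships in `inst/cli/plastinet`
(`run --preset two_pop --seed 7 --horizon 100 --schedule protoA.csv`).

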