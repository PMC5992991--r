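---
title: "Homeostatic structural plasticity: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic structural plasticity: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastinet)
```

## The model

`plastinet` simulates spiking networks whose *connectivity* is a dynamical
variable. Neurons are current-based leaky integrate-and-fire (LIF) units with
exponential post-synaptic currents,

$$C_m \dot V = -g_m (V - V_L) + I_{ex}(t) + I_{in}(t), \qquad
  \tau_{s} \dot I_{s} = -I_{s} + \textstyle\sum_f w\,\delta(t - t_f),$$

integrated with the exact propagator of this linear system at a fixed step
$dt = 0.1$ ms. A spike resets $V$ to $V_{res}$ and opens an absolute
refractory window $\tau_{ref}$ during which $V$ is clamped. Each neuron
receives an independent Poisson background stream, delivered as one
equivalent high-rate generator sampled per step from a Poisson count —
statistically identical to a bank of unit-rate generators, far cheaper.
Recurrent and background events land in the synaptic current buffers at the
end of the step in which they occur (a single global delay of one
integration step, the smallest causal choice; the delay is otherwise
unspecified in the source material).

Each neuron estimates its own firing rate $\lambda$ by an exponential
low-pass of its spike train: $\lambda$ decays as $e^{-\Delta t/\tau}$ and
jumps by $1/\tau$ per spike, with $\tau = 10$ s. Because this recursion has
a closed form between events, the filter is advanced exactly, event by
event; there is no per-step accumulation error (verified against a direct
convolution sum in the test suite). A binned trailing-window estimator is
provided as an alternative.

**Synaptic elements and growth curves.** Every neuron owns pools of synaptic
elements (axonal contact points offered to outgoing synapses; dendritic
contact points accepting incoming ones, separately for excitatory and
inhibitory synapses). Pool sizes evolve along the Gaussian growth rule

$$\frac{dn}{dt} = \nu\, H[\lambda - \eta]\,
  \left(2 \cdot 2^{-\xi^2} - 1\right), \qquad
  \xi = \frac{2(\lambda - \eta)}{\epsilon - \eta} - 1,$$

with $H$ the Heaviside step. The curve vanishes at $\eta$ and at the target
$\epsilon$ and attains $\nu$ at their midpoint $(\eta + \epsilon)/2$ — the
formula's zeros force the peak there, so a description placing it at
$(\epsilon - \eta)/2$ is the special case $\eta = 0$. With $\nu > 0$
elements are created below target and deleted above; $\nu < 0$ inverts the
orientation, which is the natural choice for inhibitory elements (inhibition
is recruited to counter overshoot and withdrawn below target).

**Rewiring.** Elements are integrated once per structural update interval
(default 100 ms) using the current $\lambda$ — with $\tau = 10$ s of rate
smoothing, $\lambda$ is nearly constant over 100 ms, so sub-stepping would
change nothing above the stochastic noise floor. Each update then
reconciles pools with the explicit connection table, deletions first:
any pool whose integer count $\lfloor z \rfloor$ fell below its bound count
loses that many synapses, chosen uniformly at random, and the counterpart
element on the partner neuron becomes free again. Free elements are then
paired *globally uniformly over individual elements* (elements, not
neurons, are the unit of connectivity supply): both slot lists are
permuted, matched, and trimmed to the smaller supply. Autapse pairs are
dropped (their elements simply remain free); multapses are allowed. Both
policies are flags. Delete-then-form ordering lets freed counterpart
elements re-pair within the same update — the mechanism behind the abrupt
"rewiring episodes" seen when the update interval is stretched.
Fractional element remainders persist across updates; discarding them would
mean small $\nu$ never produces an element.

**Steering.** Timed commands (`set_nu`, `set_eta`, `set_update_interval`,
`pause`/`resume`, `save_state`) are addressed by structural-update
iteration, mirroring how steering protocols are narrated in iteration
counts. A command applies at the boundary of its iteration; recorded
parameter values change only there. `set_nu` sets the growth-rate
*magnitude* and preserves each pool's orientation — steering interfaces
expose one non-negative growth-rate dial, while the sign is structural.
Growth curves are mutated in place with pool contents preserved (an
interpretation; rebuilding curves from scratch would discard accumulated
fractional elements for no benefit). Observers subscribe as in-process
callbacks that receive one event per iteration (time, per-population mean
rate, outgoing connections, active parameters); a sink that throws is
disabled and counted, and never halts the simulation. Delivery is
synchronous — in a single-threaded process a bounded queue would only
re-order failures, so the policy degenerates to "deliver synchronously,
disable on error".

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| $dt$ | ms | 0.1 | exact propagator; fine-step oracle agrees to < one step |
| $\tau$ (rate filter) | s | 10 | sets the homeostat's reaction lag |
| update interval | ms | 100 | steerable; longer intervals destabilize |
| $\epsilon$ (two-population) | spikes/s | 5 (exc), 20 (inh) | population targets |
| $\nu$ magnitude (two-population) | elements/ms | 1e-4 (exc), 4e-4 (inh) | per owning population |
| $\epsilon$ (region) | spikes/s | 3 (exc), 8 (inh) | region targets |
| $\nu$ magnitude (region) | elements/ms | 4e-4 | inhibitory elements only |
| $\eta$ | spikes/s | 0 | Heaviside cutoff |

## Interpreting the printed model constants

Three places required interpretation; each choice is a package-level
decision, made once and documented here.

**Unit synapse weights (two-population model).** The created synapses carry
weights "1 and −1" with no printed unit. Read as ±1 pA, a single synapse
shifts a neuron's mean potential by ~4e-4 mV; reaching the targets would
then require thousands of synapses per neuron and, at the printed growth
amplitudes, days of biological time — irreconcilable with trajectories that
converge within one or two hundred 100-ms iterations. We therefore read the
unit weight as a 1 mV peak PSP and convert it to the equivalent
exponential-PSC amplitude (≈187 pA for $\tau_m = 10$ ms, $\tau_{syn} = 2$
ms; see `psp_to_psc()`). The region model's weights are printed explicitly
in pA (+1.4/−1.0) and are used verbatim.

**Growth-curve assignment (two-population model).** The printed table gives
two growth amplitudes — "excitatory synaptic elements" 0.0001 and
"inhibitory synaptic elements" 0.0004 elements/ms — and two population
targets. We key target *and* magnitude by the owning population (excitatory
neurons: $\epsilon = 5$, $|\nu|$ = 1e-4; inhibitory neurons: $\epsilon =
20$, $|\nu|$ = 4e-4), and orientation by element nature (positive for
excitatory, negative for inhibitory elements). Keying targets by element
nature instead makes the inhibitory population regulate itself to the
excitatory target and cannot reproduce the stated 5/20 operating point;
keying magnitudes by element nature starves the inhibitory population's
excitatory in-growth and stalls it far below target. The chosen assignment
is also the reading under which "allowing faster growth of inhibition"
describes the inhibitory population, and it converges: excitation pins at
its target within ~50 s while the inhibitory population accumulates its
excitatory in-degree through element supply that is throttled once
excitation is on target — a budget of roughly 5,000 elements at an
effective production of ~15–30 elements/s, i.e. an intrinsic convergence
scale of ≈300 s of biological time. Runs and stopping rules are sized from
that estimate, not the other way round.

**Background input strength.** Not printed for either use case; for the
region model the text states it was *tuned to achieve* 3 spikes/s
(excitatory) and 8 spikes/s (inhibitory) in isolation. We performed that
tuning once and froze the results as build defaults: two-population
background 16.5 pA (disconnected baseline ≈3 spikes/s, well below both
targets so growth starts from below); region background 19.40/15.37 pA
(excitatory population with its 160 static inputs at ~3 spikes/s, the
inhibitory population just above 8 spikes/s — the latter keeps the axonal
element supply alive). With the region model's ±1.4/−1.0 pA
weights the structural feedback loop has low gain — background tuning sets
the operating point and plasticity trims the excitatory rate toward target
from above, exactly the division of labor the tuning procedure implies.

**Other unprinted constants.** The two-population neuron table omits the
membrane time constant and synaptic decay constants; we use $\tau_m = 10$
ms and $\tau_{syn} = 2$ ms, the reference simulator's defaults for this
neuron model. Initial potentials start at $V_L$ (deterministic default,
optional uniform jitter). Region neurons are described as conductance-based
but parameterized with pA-valued weights; both use cases are implemented as
current-based LIF, with the leak conductance entering only through
$\tau_m = C_m / g_m$ — the internally consistent reading of the printed
values; a conductance-based receptor model is an extension point, not a
configuration.

## The multi-region model and the synthetic connectome

Each region holds 160 excitatory + 40 inhibitory neurons with the region
parameter table, every neuron receiving exactly 160 static local excitatory
inputs (sources drawn uniformly with replacement, no autapses). Only
inhibitory→excitatory synapses are plastic. Regions are linked through one
representative neuron per excitatory population (the lowest-indexed one — a
deterministic stand-in for "a single representative neuron") with weight
$G \cdot C_{ij}$ in connectome units. Real tractography matrices are
replaced by `synth_connectome()`: Bernoulli occupancy at a configurable
density with uniform weights, max-normalized to 1 (preserving ratios, as
the global coupling sweep requires), optional symmetry and hub bias. The
physical scale of a unit bundle is `weight_scale` (default 1000 pA per
spike, a ≈3 mV PSP at the representative — an aggregated inter-areal
projection, not a unitary synapse), chosen so that the interesting coupling
regime falls inside $G \in [0.5, 2]$ at an 8-region desk scale.

`stabilization_time()` implements the coupling-step protocol: the network
first runs uncoupled until the rate filters settle at the isolated
operating point, then the inter-region links are switched on and the
measure is the number of iterations until the representatives' mean
filtered rate stays within ±25% of target for 10 consecutive updates. At
weak coupling the representatives stay inside the band and the time is
immediate; as $G$ grows they are driven further above target, and beyond a
$G$-dependent threshold the mutually excitatory representative subnetwork
becomes self-sustaining, which element-by-element inhibitory recruitment
at −1.0 pA per synapse cannot absorb within any desk-scale horizon — those
runs are censored at the horizon. Stabilization time is therefore
non-decreasing in $G$, realized at this scale as a sharp transition from
immediate stability to censored instability rather than the graded slowdown
a high-gain inhibitory loop would produce; the per-seed monotone rise of
the representatives' steady rate with $G$ carries the same ordering
continuously.

The dynamic mean-field reference (`dmfm_simulate()`) integrates the
region-level gating equations
$\dot s = -s/\tau_s + (1 - s)\gamma H(x) + \sigma\nu(t)$ with
$H(x) = (ax - b)/(1 - e^{-d(ax - b)})$ and
$x = w J_N s + G J_N C s + I_0$ by Euler–Maruyama, clamping $s$ to
$[0, 1]$. The relaxation term is implemented with a negative sign; the
printed positive sign would make relaxation destabilizing and contradicts
the source model this equation abbreviates. The removable singularity of
$H$ at $ax = b$ is evaluated as its limit $1/d$ (with a first-order series
step in a 1e-8 guard band). The transfer and kinetic constants are not
printed in the source material; the conventional reduced Wong–Wang values
($a = 270$, $b = 108$, $d = 0.154$, $\gamma = 0.641$, $\tau_s = 0.1$ s,
$w = 0.9$, $J_N = 0.2609$, $I_0 = 0.3$) are configuration defaults, not
assertions.

## Numerical choices and degenerate inputs

* Zero-input decay toward $V_L$ is exact to machine precision (propagator,
  not Euler); the regression suite checks 1e-12 agreement with the closed
  form and <0.1 ms inter-spike-interval agreement with a 100× finer grid.
* All randomness flows through R's global RNG: a `(seed, configuration,
  command log)` triple fully determines every trajectory, bit for bit.
  Snapshots store the RNG state, so a resumed run is identical to an
  uninterrupted one.
* The connection table is kept in canonical (source, target, type, weight)
  order after every structural update, so deletion sampling is independent
  of formation history — this is what makes snapshot resume exact.
* Degenerate cases: zero-duration advance is a no-op; a zero-horizon run
  yields a header-only trajectory; an empty network snapshot round-trips;
  element pools clamp at zero from below ($z \ge 0$); a deficit exceeding a
  pool's bound count is an internal-consistency error, not a silent repair.
* `pause`/`resume` are wall-clock commands: they are logged but do not touch
  dynamics or the RNG, so a paused-and-resumed run equals an unpaused one.
* Loading a snapshot into a differently sized network is rejected, not
  guessed; loading restores $\lambda$ rather than resetting it (resetting
  would transiently destabilize the homeostat on resume).

## What the synthetic data emulates — and what it does not

The generators reproduce the *study conditions*: population sizes, targets,
growth amplitudes, update interval, background rates, the zero-connectivity
start (two-population) and the 160-input local scaffold (region). They do
not emulate tractography-derived connectomes (degree distributions,
geometry), conductance-based receptor dynamics, synaptic delays beyond one
step, or trial-to-trial nonstationarities of real recordings. Passing tests
therefore demonstrate that the homeostatic machinery finds and holds the
target operating points under the stated conditions — not that the
resulting connectivity matches any biological circuit; the degeneracy of
that inverse problem is precisely why steering exists.

## Problem sizes used by the tests and acceptance script

Two-population convergence runs use the full 1,000-neuron network for 3,000
structural iterations (300 s biological) before the plateau rule — sized
from the element-budget estimate above — plus a 10 s spike-count
measurement, three seeds. Isolated-region runs plateau within 100–600
iterations. The coupling sweep uses 8 regions (configurable up to 68; full
68-region sweeps are far beyond a desk budget and were not attempted) with
three coupling values and five connectome seeds; each run warms up 150
uncoupled iterations and observes up
to 200 more after the coupling step. Steering comparisons run five paired
seeds over the horizon that contains
the protocols' command windows. Property suites (conservation, replay
determinism, snapshot continuation, pairing enumeration, filter oracles)
run on reduced networks (40–100 neurons) where the invariants are
size-independent.

## Known limitations

* Clock-driven grid spike times (no within-step interpolation): spike times
  carry an $O(dt)$ discretization; the refractory period is enforced on the
  grid (ISI ≥ $\tau_{ref}$, possibly + one step).
* One global synaptic delay of one step; no per-connection delays.
* The publish/subscribe contract is in-process and synchronous; remote
  transports can implement the same event schema but none ships here.
* Gap junctions, conductance synapses, MPI parallelism and event-queue
  exactness of production simulators are out of scope.
* With pA-scale printed weights (region model) the plasticity loop gain is
  low; convergence there is dominated by the calibrated operating point,
  and the plastic trimming is slow and gentle by construction.
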