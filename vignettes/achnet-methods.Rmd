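---
title: "Cholinergic modulation and STDP in two-module cortical networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cholinergic modulation and STDP in two-module cortical networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achnet)
```

## What this package simulates

Acetylcholine (ACh) acting through muscarinic M1 receptors suppresses the
slow, low-threshold M-type K⁺ current of cortical pyramidal cells. `achnet`
models this single knob — the maximal M-current conductance `gKs` — as the
carrier of ACh level: `gKs = 0` mS/cm² stands for strong cholinergic
modulation (high ACh, high excitability, Type 1 firing onset) and
`gKs = 1.5` mS/cm² for none (Type 2 onset, strong spike-frequency
adaptation). Two excitatory–inhibitory lattice networks ("modules") are
coupled by plastic excitatory synapses governed by an asymmetric
pair-based spike-timing-dependent plasticity (STDP) rule, and the package
asks how the spatial pattern of ACh (uniform levels, or sigmoidal
"hotspots"), constant drive (DC), Poisson noise pulses, and wiring
geometry (random vs topographic) steer the direction and spatial layout
of synaptic potentiation between the modules.

## Single-cell model

Each cell follows a Hodgkin–Huxley-type current balance

$$C\,\dot V = -g_{Na} m_\infty^3 h\,(V-V_{Na}) - g_{Kdr} n^4 (V-V_K)
  - g_{Ks} z\,(V-V_K) - g_L (V-V_L) + I_{drive} - I_{syn} + I_{noise},$$

with instantaneous Na⁺ activation and first-order kinetics for $h$, $n$
and the M-current gate $z$. Steady states are logistic with midpoints
−30 (m), −53 (h), −30 (n) and −39 (z) mV and slopes 9.5, 7, 10 and 5 mV;
$\tau_h$ and $\tau_n$ are sub-3 ms and voltage dependent while
$\tau_z = 75$ ms, which is what makes the M-current a slow adaptation
current. Fixed parameters: $C = 1\ \mu F/cm^2$, $g_{Na}=24$,
$g_{Kdr}=3$, $g_L=0.02$ mS/cm², $V_{Na}=55$, $V_K=-90$, $V_L=-60$ mV.
(The typeset source formulas for the sigmoids are ambiguous about signs;
the conventions above are those of the parent pyramidal-cell model and
reproduce the documented resting, threshold and adaptation behaviour —
`fi_curve()` and `simulate_neuron()` expose all of it for inspection.)

Two consequences matter at network level. With `gKs = 0` the f–I curve
rises continuously from zero frequency at rheobase (Type 1) and has high
gain; with `gKs = 1.5` firing starts discontinuously at a nonzero rate
(Type 2), the gain is low, and sustained firing shows marked
spike-frequency adaptation as $g_{Ks} z$ builds up over ~75 ms.

## Network architecture

Each module holds 400 E cells on a 20×20 lattice and 100 I cells on a
10×10 lattice (20% inhibitory), both with periodic boundaries. Local
excitation, global inhibition: every E cell projects to its 40 nearest E
neighbours (0.01 mS/cm²) and, overlaying the two lattices (E coordinates
halved), to its 10 nearest I cells (0.05); every I cell projects to all
400 E cells (0.04) and the 99 other I cells (0.04; self-inhibition is
excluded — a deliberate choice, exposed as `ii_self`). Distance ties at
the neighbourhood cut are resolved uniformly at random from the seeded
RNG. All synapses are conductance jumps decaying with a shared
$\tau = 3$ ms; reversal potentials are 0 mV (excitatory) and −75 mV
(inhibitory).

The two modules are connected E→E only, either **randomly** (each target
receives exactly `in_degree` synapses from uniformly drawn sources;
default 40) or **topographically** (lattices overlaid; each source
connects to its `in_degree` nearest counterparts, including the aligned
cell at distance 0; default 5 for the hotspot protocols, because high
inter-module in-degree washes out spatial specificity). Initial weights
are 0.005 mS/cm², the midpoint of the plasticity bounds.

## Spatial maps

`homogeneous_map()` and `hotspot_map()` assign per-cell `gKs` or DC
values. A hotspot is a sigmoidal radial profile around one or more
centers: value $v_{min} + (v_{max}-v_{min})\,S((d-r)/w)$ with $S$ the
logistic function, $d$ the wrapped distance to the nearest center, $r$
the hotspot radius and $w$ the transition steepness. The amplitude-scaled
form is the default because the protocols state both the hotspot and the
background values (e.g. gKs 0.6 inside, 1.5 outside), which a literal
unit-span sigmoid cannot attain; the unscaled variant is available via
`literal = TRUE`. I cells are evaluated at doubled coordinates so both
lattices share one spatial frame. Hotspot radius and steepness are free
parameters of the protocols (nothing pins them); the presets use
$r = 5$ lattice units and $w = 1$, with single hotspots centered at
(10, 10) and two-hotspot layouts at (5, 5)/(15, 15). Conclusions that
depend on hotspot *existence and location* are insensitive to moderate
changes of $r$; the sharpness of the potentiation boundary tracks $w$.

## Plasticity rule

For a post-minus-pre lag $\Delta t$, a spike pair changes the weight by
$A_+ e^{-\Delta t/\tau_+}$ for $\Delta t \ge 0$ and
$-A_- e^{\Delta t/\tau_-}$ otherwise, with $A_+ = 0.0025$,
$A_- = 0.00125$ mS/cm², $\tau_+ = 14$ ms, $\tau_- = 34$ ms; weights are
hard-clipped to [0, 0.01] mS/cm² after every update. Only inter-module
E→E synapses are plastic. The engine realizes the all-pairs rule online
with eligibility traces: a presynaptic spike depresses by
$A_- x_{post}$ and bumps $x_{pre}$; a postsynaptic spike potentiates by
$A_+ x_{pre}$ and bumps $x_{post}$. Simultaneous pre/post spikes are
processed pre-then-post, so a coincident pair takes the $\Delta t = 0$
potentiation branch. The trace realization is exactly the explicit
all-pairs double sum (a property the tests verify to 1e−12 on random
trains); nearest-neighbour pairing is available in `stdp_trains()` for
comparison. Note the kernel areas: $A_-\tau_- > A_+\tau_+$, so
*uncorrelated* pre/post firing produces net depression — this asymmetry
is load-bearing for how noise reshapes the potentiation pattern.

## Numerical engine

The compiled core advances all 1,000 cells with classical RK4 on the
full $(V, h, n, z)$ system at a fixed `dt = 0.05` ms. Synaptic
conductances and noise currents are held constant within a step and
decay/jump between steps; spikes are upward crossings of −20 mV with a
2 ms lockout (spikes overshoot 0 mV, so any threshold in [−20, 0]
detects the same events). Halving `dt` moves single-neuron spike times
by well under half a millisecond over 5 s and leaves steady rates
essentially unchanged, the convergence margins the tests enforce. Within a step the order is: integrate
membranes → detect spikes → decay conductances and traces → deliver
spikes (with the weights in force at spike time) → pre-triggered
depression → trace increments → post-triggered potentiation. An
instability guard aborts with the time and cell if |V| exceeds 200 mV.

All randomness lives on the R side. The master seed expands into named
substreams (wiring, initial conditions, noise), so identical configs
give bit-identical spike records and weights, and each stochastic
component can be reproduced independently. Poisson noise pulses are
pre-drawn event times per cell; a pulse sets the cell's noise current to
6 µA/cm² for 1 ms (overlaps saturate at one amplitude — at ≤10 Hz they
are negligible either way). Noise targets all cells of both modules by
default (`noise_params(e_only = TRUE)` restricts it to E cells), and the
module DC likewise drives both E and I cells.

**Initial conditions and bistability.** The coupled system is bistable:
a synchronized state of near-full population volleys (the
pyramidal–interneuron gamma mechanism, PING) coexists with a sparse
state in which tonically active I cells hold the E population near
rheobase. Initial potentials are drawn uniformly from [−68, −62] mV
(gates at steady state); this rest-centered, 6 mV spread starts trials
inside the volley regime the model is built to study — with a ≥ 10 mV
spread the initial desynchronization strands the network in the sparse
state and no volley dynamics develop at all.

## Analysis statistics

* `population_trace()`: spikes convolved with a Gaussian kernel
  (σ = 1 ms) on a 0.1 ms grid; `detect_bursts()` takes local maxima
  above 10% of the module's E count, merging peaks closer than 5 ms.
  Burst (volley) peak times are the unit of module-level timing.
* `mean_phase_coherence()`: for each inter-burst interval of a reference
  train, the phase of the first other-module burst inside it,
  $2\pi (t_{other}-t_k)/(t_{k+1}-t_k)$; the MPC is the modulus of the
  mean unit phasor, and the reported value averages the two directions.
  Unmatched intervals are skipped. The symmetrized estimator has a
  positive bias for unrelated trains (interval pairing is not phase-
  uniform in both directions at once), so null calibrations use
  `symmetrize = FALSE` with phases made uniform by construction.
* `weight_change()`: per-synapse percentage change
  $100(W_f - W_i)/W_i$, its per-target-cell incoming average (the
  lattice maps), and the module-wide mean. `linlog_display()` maps
  percentages to the display scale that is linear on [−2, 2] and
  logarithmic per decade outside, odd and continuous.
* `bursting_frequency()`: $(N-1)/(t_{last}-t_{first})$ from a burst
  train.
* `volley_fixture()` generates two-module spike records with known
  volley times, participation, jitter and lag, so the whole analysis
  stack is testable against ground truth without running the simulator.

## Scripted protocols

`example_registry()`/`run_example()` hold the case-study parameter sets:
the homogeneous-modulation examples E–H (module 2 fixed at gKs 0.6,
DC 2.0), the gKs-only series, and the single-/double-hotspot protocols
with random or topographic wiring. `run_sweep()` crosses a module 1
(gKs, DC) grid with noise rates and tabulates trial-averaged weight
changes (with standard errors), MPC and bursting-frequency differences;
each grid point derives its seed from the parameter values, so results
are independent of evaluation order, and an unstable point is recorded
as `NA` without aborting the sweep. Full trials run 5,000 ms and
protocol averages use 4 trials; the test suite scales down to 0.25–5 s
and 1–2 trials, sizes chosen so the checked properties (degree
structure, volley statistics, sign patterns, determinism) are already
stable.

## What the simulations do and do not reproduce

With no noise, the volley-mode dynamics behave as intended across the
case studies: the more excitable module (by higher DC or lower gKs)
fires first in each volley cycle, and its outgoing inter-module synapses
potentiate while the reverse direction depresses — up to the ±100%
saturation imposed by the weight bounds. Determinism, weight bounds,
degree structure, the STDP oracle equivalence and the analysis
statistics are all verified directly by the test suite.

Under per-cell Poisson noise the magnitude of the net weight change
collapses monotonically with noise rate (the suite asserts the
monotone trend at 0/2.5/5/10 Hz), and at 10 Hz the formerly potentiated
direction (into the less excitable module) crosses to net depression.
However, in this implementation any sustained noise tips the network out
of the volley state into the sparse asynchronous regime, where the
depression-dominant kernel drives *both* directions slightly negative:
the full sign *reversal* — noise-induced net potentiation into the more
excitable module, via secondary volleys triggered by the less excitable
module's feedback — does not occur here. The corresponding acceptance
test asserts the full reversal and is expected to fail on the
into-module-1 sign; it is kept as specified rather than weakened. The
window in which the volley state survives per-cell 6 µA/cm² pulses is
empty for the printed coupling strengths in this engine, and we did not
find a faithful variant (noise targeting, DC targeting, tighter initial
conditions, finer time steps) that keeps volleys intact under noise
while preserving the no-noise results.

## Known limitations

* The synthetic volley fixtures emulate volley timing, participation and
  jitter only — no refractoriness, adaptation or correlated noise — so
  analysis tests passing on fixtures validates the statistics, not the
  simulator's dynamics.
* Hotspot radius/steepness and the two-hotspot placements are package
  choices; protocols that depend on them are labelled accordingly.
* Weight snapshots record the plastic (inter-module) weights only;
  intra-module weights are constants by design.
* No synaptic delays, short-term plasticity, or time-varying ACh maps;
  modules are limited to two.
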