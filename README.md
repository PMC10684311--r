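# achnet

Conductance-based simulation of how spatially structured acetylcholine
(ACh) signaling steers spike-timing-dependent plasticity (STDP) between
two coupled cortical network modules.

## The scientific problem

ACh acting on muscarinic M1 receptors blocks the slow, low-threshold
M-type K⁺ current of pyramidal cells. Modeling ACh level as the maximal
M-current conductance g<sub>Ks</sub> (0 mS/cm² = high ACh, 1.5 mS/cm² =
none) changes a neuron's excitability class (Type 1 vs Type 2 firing
onset), its gain, and its spike-frequency adaptation. `achnet` embeds
this cell model in two excitatory–inhibitory lattice networks (400 E +
100 I cells each, local excitation / global inhibition, periodic
boundaries) that fire synchronous population volleys through the
pyramidal–interneuron gamma (PING) mechanism, and couples the modules
with plastic E→E synapses under an asymmetric pair-based STDP rule

&nbsp;&nbsp;Δw = A₊ e^(−Δt/τ₊) for Δt ≥ 0, −A₋ e^(Δt/τ₋) for Δt < 0,

with A₊ = 0.0025, A₋ = 0.00125 mS/cm², τ₊ = 14 ms, τ₋ = 34 ms, weights
bounded to [0, 0.01] mS/cm². Because volleys are tight, the module that
fires first in each cycle systematically potentiates its outgoing
inter-module synapses; relative excitability (set by g<sub>Ks</sub> and
DC drive, uniformly or in sigmoidal "hotspots"), Poisson noise pulses,
and wiring geometry (random vs topographic) then decide the direction
and spatial pattern of rewiring. The package provides the simulator, the
spatial-map and wiring builders, the analysis statistics (population
activity traces, volley detection, mean phase coherence, percentage
weight-change maps with a linear–log display scale), scripted
experiment protocols, and a synthetic volley-fixture generator for
testing the analysis stack.

## Worked example

The reference case study: module 1 (gKs 0.6 mS/cm², DC 3.0 µA/cm²) is
more excitable than module 2 (gKs 0.6, DC 2.0); random wiring, no noise.

```r
library(achnet)
cfg <- example_config("F", noise_rate = 0, duration = 2000, seed = 42)
res <- run_simulation(cfg)
print(res)
#> Two-module simulation result: 33473 spikes over 2000 ms
#>   mean incoming dW module 1: -99.7%
#>   mean incoming dW module 2: +99.5%

b1 <- module_bursts(res, 1); b2 <- module_bursts(res, 2)
bursting_frequency(b1)            # 27.2 Hz gamma-band volleys
burst_lead(b1, b2)                # +2.1 ms: module 1 volleys lead
mean_phase_coherence(b1, b2)      # 0.778: strong inter-module locking
plot(res)                         # raster of the last 300 ms
```

Module 1's volleys lead by ~2 ms, so spike pairs across the modules fall
on the potentiation side of the STDP window in the 1→2 direction and on
the depression side in the reverse: synapses into module 2 saturate at
the +100% bound while synapses into module 1 are driven to −100%
(weights hit the floor). `weight_change(res, into = 2)` exposes the
per-synapse and per-cell maps behind these means, and
`run_trials(cfg, 4)` repeats the protocol with fresh seeds and reports
across-trial standard errors. `run_sweep(sweep_spec(...))` tabulates the
same statistics over a (gKs, DC, noise-rate) grid, and
`run_example("fig8_D")` etc. run the hotspot protocols with topographic
wiring. See the methods vignette (`vignettes/achnet-methods.Rmd`) for
the model, the numerics, and what the simulations do and do not
reproduce.

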