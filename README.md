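# lamwave

Mechanistic simulation of forward and backward alpha-band traveling
waves in the visual system, from laminar circuits to the scalp.

In human EEG, alpha oscillations (~7-13 Hz) propagate as waves along the
occipito-frontal axis: **backward** (anterior-to-posterior) waves
dominate at rest, and the direction **reverses to forward** under visual
stimulation. `lamwave` implements a hierarchical model that reproduces
this reversal from known cortical connectivity, and the analysis chain
that measures it at the scalp:

* **Laminar mean-field network.** Each of `N` cortical areas holds
  excitatory/inhibitory node pairs in Layer 4 and supragranular layers,
  wired by the canonical microcircuit. Node rates follow the FI transfer
  function `r = (λI − β) / (1 − e^{−θ(λI − β)})` of their summed input
  current; synapses are delayed, saturating gating variables
  `ṡ = −s/τ + γ(1 − s) r(t − ΔT)`.
* **Infragranular pacemakers.** Layer 5/6 of each area is a population
  of 350 Izhikevich bursting neurons generating a ~9-10 Hz rhythm,
  coupled into the mean-field network at its input and output. Backward
  coupling between pacemakers carries the resting backward wave; a
  delayed feedback loop through the supragranular layers carries the
  stimulus-evoked forward wave.
* **Scalp projection.** Per-area source signals are low-passed,
  downsampled to 100 Hz and projected through an analytic
  spherical-head radial-dipole lead field onto a standard 64-channel
  montage, together with five 1/f noise sources at randomized
  signal-to-noise ratios.
* **Wave fitting.** Band-passed analytic phases, referenced within an
  electrode ROI and averaged in sliding 100-ms windows, are fit by an
  exhaustive plane search over 60 directions x 30 spatial frequencies;
  the circular correlation between observed and predicted phases is
  tested against an electrode-permutation null, and each window is
  classified FW / BW / Null relative to the occipito-frontal axis.
* **Experiment drivers** reproduce the model's headline behaviors:
  sigmoidal response curves with a reversal threshold near 0.88 nA,
  impulse responses to non-rhythmic random stimulation, state
  probability time-courses, frequency-current coupling, inter-areal
  delay sweeps isolating the two pathways, pulvinar-pathway sweeps that
  bias the network toward spontaneous forward waves, and lateralized
  two-hemisphere simulations.

## A worked example

```r
library(lamwave)

net <- alpha_network(network_config())
net
#> Laminar alpha traveling-wave network
#>   3 area(s) x 1 hemisphere(s); pulvinar disabled
#>   19 nodes (3 pacemaker), 30 connections, inter-areal delay 12 ms

# 1 s rest, 4 s of 1.2 nA DC stimulation
trial <- simulate(net, duration = 5, seed = 1,
                  stimulus = make_dc_stimulus(1.2, 1, 5))
fit <- fit_waves(eeg_from_traces(trial))
fit
#> Traveling-wave fit: 491 windows, band 7-13 Hz, ROI 'midline'
#>   FW 82.5%  BW 11.2%  Null 6.3%  (rho threshold 0.384)
```

The trial spends its first second at rest (backward windows) and the
rest under stimulation (forward windows); `plot(fit)` shows the fitted
gradient direction flipping from the anterior (+pi/2, backward) to the
posterior (-pi/2, forward) axis at stimulus onset. The reversal
threshold comes from a response curve:

```r
rc <- run_response_curve(currents = seq(0, 2, length.out = 11),
                         n_runs = 6, duration = 3, seed = 42)
rc
#> FW response curve over 11 currents x 6 runs
#>   reversal threshold (sigmoid midpoint): 0.913 nA
```

See the methods vignette (`vignettes/lamwave-methods.Rmd`) for the
model equations, parameter table, sign conventions and design
decisions.

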