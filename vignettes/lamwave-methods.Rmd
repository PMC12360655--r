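---
title: "Laminar network models of forward and backward alpha traveling waves"
author: "lamwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar network models of forward and backward alpha traveling waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamwave)
```

## The model

Scalp EEG alpha oscillations (~7-13 Hz) organize as traveling waves along
the occipito-frontal axis: backward waves (front to back) dominate at
rest, forward waves (back to front) appear under visual stimulation.
`lamwave` implements a multiscale mechanistic account of this reversal: a
hierarchy of `N` cortical areas, each a set of laminar mean-field nodes,
with an intrinsically bursting spiking population in infragranular layers
acting as an alpha pacemaker.

Each mean-field node carries a firing rate set instantaneously by its
input current through the FI transfer function

$$ r(I) = \frac{\lambda I - \beta}{1 - e^{-\theta(\lambda I - \beta)}}, $$

with slope $\lambda = 270$ Hz/nA, offset $\beta = 108$ Hz and curvature
$\theta = 0.154$ s (the singular point at $\lambda I = \beta$ evaluates
to $1/\theta$). The input current sums weighted synaptic gates, a base
current $I_\mathrm{base} = 0.33$ nA, a per-node Ornstein-Uhlenbeck noise
current (stationary SD 0.025 nA) and any external stimulus. Synapses are
saturating gating variables

$$ \dot s = -s/\tau + \gamma (1 - s)\, r(t - \Delta T), $$

in five classes (fast/slow, excitatory/inhibitory, plus a 1-ms
infragranular self-excitation), integrated by forward Euler at 1 ms.

Each area wires Layer 4 (excitatory/inhibitory pair, recurrent
inhibition implementing input adaptation) to supragranular layers, and
supragranular to infragranular. Two inter-areal circuits coexist:

* the **FW pathway** — supragranular output feeds the next area's Layer 4
  (weight 2), closed by inhibitory feedback from the higher area's
  infragranular node onto the lower area's supragranular interneurons.
  This delayed negative-feedback loop oscillates when driven; its
  frequency depends on the 12-ms inter-areal delay.
* the **BW pathway** — a chain of infragranular pacemakers coupled
  backward by slow excitation. It oscillates autonomously.

A stimulus input layer (a Layer-4-like pair acting as an LGN-style
relay) feeds the first area; a second input pair at the top, driven by
bounded white noise (0-0.3 nA), keeps the BW chain tonically engaged.
An optional pulvinar pathway adds a feedforward relay from each area's
infragranular node to the next area's Layer 4 with weight
$w_{\mathrm{Pul}\to\mathrm{L4}} \in [0, 2.2]$.

## The pacemaker population

The infragranular node of each area is a homogeneous population of 350
Izhikevich neurons ($a = 0.0067$, $b = 0.2$, $c = -50$ mV, $d = 2$;
membrane equations at 0.5-ms substeps). Every neuron receives
$I_n = 4 I_\mathrm{node} + \mu_\varepsilon + \sigma_\varepsilon \eta_n$
with $[\mu_\varepsilon; \sigma_\varepsilon] = [6; 4]$. Two readings of
the Gaussian term $\eta_n$ are implemented: redrawn each 1-ms step
(`pace_noise = "white"`) or frozen per neuron at trial start
(`"quenched"`, the default). The equation carries no time index, and the
quenched reading — static heterogeneity — produces the cleaner
population rhythm: with per-step white noise the single-neuron
burst-time jitter accumulates to ±34 ms per cycle and the population
desynchronizes; with quenched heterogeneity the mean-field
self-excitation (weight 0.7, $\tau$ = 1 ms) entrains the population into
a partially synchronized ~9-10 Hz rhythm, which also locks the three
areas to a common frequency in the full network.

Two conversion conventions bridge spiking and mean-field scales. The
population output entering any synapse is
`gain * spiking_fraction / dt`, an instantaneous rate in Hz; the output
gain is the one genuinely free parameter of the model and is calibrated
once (default 1.0) against the joint phenomenology: ~9 Hz resting
rhythm, ~100 ms inter-burst intervals of the isolated population, a
silent supragranular compartment at rest, and the stimulus-driven wave
reversal with its ~0.9 nA threshold. Gains of 2 or more saturate the
downstream gates (the tonic infragranular-to-supragranular inhibition
then blocks the FW pathway and the reversal threshold drifts far above
1 nA), so the calibration is tightly constrained.

Because the population is only *partially* synchronized, its rate trace
oscillates around a nonzero floor rather than bursting from silence.
`burst_intervals()` therefore removes a slow baseline (251-ms moving
average) before thresholding the smoothed trace at 50% of its robust
(97.5th-percentile) maximum. The coefficient of variation of the
detected intervals is ~0.5, reflecting that partial synchrony; interval
means are nevertheless stable across seeds.

## EEG projection

Source signals are per-area averages of the five laminar rate traces,
zero-phase low-pass filtered (3rd-order Butterworth, 20 Hz), decimated
to 100 Hz, z-scored and projected through an analytic single-sphere
radial-dipole lead field (Legendre series
$\sum_n (2n+1) b^{n-1} P_n(\cos\gamma)$). Areas sit at occipital,
parietal and frontal MNI positions, bilaterally at half amplitude in
single-stream mode. Source eccentricity is capped at 0.6 of the head
radius: at the literal anatomical eccentricities a single-sphere
potential is far more focal than a realistic multi-shell head model,
the polarity flips of neighbouring dipoles interleave on the scalp, and
multi-source phase maps stop being planar (the plane fit then locks
onto the inverted gradient). The cap restores the spatial smoothing a
realistic volume conductor provides; wave *direction* is insensitive to
the remaining forward-model detail, wave *amplitude* topography is out
of scope.

Five independent 1/f noise sources at random intracranial positions are
added per trial, each scaled to a noise-to-signal RMS ratio drawn
uniformly from [0.4, 1.6]. The ratio is enforced in source space (noise
dipole amplitude relative to the unit-RMS cortical sources); enforcing
it at the sensor level instead (also available via `snr_space`) makes
the summed noise ~2.3x the signal and suppresses the resting backward
state far below the classification probabilities the simulations are
meant to produce.

## Wave fitting

`fit_waves()` band-passes each channel (7-13 Hz linear-phase FIR, three
cycles of the low edge, applied forward and backward), takes the
analytic phase, references it to the circular mean over the electrode
ROI, and averages it circularly in sliding 100-ms windows. For each
window an exhaustive grid search (60 directions x 30 spatial
frequencies, up to one cycle over the maximum electrode distance) finds
the planar phase model $\hat\theta = ax + by + \vartheta$ maximizing
the resultant length of the circular residuals; the circular correlation
$\rho$ between observed and predicted phases is compared against a null
distribution built from 10 electrode-position permutations at
one-fifth temporal resolution (the reduction factor is a free choice;
5 gives thousands of collated null values on typical runs). A window is FW
(BW) when $\rho$ exceeds the one-sided 95% null threshold and the
fitted gradient is within 0.5 rad of the (anti-)reference axis.

Sign conventions: $\alpha = \mathrm{atan2}(b, a)$ is the direction of
*phase increase*; a wave propagates opposite its phase gradient, so a
forward wave has $\alpha = -\pi/2$ in the 2D layout (+y anterior), and
that value is the default forward reference axis. At $\xi = 0$ the
direction is undefined and the window can only be Null. For lateralized
analyses the reference axis is the circular median of the classified
directions after reflecting BW through $\pi$ and mirroring the right
ROI across the sagittal plane; symmetric distributions resolve to the
midline (ties in the circular median go to the circular mean).

The electrode ROIs are frozen lists shipped with the package, derived
once from the azimuthal-equidistant projection of the standard 64-channel
montage: the midline rectangle (38 electrodes, Iz-Fz by the central
columns) and two 20-electrode lateral boxes excluding the midline. On
this projection the literal C3-C4 / C5-C6 bounding boxes contain fewer
electrodes than the published counts (the published layout compresses
outer columns), so the mediolateral bounds were widened once to
reproduce exactly 38 and 20 electrodes; the row structure matches the
landmark description.

## Experiment drivers and problem sizes

The drivers re-create the study protocols: DC response curves with a
4-parameter logistic fit whose midpoint is the reversal threshold
(~0.9 nA under defaults); random-step impulse responses (10 Hz update,
ON probability 0.5) cross-correlated against shuffled-pairing chance
bands; 100-trial state time-courses at the threshold amplitude with two
latency metrics; spectral analyses per node type; inter-areal delay
sweeps in full and FW-isolated configurations; pulvinar weight sweeps;
and dual-hemisphere lateralized simulations.

Latency metrics follow fixed rules. *Time to first peak*: because the
onset transient can saturate the across-trial FW probability at 1, a
literal first local maximum degenerates to noise on the plateau; the
metric instead reports the midpoint of the first contiguous
near-maximal run (within one binomial standard error of the maximum)
of the lightly smoothed (50 ms) probability after onset. *Return to
baseline*: the post-offset probability is detrended by a linear fit
over the final 2 s of rest and the metric is the first re-entry into
the mean ± 2 SD band of the raw pre-stimulus baseline. Trials carry a
3-s pre-stimulus period: the network needs a couple of seconds to
relax from its synchronized initial state, and the baseline window
([-2, -0.3] s; ending before onset because the zero-phase FIR smears
the transition backward) must reflect the steady state. The re-entry
time is intrinsically seed-sensitive here because the model's
post-offset decay is fast and the corrected trace then hovers at the
band edge (see Known limitations).

Default problem sizes were chosen for stable estimates at desk scale:
20 runs per current over 15 currents for response curves, 100 trials
for time-courses, 25 trials for impulse responses, 50 resting trials
for spatial-frequency summaries, three to four seeds for spectral
estimates with 4-s Welch segments and parabolic peak interpolation
(0.25 Hz grid, sub-bin estimates). The compiled integrator simulates
roughly 100x real time on one core, and the grid fit evaluates all
1800 plane parameters for ~1000 windows per second.

## What the generator does and does not emulate

The synthetic planar-wave and lagged-dipole fixtures validate the
fitting chain on its own terms: phases exactly obeying the planar model,
and sinusoidal sources with imposed lags projected through the
production lead field. They share none of the network's dynamics, so
passing them shows the *estimator* is correct, not that the *model* is
realistic. Conversely the network simulations inherit every
simplification listed above — identical areas, radial dipoles in a
sphere, source-space noise scaling — so quantitative scalp-level
statements (e.g. absolute classification probabilities) depend on those
choices, while the qualitative reversal, its threshold and the
source-level frequencies are robust to them.

## Known limitations

* The pacemaker populations are partially, not fully, synchronized
  under the printed noise parameters. Two consequences measured by the
  acceptance checks: the network re-locks into the backward state
  within ~1-2 cycles after stimulus offset, so the post-offset
  FW-persistence latencies (return to baseline, impulse-response decay)
  come out near 100-300 ms rather than the several-hundred-ms values a
  more coherent pacemaker would give; and the supragranular peak
  frequency is fully slaved to the infragranular one, so the two
  compartments' frequency-vs-current slopes coincide (~0.65 Hz over the
  suprathreshold range) instead of separating.
* The burst-interval CV of the isolated population (~0.5) exceeds what
  a fully synchronized population would show (< 0.25).
* Dipole placements are defined for the 3-area model; larger
  hierarchies are simulated at the source level only.
* No cross-hemispheric connections, no thalamic reticular circuitry,
  no pulvino-cortical feedback to lower areas, no plasticity.

## A worked example

```{r example, eval = FALSE}
net <- alpha_network(network_config())
trial <- simulate(net, duration = 5, seed = 1,
                  stimulus = make_dc_stimulus(1.2, 1, 5))
eeg <- eeg_from_traces(trial)
fit <- fit_waves(eeg)
summary(fit)
plot(fit)
```
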