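---
title: "The engram network model: dynamics, plasticity, and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The engram network model: dynamics, plasticity, and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`engramsim` simulates a randomly connected excitatory-inhibitory circuit of
conductance-based leaky integrate-and-fire neurons in which long-term
memories are represented by *engrams*: disjoint groups of excitatory neurons
whose mutual synapses carry an elevated weight. The membrane potential of a
neuron of type $k \in \{E, I\}$ obeys

$$\tau_k \frac{dV}{dt} = V_L - V + G^{E}(t)\,(E_E - V) + G^{I}(t)\,(E_I - V),$$

where the dimensionless conductances $G^{E}$ and $G^{I}$ sum bi-exponential
receptor kernels over all presynaptic spikes. Excitatory transmission
combines a fast AMPA component and a slow NMDA component; inhibition is
GABAergic. Each kernel is

$$S_R(t) = \frac{\mu_R\,\Theta(t-\tau_l)}{\tau_d^R - \tau_r^R}
  \left(e^{-(t-\tau_l)/\tau_d^R} - e^{-(t-\tau_l)/\tau_r^R}\right),$$

with time integral $\mu_R$. Recurrent excitatory synapses are additionally
modulated by presynaptic short-term plasticity in the facilitation-dominated
Tsodyks-Markram form ($u$ facilitates with $\tau_F = 1500$ ms, the resource
$x$ recovers with $\tau_D = 200$ ms, baseline release $U = 0.2$): at each
presynaptic spike the conductance increment is scaled by $u \cdot x$ sampled
at the spike. External input to every neuron is 400 independent 2.5 Hz
Poisson trains; since only their sum enters the conductance, they are
simulated as a single Poisson process of the summed rate, which is exactly
equivalent in distribution.

Recall is probed by *cueing* one engram at a time — adding 12.5 Hz per train
for 5 s — and asking whether the engram keeps firing above 5 spikes/s after
the cue ends (a *persistent state*, the model's proxy of successful recall).
Synaptic impairment is modelled by lowering the connection probability $C$,
and by the degradation operators `apply_degradation()` (fractions of
remaining neurons $R_N$, connections $R_C$, and weight $R_w$) and
`set_ei_manipulation()` (the excitatory-to-inhibitory weight).

## Long-term plasticity

All E→E synapses evolve, while learning is enabled, under a composite rule:
triplet STDP (potentiation $A\,z_j z_i^{slow}$ at each postsynaptic spike,
depression $B\,z_i$ at each presynaptic spike), heterosynaptic
stabilisation $-\beta\,z_i^3\,((w - \tilde w)/\tilde w)^3$ at each
postsynaptic spike, and a transmitter-induced increment $\delta_1$ at each
presynaptic spike. The traces $z$ gain one per spike of their own neuron and
decay with $\tau_{STDP} = 20$ ms (fast) and $\tau_{STDP}^{slow} = 100$ ms
(slow). Because the heterosynaptic term grows with the fourth power of
activity while the triplet term grows with the third, strong firing recruits
the stabiliser first, which is what bounds weights without a hard cap; a
hard floor of 0.001 prevents silent synapses. Plasticity updates are applied
with traces at their pre-update values, presynaptic terms before
postsynaptic terms at simultaneous events — the convention of the source
rule family; both orderings compose the same trajectories up to
$O(\text{amplitude}^2)$ per coincidence.

## Numerical scheme

The core (`src/sim_core.cpp`) advances the network on a fixed grid of
$dt = 0.05$ ms with second-order Runge-Kutta on the membrane equation,
conductances held constant within a step (they vary on 2–100 ms scales, so
the splitting error is far below the RK2 truncation error). Threshold
crossings are located by linear interpolation inside the step; the spike is
recorded at the interpolated time and the refractory clock starts there.
Each bi-exponential kernel is maintained by the *exact* two-accumulator
recursion (one decaying exponential per accumulator), so between-event decay
is exact to machine precision; the tests verify agreement with brute-force
kernel summation to $10^{-10}$ relative error. Synaptic increments travel
through a ring buffer implementing the 1 ms transmission latency rounded to
the grid. Short-term plasticity and the plasticity traces use exact
exponential relaxation per step, which composes to the event-based closed
form exactly; the clock-driven and event-based integrations of the
two-neuron laboratory agree to $<10^{-6}$ over 100 s.

Three RNG streams are kept independent and separately seeded: connectivity
(R's RNG inside `build_network()`), external drive, and rescue resets (two
`mt19937_64` streams inside the core). Two runs with the same graph and
seed are bit-identical.

## Parameter provenance and calibration

The architecture (2000 E / 400 I, ten engrams of 200, $C$ varied around
0.25, 400 × 2.5 Hz background trains, 12.5 Hz cues), the plasticity
structure, and the analysis thresholds are fixed by the design of this
model family. The remaining constants of the membrane, receptor,
short-term-plasticity, and learning-rule blocks are free parameters here;
we adopt the standard constants of the respective source-model families —
membrane: $\tau_E = 20$ ms, $\tau_I = 10$ ms,
$V_L = -70$ mV, $V_{th} = -50$ mV, $V_{reset} = -60$ mV, $E_E = 0$ mV,
$E_I = -80$ mV, 2 ms refractory; kernels: AMPA 0.5/2 ms, NMDA 2/100 ms,
GABA 0.5/5 ms — and calibrate the free amplitudes ($\mu_R$ and the weight
set) against the behaviour the model is documented to have:

* a low-rate asynchronous background of the excitatory population
  (< 5 spikes/s) with no spontaneous engram activation over tens of seconds;
* a cued engram that remains in a persistent state at $C \approx 0.25$
  (bistability), with persistence lost when $C$ falls to roughly 0.15;
* sequential recall in which the cue to the next engram terminates the
  previous persistent state (persistence score near 1 at high $C$, low
  engram overlap);
* after learning at high $C$, intra-engram weights settling at 0.5–0.6,
  comparable to the preset intra-engram weight.

The calibrated weight set (package defaults) uses $g^M_{EE} = 0.68$,
baseline $g_{EE} = 0.02$, $g_{IE} = 0.41$, $g_{EI} = 0.56$, $g_{II} = 0.14$,
external weights 0.082 (E) and 0.172 (I), with kernel amplitudes
$\mu_{AMPA} = \mu_{GABA} = 0.145$ and $\mu_{NMDA} = 0.0725$. Because only
the products $w\,\mu_R$ enter the dynamics, these weights are meaningful in
the package's own conductance units; they are not interchangeable with
values quoted for other implementations whose kernel amplitudes differ.
The stronger external weight onto inhibitory neurons supplies the tonic
inhibitory tone that keeps the low-activity state stable against background
fluctuations — the ingredient that makes the engram genuinely bistable
rather than self-igniting.

Plasticity amplitudes default to $A = 2\times10^{-4}$,
$B = 1.2\times10^{-4}$, $\beta = 0.05$, $\delta_1 = 2\times10^{-5}$,
$\tilde w = 0.5$; $\beta$ was calibrated so that the learnt engram's weights
equilibrate near $\tilde w$ (the observed end-of-learning mean is ~0.6 at
$C = 0.25$), satisfying the "comparable to the preset weight" criterion.

## The scaled network

Desk-scale work (tests, examples) uses `scaled_config()`: 600 E / 120 I
with **three engrams of 200 neurons**. We deliberately preserve the engram
size, and with it the intra-engram input statistics (≈ 50 recurrent
partners per engram neuron at $C = 0.25$), and shrink only the number of
engrams and the background/inhibitory pools; the count-sensitive weights
(baseline E→E and everything touching the inhibitory population) are scaled
up by the population ratio so per-neuron input sums match the full circuit.
Shrinking the engram itself (for example to 60 neurons) makes finite-size
fluctuations so large that the low-activity state ignites spontaneously —
there is then no bistable window at all — which is why the scaled model
keeps 200-neuron engrams.

Under the scaled conditions the model reproduces, qualitatively, the
connectivity phenomenology: persistence score ≈ 0.97 and overlap ≈ 0 at
$C = 0.25$; loss of persistence below $C \approx 0.14$; a hysteresis loop
whose switch points straddle the background rate, with both stability
margins ($S_p$ for the persistent state, $S_l$ for the low state) shrinking
as $C$ is lowered; rescue stimulation (periodic membrane resets of half the
interneurons at 40 Hz, 50% duty cycle) restoring persistence at marginal
$C$ at the cost of co-activating non-cued engrams; and learning that
potentiates the new engram more at high than at low connectivity.

Two caveats on what desk-scale agreement does and does not show. First, the
$S_p$/$S_l$ trends are measured on a 0.2 Hz ramp grid and are small
(0.2–0.4 Hz) relative to that grid at this scale, so they are assessed as
rank correlations over seeds rather than as smooth curves. Second, the
learning contrast between high and low $C$ is systematic across seeds but
numerically small here: with the calibrated external weights the 12.5 Hz
learning signal drives the engram close to its rate ceiling at every $C$,
so the connectivity acts mainly through feedback inhibition rather than
through the burstiness route that dominates at full scale. The direction of
the effect matches; its magnitude at full scale should not be inferred from
the scaled runs.

## Analysis conventions

* Persistent states: population rate in a 1 s moving window stepped at
  1 ms, assigned to the window's left edge; threshold 5 spikes/s; sub-1 s
  gaps merged; intervals half-open in ms. The window introduces edge
  effects of up to one window length at state boundaries.
* Persistence score: per engram $x_i = 1 - |T_i^{persist} -
  T_{ideal}|/T_{ideal}$, rectified at 0 and averaged **over engrams** (the
  total duration is defined per engram, so the engram is the natural
  averaging unit); the engram's own cue window is excluded from
  $T^{persist}$.
* Overlapping proportion: intersection-over-union of the engrams'
  persistent-state time sets, with all cue windows excluded from both the
  intersection and the union, so the measure reflects spontaneous
  co-activation rather than cue bookkeeping.
* Synchrony index: coincident 1 ms bins normalised by
  $\sqrt{\sum B_i \sum B_j}$, so identical trains score exactly 1; the
  unrooted variant is available via `sqrt_norm = FALSE`. Population values
  average up to 2000 sampled within-engram pairs.
* Oscillation power: FFT of the mean-detrended average excitatory membrane
  potential in the 10 s window after cue offset, normalised to the
  spectrum's own mean; theta 4–12 Hz, slow gamma 30–60 Hz, fast gamma
  60–120 Hz.
* Bifurcation ramp: the single engram's external rate is stepped 0.2 Hz
  per second from the background rate up to +2 Hz and back down to −2 Hz;
  switch points are the first 1 s blocks crossing 5 spikes/s on each
  branch (no interpolation — the ramp step is the resolution). $S_l$ is
  reported as the distance of the ascending switch point from the
  background rate, consistent with its description as a distance; the
  literal unsubtracted variant is available via `literal_sl = TRUE`.
* Degenerate inputs: engrams must be non-empty; a branch with no threshold
  crossing yields `NA` switch points (absent, never zero); receptor rise
  and decay constants must differ in the network core, while
  `kernel_value()` handles the equal-constant alpha-function limit
  analytically.

## What the fixture generator emulates

`generate_fixture_raster()` draws inhomogeneous Poisson spikes with
prescribed elevated intervals per engram. It reproduces exactly the
features the persistent-state metrics consume — rate steps with known
boundaries — and none of the features the simulator produces beyond them
(oscillations, synchrony, refractoriness, rate adaptation). Metric tests on
fixtures therefore validate the measurement layer, not the network
dynamics; the protocol-level tests on the scaled network cover the latter.

## Known limitations

* No NMDA voltage dependence (magnesium block), receptor saturation,
  homeostatic or inhibitory plasticity, or adaptive thresholds.
* Connectivity is homogeneous (no spatial structure); engrams are
  contiguous index blocks.
* The rescue abstraction is a membrane reset, not an optogenetic
  biophysical model.
* The full-scale default configuration reproduces background stability and
  cue-driven persistence, but the package's quantitative statements are
  made, and tested, at the scaled size; full-scale sweeps are expensive and
  are left to the user.
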