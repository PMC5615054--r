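---
title: "Dendritic spikes, plasticity and memory retention: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic spikes, plasticity and memory retention: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendplast)
```

`dendplast` simulates a reduced multicompartment pyramidal neuron with a
local voltage-dependent plasticity rule, and the stimulation protocols that
probe how NMDA-spike-mediated dendritic LTP (dLTP) protects synapses from
being overwritten by ongoing activity. This vignette is the package's
account of the model, the numerical choices behind the implementation, and
what the shipped experiments do and do not show.

## The reduced neuron

A neuron is one somatic compartment coupled to `n_dendrites` dendrites of
two point compartments each, a proximal and a distal one. Every compartment
integrates

$$C\,\dot u = -g_L (u - E_L) + I_{\mathrm{exp}} + I_{\mathrm{axial}} +
I_{\mathrm{syn}} + I_{\mathrm{ext}} + I_{\mathrm{noise}},$$

with $C = 281$ pF, $g_L = 40$ nS and $E_L = -69$ mV. The soma additionally
carries the exponential spike-initiation current
$I_{\mathrm{exp}} = g_L \Delta_T \exp((u - V_T)/\Delta_T)$ with slope
$\Delta_T = 2$ mV and an adaptive threshold $V_T$ that jumps to $-30.4$ mV
after each spike and relaxes to $-50.4$ mV with $\tau_{V_T} = 50$ ms. When
the somatic voltage crosses $20$ mV (or a spike is forced by a protocol),
the soma is held at $30$ mV for one spike width (1 ms) and then reset to
$-55$ mV; all dendritic compartments of the neuron are held at the
back-propagation values ($10$ mV proximal, $-3$ mV distal) for 1 ms,
starting at the first step boundary at or after 0.3 ms (realised delay:
0.5 ms at the default step).

### Axial coupling and its sign convention

The compartments exchange current through rectified couplings: each
direction of flow has its own conductance. In the default `"diffusive"`
convention a proximal compartment gains $2500\,\mathrm{nS}\,(u_s - u_p)$
when the soma is higher and loses $1250\,\mathrm{nS}\,(u_p - u_s)$
otherwise, of which the soma receives only $50$ nS per dendrite — backward
propagation is heavily attenuated, which is why an NMDA plateau on a single
dendrite stays sub-threshold at the soma. The proximal–distal pair
exchanges charge conservatively: 1500 nS in the forward (toward the tip)
direction and 225 nS backward.

An alternative `"as_printed"` convention (available in
`axial_currents()`) applies a leading minus to the soma-proximal terms and
pairs the distal conductances the other way round. It is retained for
comparison only: under that reading the soma–proximal coupling is
anti-diffusive, so a single somatic spike arms a positive-feedback loop
between soma and dendrite that never stops spiking, and an elevated distal
compartment is drained through 1500 nS, which puts the NMDA-plateau
voltage out of reach of any physiological synaptic conductance. Both
pathologies are demonstrated in the test suite's stability checks; the
diffusive convention reproduces the intended phenomenology (clean return
to rest after a spike; plateaus ignite under clustered drive).

### Integration scheme

All compartments advance by **exponential Euler** at $\Delta t = 250$ μs:
per step, every conductance-like term (leak, the currently active axial
branches, AMPA, NMDA with the magnesium block frozen at the current
voltage, inhibition) is folded into a total conductance $G$ and a drive
$b$, and the voltage relaxes exactly toward $b/G$ with factor
$e^{-G\Delta t/C}$. This matters because the axial branch conductances
(up to 2500–4000 nS against 281 pF) give compartment time constants of
0.07–0.2 ms, shorter than the step: a plain forward-Euler update is
unconditionally unstable there, while the exponential update is stable for
any step size and exact for piecewise-constant coefficients. The test
suite checks the integrator against an independent forward-Euler reference
at $\Delta t/16$: fixed-current trajectories agree within 0.2 mV over
100 ms; trajectories with synaptic events are limited by the one-step
transient at each conductance jump (the jump acts over a whole coarse
step) and agree within ~0.75 mV at the default step, halving as the step
is refined.

### Spike holds as an overlay

The spike and back-propagation holds are *imposed observables*, not
current sources. Two consequences are built into the engine. First, while
the soma is held at 30 mV the dendrites do not see it through the axial
coupling — otherwise the 2500 nS forward branch would drive the proximal
compartments to ~+25 mV before their own 10 mV hold, inflating the
realised dendritic spike height. Second, while a neuron's dendritic hold
is active the soma does not receive axial current from the held
compartments, and when the hold ends each dendritic compartment resumes
from its pre-spike voltage. With 15 dendrites, letting the 10 mV holds
discharge into the freshly reset soma would inject ~48 nA and re-trigger a
spike indefinitely; restoring the pre-spike state also means an ongoing
NMDA plateau survives a somatic spike, which is essential for dLTP during
network events. The plasticity rule, by contrast, always sees the held
voltages — that is what makes bAP-driven potentiation work.

## Synapses

AMPA ($\tau = 2$ ms) and NMDA ($\tau = 50$ ms) conductances jump by
$w \cdot g_{\max}$ per presynaptic spike ($g_{\mathrm{AMPA}} = 100$ nS,
$g_{\mathrm{NMDA}} = 50$ nS at weight 1; the `"detailed"` preset carries
the morphological-model values of 1.5 nS) and decay with the exact factor
$e^{-\Delta t/\tau}$. The NMDA current is gated by
$B(v) = 1/(1 + e^{-0.062 v}/3.57)$; its supralinearity near $-40$ to
$-20$ mV is the regenerative mechanism behind NMDA spikes. Currents at
distal compartments are multiplied by 2.5, standing in for their higher
input resistance; the gain is treated as a property of the compartment, so
recurrent synapses landing distally receive it too (switchable in
`circuit()`). Whether the NMDA jump scales with the instantaneous weight
is ambiguous where only the AMPA arm is plastic; the default scales both
jumps with $w$ while keeping $g_{\mathrm{NMDA}}$ itself fixed
(`nmda_scales_with_w` switches this off).

## The plasticity rule

$$\dot w = -A_{\mathrm{LTD}}\,X(t)\,(\bar u_- - \theta_-)_+ +
A_{\mathrm{LTP}}\,\bar x(t)\,(u - \theta_+)_+\,(\bar u_+ - \theta_-)_+$$

acting on the *local dendritic* voltage of the synapse's compartment, with
hard bounds $w \in [0.01, 1]$, $\theta_- = -69$ mV, $\theta_+ = -15$ mV,
$A_{\mathrm{LTD}} = 5\times10^{-4}$ /mV,
$A_{\mathrm{LTP}} = 15\times10^{-4}$ /mV²/ms, $\tau_x = 15$ ms and
$\tau_\pm = 35$ ms. Depression fires per presynaptic spike when the slow
voltage filter is above $\theta_-$; potentiation requires presynaptic
traces *and* instantaneous depolarisation above $\theta_+$ *and* a
depolarised $\bar u_+$ — an isolated post–pre pairing depresses, while
pre–post–post triplets (bursts) and NMDA plateaus potentiate. The
`"reduced_delay"` variant feeds the filters with the voltage delayed by
$\varepsilon = 1$ ms (realised as 4 steps); the `"detailed_u1"` variant
(the `"detailed"` preset) introduces the delay through an extra 5 ms filter and
applies no plateau gating.

The dLTP gate compares the local voltage with its value 1.3 ms earlier
(realised lookback: 5 steps = 1.25 ms, longer than the 1 ms spike width,
so only a plateau can open it) and scales $A_{\mathrm{LTP}}$ by 0.15 while
open, applied per step. Numerical semantics, mirrored exactly between the
engine and the standalone `plasticity_trajectory()`:

* the presynaptic impulse acts at the start of its step: depression reads
  the filter value just before the impulse, and the trace increments
  before the step's potentiation;
* filters use the exact decay factor per step;
* the potentiation integral uses mid-step values of $\bar x$ and
  $\bar u_+$ (midpoint rule; the voltage itself is constant within a
  step), which brings agreement with a $\Delta t/16$ scalar reference to
  within 0.2% of the weight change on random 1 s episodes — the right-
  endpoint rule leaves a ~2% bias;
* weights are clipped to the bounds after every update.

## Stimuli, noise and the network generator

Protocol drive is built from seeded homogeneous Poisson trains snapped to
the step grid (`poisson_train()`, `schedule_input_spikes()`); forced
somatic spikes stand in for the brief suprathreshold current injections of
the corresponding experiments, producing the identical observable (a
somatic spike plus its back-propagation holds) without tuning a current.
Somatic noise is an Ornstein–Uhlenbeck current parameterised by its
stationary mean and s.d., discretised with the exact transition so the
moments hold at any step; the association protocol uses (35, 3.5) pA with
$\tau = 20$ ms and the network protocols (150, 15) pA. The correlation
time of the network noise is not separately specified anywhere, so the
package adopts the 20 ms used by the association protocol as its default.

`build_network()` wires all-to-all plastic connectivity (one synapse per
ordered pair), places exactly half the connections distally, clusters the
distal synapses arriving from one feature onto a single distal compartment
per postsynaptic neuron (distinct compartments across features — hence at
most as many features as dendrites), and attaches 50 non-plastic input
synapses per neuron uniformly over proximal compartments. The input weight
is not specified by the source experiments; the package uses 1.0 (the
reference weight), chosen once so that a 350 Hz × 10 ms activation event
drives each targeted neuron to fire a handful of spikes — at weights below
~0.5 the adaptive threshold limits neurons to at most one spike per event
and the network dynamics stretch far beyond the scaled run lengths. Somatic
feedback inhibition follows the filtered presynaptic spike count
($\tau_{\mathrm{inhib}} = 30$ ms, $\tau_{\mathrm{rise}} = 2$ ms,
$E_{\mathrm{GABA}} = -75$ mV, scale 0.125 nS for the four-feature network
and 0.100 nS for the overlapping-association network).

## Protocols and scaled run lengths

The single-neuron protocols run at their stated sizes. The network runs
are scaled down to keep a full reproduction under a few minutes on one
CPU: the feature network runs 20 s (events every 260 ms) instead of 100 s,
and the overlapping-association network 10 s per phase instead of 100 s;
the full-length durations remain available through the `duration_s` and
`phase_s` arguments. With the compressed drive the qualitative orderings
emerge well within these windows: proximal between-feature weights
depress while distal ones are held up by clustered plateaus, and after the
probability reversal the proximal shared-to-unshared weights of the first
association sit below the corresponding distal ones.

## What the experiments do and do not show

* **Temporal order (two-neuron, clustered).** Distal clusters classify as
  bidirectional in every run. Proximal clusters classify as unidirectional
  (first-to-second) in ~90% of runs; in the remainder, a presynaptic spike
  of the second neuron lands within ~1 ms of the first neuron's final
  back-propagating spike at the 10 ms window boundary — a genuine
  pre–post–post triplet under the rule, whose potentiation can outweigh
  the accumulated depression and flip the pair to bidirectional. This is
  intrinsic to adjacent induction windows with Poisson drive at these
  parameters, not a numerical artefact; the published all-or-none proximal
  outcome came from a small number of runs of the morphological model.
* **Single-cell association.** Proximally clustered pools lose weight
  while distally clustered pools stay near the upper bound at typical
  seeds. Four-synapse pools sit close to the plateau-ignition margin of
  the reduced geometry, so on some stimulus draws a distal pool fails to
  ignite reliably and loses weight as well — larger pools or rates move
  the protocol away from that margin. The *output* side of the experiment
  does not transfer at all: two simultaneous distal plateaus deliver only
  $2 \times 50\,\mathrm{nS} \times (u_p - u_s)$ to the soma, which stays
  a few mV below spike initiation, so joint activations are recorded but
  rarely fire the cell.
* **Overlapping associations.** In the compressed regime the assemblies
  saturate within seconds and the network sustains activity between
  events; the proximal-vs-distal stability contrast still forms — and for
  the stated reason, presynaptic activity against weakly depolarised
  postsynaptic dendrites erodes proximal synapses while clustered
  plateaus pin the distal ones — but the proximal erosion is milder than
  in the published full-length, gently driven curves.
* The synthetic stimuli are homogeneous Poisson trains with fixed event
  schedules; real afferent activity is neither stationary nor
  independent across synapses, so passing these tests says nothing about
  temporally structured natural input.

## The distance re-analysis

`connection_distance_summary()` computes multiplicity-weighted means and
population (N-divisor) standard deviations of published synapse-to-soma
distances for unidirectionally and bidirectionally connected thick-tufted
layer-5 pairs (basal and oblique dendrites only; the table ships in
`inst/extdata/markram_distances.tsv`). The N-divisor convention is the one
that reproduces the published values (the N−1 form gives 29.1 rather than
28.6 μm for the unidirectional class); the tests pin both. Bidirectional
pairs synapse on average ~17 μm further from the soma — consistent with
the model's prediction that bidirectional connectivity survives where
dLTP is available.

```{r}
connection_distance_summary()
```
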