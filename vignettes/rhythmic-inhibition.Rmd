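---
title: "Rhythmic inhibition and dendritic integration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythmic inhibition and dendritic integration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dendrhythm)
```

## The scientific question

Cortical pyramidal neurons receive inhibition from interneuron classes that
differ in two coupled ways: *where* they synapse (parvalbumin-like basket
cells target the soma and proximal dendrites; somatostatin-like cells target
distal dendrites) and *when* they fire (perisomatic inhibition is associated
with gamma rhythms, 40--80 Hz; dendritic inhibition with beta, 12--35 Hz).
Because the dendrites of a layer 5 pyramidal neuron are themselves
excitable -- supporting Na^+^ spikelets, NMDA plateau potentials, and a
Ca^2+^ plateau at the apical nexus -- the *consequences* of inhibition depend
on which of these regenerative mechanisms it reaches and on whether its
rhythm is commensurate with their timescales. `dendrhythm` implements an
in-silico version of this question end to end: synthetic presynaptic drive,
a conductance-based multicompartment neuron, detectors for each dendritic
event class, and the phase-resolved statistics that quantify how inhibition
shapes them.

## The neuron model

The cell is a reduced, synthetic stand-in for a reconstructed layer 5
pyramidal tract neuron: a somatic cylinder, a short axon, a tapering apical
trunk rising to a nexus section where a three-order tuft expands, and a fan
of bifurcating basal dendrites. At full scale the apical cable totals
7440 um and the basal cable 4649 um -- the values the synapse-density
budget is built on -- and every branch is divided into compartments of at
most 20 um. `morphology_params(scale = )` shrinks all branch lengths
proportionally; synapse placement always uses densities per um of cable, so
the local synaptic physiology is preserved at reduced scale.

Membrane dynamics follow the Hodgkin--Huxley formalism with ten voltage- or
calcium-gated conductances (fast and persistent Na^+^, h-current,
muscarinic K^+^, slow- and fast-inactivating K^+^, Kv3.1-type K^+^, high-
and low-voltage-activated Ca^2+^, and SK). Gating kinetics follow the
standard published forms for this channel family at 34 degrees C. The soma
carries every channel except the muscarinic current; dendrites carry exactly
the seven-channel roster \{NaT, Ih, Im, Kv3.1, CaHVA, CaLVA, SK\}. Passive
parameters: 1 uF/cm^2^ (soma/axon) and 2 uF/cm^2^ (dendrites, correcting
for spine membrane), axial resistivity 100 Ohm cm, leak reversal -90 mV.

Per-region peak densities (`channel_density_map()`) are **configuration,
not measurements**: the source publication for this class of study does not
print per-compartment density tables, so the defaults here were tuned once
so that the default cell is *event-competent* -- it fires overshooting
somatic action potentials with a rheobase of a few hundred pA, produces
NMDA plateaus (> -40 mV for >= 26 ms) in thin dendrites under clustered
volleys, generates a nexus Ca^2+^ plateau that converts a single somatic
spike into a burst, and supports backpropagating action potentials that
decay from trunk to tuft. Two deliberate departures from a uniform
channel carpet matter:

* the **nexus** carries a calcium hot zone dominated by the HVA current
  (0.012 S/cm^2^ HVA vs 0.008 LVA). An LVA-dominated hot zone produces
  plateaus that inactivate in ~20 ms, too short for the 26 ms detection
  criterion; the HVA-dominated mix sustains 25--35 ms plateaus.
* the **tuft** is damped by elevated leak (1.77e-4 S/cm^2^), Kv3.1
  (0.02 S/cm^2^), Im (0.001 S/cm^2^), and an SK/CaLVA pair
  (0.024/0.001 S/cm^2^). Without this, the 2.16 synapses/um excitatory
  density drives thin terminal branches into permanent depolarisation
  block (the tuft sits above -40 mV most of the time and no discrete
  events exist to detect). The SK route was chosen over pure Kv damping
  because calcium-dependent termination leaves plateau *duration* sensitive
  to synaptic input, which is what lets a slow inhibitory rhythm entrain
  plateau onsets.

## Synapses

Excitatory contacts carry AMPA and NMDA receptors, inhibitory contacts
GABA~A~. Each receptor follows the two-state transmitter-gating scheme
`r' = alpha*ON*(1 - r) - beta*r`, with `beta = 1/tau_decay` and
`alpha + beta = 1/tau_rise` derived from the printed rise/decay constants
(AMPA 0.6/6.9 ms, NMDA 3.7/125 ms, GABA~A~ 0.5/6.8 ms; reversals 0 and
-75 mV). The transmitter pulse duration defaults to the dual-exponential
time-to-peak (1.61, 13.43, and 1.41 ms respectively) so that a single
activation peaks at the closed-form time
`tau_r*tau_d/(tau_d - tau_r)*log(tau_d/tau_r)`; it is exposed as the
`t_on` field of `kinetic_params()`. The NMDA conductance is additionally
scaled by the magnesium block `s(V) = 1/(1 + 0.33*exp(-0.06 V))`.

Short-term depression uses two multiplicative factors that recover
exponentially (`tau_D1`, `tau_D2`) and are scaled by constants `d1`, `d2`
at each presynaptic stimulus; the effective depression is their product,
clamped at 1. The three presets (excitatory 35 ms/0.95 + 250 ms/0.8;
perisomatic inhibition 40 ms/0.7 + 500 ms/0.7; dendritic inhibition
200 ms/0.8 with the slow factor disabled) reproduce the intended ordering
of 8-pulse/50 Hz train-induction values: perisomatic inhibition depresses
hardest, dendritic least. Depression advances on every presynaptic
stimulus whether or not it releases; a Bernoulli gate with the contact's
release probability decides transmission.

Maximal conductances: excitatory contacts are drawn from a log-normal with
distribution mean 0.2 nS and SD 0.345 nS; inhibitory contacts are fixed at
1 nS. The NMDA:AMPA peak-conductance ratio is not constrained by the
printed postsynaptic-current magnitudes (those are AMPA-dominated at
hyperpolarised holding) and is the single most consequential free synaptic
parameter: it defaults to **0.8** (`nmda_ratio` in `integrate_cell()`),
the value at which the default cell's tuft produces discrete, sparse NMDA
plateaus rather than saturating. Values near 2 are appropriate for
single-branch plateau demonstrations; values above ~1 under the full
in-vivo-like drive push the tuft into depolarisation block.

## Presynaptic drive (the synthetic-data generator)

The generator emulates in-vivo-like afferent statistics; its defaults *are*
the study conditions.

* **Per-node rates.** Excitatory node means are gamma-distributed with
  mean 4.43 Hz and SD 2.9 Hz (moment-matched, truncated at 0.1 Hz);
  perisomatic inhibitory nodes use 16.9 +/- 14.3 Hz and dendritic
  inhibitory nodes 3.9 +/- 4.9 Hz, the same way.
* **Functional groups.** Excitatory nodes form groups of 100 (scaled down
  proportionally with the morphology, minimum 20) sharing one slow
  modulator: white noise filtered with a 1/sqrt(f) spectral mask and
  min--max normalised to exactly [0.5, 1.5]. Group members are therefore
  correlated, emulating presynaptic assemblies; their contacts cluster
  within 5--10 um on one branch, 2--8 contacts per node, with all of a
  group's clusters inside a 100 um path-distance span.
* **E/I balance.** The average excitatory modulator, shifted forward by
  4 ms (configurable to 125/250/500 ms for lag experiments) and rescaled,
  modulates the inhibitory nodes. For lag experiments the excitatory
  modulator is first raised to the fourth power and renormalised to its
  mean, exaggerating excursions.
* **Rhythms.** A sinusoidal modulator `A*sin(2*pi*f*t + phi) + off` with
  `A = off*d/(1 - d)` (depth `d`) replaces the E/I-tracking modulator for
  the targeted inhibitory zone; excitation is then homogeneous Poisson, so
  any phase structure in the output is attributable to inhibition. Beta is
  16 Hz at 20% depth on distal synapses; gamma 64 Hz at 40% perisomatically.
  Bursts multiply the oscillatory term by Gaussian envelopes with sigma of
  two cycles. The printed sine expression places `phi` additively outside
  the sine; that is dimensionally a rate offset, so `phi` lives inside the
  argument here.
* **Spike generation.** Bernoulli-per-bin thinning on a 1 ms grid
  (`spike if u <= r[t]*dt`, dt in seconds); delivery to the membrane solver
  rounds event times to the nearest 0.1 ms step.
* **Clustered input.** Forty spike trains made by jittering one 10 Hz
  Poisson process by +/- 2 ms drive a patch of 187 synapses over 140 um of
  cable (1.3/um) at the nexus or on soma-adjacent basal branches. The
  source rate of the base process is not a printed value; 10 Hz was chosen
  as a realistic evoked-assembly rate that gives the cross-correlogram
  enough presynaptic volleys to be estimable in a 20 s run. The patch is a
  fixed experimental manipulation and does not shrink with morphology
  scale.

What the generator does *not* emulate: adaptation or refractoriness in the
afferents, spatial rate gradients, interneuron network dynamics (rhythms
are imposed, not emergent), and any fitted empirical rate distribution
beyond the stated moments. Passing tests therefore demonstrate the
mechanisms under idealised Poisson statistics, not a fit to recorded data.

## Event detection

Operational criteria, applied to recorded traces:

* **AP**: somatic V crosses -10 mV with positive slope; the peak time is
  kept for threshold analysis (threshold = V one millisecond before the
  peak).
* **Na^+^ spike**: activated Na^+^ conductance density exceeds
  0.3 mS/cm^2^, unless within 2 ms after a somatic AP (backpropagation
  guard; the window is configurable, and 5 ms reproduces the stricter
  variant).
* **NMDA / Ca^2+^ spike**: V above -40 mV for at least 26 ms *and* the
  relevant current magnitude (NMDA current, or summed HVA+LVA calcium
  current) reaches 130% of its value at the -40 mV crossing; the event
  ends when the current falls back to 115% of that reference.

The joint criterion distinguishes the two plateau classes on constructed
fixtures by design (a flat calcium current can never satisfy the Ca^2+^
ratio rule during an NMDA plateau). On *simulated* tuft plateaus, however,
both currents typically grow with voltage, so the same depolarisation is
often counted by both detectors; pooled NMDA and Ca^2+^ rates from
naturalistic runs should be read with that overlap in mind. This is a
property of the ratio-based criterion itself, which contains no absolute
scale.

## Phase conventions and analytics

All phase assignment goes through `phase_of()`: phase 0 is the *maximum*
of the modulated inhibitory rate and +/- pi its minimum. The peak stratum
is where inhibition exceeds its offset. Phase histograms use eight pi/4
bins; entrainment of event onsets uses the pairwise phase consistency
(PPC), the unbiased mean cosine of pairwise phase differences, computed
through the resultant identity.

One deliberate refinement: analyses of *somatic excitability* (AP
threshold and membrane statistics by stratum, and the stratification of
presynaptic arrivals in the clustered-input experiment) shift event times
back by the synaptic kernel's phase lag
`(atan(w*tau_r) + atan(w*tau_d))/w` (`synaptic_phase_lag()`) before
assigning phase. The inhibitory *conductance* -- the quantity that shunts
-- lags the presynaptic rate by ~81 degrees at 64 Hz, nearly a quarter
cycle; stratifying by raw rate phase at gamma frequencies averages over
opposite conductance states and nulls the mechanism being measured. A
regression of AP threshold on the sine and cosine of rate phase confirms
that the modulation sits almost entirely in the quadrature component.
Dendritic-spike phase histograms keep the raw rate-phase convention.

The phase-stratified cross-correlogram (1 ms bins) is corrected for the
periodicity that the rhythm and the stratification themselves induce:
the correlogram and both autocorrelograms are Fourier-transformed, the
coefficients at the modulation frequency (nearest bin plus one neighbour
each side, and conjugates) are zeroed, the CC transform is divided
element-wise by the square root of the product of the autocorrelogram
transforms, and the result inverse-transformed. The transmission summary
is the integral of the positive peak nearest zero lag between its flanking
zero crossings, searched over causal lags (0--30 ms) in the clustered
experiment.

## Numerics

The cable equation on the branched tree is solved implicitly
(backward-Euler voltage step with channel conductances frozen over the
step) by Hines elimination in parent-before-child order; gating variables
advance by exact exponential (Rush--Larsen) updates with rate functions
tabulated on a 0.05 mV grid. The default step is 0.1 ms; halving it
changes a subthreshold active trace by well under 0.5 mV RMS, and the
passive solver matches an independent frequency-domain admittance solution
to ~1e-12 relative error. Synaptic state uses an exact aggregation: all
contacts of a compartment whose transmitter pulse has ended share one
decay factor per receptor class, so their summed conductance is advanced
as a single scalar, while contacts inside their pulse are integrated
individually; a contact's residual is extracted exactly from the aggregate
when a new release arrives. Calcium pools are integrated forward-Euler
(decay constants >= 80 ms make this benign), and the calcium reversal
follows the Nernst relation at each step. Electrotonic attenuation is
computed from the complex admittance matrix at 20 Hz (10 Hz gives the same
ordering); decile grouping ranks compartments per dendrite class with ties
broken by compartment id.

Degenerate inputs are handled explicitly: empty strata in the CC return an
empty result with a warning, compartments with zero event rates are
excluded from STA aggregation with a warning, plateau excursions shorter
than 26 ms or lacking the current criterion yield no event, and an
all-subthreshold f-I curve flags itself rather than fitting a slope.

## Scale of the shipped experiments

The packaged experiment helpers default to a half-scale morphology
(~5900 um of cable, ~330 compartments, ~4400 excitatory and ~900
inhibitory contacts, with the 150-contact somatic contingent kept at full
strength because the soma does not shrink). Default condition lengths are
10 s (tonic contrasts), 12 s (beta), 20 s (gamma and clustered runs), with
three seeds per stochastic comparison and medians across seeds; the
acceptance checks in `tests/testthat/test-acceptance.R` state the exact
protocols. These sizes were chosen as the point where the robust effects
(distal suppression of plateau events, beta entrainment of dendritic
spikes, gamma entrainment of AP timing) are statistically stable on a
single workstation run.

## Known limitations

* **Perisomatic inhibitory leverage is weaker than in the full-scale
  reference model.** The sustained somatic GABA~A~ conductance increment
  from doubling perisomatic drive (~2--3 nS after the strong perisomatic
  depression) is small against the somatic input conductance, so two
  divisive signatures are not resolved here: the f-I slope reduction under
  doubled perisomatic drive measures as ~0 even with 10 s current steps,
  and the trough-versus-peak transmission advantage for clustered inputs
  is sign-unstable across seeds. The corresponding acceptance assertions
  are kept faithful to the expected directions and fail honestly.
* **Basal NMDA plateaus are rare under naturalistic drive** (the scaled
  basal tree is electrotonically close to the soma and its excursions are
  truncated by somatic spiking); plateau statistics are carried almost
  entirely by the apical tree.
* **NMDA/Ca^2+^ detector overlap** on tuft plateaus, as discussed above.
* The morphology is a template, not a reconstruction; electrotonic
  profiles are qualitatively correct (trunk attenuation ~10%, tuft tips
  ~0.1%, basal tips ~1%) but no per-compartment quantity should be
  compared to a specific reconstructed cell.
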