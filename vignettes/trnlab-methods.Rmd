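---
title: "Modelling rebound bursting in thalamic reticular neurons with trnlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rebound bursting in thalamic reticular neurons with trnlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trnlab)
```

## The scientific problem

Neurons of the thalamic reticular nucleus (TRN) fire in two modes. At
depolarized potentials they emit regular tonic sodium spikes; after release
from hyperpolarization they generate low-threshold calcium spikes crowned by
high-frequency sodium bursts. The propensity to rebound-burst varies widely
across TRN cells: transcriptomically defined Ecel1-positive cells burst a few
times and stop, Spp1-positive cells burst many times, and a subset of Spp1
cells ("runaway" cells) keep bursting indefinitely at suitable holding
potentials. This heterogeneity shapes sleep-spindle oscillations in the
thalamoreticular loop.

`trnlab` implements a complete modelling stack for this problem:
conductance-based compartmental TRN neuron models, the rebound-burst and
tonic current-clamp protocols, bespoke burst-feature extraction, burst-curve
fitting, Markov chain Monte Carlo (MCMC) sampling of model populations, and
a reduced thalamoreticular network for spindle analyses.

## The cell model

A cell is a soma cylinder plus a basal dendrite tree of constant-diameter
cylindrical sections (lateral areas only, the compartmental-simulator
convention). Mechanisms follow the classic thalamic model family:

* soma: fast Na and delayed-rectifier K (Traub-style `hh2`, threshold set by
  `vtraub`), generic T-type calcium `IT` (m^2 h), SK-type calcium-activated
  K `IAHP` (m^2, gated by intracellular calcium), passive leak;
* basal dendrites: `IT` with a linear density gradient
  `g0 (1 + d * slope)` of path distance `d`, `IAHP`, a calcium-activated
  nonselective cation current `ICAN`, and an A-type transient K current
  `IA`;
* calcium dynamics everywhere `IT` lives: inward-rectified influx with a
  first-order 150 ms decay to a 240 nM floor; the T-current reversal follows
  the calcium Nernst potential.

All rate constants are exposed in `trn_mechanisms()` and can be overridden;
the compiled integrator consumes exactly the same constants. A voltage-shift
parameter on `IT` moves its window current (positive shifts toward more
negative voltages, implemented by evaluating the gates at `v + vshift`);
mixtures of Cav3-like isoforms are modelled by `split_it_isoforms()`, which
replaces the generic channel by up- and down-shifted copies that conserve
total conductance.

Numerics: a backward-Euler solve of the voltage/axial system (Hines
elimination over the compartment tree) with staggered exponential-Euler gate
updates; voltage-dependent rates are tabulated on a 0.05 mV grid. The
default step is 0.025 ms for single-cell work; the MCMC and network studies
use 0.1-0.2 ms, where burst counts are unchanged and spike times shift by
well under a millisecond. Temperature enters through per-mechanism q10
factors (gating rates scale as `q10^((T - t_ref)/10)`).

### Parameter choices that matter

* `gbar_IT_basal` (S/cm^2) is the central knob: about 6e-4 gives an
  Ecel1-like model (a few rebound bursts), 1.1e-3 an Spp1-like model,
  2.4e-3 a runaway model whose bursting does not decay. These three are the
  shipped reference models (`trn_reference_model()`).
* `gbar_IAHP` controls the slow afterhyperpolarization (AHP) between
  bursts. Its reversal is `ek + ahp_rev_shift` with `ahp_rev_shift = -5` mV
  by default. The sign of this shift is a genuine design decision: with a
  positive shift the slow AHP cannot undershoot the resting potential, the
  T channels never de-inactivate between bursts, and repetitive rebound
  bursting is impossible. A -5 mV shift lets the AHP undershoot rest enough
  to recharge the T current at -65 mV holds while keeping the -80 mV hold
  quiescent; deeper reversals re-ignite bursts even at -80 mV.
* The IAHP and ICAN calcium half-activations (0.05 mM and 0.01 mM) are set
  so that the standing window-current calcium influx at holding potentials
  does not tonically activate them; only the large calcium transients of
  low-threshold spikes do. With substantially lower half-activations the
  cell is clamped by SK at rest or develops a depolarized ICAN attractor.
* T-current kinetics are transcribed at their 24 C reference with q10 2.5.
  The slow inactivation recovery (tau_h ~ 85-500 ms when hyperpolarized) is
  what lets the AHP recharge the burst generator; artificially fast h
  kinetics abolish re-bursting.

## Protocols

`run_burst_protocol()` reproduces the rebound-burst protocol: 5 s holding at
a target steady-state voltage (current found by a bisection search on a 2 s
test step, tolerance 0.5 mV), a 500 ms step with the current that holds
-100 mV, then the original holding current for 25 s (14 s for
experiment-matched analyses). A 500 ms settle period is simulated and
discarded. The bisection starts its test step from rest: with a strong
T-window the current that *maintains* a hyperpolarized level differs from
the one that *reaches* it, and the protocol requires the latter. For cells
that oscillate at the target, the accepted current yields the oscillation
mean; strongly non-monotone cases are rescued by scanning for an interior
straddling bracket.

`run_tonic_protocol()` holds the cell at -60 mV and applies a 500 ms,
0.15 nA depolarizing step; the reference models fire at a few tens of Hz
there, inside the physiological envelope.

## Burst features

Spikes are contiguous excursions above -20 mV (peak-timed, 1 ms merge).
Burst segmentation searches for a bimodal split of the log inter-spike
intervals by a two-class variance-maximizing threshold, accepted only when
the class geometric means differ at least three-fold; if every ISI is below
50 ms the train is one burst; if all bursts would be single spikes the
train is not bursting. Features are measured on the post-step analysis
window. The runaway metric is the least-squares slope of the slow-AHP
minima between bursts (first and last burst discarded, minima within 5 ms
of a burst's last spike discarded; sentinel 2 when fewer than four usable
minima); slopes below 0.05 mV/ms mark stable runaway bursting. The
post-burst tonic count finds inter-burst gaps whose minima are no deeper
than the fast (within-burst) AHP reference and returns their number plus
one. E-type classification applies, in order: post-burst tonic count > 0;
runaway metric < 0.05 mV/ms; burst number >= 5 (Spp1) else Ecel1.

The synthetic generators (`make_burst_trace()`, `make_cohort()`) render
stylized traces with exactly known burst counts, drift slopes and tonic
tails; they emulate the phenomenology of the recordings (AP peaks near
+20 mV, slow-AHP drift, tonic tails at fast-AHP depth) but not their noise
structure, channel kinetics, or cell-to-cell waveform variability — passing
recovery tests shows the feature definitions are implemented consistently,
not that they are robust to every experimental artifact.

## Burst curves

`scan_burst_curve()` runs the protocol over a steady-state voltage grid and
`fit_burst_curve()` fits `a exp(-(v - c)^2 / w) (1 + erf(s (v - c))) + d`
with bounds `a in [0,100]`, `w in [20,180]`, `c in [-100,-40]`,
`s in [-2,2]`, `d in [0,1]` by bounded least squares from a fixed
multi-start grid (3 x 3 x 3 over center, width, skewness, plus the
empirical peak), unweighted. The printed width parameter plays the role of
`2 sigma^2`; with voltages in mV the stated bounds are only dimensionally
sensible under this reading. In this model family, increasing the window
shift (window current toward more negative voltages) extends bursting to
*higher* steady-state voltages and moves the fitted center up, while
negative shifts move the peak to lower voltages — the direction the source
figure describes; the interplay of SK recharging and T-window ignition,
not the window position alone, sets the curve's peak.

## MCMC model populations

`mcmc_sample()` runs Metropolis-Hastings chains on the ten-dimensional
conductance space (bounds roughly tenfold around the reference values)
targeting `exp(-beta * cost)` with `beta = 2` and Gaussian proposals
reflected at the bounds. The cost is the *maximum* absolute Z-score of the
features against the target table (`trn_cost_spec()`), evaluated on
rebound-burst protocols at -80, -65 and -55 mV; validity is cost < 2 SD.
The default targets are package fixtures chosen like the original
constraints were: no bursts at -80 mV, burst numbers spanning the
Ecel1-to-Runaway continuum at -65 and -55 mV, spike-amplitude targets (mean
peak, drop between the first two peaks) that tie the sodium conductance to
the dendritic calcium load, and a slow-AHP-depth target that ties the SK
conductance. Sampling uses the two-compartment reduction at dt 0.2 ms with
shortened holding (0.7 s) and analysis (3.5 s) windows and warm-started
holding-current searches, which keeps one cost evaluation under 0.1 s.
The study size used by the tests and the acceptance script is 4 chains x
1250 steps with a 20% burn-in; at that size the valid population contains
all three e-types, and mean dendritic IT, IAHP, Na and ICAN increase from
the Ecel1- to the Runaway-labelled subpopulation while the passive leak
decreases. Single-temperature MH is deliberate; parallel tempering is an
extension point, not a need, at these chain lengths.

## The reduced network

`simulate_network()` integrates 40 TRN (two-compartment reductions of the
reference models; soma + lumped basal cable carrying the area-weighted mean
T density) and 80 TC relay cells (single compartment with a T current and
weak SK, silent at rest, responding to hyperpolarization with one strong
rebound burst). Chemical synapses use the Tsodyks-Markram release model
(depressing TC->TRN at 18 nS and TRN->TC GABA-A at 30 nS onto reversal
-85 mV; facilitating corticothalamic (CT) synapses at 6 nS onto TRN and
0.6 nS onto TC), gap junctions (0.8 nS, 10% of TRN pairs) couple TRN
dendrites semi-implicitly, and CT drive arrives as Poisson trains (30 Hz
per afferent, 10 afferents per cell from a pool of 60) during up states
(1 s up / 2 s down, 16 cycles by default; the tests use 3-4 cycles). All
wiring and drive randomness flows through the configuration seed.

The spindle readout is the TRN peri-event time histogram over up states,
skipping the first 150 ms of each up state so the stereotyped CT-onset
volley does not masquerade as an oscillation peak; `mean_peak_firing()`
averages the detected cycle peaks per event and over events. The balance of
the loop was fixed once so that weak CT input fails to recruit
oscillations, full input recruits them robustly, and the recruitment
threshold depends on the TRN T conductance: TC cells are kept in rebound
mode (weak direct CT drive, strong TRN inhibition), because tonically
firing TC cells depress their synapses and decouple the loop. Turning
points of the shared-shape sigmoid (plateau and steepness fitted jointly
over the uniform circuits, then frozen) decrease linearly with the
effective dendritic IT conductance — the composition-weighted *harmonic*
mean, appropriate for density-like quantities — and the mixed-circuit
turning point is predicted by the uniform-circuit line
(`ct_sigmoid_study()`).

At 20 + 40 cells and a handful of cycles these analyses are directional
demonstrations, not quantitative reproductions of a full-scale
thalamoreticular circuit; absolute peak rates depend on the synaptic
fixture values.

## Numerical and degenerate-input conventions

* Soma areas are lateral-only; the soma is the path-distance origin.
* A single-point SWC soma reads as a sphere-equivalent cylinder
  (length = diameter = 2r); unbranched constant-radius SWC runs merge into
  one section, so round-trips preserve geometry and branching topology but
  not redundant sample counts.
* Bisection accepts the midpoint when the bracket collapses below 1e-4 nA
  (oscillating holds), and fails when no straddling interval exists.
* `segment_bursts()` ties are resolved by the first variance-maximizing
  split in sorted order; the threshold sits at the geometric midpoint of
  the straddling interval.
* The runaway sentinel is exactly 2, so thresholding code is uniform.
* Empty traces give zero counts, `NA` amplitudes, and sentinel runaway.

## Known limitations

* The runaway reference model (large dendritic IT) re-ignites bursts even
  at the -80 mV hold after the hyperpolarizing step; only Ecel1/Spp1-range
  models keep that window burst-free. The MCMC cost (no bursts at -80)
  therefore bounds valid models to moderate IT, and runaway-classified
  samples in the valid population are fast bursters with small drift
  rather than extreme-IT cells.
* Generic T kinetics only: isoform-specific time constants and GHK flux
  are out of scope; isoform mixtures are voltage-shifted copies.
* Depolarization block is not modelled.
* The parametric morphology generator stands in for reconstruction
  populations; slopes of burst number against dendritic area from real
  reconstruction sets are not reproduced quantitatively.
* Tonic IF curves emerge from the burst-constrained models rather than
  being fitted; they sit in the physiological envelope but are not
  calibrated point-wise.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` re-runs the
whole stack at the study sizes above and writes the headline quantities
(feature-recovery rates, reference burst counts, fit-recovery errors, the
isoform-split center shift, MCMC validity and gradient ratios, spindle peak
rates and turning points) as JSON. The test suite asserts the corresponding
qualitative properties at the same sizes.
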