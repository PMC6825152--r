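---
title: "Measuring and simulating fast-spiking conversion in cortical interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and simulating fast-spiking conversion in cortical interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinphys)
```

## The scientific problem

Cortical GABAergic interneurons of the medial-ganglionic-eminence lineage
split into two canonical physiological phenotypes: somatostatin-positive
cells are typically *regular-spiking* (RS) — accommodating trains, wide
action potentials, small fast afterhyperpolarizations — while
parvalbumin-positive cells are *fast-spiking* (FS): sustained high-frequency
firing, sub-half-millisecond spikes and deep fAHPs. The difference is
carried largely by the fast delayed-rectifier potassium channel Kv3.1.
Perturbations that raise Kv3.1 expression in somatostatin-lineage cells can
push them along a continuum from RS toward FS.

`cinphys` implements the quantitative toolchain needed to study that
switch at the level of patch-clamp data:

1. intrinsic-property and single-spike feature extraction from
   current-clamp step families;
2. a four-criterion FS/RS classifier;
3. quantification of spontaneous, evoked and unitary inhibitory
   postsynaptic currents (IPSCs), including short-term plasticity;
4. a reduced single-compartment conductance-based simulator in which the
   Kv3.1 density is the experimental variable; and
5. a seeded synthetic-data generator that stands in for animal recordings
   and provides exact ground truth for every measurement.

## Intrinsic features

All measurements operate on a `sweep_set`: a family of stimulus-aligned
traces from one cell, sharing a sampling interval (`dt`, ms) and unit. Time
is always reconstructed as `t0 + i * dt` (0-based `i`).

* **Resting potential** — mean voltage over a pre-stimulus window
  (default: the 100 ms before stimulus onset).
* **Input resistance** — least-squares slope of the steady-state voltage
  deflection against injected current over spike-free sweeps, using the
  final 25% of the step as the steady-state window; mV/pA is converted to
  megaohms. Sweeps containing spikes are excluded rather than clipped.
* **Spike detection** — an upstroke criterion (dV/dt >= 20 mV/ms) followed
  by a climb to the local voltage maximum, with a 1 ms refractory merge.
  The derivative is taken as a centered finite difference over a 0.2 ms
  span: recording noise of 0.2 mV at a 20-50 kHz sampling rate produces
  sample-to-sample derivative noise of tens of mV/ms, while a 0.2 ms span
  leaves the (much faster) spike upstroke intact. Spike counts are
  invariant to 0.2 mV Gaussian noise by test.
* **Firing curve / rheobase** — spikes are counted inside the stimulus
  window only; frequency is count over step duration; rheobase is the
  smallest tested amplitude with at least one spike, so its resolution is
  the amplitude grid (25 pA on the standard protocol).
* **Single-AP features** — measured on the first spike of the sweep 50 pA
  above rheobase (or the nearest tested suprathreshold amplitude, which is
  recorded in the output). Threshold is the voltage at the maximum of the
  third time derivative; amplitude is threshold to peak; half-width is the
  interpolated width at half-amplitude above threshold; `max_dvdt` is the
  largest first derivative on the upstroke; fAHP is threshold minus the
  post-peak minimum within 10 ms (truncated at the next spike).
* **Accommodation and variability** — SFA is the last inter-spike interval
  over the first; the CV uses the sample (n-1) standard deviation over the
  mean. Both are taken from the lowest-amplitude sweep with at least 10
  spikes (configurable), since the sweep used in recordings is otherwise
  unspecified.
* **Sag and rebound** — sag ratio is the steady-state hyperpolarizing
  deflection divided by the peak deflection (1 = pure RC, < 1 with an
  HCN-type conductance); rebound is the post-stimulus peak minus baseline.

### Numerical conditioning of the threshold

Raw third differences amplify noise, so the trace is smoothed with a
Savitzky-Golay filter (order 3, ~0.5 ms window) before differentiation, and
the first window-length of filtered samples is excluded from the search
(filter edge effects). One further restriction matters: on
conductance-model waveforms the upstroke is nearly super-exponential, so
the third derivative keeps growing almost to the peak; an unrestricted
argmax would place the "threshold" half-way up the spike and inflate the
fAHP by tens of millivolts. The search is therefore capped at the foot of
the final fast upstroke — the last point, walking back from the peak, at
which dV/dt falls below the 20 mV/ms spike criterion. On slowly rising
waveforms (max dV/dt below the criterion) the cap never engages and the
measure reduces to the plain third-derivative maximum, which is what the
test-suite oracle checks against a 100-fold denser grid.

## The FS/RS classifier

A cell is fast-spiking iff **all four** hold, with strict inequalities:
half-width < 0.5 ms, maximal firing frequency > 50 Hz, fAHP > 14 mV, and
SFA < 2. Boundary values therefore classify RS. A cell missing any feature
(for example SFA with fewer than three spikes) is reported
`unclassifiable`, never silently RS — a cell that barely spikes must not
masquerade as regular-spiking. Thresholds are overridable and the values
used are embedded in every classification record.

## Synaptic measurements

IPSCs recorded at a +10 mV holding potential are outward; the package (and
its generator) treat events as positive deflections.

* **Detection** — the trace is baseline-corrected with a 200 ms running
  median and lightly smoothed; crests above 4 robust noise SDs (MAD of the
  first-difference residual, scaled) are candidate events; candidates
  closer than 5 ms merge (so genuinely inseparable events count once — a
  documented limitation); and each crest must rise at least the threshold
  above the local minimum since the previous accepted event, which rejects
  noise maxima riding on a decay while keeping true superimposed events.
  Onsets are placed at the 10% rise above the local pre-crest minimum.
* **Event measurement** — amplitude is local baseline to peak, with the
  peak located on a ~1 ms-smoothed copy and read as the mean of raw
  samples within ±0.25 ms (a raw maximum over a noisy crest is biased
  upward by the largest noise excursion); rise time is the interpolated
  10-90% interval; decay tau is a single-exponential least-squares fit
  from peak to 10% of amplitude (log-linear start, Levenberg-Marquardt
  refinement); charge is the trapezoidal integral from onset to the first
  return within 0.5 noise SD of baseline, capped at 200 ms. When the next
  event's onset is known, the peak window, fit and integral stop there.
* **Trains** — per-pulse amplitudes are measured from a local pre-pulse
  baseline; the series is reported normalized to pulse 1; the paired-pulse
  ratio is amplitude 2 over amplitude 1. Overlapping measurement windows
  are flagged, not hidden.

## The reduced conductance-based model

The simulator is a single-compartment membrane,

C dV/dt = I/A − Σ g̅ᵢ·xᵃ·yᵇ·(V − Eᵢ) − g_L(V − E_L),

with first-order gate kinetics dx/dt = (x∞(V) − x)/τₓ(V). All kinetics live
in a data-driven channel registry (serializable with the model
configurations to YAML), not in code constants:

* fast transient sodium (m³h) and a delayed rectifier (n⁴) with classic
  interneuron alpha/beta rate functions (temperature factor 5; the sodium
  activation additionally gets a rate factor that keeps its time constant
  under 0.1 ms, since near-instantaneous activation is required for full
  spike overshoot);
* an M-type slow potassium conductance (first order, τ ≈ 100-150 ms near
  rest) that produces the RS phenotype's accommodation;
* **Kv3.1**: first-order activation with
  x∞ = 1/(1+exp(−(V−18.7)/9.7)) and τ = 4/(1+exp(−(V+46.56)/44.14)) ms —
  the public cell-type-database description of this channel. Its high
  activation threshold means it is nearly closed at rest but recruited
  strongly by each spike, repolarizing it rapidly and deactivating within
  a few milliseconds.

Integration is fixed-step (default dt = 0.025 ms): gates use the analytic
Rush-Larsen exponential update against voltage-tabulated steady states and
decay factors (0.1 mV grid, linear interpolation), and the voltage uses an
exponential update against the instantaneous total conductance — stable for
this stiff system at desk scale. Convergence is tested, not assumed:
halving dt leaves spike counts unchanged and moves spike times by less than
0.5 ms.

### Scale of the reduced compartment

The shipped models use a somatic-scale compartment (10⁻⁵ cm², 1 µF/cm²,
leak 4.5-5.5 × 10⁻⁴ S/cm², i.e. an input resistance near 200 MΩ). This
choice is load-bearing: Kv3.1 densities up to 1.5 S/cm² must coexist with
current injections in the 25-500 pA range, as they do in morphologically
detailed models where such densities are somatic. In a large-area
compartment with a proportionally small leak density, the subthreshold tail
of 1.5 S/cm² of Kv3.1 would clamp the cell below threshold at every tested
current. The models' baseline Kv3.1 densities (0.009-0.03 S/cm²) are
likewise chosen for the reduced geometry — at full density every channel of
the reduced cell sees the somatic conductance directly, so the baselines
sit lower than those of morphologically detailed reconstructions, and the
printed effect sizes of such models are not expected to transfer
quantitatively. What is expected to transfer, and is asserted for every
shipped configuration, is the sign pattern of the conversion: raising
ḡ_Kv3.1 to 1.5 S/cm² increases firing output, reduces accommodation,
narrows spikes, deepens the fAHP, raises rheobase, lowers input resistance
— and flips the four-criterion classification from RS to FS.

## The synthetic-data generator

The generator defines the study conditions and provides exact ground truth.

* **Cohorts** — each cell draws a class (FS with probability
  `fs_fraction`), then model parameters uniformly and independently from
  the class ranges in `inst/extdata/cohort_profile.yaml` (RS: substantial
  M-conductance, Kv3.1 at 0.005-0.03 S/cm²; FS: little M-conductance,
  Kv3.1 at 1.2-1.5 S/cm²). The standard protocol is the recording one:
  800 ms steps, −50 to +20 pA by 10 pA subthreshold and 25-500 pA by 25 pA
  depolarizing, recorded at 20 kHz with 0.2 mV Gaussian noise. Sub-streams
  are derived per cell from the base seed by counter, so cohorts are
  bit-reproducible and cells are independent of cohort size. Real
  within-class feature covariance is unknown; draws are independent, which
  the tests inherit as an assumption.
* **Spontaneous IPSCs** — Poisson onsets, log-normal amplitudes,
  normalized difference-of-exponentials waveforms, additive Gaussian
  noise. The default scenario (5 Hz, ~40 pA mean, τ_rise 1 ms, τ_decay
  15 ms, noise 2 pA, 60 s) gives a signal-to-noise ratio near 20 and about
  300 events.
* **Evoked trains** — pulse-n amplitude follows the Tsodyks-Markram
  recursion over resources R and utilization u
  (R₁ = 1, u = U without facilitation;
  R_{n+1} = 1 − (1 − R_n(1−u_n))·e^(−Δt/τ_rec)); for U = 0.5,
  τ_rec = 200 ms and Δt = 100 ms the closed form gives a paired-pulse
  ratio of 1 − 0.5·e^(−0.5) = 0.6967, which the measurement pipeline must
  reproduce within 1%.

What passing tests do **not** show about real data: the generator's cells
have no dendrites, no channel covariance, no electrode artifacts, and its
synaptic events are kinetically homogeneous; absolute event counts from a
proprietary detector on real recordings are therefore not a validation
surface — only generator ground truth and closed forms are.

## Degenerate inputs and tie-breaks

Ties in the third-derivative argmax resolve to the earliest time. Rheobase
with no spiking sweep, SFA with fewer than 3 spikes, CV of fewer than 2
values or zero mean, and averaging fewer than 2 events are errors, not
defaults. Event windows truncated by trace bounds are dropped and counted.
A diverging simulation (|V| > 200 mV) aborts with the offending current;
diverging cohort cells are redrawn with the redraw count reported.

## Problem sizes

The shipped analyses and tests run on one CPU at desk scale: cohorts of
40-200 cells (28 sweeps of 1 s each, 20 kHz), 60 s synaptic recordings at
10 kHz, and conductance sweeps of three models over seven currents and two
to six densities. The full test suite completes in a few minutes; the
acceptance script in roughly two.

## Known limitations

* The classifier is the printed conjunctive rule; no probabilistic or
  cluster-based typing, and no intermediate "quasi-FS" class.
* Decay kinetics are single-exponential by design; multi-exponential
  IPSCs are out of scope.
* The simulator is single-compartment: no morphology, synaptic
  conductances, or network context, and no claim to reproduce the percent
  effect sizes of morphologically detailed models.
* The native I/O dialect (per-sweep CSV plus JSON sidecar) is the only
  reader shipped; acquisition formats (ABF/NWB) would enter behind the
  same `read_sweep_set()` contract.
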