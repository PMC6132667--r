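---
title: "Laminar analysis of evoked VSD and field potential recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar analysis of evoked VSD and field potential recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdlamina)
```

## The measurement problem

In auditory thalamocortical slices, electrical stimulation of the internal
capsule evokes activity that sweeps through the layers of primary auditory
cortex (A1).  Two simultaneous read-outs capture it: voltage-sensitive dye
(VSD) imaging on a hexagonal photodiode array (464 active elements, 0.416
mm² field of view, 1.274 ms sampling), and local field potentials (FP) from
two electrodes, one in the supragranular (layers I–III) and one in the
infragranular (layers IV–VI) band.  Demyelination models (cuprizone) and
candidate therapies (dimethyl fumarate) change the amplitude, latency and
laminar sequence of these responses, and, downstream, the animals' ability
to discriminate conditioned tones.  `vsdlamina` implements the complete
measurement chain plus the inferential layer used for such group
comparisons, and pairs it with a synthetic-cohort generator so that every
stage can be validated by parameter recovery.

## Optical signal model

Raw diode intensities are converted to fractional fluorescence

$$\frac{dI}{I}(t) = \frac{I_\mathrm{rest} - I(t)}{I_\mathrm{rest}},$$

where \(I_\mathrm{rest}\) is the per-diode mean over the 50 ms preceding the
stimulus.  Membrane depolarisation quenches the dye's emission, so this
orientation makes evoked responses positive.  Values are reported in
percent.  Three stimulus-locked trials are averaged; each trial uses its own
baseline, which makes the estimate robust to slow bleaching between trials
(averaging raw intensities first is equivalent when baselines are equal —
a property the test suite verifies).

Layer read-outs average **six adjacent diodes**: the in-band site nearest
the recording electrode plus its five nearest in-band neighbours (Euclidean
distance, ties broken by site id).  The selection rule is a package
commitment — fixed per slice by the electrode coordinate, with a per-response
override available through the `electrode_xy` argument.

Amplitude is the peak of the baseline-subtracted trace in a post-stimulus
search window, latency the stimulus-to-peak time at sample resolution (no
sub-sample interpolation: 1.274 ms is the acquisition limit).  The search
window defaults to 100 ms, which comfortably contains all physiological
stimulus-to-peak times (≤ 13 ms here) while excluding late drift.

## Array geometry

The detector is modelled as a 12-ring centered hexagonal lattice (469
sites) with five designated corner sites deactivated, yielding the 464
active channels; commercial arrays of this channel count are
corner-truncated hexagons, and 469 is the nearest centered hexagonal
number.  The quantity fixed by the hardware is the field of view, not the
diode pitch, so the spacing is derived from
\(464 \cdot (\sqrt{3}/2)\, s^2 = 0.416\ \mathrm{mm}^2\) (≈ 32 µm).  Layer
bands partition active sites by the projection onto the cortical depth
axis; the shallow 40% of the span (layers I–III of six) is supragranular by
default, configurable via `supra_fraction`.

```{r geometry}
g <- standard_geometry()
g
```

## Field potential scoring

FP amplitude is peak-to-peak (most negative to most positive) inside the
25 ms post-stimulus assessment horizon; return to baseline is checked over
the 25–30 ms window against 3 baseline SDs.

Population spikes were scored by eye in the original workflow, so the
package commits to an explicit operationalisation: a spike is a contiguous
run of first differences exceeding `k_sd` (default 4) baseline
first-difference SDs, lasting at most 3 ms, containing a suprathreshold
*negative* step.  The polarity test is on the steepest step rather than the
run's net deflection because a one-sample transient is a down-step
immediately undone by an up-step — its net deflection is zero by
construction.  Slow evoked components fail the duration cap (their steep
segments last longer than 3 ms) or the polarity test (rising limbs).  This
criterion is validated only against the synthetic generator: on generator
ground truth it achieves ≥ 98% recall and ≤ 2% false positives (the test
suite measures both on 1,000 traces).

## The synthetic cohort generator

The generator is the package's study-conditions artefact, not a test
fixture.  Each experimental group (control, cuprizone, 7/25-day
remyelination, DMF/vehicle/non-injected arms) has a preset carrying the
group means ± SEM at the study group sizes: per-layer VSD amplitude (% dI/I)
and FP amplitude (mV) at 50% stimulation intensity, per-layer/per-distance
stimulus-to-peak latencies, per-intensity population-spike probabilities,
and per-tone freezing percentages.  Values not reported for a group are
fixed once at plausible levels consistent with the qualitative description
and are marked `assumed` in the preset file; none backs a recovery target.

Design choices that matter:

* **Between-slice dispersion.**  A printed mean ± SEM at group size *n*
  implies a between-slice SD of \(\mathrm{SEM}\sqrt{n}\); cohorts of the
  printed size then reproduce the printed SEM in expectation.
* **Positive-quantity draws.**  Amplitudes are drawn from a moment-matched
  Gamma (exact mean and SD, positive support).  A zero-truncated normal
  was considered and rejected: for the FP presets the implied SD exceeds
  the mean, and truncation would inflate the group mean by ~50%.
* **Freezing** is drawn from a Beta distribution moment-matched on the
  0–100 scale; the paired structure (each animal hears both tones) is
  preserved through a Gaussian copula with correlation 0.5.
* **Response kernels.**  Per site, the VSD response rises linearly to its
  peak at the slice's latency (snapped to the sampling grid, so zero-noise
  recovery is exact) and decays exponentially — transiently in the
  supragranular band (τ = 5 ms) and sustained in the infragranular band
  (τ = 20 ms), reproducing the canonical transient-then-sustained laminar
  sequence.  A pure alpha kernel was rejected because its peak falls one
  time constant after response onset, which would break the latency
  calibration for sustained kernels.
* **FP wave shape.**  A stylised biphasic wave: one-sample rise to the
  positive peak, a plateau over the 3–10 ms window carrying optional
  population-spike transients (one-sample, 0.35 mV), then a negative-going
  fall and return to baseline by ~24 ms.  The fall's per-sample slope is
  deliberately kept away from the detector's threshold band — shallow
  (sub-threshold) for small waves, steep over ≥ 3 samples (rejected by the
  duration cap) for large ones — so that detector specificity is a property
  of the signal model, not luck.  Baseline noise defaults: 0.005 mV for FP,
  0.03% dI/I per diode and sample for VSD; both are at the clean end of
  what slice rigs achieve, chosen so that measurement bias (peak-picking on
  noisy traces biases amplitudes upward) stays well below the smallest
  group SEM in the presets.
* **Seeding.**  One master seed; per-slice, per-trial and per-modality
  streams are derived by counter-based splitting, so growing a cohort never
  reshuffles earlier slices, and identical (preset, seed) pairs are
  bit-identical.  Spike *occurrence* is drawn once per slice × intensity
  (a population spike is a network event seen by both electrodes), spike
  times per electrode.

What the generator does **not** emulate: bleaching, optical point spread,
stimulus artefacts, heterogeneous within-band response amplitudes,
conduction-velocity physics (the long/short electrode-distance latency
difference is encoded directly from the per-condition presets), or any
cuprizone biology — presets are phenomenological.  Passing recovery tests
therefore demonstrates that the pipeline measures what the forward model
encodes, not that it is robust to every artefact of real optics.

```{r recovery}
p <- condition_preset("control")
g <- standard_geometry()
stim <- stimulus_spec(50)
recs <- lapply(1:3, function(tr) generate_vsd_trial(p, g, stim, 1, tr, seed = 1))
sig <- average_trials(lapply(recs, fractional_fluorescence))
amplitude_latency(layer_signal(sig, g, "infragranular"), sig$stimulus_onset)[c("amplitude", "latency_ms")]
```

## Behaviour

Freezing is the percentage of the scored window spent immobile; sessions
store per-tone percentages directly (that is what is reported), with a
10 Hz immobility-series path for interface completeness (scored window
default 180 s — the test-day observation length is not standardised, so it
is configurable).  `discrimination_summary()` gives per-tone mean ± SEM,
per-animal paired deltas, and a paired CS+/CS− contrast; a condition
"discriminates" when that within-condition frequency effect is significant.

## Inference

One-way and two-way factorial ANOVA ride on the standard linear-model
machinery; unbalanced factorials (the study's group sizes differ, e.g.
16 vs 11 slices) use Type II sums of squares, so main effects are adjusted
for each other without sequential-order ambiguity.  The mixed
(between × within) ANOVA is the classical split-plot decomposition:
between-subject effects tested against subjects-within-groups, within
effects against the within × subjects stratum.  No sphericity correction is
applied — with a two-level within factor none is needed — and the result
notes this in its metadata.

Newman–Keuls is authored in the package: means are ordered and stepped
down by stretch size with studentized-range critical values from the
distribution function itself (`ptukey`/`qtukey`, i.e. numerical CDF
inversion rather than printed tables); interior pairs of a non-significant
stretch are blocked.  Decisions are validated in the tests against
brute-force enumeration with published q-table constants, and Tukey HSD
against `TukeyHSD()` on a fitted model.  Type-I error of the one-way F is
calibrated to 0.05 ± 0.01 over 10,000 null replicates in the acceptance
suite.

## Numerical conventions and degenerate inputs

Sample indices are 0-based, the stimulus time is the pulse onset, windows
are half-open `[start, end)` (baseline) and `(start, end]` (post-stimulus).
Recordings are capped at 1024 samples (1024 × 1.274 ms ≈ 1305 ms, the
maximal exposure length).  A flat trace yields amplitude 0 with a `"flat"`
flag; a noiseless baseline switches the spike detector to an absolute
threshold with a warning; one-animal cohorts are flagged because the SEM is
undefined; all-equal ANOVA inputs are flagged degenerate.

## Validation strategy and problem sizes

The test suite validates each operation against an independent brute-force
oracle (element-wise dI/I recomputation, explicit argmax, exhaustive
distance sorts, hand counts) on 1,000 random instances per operation, and
the full chain by parameter recovery: exactly at zero noise, within two
generative SEM at the study group sizes under default noise, and within 2%
(relative) for measurement-noise-only cohorts (between-slice SD set to
zero, 40 slices for the VSD chain, 200 FP traces — the bias being measured
is independent of cohort size).  Detector operating characteristics use
1,000 traces per side.  Routine tests run on a reduced 19-site array and
256-sample recordings; recovery checks use the full 464-channel geometry.

`scripts/acceptance.R` regenerates all twelve reference group statistics
(FP amplitudes, VSD amplitudes, spike incidence, latencies, freezing) from
scratch at the study group sizes under a caller-supplied seed.

## Known limitations

* The population-spike criterion is a declared operationalisation of a
  by-eye judgement; its thresholds are tunable but its ground truth is
  synthetic.
* Presets for unreported group parameters are plausible placeholders, fit
  for pipeline exercise, not for biological inference.
* With cohorts at the printed group sizes, a recovered mean lies within two
  generative SEM of the target with ≈ 95% probability per read-out — the
  tolerance is a statistical band, not a deterministic bound.
* No bleaching correction, point-spread deconvolution or tonotopic-map
  inference; the pseudocolour renderer is utilitarian.
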