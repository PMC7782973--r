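---
title: "Methods: walking, occipital alpha and eye movements in gaitalpha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: walking, occipital alpha and eye movements in gaitalpha}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

A mobile-EEG walking experiment records, per participant, six 76.5-s
sessions crossing lighting (light, dark) with movement (standing still,
slow walking, normal walking). Four synchronized streams are available:
24-channel EEG/EOG at 500 Hz (16 scalp channels, 6 EOG, 2 earlobes),
3-axis velocity from ankle- and back-mounted motion sensors at 120 Hz,
and pupil radius at 120 Hz with track-loss dropouts. The scientific
questions are (a) whether occipital alpha power (~8–12 Hz) is lower
during walking than standing, independent of visual input, (b) whether
eye-movement rates and pupil size change with walking, (c) whether alpha
and eye metrics are modulated within the stride cycle, and (d) whether
any within-stride alpha modulation could be an electrode-impedance
artifact. `gaitalpha` implements the full chain and a ground-truth
synthetic generator so each stage is testable.

## Alpha extraction

Per subject, scalp EEG of every session is re-referenced to the mean of
the 16 scalp channels, low-passed at 100 Hz and high-passed at 1 Hz.
All filtering in the package uses zero-phase windowed-sinc FIR filters
(Kaiser window, 60 dB stopband, transition width `min(2 Hz, cutoff)`;
the 8–12 Hz alpha band-pass uses a Hamming window). Zero phase is
obtained by applying the linear-phase kernel to symmetrically padded
data and compensating the group delay; phase-resolved analyses
(stride-phase binning, Hilbert envelopes) would otherwise inherit a
frequency-dependent lag. The two exceptions are the saccade band-pass
(20–90 Hz Butterworth of overall order 6, run forward and backward) and
the 200-ms Hamming window of the impedance estimator.

The six filtered sessions are concatenated, reduced to 10 principal
components, whitened, and unmixed with plain (non-extended) Infomax ICA
— natural-gradient updates with the logistic nonlinearity, mini-batches
of 1024 samples, learning-rate annealing on divergence, convergence when
the summed squared weight change per sweep falls below 3e-7. No ICA
implementation was available in the dependency stack, so the algorithm
is implemented in the package and validated against a known-mixing
oracle (three super-Gaussian sources, recovery correlation > 0.95). Two
numerical choices matter:

- *Determinism.* The ICA seed fixes the per-sweep sample permutation;
  identical seeds give identical decompositions. The seed is recorded in
  the result object.
- *Decimation.* Weights are estimated on every 6th sample. ICA treats
  samples as i.i.d. draws — temporal order never enters the estimator —
  so decimation merely subsamples the marginal distribution (~38k
  samples still remain per subject). Activations, spectra and envelopes
  always use full-rate data.

Components are selected by four rules evaluated on the 2–50 Hz Welch
spectrum (1-s windows, 50% overlap, 1 Hz resolution): a local peak in
6–14 Hz; peak width ≥ 4 Hz between the flanking local minima; peak power
at least 3× the mean 20–50 Hz power; topography maximum (absolute
weight) on O1/O2/POz. A "local peak" is a bin strictly greater than both
neighbours; with several 6–14 Hz peaks the widest is taken, ties broken
toward lower frequency (the strictness and tie-break are conventions the
selection rule needs but that are otherwise unspecified). An empty
selection excludes the subject from alpha analyses — the pipeline logs
this instead of failing.

Session alpha power is the 8–12 Hz mean (inclusive integer bins) of the
arithmetic mean of the selected components' power spectra. Arithmetic
(not log) averaging across components was chosen because back-projected
sensor power is additive in component power.

## Epoch grid and the Welch equivalence

Epoch-level analyses use 1-s epochs at 0.5-s steps anchored at t = 0,
dropping any final partial window: a 76.5-s session gives 152 epochs,
six sessions 912. Per-epoch alpha power is the Hamming-windowed
periodogram mean over 8–12 Hz. Because this grid is exactly the Welch
segmentation, the session mean of epoch powers equals the session's
Welch alpha power by construction; the test suite asserts agreement to
1e-6 relative on every synthetic session. Epochs with extreme alpha are
flagged by the MAD-median rule (below) within each session.

The continuous alpha envelope (for phase analyses) band-passes each
selected component at 8–12 Hz (Hamming-window FIR), Hilbert-transforms
it and averages squared magnitudes across components. Envelope power
and Welch band power are on different scales (the envelope carries the
full oscillation power, the 1-Hz-bin mean divides it over bins); no
cross-scale comparison is made anywhere.

## Eye events

- *Saccades.* REOG = mean of the six EOG channels minus Pz, mean-centred,
  band-passed 20–90 Hz, Hilbert envelope; samples above
  mean + 2.5 SD of the session's envelope (computed on the full
  envelope, outliers included — the simplest reading) are saccadic,
  groups < 20 ms apart merge. A threshold defined in SD units of the
  session's own envelope self-scales: with realistic saccade rates the
  spikes dominate the envelope SD and false detections in background
  noise become rare. At very low event rates the same rule necessarily
  marks the envelope's upper ~1.5% tail regardless of content — a
  property of the rule, not of its implementation — so detector
  validation is run at the generator's default rates.
- *Blinks.* Vertical EOG = above-eye minus below-eye (left eye), filtered
  0.2–10 Hz; upward crossings of a per-participant threshold, crossings
  within 100 ms merged, and events with amplitude SD/mean < 0.2
  excluded. The ratio's support is the event extended to the
  surrounding half-threshold crossings: on strictly supra-threshold
  samples a clean raised-cosine blink cresting at twice the threshold
  already scores ≈ 0.19 and would be misclassified, while the extended
  support separates peaked blinks (> 0.3) from flat drifts (≈ 0).
- *Blink threshold.* The original procedure sets it by condition-blind
  visual inspection. The automated surrogate is `k = 5` times the robust
  spread (1.4826 × MAD) of the blink-free background of the vertical
  component, pooled over all of the participant's sessions. Because the
  0.2 Hz high-pass spreads a rebound tail of roughly ±2 s around every
  blink, a single-pass MAD still scales with blink amplitude; the
  spread is therefore re-estimated after excluding > 3-SD excursions
  dilated by ±2 s (three passes). Condition labels are never consulted.
- *Pupil.* Missing samples are non-finite values or exact zeros. The
  0.5 Hz low-pass is applied gap-aware, per contiguous valid run
  (filtering the concatenated valid samples would smear any level
  difference across a gap far into the valid data; runs shorter than
  the kernel pass through unfiltered), then gaps are filled by linear
  interpolation and the session mean taken. Participants with > 99%
  missing are excluded, not crashed on.

## Gait and walking phases

Combined ankle speed is the sum of the two ankles' Euclidean speed
magnitudes, low-passed at 2 Hz. Stride boundaries are local minima of
this series, found from the instantaneous phase of its mean-removed
analytic signal (wrap crossings → minima, upward zero crossings →
maxima) and refined to the nearest true local extremum within a quarter
stride — phase crossings are robust to ripple, the local search restores
exactness. First/last incomplete strides are discarded; stride durations
are screened by the MAD-median rule. Left and right strides are not
distinguished.

Each retained stride's `[start, end)` is split into nine equal-duration
bins. Means average the samples in a bin and then across strides;
event rates divide onset counts by total bin time (half-open bins;
boundary events belong to the earlier bin). The alpha envelope is
binned by converting bin edges to the 500 Hz timebase directly — power
is never interpolated. Strides with outlying mean alpha are excluded by
the same MAD-median rule.

Electrode impedance is estimated per sample by complex demodulation at
125 Hz with a sliding 200-ms Hamming window, scaled so that a carrier of
amplitude `sqrt(2Z)` reads `Z` kΩ (the hardware calibration constant is
arbitrary; the synthetic generator and estimator share this convention).
The estimate is undefined within half a window of the recording edges
and is NA there. The impedance-by-phase control bins the averaged
O1/O2/P7/P8 trace with *one stride per bin* (round-robin): the 200-ms
window correlates neighbouring bins of a shared-stride profile, and a
cell-exchange randomization test is measurably anti-conservative under
such dependence, so the control uses disjoint strides per bin to make
its null exact. The alpha and event phase analyses keep the all-strides
binning (their purpose is detection, not null calibration); their
p-values inherit the same mild anti-conservativeness, a limitation noted
below.

## Randomization statistics

All inference is by randomization. The within-subject ANOVA computes
classical balanced sums of squares (each effect tested against its
interaction with subject) for any fully crossed design; the null
distribution exchanges cell labels within each participant — one full
random reassignment per permutation serving all effects, matching the
described scheme — with `p = (1 + #{F* ≥ F}) / (1 + n_perm)`. The
implementation is validated against `stats::aov` F statistics on 2×3 and
2×2×9 designs and calibrated by simulation (type-I error within
[0.035, 0.065] at α = 0.05 over 1000 null replicates). The paired test
sign-flips within-subject differences, two-tailed on the mean
difference. Degenerate inputs (all cells equal) give F = 0 and p ≈ 1
rather than NaN. Default `n_perm` is 5000 with the floor 1/(n_perm+1);
seeds are recorded in every result.

Epoch grouping follows the exclusion bookkeeping: MAD-median alpha
outliers first; epochs with five or more saccades excluded (groups run
0–4 — the grouping and the printed exclusion wording conflict for
exactly five, and the group list is taken as authoritative); blink
groups 0–1 with > 1 excluded; pupil quintiles per participant with equal
counts, ties broken by epoch order. The per-frequency speed comparison
runs a one-way within-subject randomization ANOVA at each 1-Hz bin from
2–50 Hz per lighting level and masks with Benjamini–Yekutieli FDR
(`stats::p.adjust(method = "BY")`; the step-up oracle in the tests is
independent).

The MAD-median rule flags `p` when
`|p − median(P)| × 0.6745 > 2.24 × median(|P − median(P)|)`. When the
MAD-median is zero the rule degenerates to flagging everything unequal
to the median — documented, and the only reading that keeps the rule
monotone.

## The synthetic generator

`gt_config()` defines ground truth; `generate_session()` renders one
condition cell deterministically from `(seed, subject, condition)`, and
`generate_cohort()` renders jittered subjects with all six cells in
randomized order. The defaults encode the study conditions the pipeline
targets:

| parameter | default | rationale |
|---|---|---|
| alpha amplitude (μV) | light 12/9.6/9.6, dark 20/16/16 (still/slow/normal) | 20% walking suppression; stronger alpha in darkness |
| alpha frequency | 10 Hz (subjects jittered ±0.6) | individual alpha frequency range |
| phase modulation depth | 0.15 | amplitude dip at double support |
| saccade rate (/s) | light 1.2/1.7/2.0; dark ~1.0 flat | speed effect in light only |
| blink rate (/s) | 0.30/0.45/0.60 both lightings | speed effect independent of light |
| phase concentration | 0.5 | events prefer the low-speed phase |
| stride period | slow 1.13 s, normal 0.64 s | published stride durations |
| back speed (m/s) | light 0.53/1.12; dark 0.50/0.96 | published walking speeds |
| pupil mean (a.u.) | light 3.0; dark 4.6–5.0 | darkness dilation, walking effect in dark |
| pupil missing fraction | 0.12 | realistic track loss, contiguous runs |
| noise SD | 8 μV per channel (1/f) | mobile-EEG background |
| saccade/blink amplitude | 40 / 150 μV | spike above the 20–90 Hz noise envelope; blink well above the ~50 μV threshold regime |

Design details: the alpha source is a bursty (lognormal-envelope)
sinusoid mixed through an occipitally dominant topography — burstiness
is both realistic and necessary for a super-Gaussian ICA model; blink
waveforms are 250-ms raised cosines, positive above and negative below
the eye, with a frontal scalp leak; saccades are 15-ms biphasic spikes
on all six EOG channels with attenuated frontal leakage; events are
renewal processes with a hard refractory gap (150 ms saccades, 400 ms
blinks) whose candidate rate is calibrated so the configured mean rate
is preserved — without the gap, overlapping blink waveforms fuse into
single threshold crossings and no detector could attribute them.
Phase preference thins candidates with acceptance
∝ 1 + c·cos(2π·stride fraction). Stride durations jitter lognormally at
4% CV (within-session variability of healthy gait), stride phase starts
at a random offset (walking is ongoing at session start), and the truth
block records only in-window boundaries — edge strides are partial and
unrecoverable. Ankle velocities are split so that their speed magnitudes
sum exactly to the target profile; the back sensor carries the mean
walking speed. Pupil dropout comes in geometric runs (mean 0.2 s), not
i.i.d., to exercise interpolation.

What the generator does **not** emulate: biomechanically realistic gait
(no heel-strike/toe-off events), head movement and cable-sway artifacts,
vestibulo-ocular dynamics, non-stationary electrode drift, or volume
conduction beyond a fixed linear topography. Passing tests therefore
demonstrate correctness of the *pipeline* under the stated statistical
structure, not robustness to every artifact of real mobile EEG.

Sessions round-trip through plain CSV + JSON; the writer emits
shortest-round-trip doubles and the loader parses with strtod, so
loading is bit-exact.

## Validation problem sizes

The standard check sizes, chosen once: detector recovery on 9 subjects ×
6 conditions (54 sessions); gait recovery on 12 walking sessions;
type-I calibration with 1000 null replicates at 400 permutations
(n = 20 paired, n = 26 for the 2×3 ANOVA); power for the speed main
effect on 3 independent 26-subject cohorts at 500 permutations; null
controls with 20 replicates each (8-subject impedance cohorts; 4-subject
covariate cohorts at 30 s per session, using the null template —
constant alpha amplitude and zero phase modulation, since the default
template couples alpha and events through condition and stride phase by
design). `scripts/acceptance.R` re-runs all of these from a single seed.

## Known limitations

- With 16 scalp channels there is no source localization; "occipital"
  means sensor-space topography maxima.
- The cell-exchange randomization is slightly anti-conservative when
  cell values are serially dependent (smooth phase profiles); the
  impedance null control therefore uses independent (round-robin)
  stride-to-bin assignment, and phase-effect p-values from all-strides
  binning should be read with this caveat.
- The saccade envelope threshold marks the envelope's upper tail
  whatever its content; at very low true event rates the detector's
  false-alarm count is governed by the rule itself.
- The automated blink threshold is a surrogate for per-participant
  visual inspection; its `k` is a convention validated only against the
  generator's amplitude regime.
- Welch/epoch alpha power is reported in density units of the 1-Hz
  grid; absolute values are not comparable across different window
  lengths or to envelope power.
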