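---
title: "Methods: event-locked high-gamma analysis for iEEG recognition memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked high-gamma analysis for iEEG recognition memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscan)
```

# Scope

`memscan` implements an analysis pipeline for intracranial EEG recorded
during a visuospatial recognition-memory task: participants encode lists of
four natural-scene images (5 s each, preceded by a 1 s fixation cross) and
are then tested on the same images in the same order, 28% repeated
unchanged and 72% manipulated by adding or removing an item (36% each).
The scientific questions the pipeline addresses are (a) how event-locked
80–120 Hz ("high-gamma") power propagates across the visual hierarchy —
lateral occipital cortex (LOC), parietal cortex (PAR), posterior temporal
cortex (PT), medial temporal lobe (MTL) — during recognition, (b) whether
the distributed spatial pattern of high-gamma power present at encoding is
reinstated at retrieval, image by image, (c) whether and when a
condition difference (correctly recognised manipulated images versus
repeated images) emerges in each region, and (d) how the regions
communicate, measured by power cross-correlograms, alpha-band (8–12 Hz)
spectral coherence, and phase-locking.

Real patient recordings are not distributable, so the package is organised
around a synthetic-session generator with known ground truth. Every
analysis is exercised end-to-end against injected structure, which turns
the pipeline's scientific claims into testable recovery problems.

# The synthetic generator

`generate_recording()` synthesises one session. The background of every
channel is 1/f ("pink") noise — matching the qualitative shape of iEEG
spectra without modelling physiology — scaled to a configurable standard
deviation (default 10 µV), with optional 60 Hz line noise. On top of this
the generator injects:

* **An image-evoked high-gamma burst** on every trial of both phases: a
  100 Hz carrier under a raised-sine envelope (default onset 50 ms,
  duration 1 s, so band power peaks near 550 ms, consistent with
  event-locked high-gamma responses peaking within 600 ms). The burst
  amplitude on channel $l$ for image $i$ is `burst_amp` times a spatial
  gain $g_{l,i}$, drawn once per (channel, image) from a log-normal with
  unit mean (`gain_sd`, default 0.5). Because the same gains apply at
  encoding and recognition, the *pattern* of high-gamma power across
  channels recurs when an image is seen again — the substrate of
  reinstatement. How variable the reinstated pattern is from trial to
  trial is not well characterised empirically, so it is exposed as a knob
  (`pattern_noise`, log-normal trial-by-channel jitter, default 0.2)
  rather than fixed.
* **Trial-specific envelope modulation**: the burst envelope is multiplied
  by `1 + env_mod * f(t)` where $f$ is low-pass-filtered noise (default
  8 Hz bandwidth, depth 0.5), drawn per trial and *shared by all
  channels*. MTL channels read the same modulation shifted by `lag_ms`
  (default 40 ms), together with their envelope. This reproduces the key
  property that inter-regional lag estimation exploits: power fluctuations
  that are trial-specific and coupled across regions at a fixed delay. A
  single smooth envelope without such modulation carries almost no timing
  information — its cross-correlogram is flat near the peak — and lag
  estimates would be dominated by noise.
* **A condition effect**: correctly recognised manipulated trials receive
  an excess high-gamma burst with region-specific onsets (defaults 250,
  295, 270, 480 ms for LOC/PAR/PT/MTL, duration 600 ms, amplitude
  `effect_amp`). These are the onsets the dynamics module must recover.
* **Alpha coupling**: on the same trials, a 10 Hz component (tapered to
  the 0.3–1.8 s window after image onset) is added to PT and MTL channels
  with a fixed phase lag (default $\pi/4$), shared trial phase, giving the
  coherence and phase-locking analyses a condition-specific target.
* **Artifacts** (off by default, enabled per test): biphasic 20 ms
  transients with a sharp ~2 ms leading edge at 8 times the background SD
  (interictal-discharge-like, guaranteed to trip a z > 5 gradient
  detector), and outlier trials amplified by a fixed gain (targets of the
  quartile screening rule).

Behavioural structure follows the task: per-condition recognition
accuracy defaults to 88/65/68% (repeated/added/removed), response times
are truncated normal (mean 2.5 s, SD 0.4 s, minimum 1.2 s), and condition
labels are apportioned by largest remainder so a session's composition is
exactly 28/36/36 up to rounding. `generate_gaze()` adds a 120 Hz gaze
stream: piecewise-stationary dwells (sub-degree jitter) during recognition
trials that land inside the image's critical-region rectangle with a
per-condition probability, separated by saccade-like scatter constrained
so that no spurious fixation can form between dwells.

What the generator does *not* emulate: volume conduction and shared
reference artifacts across channels (bipolar referencing is therefore
validated on constructed common-mode examples, not on the generator),
physiological cross-frequency structure, non-stationary drift, and
realistic saccade kinematics. Passing recovery tests on synthetic data
therefore demonstrates the *estimators* are correct and calibrated at
realistic signal-to-noise, not that real recordings satisfy the model.

The default session is a compact testbed — 12 four-image lists and a
2/4/6/4 LOC/PAR/PT/MTL montage — chosen so that a full session synthesises
in about a second; the task structure (presentation timing, proportions,
accuracies) matches the study design at any size, and tests choose sizes
per analysis (see below).

# Preprocessing

**Bipolar referencing.** `build_bipolar()` pairs all immediately adjacent
contacts on each grid or strip (depth probes as 1-D strips);
`apply_bipolar()` subtracts cathode from anode, sample-aligned. Pairs
straddling a region boundary inherit the anode's label and are flagged.
Common-mode signals cancel exactly.

**Conditioning.** `condition_signal()` accepts 1000 or 2000 Hz input,
decimates 2000 Hz recordings to 1000 Hz after a zero-phase anti-alias
low-pass, and applies a fourth-order Butterworth band-stop 2 Hz wide at
60 Hz. All filtering is forward–backward (zero phase): onset and lag
analyses downstream must not inherit filter delay. The trade-off is a
non-causal impulse response, irrelevant here because no analysis is
causal.

**Quartile screening.** `reject_by_quartile()` drops values strictly above
$Q_3 + w(Q_3 - Q_1)$ with $w = 2.3$; quartiles use linear interpolation
(R's type-7 default), which is logged in the result so decisions are
reproducible. The statistic screened is the **mean absolute** voltage per
trial per electrode (then per-trial means across electrodes, then
per-electrode session means with trials already cleaned): a signed mean of
a zero-centred trace would be near zero regardless of amplitude and make
the rule vacuous; the absolute-value form preserves its intent of catching
high-amplitude epochs. The signed variant remains available
(`stat = "mean"`). With fewer than four values quartiles are undefined:
nothing is rejected and a warning is raised.

**Event-level artifact masking.** `detect_artifact_events()` z-scores, over
the whole trace, (a) the first difference and (b) the amplitude after a
fourth-order 250 Hz high-pass (the filter order is a package choice), and
masks every sample where either |z| exceeds 5, extended by ±100 ms and
merged. The trace is reflection-padded before the high-pass so filter
start-up transients at the recording edges are not themselves flagged.
Masked samples are excluded from normalisation statistics and propagate as
missing bins.

# Spectral analysis

`morlet_tfr()` convolves each channel with complex Morlet wavelets
(wavelet number 6) on a grid of 32 log-spaced centre frequencies spanning
2–431 Hz inclusive, $f_k = 2\,(431/2)^{k/31}$; the 80–120 Hz band is the
mean z-score over the centres inside it (90.6 and 107.7 Hz). Power is the
squared magnitude, natural-log-transformed with a tiny positive floor
(`1e-300`, recorded in the call) so exact zeros cannot produce $-\infty$.
z-scoring (`zscore_session()`) is per channel and per frequency over all
retained samples of the session; whether the original analysis pooled
channels is not determinable from its description, so per-channel is the
default with `pool_channels` as a switch. Per-channel scaling makes all
downstream statistics invariant to electrode gain.

`bin_power()` epochs the continuous z-scored power at image onset and
averages 200 ms windows stepped by 100 ms (50% overlap), half-open
`[start, start + width)`, with the trailing partial bin dropped.
Recognition epochs run from onset to the response; responses slower than
10 s are excluded. Bins beyond a trial's own extent are missing, not
truncated, so all trials share one bin grid. Analyses that feed
permutation statistics restrict to the window complete in every trial
(0–1.2 s under the default response-time floor) to avoid bins whose
trial support varies.

`bootstrap_match()` equalises trial counts between conditions: the larger
condition is subsampled to the smaller one's size 100 times and the
subsample means averaged. The smaller condition is untouched.

# Reinstatement

For each temporal epoch the feature vector stacks the z-scored band power
of the scoped electrodes ($K = L$ entries for one band, $K = LF$ in
general). For trial $n$, the reinstatement map is the cosine similarity
$C_n(i,j) = \vec E_i \cdot \vec R_j / (\lVert\vec E_i\rVert\,\lVert\vec
R_j\rVert)$ between every encoding epoch $i$ and retrieval epoch $j$.
Cosine rather than Pearson similarity is deliberate: a broadband power
increase shared by all electrodes *is* reinstatement-like evidence and
should score high, which centring would destroy.

The image-specificity null re-pairs each trial's retrieval epochs with the
encoding epochs of a *different* image from the same four-image list — a
strict within-list derangement, never a self-pairing. All derangements of
a list (9 for a list of four) are enumerated and averaged instead of
sampled: enumeration is cheap and removes Monte-Carlo noise from the null.
Lists with a single usable image cannot be deranged and are excluded with
a log entry. Normalisation of maps across trials is cell-wise z-scoring by
default; the alternative reading of normalising by the grand mean
similarity is available (`method = "global"`). The true-minus-shuffled
difference feeds the 2-D cluster machinery; retrieval-locked time series
average the normalised maps over the encoding epochs found significant.

# Connectivity

**Cross-correlograms.** Band power over the first second after image
onset is averaged into non-overlapping 10 ms bins. For each electrode
pair, the per-trial lagged correlation is computed at every lag (Pearson-
normalised per lag so pairs are comparable across electrodes; raw
covariance is a switch) and averaged over trials. The chance correlogram
repeats this with mismatched trial pairs (100 draws), capturing
stimulus-locked coupling; the true-minus-chance difference isolates
trial-specific coupling. Peaks are searched within ±200 ms (wider lags are
edge-dominated), ties resolve toward zero lag, per-pair peak lags are
averaged within participant, and the across-participant mean is tested
against zero (two-sided paired t). Significance of a single pair compares
true versus chance values within ±50 ms.

**Coherence.** Magnitude-squared coherence $C(f) = |P_{xy}|^2 /
(P_{xx} P_{yy})$ is estimated by Welch averaging (500 ms Hann segments,
50% overlap inside each 1 s epoch; segmenting is a package choice recorded
in the call) on common-average-referenced original contacts — bipolar
referencing removes exactly the low-frequency coherence being measured.
With $K$ independent segments the estimator's null expectation is
approximately $1/K$, which the tests verify. The alpha band is fixed at
8–12 Hz.

**Phase-locking value.** $\bar R_{pq}(t,f) = \frac{1}{N}\lvert \sum_n
e^{i(\phi_p - \phi_q)} \rvert$ over trials, with phases from the Hilbert
transform of the zero-phase band-passed signal (fourth-order Butterworth).
PLV is amplitude-blind, so it confirms that coherence increases are not
power artifacts. Under uniform random phase differences
$E[\bar R] \approx \sqrt{\pi/4N}$, the Rayleigh expectation used as an
oracle.

# Temporal dynamics

The condition-difference series (manipulated-correct minus
repeated-correct, after bootstrap matching) is characterised per region by:

* **Onset**: global peak inside the analysis window; the local minimum
  immediately preceding it (strict neighbours, plateaus resolved to their
  latest bin; absent a minimum the window start is used and flagged); a
  least-squares line through all bins between minimum and peak; the
  onset is that line's zero crossing, clamped to non-negative times with a
  flag. The default peak-search window is 0–2 s (configurable); pipeline
  code uses 0–1.2 s, the window complete in every trial.
* **Half-peak time**: first time the series reaches 50% of the peak,
  linearly interpolated between bins, not earlier than the local minimum.
* **Instantaneous slope**: mean of adjacent-bin differences within the
  first 500 ms (telescopes to the exact slope on a ramp), compared across
  regions by unpaired t.
* **Peak-time test**: difference of argmax times of the two regions'
  across-participant mean series, against the null of independently
  swapping region labels within each participant; all $2^n$ relabellings
  are enumerated for $n \le 12$ (the test is then exact by construction),
  sampled otherwise. Non-unique maxima resolve to the earliest bin.

The condition-difference series is baseline-corrected against the mean of
the pre-onset bins (default 400 ms), anchoring the pre-stimulus difference
at zero so that sampling offsets between condition groups cannot shift the
zero crossing. Onsets are estimated per session (per participant) and the
*onset estimates* averaged, matching how onset distributions are compared
across participants. This matters: averaging difference *series* across
participants before estimating propagates each participant's
burst-amplitude sampling noise nonlinearly into the local-minimum search
and leaves a heavy early tail in the estimate, whereas averaging the
per-participant onsets is unbiased and concentrates at the usual
square-root rate (the package's validation recovers the injected
270/480 ms pair as ~0.28/0.51 s means across experiments).

# Cluster-based permutation statistics

Pointwise statistics (paired t across participants, or unpaired t across
trials for single-electrode contrasts) are thresholded at a cluster-
forming p of 0.05; contiguous suprathreshold bins of common sign (1-D) or
4-connected cells (2-D; 8-connectivity is a switch) form clusters scored
by their summed t. The null permutes the randomisation unit — sign flips
of participant differences, or condition-label permutations over trials
(label counts are preserved, so no permutation empties a condition) — and
retains each permutation's maximum cluster statistic, correcting for
multiple comparisons. Two-sided testing clusters the two signs separately
and compares |sums| to the max-|statistic| null; the one-sided option
exists for directional contrasts.

For $n \le 10$ participants all $2^n$ sign patterns are enumerated: the
p-value is then `count / 2^n` (identity included) and the test exact.
Sampled permutations use the `(1 + count)/(1 + n_perm)` convention so no
p-value is zero. Degenerate zero-variance bins receive the largest
representable statistic and a flag rather than an error, since a uniform
nonzero difference is maximal evidence, not an invalid input.

# Behaviour

`detect_fixations()` is a dispersion-threshold (I-DT) detector: a window
grows while gaze stays within 2 degrees — maximum pairwise distance by
default; the bounding-box variant is a switch — and emits a fixation at
≥100 ms. Sampling gaps beyond ~2 sample periods split windows.
`critical_region_metrics()` scores fixations and localisation clicks
against each image's critical-region rectangle; trials without fixations
contribute probability 0 and time fraction 0 (not missing). Cowan's
working-memory capacity is $K = (HR + CR - 1)N$; the hit rate is the mean
of the added and removed correct-recognition rates (this composition
reproduces the published capacity range of roughly 4.4–10.9 items at set
sizes 8–20) with trial-weighted pooling as an option, and the correct
rejection rate is the repeated-condition accuracy. Negative estimates are
returned flagged, not clipped.

# Validation problem sizes

The test-suite study conditions, chosen once: lag recovery uses six-list,
2+2-channel two-region sessions (50 regenerations); reinstatement
specificity uses five-list, eight-channel sessions across all four regions
(50 regenerations each for image-specific and shared-gain variants, with a
trial-level sign-flip 2-D cluster test per session); onset ordering uses
four-session experiments of ten lists and 3+3 channels, with shortened
(1 s) encoding presentations since encoding epochs do not enter that
analysis (100 experiments);
cluster calibration uses 200 simulated eight-participant experiments with
exact enumeration. Identity checks (PLV, coherence, Cowan's K, quartile
thresholds) are closed-form. `scripts/acceptance.R` re-runs the same
pipelines at moderately reduced regeneration counts and writes the
resulting quantities as JSON.

# Known limitations

* The generator's effects are additive sinusoid-carrier bursts; real
  high-gamma is broadband and non-sinusoidal. Wavelet band-averaging makes
  the analyses insensitive to this, but carrier-specific artifacts (e.g.
  harmonics) are not represented.
* Electrode localisation is out of scope: region labels are trusted input
  metadata.
* The kurtosis variant of trial screening mentioned alongside the
  quartile rule is not separately parameterised; only the quartile form
  is implemented, applied to trials and then electrodes.
* Participant-level averaging weights sessions equally, not by trial
  count; the alternative would need a weighting convention the source
  analyses do not specify.
* Theta/alpha–high-gamma phase-amplitude coupling is not implemented.
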