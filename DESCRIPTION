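Package: memscan
Title: Event-Locked High-Gamma Dynamics, Reinstatement, and Connectivity
    Analysis for Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing episodic-memory experiments recorded with
    intracranial EEG. Implements bipolar re-referencing of grid and strip
    montages, two-tier artifact rejection (quartile-based trial/electrode
    screening and gradient/high-frequency event masking), Morlet wavelet
    time-frequency decomposition with session-wise normalisation and
    overlapping temporal binning, encoding-retrieval reinstatement via cosine
    similarity of distributed high-gamma (80-120 Hz) patterns with
    within-list shuffle nulls, inter-regional lag estimation from power
    cross-correlograms, magnitude-squared coherence and phase-locking value,
    onset estimation of condition differences, and nonparametric
    cluster-based permutation statistics in one and two dimensions. Includes
    a synthetic-data generator with known ground truth (recurring per-image
    spatial patterns, region-specific onsets, fixed inter-regional envelope
    lags, alpha-band coupling, artifacts, and gaze streams) used to validate
    the full pipeline, plus dispersion-based fixation detection and
    behavioural summaries including Cowan's K.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
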