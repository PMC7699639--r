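# Higher-level wrappers composing the module operations into the standard
# analyses: high-gamma band power extraction, condition-difference time
# series, inter-regional lag recovery, and session-level reinstatement.

#' Trial condition classes used in contrasts
#'
#' Collapses added and removed into "manipulated" and crosses with
#' correctness: manip_correct, manip_incorrect, repeated_correct,
#' repeated_incorrect (encoding rows get NA).
#'
#' @param trials trial table.
#' @return character vector, one entry per row of `trials`.
#' @export
condition_class <- function(trials) {
  cls <- rep(NA_character_, nrow(trials))
  rec <- trials$phase == "recognition"
  manip <- trials$condition %in% c("added", "removed")
  cls[rec & manip & trials$correct %in% TRUE] <- "manip_correct"
  cls[rec & manip & trials$correct %in% FALSE] <- "manip_incorrect"
  cls[rec & !manip & trials$correct %in% TRUE] <- "repeated_correct"
  cls[rec & !manip & trials$correct %in% FALSE] <- "repeated_incorrect"
  cls
}

#' High-gamma (80-120 Hz) z-scored power of a session
#'
#' Runs the Morlet transform restricted to the wavelet centres of the
#' 32-frequency grid that fall inside the band, then z-scores per channel
#' and frequency over the session.
#'
#' @param rec conditioned `ieeg_recording`.
#' @param band frequency band (Hz).
#' @param mask optional artifact mask (samples x channels).
#' @return z-scored `tfr` holding only the in-band wavelet centres.
#' @export
hg_power <- function(rec, band = c(80, 120), mask = NULL) {
  grid <- morlet_frequencies()
  freqs <- grid[band_members(grid, band)]
  zscore_session(morlet_tfr(rec, freqs = freqs), mask = mask)
}

#' Channel indices of a region
#'
#' @param channels channel metadata data frame.
#' @param region region label.
#' @return integer indices.
#' @export
region_channels <- function(channels, region) {
  idx <- which(channels$region == region)
  stop_if_not(length(idx) > 0, "no channels in region %s", region)
  idx
}

#' Condition-difference band-power time series for one region
#'
#' Bins the z-scored band power of the region's channels per recognition
#' trial, averages channels, matches trial counts between the two condition
#' classes with the bootstrap, and returns the difference of condition
#' means per bin.
#'
#' @param tfr z-scored `tfr` (band centres only, e.g. from [hg_power()]).
#' @param trials trial table.
#' @param region region label.
#' @param class_a,class_b condition classes (see [condition_class()]);
#'   either may pool several classes, e.g. `class_b = c("repeated_correct",
#'   "manip_incorrect")` compares against all trials without the
#'   recognition-difference response.
#' @param window analysis window (s).
#' @param baseline_s length of the pre-onset baseline (s); the mean
#'   difference over bins ending at or before image onset is subtracted,
#'   anchoring the pre-stimulus difference at zero. 0 disables.
#' @param n_iter bootstrap iterations for trial-count matching.
#' @param seed integer seed.
#' @return list with `diff` (per-bin difference, a minus b, baseline-
#'   corrected), `mean_a`, `mean_b`, `centers`, `n_a`, `n_b`, `baseline`.
#' @export
condition_diff_series <- function(tfr, trials, region,
                                  class_a = "manip_correct",
                                  class_b = "repeated_correct",
                                  window = c(0, 2), baseline_s = 0.4,
                                  n_iter = 100, seed = 1) {
  chans <- region_channels(tfr$channels, region)
  bp <- bin_power(tfr, trials, phase = "recognition",
                  window = c(window[1] - baseline_s, window[2]),
                  band = range(tfr$freqs))
  cls <- condition_class(bp$trials)
  a <- which(cls %in% class_a)
  b <- which(cls %in% class_b)
  stop_if_not(length(a) > 0 && length(b) > 0,
              "both condition classes must be non-empty")
  # trials x bins after averaging the region's channels
  reg <- apply(bp$values[, chans, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
  bm <- bootstrap_match(reg[a, , drop = FALSE], reg[b, , drop = FALSE],
                        n_iter = n_iter, seed = seed)
  d <- bm$mean_a - bm$mean_b
  starts <- bp$centers - bp$width / 2
  ends <- bp$centers + bp$width / 2
  base <- 0
  if (baseline_s > 0) {
    bl <- which(ends <= window[1] + 1e-9)
    if (length(bl)) base <- mean(d[bl], na.rm = TRUE)
  }
  keep <- which(starts >= window[1] - 1e-9)
  list(diff = d[keep] - base, mean_a = bm$mean_a[keep], mean_b = bm$mean_b[keep],
       centers = bp$centers[keep], n_a = bm$n_a, n_b = bm$n_b, baseline = base)
}

#' Recover the inter-regional power lag of a session
#'
#' Builds 10 ms binned high-gamma power over the first second after image
#' onset for every recognition trial, computes the true (and optionally
#' chance) cross-correlogram for every cross-region electrode pair, and
#' averages the per-pair peak lags. Positive lags mean `region_a` leads.
#'
#' @param tfr z-scored band `tfr`.
#' @param trials trial table.
#' @param region_a,region_b region labels (defaults PT and MTL).
#' @param band frequency band (Hz).
#' @param with_chance also compute chance correlograms (slower).
#' @param n_perm chance draws per pair.
#' @param seed integer seed.
#' @param max_pairs cap on electrode pairs (first `max_pairs` used).
#' @return list with `pairs` (per-pair data frame with `peak_ms`),
#'   `mean_lag_ms`, and `ccgs` (list of true/chance correlograms).
#' @export
recover_region_lag <- function(tfr, trials, region_a = "PT", region_b = "MTL",
                               band = c(80, 120), with_chance = FALSE,
                               n_perm = 100, seed = 1, max_pairs = Inf) {
  ia <- region_channels(tfr$channels, region_a)
  ib <- region_channels(tfr$channels, region_b)
  pw <- list()
  for (ch in union(ia, ib)) {
    pw[[as.character(ch)]] <- trial_band_power(tfr, trials, ch, band = band)
  }
  combos <- expand.grid(a = ia, b = ib)
  if (nrow(combos) > max_pairs) combos <- combos[seq_len(max_pairs), ]
  ccgs <- vector("list", nrow(combos))
  peak <- numeric(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    A <- pw[[as.character(combos$a[k])]]
    B <- pw[[as.character(combos$b[k])]]
    tru <- crosscorrelogram(A, B)
    ch <- if (with_chance)
      chance_crosscorrelogram(A, B, n_perm = n_perm, seed = seed + k) else NULL
    ccgs[[k]] <- list(true = tru, chance = ch)
    peak[k] <- peak_lag(tru)
  }
  pairs <- data.frame(a = combos$a, b = combos$b, peak_ms = peak)
  list(pairs = pairs, mean_lag_ms = mean(peak), ccgs = ccgs)
}

#' Session-level reinstatement: true and within-list shuffled maps
#'
#' Bins encoding and recognition high-gamma power, builds feature vectors
#' over the scoped electrodes, and returns the across-trial mean true and
#' shuffled cosine maps for the session (one "participant").
#'
#' @param tfr z-scored band `tfr`.
#' @param trials trial table.
#' @param scope optional electrode indices (default all).
#' @param enc_window,ret_window epoch windows (s).
#' @param seed seed for sampled derangements (lists of <= 5 images are
#'   enumerated exactly).
#' @return list with `true_mean`, `null_mean` (enc x ret matrices),
#'   `enc_centers`, `ret_centers`, `n_trials`.
#' @export
session_reinstatement <- function(tfr, trials, scope = NULL,
                                  enc_window = c(0, 2), ret_window = c(0, 2),
                                  seed = 1) {
  bp_enc <- bin_power(tfr, trials, phase = "encoding", window = enc_window,
                      band = range(tfr$freqs))
  bp_ret <- bin_power(tfr, trials, phase = "recognition", window = ret_window,
                      band = range(tfr$freqs))
  feat <- build_features(bp_enc, bp_ret, scope = scope)
  true_maps <- cosine_map(feat)
  null_maps <- shuffle_null(feat, seed = seed)
  list(true_mean = apply(true_maps, c(2, 3), mean, na.rm = TRUE),
       null_mean = apply(null_maps, c(2, 3), mean, na.rm = TRUE),
       enc_centers = feat$enc_centers, ret_centers = feat$ret_centers,
       n_trials = dim(true_maps)[1])
}
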