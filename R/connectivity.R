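# Inter-regional lag (cross-correlograms of band power), magnitude-squared
# coherence, and phase-locking value.

#' Trial-wise band-power time series in coarse bins
#'
#' Extracts `window` seconds of continuous z-scored band power after each
#' image onset and averages it into non-overlapping bins (10 ms by
#' default), the substrate of the cross-correlogram analysis.
#'
#' @param tfr z-scored [morlet_tfr()] result.
#' @param trials trial table.
#' @param channel channel index.
#' @param band frequency band (Hz) averaged over wavelet centres.
#' @param phase trial phase to use.
#' @param window window after image onset (s); the lag analysis uses the
#'   first second.
#' @param bin_s bin width (s).
#' @return trials x bins matrix.
#' @export
trial_band_power <- function(tfr, trials, channel, band = c(80, 120),
                             phase = "recognition", window = c(0, 1),
                             bin_s = 0.01) {
  stop_if_not(inherits(tfr, "tfr"), "tfr must come from morlet_tfr()")
  bi <- band_members(tfr$freqs, band)
  stop_if_not(length(bi) > 0, "no wavelet centres inside the band")
  fs <- tfr$fs
  rows <- trials[trials$phase == phase, , drop = FALSE]
  nb <- round(bin_s * fs)
  n_bins <- floor((window[2] - window[1]) / bin_s)
  out <- matrix(NA_real_, nrow(rows), n_bins)
  for (r in seq_len(nrow(rows))) {
    i0 <- floor((rows$image_onset_s[r] + window[1]) * fs) + 1L
    i1 <- i0 + n_bins * nb - 1L
    if (i0 < 1 || i1 > dim(tfr$power)[1]) next
    x <- rowMeans(tfr$power[i0:i1, channel, bi, drop = FALSE], dims = 1)
    out[r, ] <- bin_mean(as.numeric(x), nb)
  }
  out
}

new_ccg <- function(lags_ms, r, n_trials, kind) {
  structure(list(lags_ms = lags_ms, r = r, n_trials = n_trials, kind = kind),
            class = "crosscorrelogram")
}

ccg_core <- function(A, B, pairs_a, pairs_b, max_lag_bins, bin_ms,
                     normalize = TRUE) {
  lags <- -max_lag_bins:max_lag_bins
  n_bins <- ncol(A)
  acc <- numeric(length(lags))
  cnt <- numeric(length(lags))
  for (p in seq_along(pairs_a)) {
    a <- A[pairs_a[p], ]
    b <- B[pairs_b[p], ]
    if (anyNA(a) || anyNA(b)) next
    for (li in seq_along(lags)) {
      L <- lags[li]
      if (L >= 0) {
        ia <- seq_len(n_bins - L); ib <- ia + L
      } else {
        ib <- seq_len(n_bins + L); ia <- ib - L
      }
      if (length(ia) < 2) next
      v <- if (normalize) {
        if (sd(a[ia]) == 0 || sd(b[ib]) == 0) NA_real_ else cor(a[ia], b[ib])
      } else {
        mean((a[ia] - mean(a[ia])) * (b[ib] - mean(b[ib])))
      }
      if (!is.na(v)) { acc[li] <- acc[li] + v; cnt[li] <- cnt[li] + 1 }
    }
  }
  ifelse(cnt > 0, acc / cnt, NA_real_)
}

#' True cross-correlogram of two band-power series
#'
#' Computes, for every trial, the lagged correlation between the 10 ms
#' binned power of two electrodes over the first second after image onset,
#' and averages over trials. A positive lag means the first electrode's
#' power leads the second's. Per-trial correlations are Pearson-normalised
#' per lag by default so pairs are comparable across electrodes
#' (`normalize = FALSE` gives raw lagged covariance).
#'
#' @param powerA,powerB trials x bins matrices from [trial_band_power()]
#'   (same trials).
#' @param bin_ms bin width of the inputs (ms).
#' @param max_lag_ms largest lag examined (ms); restricted to 200 ms to
#'   avoid edge-dominated lags.
#' @param normalize Pearson-normalise each per-trial correlation.
#' @return a `crosscorrelogram`: `lags_ms`, `r` (trial-averaged), `n_trials`.
#' @export
crosscorrelogram <- function(powerA, powerB, bin_ms = 10, max_lag_ms = 200,
                             normalize = TRUE) {
  stop_if_not(nrow(powerA) == nrow(powerB) && ncol(powerA) == ncol(powerB),
              "powerA and powerB must share trials and bins")
  ok <- !apply(powerA, 1, anyNA) & !apply(powerB, 1, anyNA)
  stop_if_not(any(ok), "no complete trials")
  mlb <- floor(max_lag_ms / bin_ms)
  r <- ccg_core(powerA, powerB, which(ok), which(ok), mlb, bin_ms, normalize)
  new_ccg((-mlb:mlb) * bin_ms, r, sum(ok), "true")
}

#' Chance cross-correlogram from mismatched trials
#'
#' Repeats the cross-correlation with the power series of one electrode on
#' a randomly chosen trial paired against the other electrode on a
#' *different* randomly chosen trial, averaged over `n_perm` draws. The
#' chance correlogram captures stimulus-locked (non-trial-specific)
#' coupling; true minus chance isolates trial-specific coupling.
#'
#' @inheritParams crosscorrelogram
#' @param n_perm number of mismatched-trial draws.
#' @param seed integer seed.
#' @return a `crosscorrelogram` with `kind = "chance"`.
#' @export
chance_crosscorrelogram <- function(powerA, powerB, n_perm = 100, seed = 1,
                                    bin_ms = 10, max_lag_ms = 200,
                                    normalize = TRUE) {
  stop_if_not(n_perm >= 1, "n_perm must be at least 1")
  ok <- which(!apply(powerA, 1, anyNA) & !apply(powerB, 1, anyNA))
  stop_if_not(length(ok) >= 2, "need at least 2 complete trials")
  set.seed(seed)
  ia <- integer(n_perm); ib <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    pair <- sample(ok, 2L)
    ia[p] <- pair[1]; ib[p] <- pair[2]
  }
  mlb <- floor(max_lag_ms / bin_ms)
  r <- ccg_core(powerA, powerB, ia, ib, mlb, bin_ms, normalize)
  new_ccg((-mlb:mlb) * bin_ms, r, n_perm, "chance")
}

#' Peak lag of a cross-correlogram
#'
#' Lag of the maximum correlation within `search_ms`; ties are broken
#' toward the lag nearest zero.
#'
#' @param ccg a `crosscorrelogram`.
#' @param search_ms half-width of the peak search window (ms).
#' @return peak lag in ms.
#' @export
peak_lag <- function(ccg, search_ms = 200) {
  idx <- which(abs(ccg$lags_ms) <= search_ms & !is.na(ccg$r))
  stop_if_not(length(idx) > 0, "no valid lags inside the search window")
  mx <- max(ccg$r[idx])
  cand <- idx[ccg$r[idx] >= mx - 1e-12]
  cand <- cand[which.min(abs(ccg$lags_ms[cand]))]
  ccg$lags_ms[cand]
}

#' Region-pair latency summary across electrode pairs and participants
#'
#' For each electrode pair: a paired comparison of true versus chance
#' correlogram values within +/- 50 ms (significant coupling), and the
#' true correlogram's peak lag. Peak lags are averaged across pairs within
#' a participant, and the across-participant distribution of mean peak lags
#' is tested against zero with a two-sided paired t test.
#'
#' @param pairs list of entries, each a list with `participant`, `true` and
#'   `chance` crosscorrelograms.
#' @param window_ms half-width of the true-vs-chance test window (ms).
#' @param search_ms peak-search half-width (ms).
#' @return list with `pair_stats` (one row per electrode pair),
#'   `participant_means`, `mean_lag_ms`, and `lag_test` (the t test, NULL
#'   with a single participant).
#' @export
peak_lag_stats <- function(pairs, window_ms = 50, search_ms = 200) {
  stop_if_not(length(pairs) > 0, "no electrode pairs supplied")
  rows <- lapply(pairs, function(p) {
    idx <- which(abs(p$true$lags_ms) <= window_ms)
    tt <- tryCatch(t.test(p$true$r[idx], p$chance$r[idx], paired = TRUE),
                   error = function(e) NULL)
    data.frame(participant = p$participant,
               peak_ms = peak_lag(p$true, search_ms),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  pair_stats <- do.call(rbind, rows)
  pm <- tapply(pair_stats$peak_ms, pair_stats$participant, mean)
  participant_means <- data.frame(participant = names(pm),
                                  mean_peak_ms = as.numeric(pm))
  lag_test <- if (nrow(participant_means) >= 2)
    t.test(participant_means$mean_peak_ms, mu = 0) else NULL
  list(pair_stats = pair_stats, participant_means = participant_means,
       mean_lag_ms = mean(participant_means$mean_peak_ms),
       lag_test = lag_test)
}

#' Magnitude-squared coherence (Welch estimate)
#'
#' `C(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` with spectral densities
#' estimated by windowed, overlapping segment averaging within the supplied
#' epoch. Inputs should be common-average-referenced original contacts
#' (see [common_average_reference()]): bipolar referencing removes the
#' low-frequency coherence being measured. Coherence lies in `[0, 1]`; with
#' `K` independent segments its expectation under independence is roughly
#' `1/K`.
#'
#' @param x,y numeric vectors (one epoch, typically 1 s).
#' @param fs sampling rate (Hz).
#' @param seg_s segment length (s).
#' @param overlap fractional segment overlap.
#' @param window "hann" or "rect".
#' @return list of class `coherence_spectrum`: `freq` (Hz), `coherence`,
#'   `n_segments`.
#' @export
msc_coherence <- function(x, y, fs, seg_s = 0.5, overlap = 0.5,
                          window = c("hann", "rect")) {
  window <- match.arg(window)
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  nseg <- round(seg_s * fs)
  step <- max(1L, round(nseg * (1 - overlap)))
  stop_if_not(length(x) >= nseg + step,
              "epoch holds fewer than 2 segments; shorten seg_s")
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
       else rep(1, nseg)
  nf <- nseg %/% 2L
  pxx <- pyy <- numeric(nf)
  pxy <- complex(real = numeric(nf), imaginary = numeric(nf))
  for (s in starts) {
    xs <- x[s:(s + nseg - 1L)]; ys <- y[s:(s + nseg - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)[2:(nf + 1L)]
    Y <- stats::fft((ys - mean(ys)) * w)[2:(nf + 1L)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  coh <- Mod(pxy)^2 / (pxx * pyy)
  structure(list(freq = (1:nf) * fs / nseg, coherence = coh,
                 n_segments = length(starts)),
            class = "coherence_spectrum")
}

#' Alpha-band mean of a coherence spectrum
#'
#' @param cs a `coherence_spectrum`.
#' @param band band edges (Hz); the alpha band is 8-12 Hz.
#' @return mean coherence over frequencies inside the band.
#' @export
band_coherence <- function(cs, band = c(8, 12)) {
  idx <- cs$freq >= band[1] & cs$freq <= band[2]
  stop_if_not(any(idx), "no coherence frequencies inside the band")
  mean(cs$coherence[idx])
}

#' Phase-locking value across trials
#'
#' `R(t) = |mean over trials of exp(i * (phi_p - phi_q))|` at every time
#' point: the modulus of the mean unit phasor of phase differences. Equals
#' 1 for a constant phase lag and approaches `sqrt(pi / (4 N))` in
#' expectation for uniform random phase differences over `N` trials.
#' Insensitive to amplitude by construction, so it disambiguates coherence
#' changes from power changes.
#'
#' @param phaseP,phaseQ trials x time matrices of instantaneous phase
#'   (radians), e.g. from [hilbert_phase()] applied per trial.
#' @param zscore also return the PLV time series z-scored over time.
#' @return list of class `plv_series`: `plv` (per time point), `z`
#'   (if requested), `n_trials`.
#' @export
plv <- function(phaseP, phaseQ, zscore = TRUE) {
  stop_if_not(all(dim(phaseP) == dim(phaseQ)),
              "phase matrices must share dimensions")
  stop_if_not(nrow(phaseP) >= 2, "PLV needs at least 2 trials")
  v <- Mod(colMeans(exp(1i * (phaseP - phaseQ))))
  z <- if (zscore) as.numeric(scale(v)) else NULL
  structure(list(plv = v, z = z, n_trials = nrow(phaseP)),
            class = "plv_series")
}
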