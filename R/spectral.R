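# Morlet time-frequency decomposition, session-wise normalisation,
# overlapping temporal binning, and bootstrap trial-count matching.

#' Logarithmically spaced wavelet centre frequencies
#'
#' `n` frequencies spanning `[fmin, fmax]` inclusive:
#' `f_k = fmin * (fmax/fmin)^(k/(n-1))`. The default grid is the 32-wavelet
#' 2-431 Hz set.
#'
#' @param n number of frequencies.
#' @param fmin,fmax endpoints (Hz), both included.
#' @return numeric vector of length `n`.
#' @export
morlet_frequencies <- function(n = 32, fmin = 2, fmax = 431) {
  fmin * (fmax / fmin)^((seq_len(n) - 1) / (n - 1))
}

#' Wavelet centres of a frequency band
#'
#' Indices of wavelet centre frequencies falling inside `[band[1], band[2]]`
#' (endpoints included). The high-gamma band of interest is 80-120 Hz.
#'
#' @param freqs centre frequencies (Hz).
#' @param band length-2 numeric band edges (Hz).
#' @return integer indices into `freqs`.
#' @export
band_members <- function(freqs, band = c(80, 120)) {
  which(freqs >= band[1] & freqs <= band[2])
}

# Complex Morlet kernel at frequency f: Gaussian envelope of width
# sigma_t = n_cycles / (2 pi f), truncated at +/- 4 sigma, unit energy.
morlet_kernel <- function(f, fs, n_cycles = 6) {
  sigma <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma^2)) * exp(1i * 2 * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet transform of a recording
#'
#' Convolves every channel with complex Morlet wavelets (wavelet number 6 by
#' default) at the requested centre frequencies over the continuous session,
#' squares and log-transforms the magnitude to obtain instantaneous power,
#' and optionally keeps the instantaneous phase. Trials are epoched later
#' (see [bin_power()]) with a surrounding buffer, so edge effects from the
#' convolution never enter binned statistics: only the outermost
#' `4 * sigma_t` samples of the session are affected and a 1 s buffer is
#' enforced at epoching.
#'
#' @param rec conditioned `ieeg_recording`.
#' @param freqs wavelet centre frequencies (Hz); defaults to the 32-wavelet
#'   2-431 Hz grid. Pass a subset (e.g. `morlet_frequencies()[band_members(
#'   morlet_frequencies())]`) to save memory.
#' @param n_cycles wavelet number (cycles per Gaussian SD scale).
#' @param keep_phase keep the instantaneous phase array.
#' @param log_power log-transform squared magnitude (natural log, with a
#'   tiny positive floor so exact zeros do not map to -Inf).
#' @param power_floor floor added to squared magnitude before the log.
#' @return list of class `tfr`: `power` (samples x channels x freqs),
#'   optional `phase`, `freqs`, `fs`, `n_cycles`, `channels`, `session_id`,
#'   `zscored` flag.
#' @export
morlet_tfr <- function(rec, freqs = morlet_frequencies(), n_cycles = 6,
                       keep_phase = FALSE, log_power = TRUE,
                       power_floor = 1e-300) {
  stop_if_not(inherits(rec, "ieeg_recording"), "rec must be an ieeg_recording")
  stop_if_not(all(freqs > 0 & freqs < rec$fs / 2),
              "all frequencies must lie in (0, fs/2)")
  n <- nrow(rec$traces)
  n_ch <- ncol(rec$traces)
  n_f <- length(freqs)
  power <- array(NA_real_, dim = c(n, n_ch, n_f))
  phase <- if (keep_phase) array(NA_real_, dim = c(n, n_ch, n_f)) else NULL
  # one shared FFT length: signal spectra are computed once per channel and
  # reused across wavelets
  kernels <- lapply(freqs, morlet_kernel, fs = rec$fs, n_cycles = n_cycles)
  max_m <- max(vapply(kernels, length, 1L))
  nfft <- stats::nextn(n + max_m - 1L, c(2L, 3L, 5L))
  K <- lapply(kernels, function(k) stats::fft(c(k, rep(0, nfft - length(k)))))
  for (ch in seq_len(n_ch)) {
    X <- stats::fft(c(rec$traces[, ch], rep(0, nfft - n)))
    for (fi in seq_len(n_f)) {
      w <- stats::fft(X * K[[fi]], inverse = TRUE) / nfft
      off <- (length(kernels[[fi]]) - 1L) %/% 2L
      w <- w[(off + 1L):(off + n)]
      p <- Mod(w)^2
      power[, ch, fi] <- if (log_power) log(p + power_floor) else p
      if (keep_phase) phase[, ch, fi] <- Arg(w)
    }
  }
  structure(list(power = power, phase = phase, freqs = freqs, fs = rec$fs,
                 n_cycles = n_cycles, channels = rec$channels,
                 session_id = rec$session_id, zscored = FALSE),
            class = "tfr")
}

#' Session-wise z-scoring of spectral power
#'
#' Standardises power separately for each channel and frequency using the
#' mean and SD over all retained samples of the session, so downstream
#' statistics are comparable across sessions and insensitive to per-channel
#' gain. Masked (artifactual) samples are excluded from the statistics and
#' set to NA.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param mask optional logical samples x channels matrix (or per-sample
#'   vector), TRUE = exclude.
#' @param pool_channels if TRUE, pool statistics across channels within each
#'   frequency instead of per channel.
#' @return the `tfr` with standardised power.
#' @export
zscore_session <- function(tfr, mask = NULL, pool_channels = FALSE) {
  stop_if_not(inherits(tfr, "tfr"), "tfr must come from morlet_tfr()")
  dm <- dim(tfr$power)
  if (!is.null(mask)) {
    if (is.vector(mask)) mask <- matrix(mask, nrow = dm[1], ncol = dm[2])
    stop_if_not(nrow(mask) == dm[1] && ncol(mask) == dm[2],
                "mask must be samples x channels")
  }
  for (fi in seq_len(dm[3])) {
    sl <- tfr$power[, , fi, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, ncol = 1L)
    if (!is.null(mask)) sl[mask] <- NA_real_
    if (pool_channels) {
      mu <- mean(sl, na.rm = TRUE)
      sg <- sd(as.vector(sl), na.rm = TRUE)
      stop_if_not(is.finite(sg) && sg > 0,
                  "zero variance at frequency %.3g Hz", tfr$freqs[fi])
      sl <- (sl - mu) / sg
    } else {
      for (ch in seq_len(dm[2])) {
        v <- sl[, ch]
        mu <- mean(v, na.rm = TRUE)
        sg <- sd(v, na.rm = TRUE)
        stop_if_not(is.finite(sg) && sg > 0,
                    "zero variance in channel %s at %.3g Hz",
                    tfr$channels$label[ch], tfr$freqs[fi])
        sl[, ch] <- (v - mu) / sg
      }
    }
    tfr$power[, , fi] <- sl
  }
  tfr$zscored <- TRUE
  tfr
}

#' Bin z-scored power into overlapping temporal epochs
#'
#' Cuts event-locked epochs from the continuous transform and averages power
#' in 200 ms windows stepped every 100 ms (50% overlap) by default. Bin `b`
#' (0-based) covers `[b*step, b*step + width)` seconds relative to image
#' onset; a trailing partial bin is dropped. Bins extending beyond the
#' trial's own extent (image offset during encoding, response during
#' recognition) are NA. Trials whose epoch (with a 1 s buffer) falls outside
#' the recording are skipped with a log entry. Any NA sample inside a bin
#' (e.g. masked artifact) makes that bin NA.
#'
#' @param tfr a z-scored [morlet_tfr()] result.
#' @param trials trial table.
#' @param phase "recognition" or "encoding".
#' @param window analysis window relative to onset (s); default `c(0, 2)`.
#' @param width,step bin width and step (s); must be multiples of the sample
#'   period.
#' @param band optional length-2 band (Hz): averages z-scores over wavelet
#'   centres inside the band, collapsing the frequency dimension.
#' @param buffer_s required buffer inside the recording on both sides (s).
#' @param max_rt trials with response time above this are excluded (s).
#' @return list of class `binned_power`: `values` (trials x channels x
#'   freqs x bins, or trials x channels x bins if `band` given), `centers`
#'   (bin centres, s), `trials` (the rows used), `skipped` (trial ids),
#'   `width`, `step`, `band`.
#' @export
bin_power <- function(tfr, trials, phase = "recognition", window = c(0, 2),
                      width = 0.2, step = 0.1, band = NULL, buffer_s = 1,
                      max_rt = 10) {
  stop_if_not(inherits(tfr, "tfr"), "tfr must come from morlet_tfr()")
  fs <- tfr$fs
  wn <- round(width * fs); sn <- round(step * fs)
  stop_if_not(abs(wn - width * fs) < 1e-9 && abs(sn - step * fs) < 1e-9,
              "width and step must be integer multiples of the sample period")
  rows <- trials[trials$phase == phase, , drop = FALSE]
  if (phase == "recognition" && "response_time_s" %in% names(rows)) {
    rows <- rows[is.na(rows$response_time_s) | rows$response_time_s <= max_rt, ,
                 drop = FALSE]
  }
  stop_if_not(nrow(rows) > 0, "no %s trials to bin", phase)
  n <- dim(tfr$power)[1]
  n_ch <- dim(tfr$power)[2]
  n_f <- dim(tfr$power)[3]
  n_bins <- floor((window[2] - window[1] - width) / step) + 1L
  stop_if_not(n_bins >= 1, "window too short for a single bin")
  starts <- window[1] + (seq_len(n_bins) - 1L) * step
  centers <- starts + width / 2

  keep <- rep(TRUE, nrow(rows))
  vals <- array(NA_real_, dim = c(nrow(rows), n_ch, n_f, n_bins))
  for (r in seq_len(nrow(rows))) {
    on <- rows$image_onset_s[r]
    ext <- rows$image_offset_s[r] - on
    i_lo <- floor((on + window[1] - buffer_s) * fs) + 1L
    i_hi <- ceiling((on + window[2] + buffer_s) * fs)
    if (i_lo < 1L || i_hi > n) { keep[r] <- FALSE; next }
    for (b in seq_len(n_bins)) {
      if (starts[b] + width > min(ext, window[2])) next  # beyond trial extent
      j0 <- floor((on + starts[b]) * fs) + 1L
      j1 <- j0 + wn - 1L
      seg <- tfr$power[j0:j1, , , drop = FALSE]
      vals[r, , , b] <- colMeans(seg, dims = 1)  # NA propagates
    }
  }
  skipped <- rows$trial_id[!keep]
  vals <- vals[keep, , , , drop = FALSE]
  rows <- rows[keep, , drop = FALSE]
  if (!is.null(band)) {
    bi <- band_members(tfr$freqs, band)
    stop_if_not(length(bi) > 0, "no wavelet centres inside the band")
    vals <- apply(vals[, , bi, , drop = FALSE], c(1, 2, 4), mean)
  }
  structure(list(values = vals, centers = centers, trials = rows,
                 skipped = skipped, width = width, step = step,
                 band = band, freqs = tfr$freqs,
                 channels = tfr$channels),
            class = "binned_power")
}

#' Bootstrap trial-count matching of two conditions
#'
#' When two conditions have unequal trial counts, repeatedly subsamples the
#' larger condition to the size of the smaller one (100 iterations by
#' default), averages each subsample, and uses the across-iteration average
#' as the larger condition's mean; the smaller condition's mean is the plain
#' trial average.
#'
#' @param x_a,x_b arrays with trials on the first dimension (matching
#'   trailing dimensions).
#' @param n_iter number of bootstrap iterations.
#' @param seed integer seed (reproducible subsampling).
#' @return list with `mean_a`, `mean_b` (trial dimension dropped), `n_a`,
#'   `n_b`, `n_matched`, `n_iter`.
#' @export
bootstrap_match <- function(x_a, x_b, n_iter = 100, seed = 1) {
  stop_if_not(n_iter >= 1, "n_iter must be at least 1")
  a <- if (is.null(dim(x_a))) matrix(x_a, ncol = 1) else
    matrix(x_a, nrow = dim(x_a)[1])
  b <- if (is.null(dim(x_b))) matrix(x_b, ncol = 1) else
    matrix(x_b, nrow = dim(x_b)[1])
  na <- nrow(a); nb <- nrow(b)
  stop_if_not(na > 0 && nb > 0, "both conditions must be non-empty")
  n_min <- min(na, nb)
  sub_mean <- function(m, n_target) {
    if (nrow(m) == n_target) return(colMeans(m, na.rm = TRUE))
    set.seed(seed)
    acc <- 0
    for (i in seq_len(n_iter)) {
      idx <- sample.int(nrow(m), n_target)
      acc <- acc + colMeans(m[idx, , drop = FALSE], na.rm = TRUE)
    }
    acc / n_iter
  }
  shape <- function(v, x) {
    d <- dim(x)
    if (is.null(d) || length(d) <= 2) return(as.numeric(v))
    array(v, dim = d[-1], dimnames = dimnames(x)[-1])
  }
  list(mean_a = shape(sub_mean(a, n_min), x_a),
       mean_b = shape(sub_mean(b, n_min), x_b),
       n_a = na, n_b = nb, n_matched = n_min, n_iter = n_iter)
}
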