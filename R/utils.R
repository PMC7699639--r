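# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Linear FFT convolution with a centered kernel
#'
#' Convolves `x` with kernel `k` and returns the "same"-length central part,
#' so that a symmetric kernel introduces no delay.
#'
#' @param x numeric vector.
#' @param k numeric or complex kernel, odd length preferred.
#' @return vector of `length(x)` (complex if `k` is complex).
#' @keywords internal
#' @noRd
fft_convolve_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nfft <- stats::nextn(n + m - 1L, 2L)
  y <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                  stats::fft(c(k, rep(0, nfft - m))), inverse = TRUE) / nfft
  off <- (m - 1L) %/% 2L
  y[(off + 1L):(off + n)]
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real numeric vector.
#' @return complex vector whose real part is `x` and whose argument is the
#'   instantaneous phase.
#' @export
analytic_signal <- function(x) {
  stop_if_not(is.numeric(x) && length(x) > 1, "analytic_signal() needs a numeric vector")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward filtering so band-limited phase/latency estimates are not
#' shifted by the filter delay.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param band length-2 numeric, passband edges (Hz).
#' @param order Butterworth design order (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, band, order = 4) {
  stop_if_not(length(band) == 2 && band[1] > 0 && band[2] > band[1] &&
                band[2] < fs / 2,
              "band must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Instantaneous phase of a band-limited signal
#'
#' Band-pass filters `x` (zero-phase) and returns the argument of its
#' analytic signal.
#'
#' @inheritParams bandpass_filter
#' @return phase in radians, in (-pi, pi].
#' @export
hilbert_phase <- function(x, fs, band, order = 4) {
  Arg(analytic_signal(bandpass_filter(x, fs, band, order = order)))
}

# Merge overlapping/adjacent integer index spans given as a 2-column matrix
# [start, end] (inclusive). Returns a matrix in the same form.
merge_spans <- function(spans) {
  if (nrow(spans) == 0) return(spans)
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) {
    for (i in 2:nrow(spans)) {
      if (spans[i, 1] <= out[nrow(out), 2] + 1L) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], spans[i, 2])
      } else {
        out <- rbind(out, spans[i, , drop = FALSE])
      }
    }
  }
  out
}

# Average a vector into consecutive non-overlapping bins of `bin` samples;
# trailing partial bin dropped.
bin_mean <- function(x, bin) {
  nb <- length(x) %/% bin
  if (nb == 0) return(numeric(0))
  colMeans(matrix(x[seq_len(nb * bin)], nrow = bin))
}
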