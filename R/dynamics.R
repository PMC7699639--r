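# Temporal characterisation of band-power time series: peak-time
# comparisons with region-label shuffles, instantaneous slope, onset
# estimation via local-minimum-to-peak line fits, and half-peak latency.

#' Region peak-time difference with region-label shuffles
#'
#' True statistic: the difference of the argmax times of the two regions'
#' across-participant mean time series. Null: independently swap the two
#' region labels within each participant and recompute; for n participants
#' this yields 2^n equally likely relabellings, enumerated exactly for
#' `n <= exact_n_max` and sampled `n_perm` times otherwise. Two-sided p
#' value: fraction of null |differences| at least as large as the true one.
#' A non-unique argmax resolves to the earliest peak.
#'
#' @param seriesA,seriesB participants x bins matrices (paired rows: one
#'   participant's series in each region).
#' @param centers bin centres (s).
#' @param n_perm permutation draws when not enumerating.
#' @param seed integer seed.
#' @param exact_n_max largest n enumerated exactly.
#' @return list with `true_diff_s`, `p_value`, `peakA_s`, `peakB_s`,
#'   `exact`, `n_perm`.
#' @export
peak_time_shuffle_test <- function(seriesA, seriesB, centers = NULL,
                                   n_perm = 1000, seed = 1, exact_n_max = 12) {
  stop_if_not(all(dim(seriesA) == dim(seriesB)),
              "region series must share dimensions")
  n <- nrow(seriesA)
  stop_if_not(n >= 2, "need at least 2 participants per region")
  if (is.null(centers)) centers <- seq_len(ncol(seriesA))
  peak_t <- function(v) centers[which.max(v)]  # earliest max on ties
  diff_for <- function(swap) {
    A <- seriesA; B <- seriesB
    A[swap, ] <- seriesB[swap, , drop = FALSE]
    B[swap, ] <- seriesA[swap, , drop = FALSE]
    peak_t(colMeans(A, na.rm = TRUE)) - peak_t(colMeans(B, na.rm = TRUE))
  }
  true_diff <- diff_for(rep(FALSE, n))
  exact <- n <= exact_n_max
  if (exact) {
    n_pat <- 2L^n
    null <- vapply(seq_len(n_pat), function(i) {
      diff_for(as.logical(as.integer(intToBits(i - 1L))[seq_len(n)]))
    }, numeric(1))
    p <- mean(abs(null) >= abs(true_diff) - 1e-12)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      diff_for(runif(n) < 0.5)
    }, numeric(1))
    p <- (1 + sum(abs(null) >= abs(true_diff) - 1e-12)) / (1 + n_perm)
  }
  list(true_diff_s = true_diff, p_value = p,
       peakA_s = peak_t(colMeans(seriesA, na.rm = TRUE)),
       peakB_s = peak_t(colMeans(seriesB, na.rm = TRUE)),
       exact = exact, n_perm = if (exact) 2L^n else n_perm)
}

#' Mean instantaneous slope over an early window
#'
#' Mean of adjacent-bin differences of a binned power series inside the
#' window (the first 500 ms after image presentation by default), in
#' z-units per bin. On a noiseless linear ramp this telescopes to the exact
#' slope.
#'
#' @param series numeric vector of binned power.
#' @param centers bin centres (s).
#' @param window time window (s).
#' @return mean adjacent-bin difference (z-units per bin).
#' @export
instantaneous_slope <- function(series, centers, window = c(0, 0.5)) {
  idx <- which(centers >= window[1] & centers <= window[2])
  stop_if_not(length(idx) >= 2, "window must contain at least 2 bins")
  mean(diff(series[idx]))
}

#' Onset of a condition-difference time series
#'
#' Finds the global peak of the series inside the analysis window, walks
#' back to the local minimum immediately preceding it (plateaus resolve to
#' their latest bin; absent a local minimum the window start is used and
#' flagged), fits a least-squares line through all bins between the minimum
#' and the peak, and reports the line's zero crossing as the onset,
#' clamped to not precede the local minimum the line was fit from (the
#' raw crossing is kept in `zero_crossing_s`).
#' Pre-stimulus crossings clamp to 0 with a flag. Also reports the
#' half-peak time: the first time (linear interpolation between bins) the
#' series reaches 50% of the peak value, at or after the local minimum.
#'
#' @param series numeric vector (condition-difference band power per bin).
#' @param centers bin centres (s).
#' @param window peak-search window (s).
#' @return list of class `onset_estimate`: `onset_s`, `zero_crossing_s`,
#'   `half_peak_s`,
#'   `peak_s`, `peak_value`, `local_min_s`, `slope`, `intercept`, `flags`
#'   (character vector).
#' @export
estimate_onset <- function(series, centers, window = c(0, 2)) {
  idx <- which(centers >= window[1] & centers <= window[2] & !is.na(series))
  stop_if_not(length(idx) >= 3, "too few bins inside the analysis window")
  flags <- character(0)
  pk_rel <- which.max(series[idx])
  pk <- idx[pk_rel]
  stop_if_not(series[pk] > 0, "series has no positive peak in the window")

  # local minimum immediately preceding the peak (strict neighbours;
  # plateaus resolve to the latest bin of the plateau)
  lm_i <- NA_integer_
  if (pk_rel > 1) {
    sub <- series[idx[1:pk_rel]]
    for (k in (pk_rel - 1):1) {
      left_ok <- k == 1 || sub[k - 1] >= sub[k]
      if (sub[k + 1] > sub[k] && left_ok) {
        if (k > 1 && sub[k - 1] == sub[k]) {
          # on a plateau: latest bin already selected by scanning backwards
        }
        lm_i <- idx[k]
        break
      }
    }
  }
  if (is.na(lm_i)) {
    lm_i <- idx[1]
    flags <- c(flags, "no_preceding_local_min")
  }

  seg <- lm_i:pk
  fit <- lm(y ~ x, data = data.frame(x = centers[seg], y = series[seg]))
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  crossing <- NA_real_
  if (!is.finite(a) || a <= 0) {
    onset <- NA_real_
    flags <- c(flags, "nonpositive_slope")
  } else {
    crossing <- -b / a
    # the onset cannot precede the local minimum the line was fit from: a
    # positive-valued minimum would otherwise extrapolate the crossing into
    # the flat baseline to its left; the raw crossing is kept alongside
    onset <- crossing
    if (onset < centers[lm_i]) {
      onset <- centers[lm_i]
      flags <- c(flags, "clamped_to_local_min")
    }
    if (onset < 0) { onset <- 0; flags <- c(flags, "clamped_to_zero") }
  }

  half <- 0.5 * series[pk]
  half_t <- NA_real_
  for (k in seg) {
    if (series[k] >= half) {
      if (k == seg[1] || k == 1) { half_t <- centers[k]; break }
      # linear interpolation between the previous bin and this one
      y0 <- series[k - 1]; y1 <- series[k]
      half_t <- centers[k - 1] + (half - y0) / (y1 - y0) *
        (centers[k] - centers[k - 1])
      break
    }
  }
  if (is.na(half_t)) half_t <- centers[pk]
  half_t <- max(half_t, centers[lm_i])

  structure(list(onset_s = onset, zero_crossing_s = crossing,
                 half_peak_s = half_t,
                 peak_s = centers[pk], peak_value = series[pk],
                 local_min_s = centers[lm_i],
                 slope = a, intercept = b, flags = flags),
            class = "onset_estimate")
}

#' First significant time per electrode, summarised per region
#'
#' For each electrode's trial-level cluster result, takes the centre of the
#' earliest bin inside any significant cluster; electrodes with no
#' significant cluster are excluded. First times are averaged within
#' participant, and two regions are compared across participants with an
#' unpaired t test.
#'
#' @param results list of entries, each with `participant`, `region` and
#'   `cluster` (a `cluster_result` over time bins).
#' @param centers bin centres (s).
#' @param alpha cluster-level significance threshold.
#' @return list with `electrode_times` (data frame), `participant_means`
#'   and `region_test` (function of two region names returning a t test).
#' @export
first_significant_time <- function(results, centers, alpha = 0.05) {
  rows <- lapply(results, function(e) {
    msk <- cluster_mask(e$cluster, alpha)
    if (!any(msk)) return(NULL)
    data.frame(participant = e$participant, region = e$region,
               first_s = centers[which(msk)[1]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  electrode_times <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(0), region = character(0),
               first_s = numeric(0))
  pm <- if (nrow(electrode_times)) {
    stats::aggregate(first_s ~ participant + region, electrode_times, mean)
  } else electrode_times
  region_test <- function(region_a, region_b) {
    a <- pm$first_s[pm$region == region_a]
    b <- pm$first_s[pm$region == region_b]
    stop_if_not(length(a) >= 2 && length(b) >= 2,
                "need at least 2 participants per region")
    t.test(a, b, var.equal = TRUE)
  }
  list(electrode_times = electrode_times, participant_means = pm,
       region_test = region_test)
}
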