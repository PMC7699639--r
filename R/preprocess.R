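# Referencing, signal conditioning, and two-tier artifact rejection.

#' Build a bipolar montage from channel metadata
#'
#' Pairs every two immediately adjacent contacts on each grid or strip
#' (horizontal and vertical neighbours; depth probes are treated as 1-D
#' strips ordered by `grid_col`). The virtual channel inherits the region
#' label shared by the pair; pairs straddling two regions take the anode's
#' label and are flagged in the `straddles` column. Contacts that end up in
#' no pair are reported in the `unpaired` attribute rather than failing.
#'
#' @param channels channel metadata data frame with `label`, `region`,
#'   `grid_id`, `grid_row`, `grid_col` (and optionally `x`, `y`, `z`).
#' @return data frame of class `bipolar_montage` with columns `anode`,
#'   `cathode` (channel indices), `label`, `region`, `grid_id`, `straddles`.
#' @export
build_bipolar <- function(channels) {
  stop_if_not(all(c("label", "region", "grid_id", "grid_row", "grid_col") %in%
                    names(channels)),
              "channel metadata needs label, region, grid_id, grid_row, grid_col")
  pairs <- list()
  for (g in unique(channels$grid_id)) {
    idx <- which(channels$grid_id == g)
    rw <- channels$grid_row[idx]; cl <- channels$grid_col[idx]
    for (i in seq_along(idx)) {
      # right neighbour and lower neighbour; each adjacency emitted once
      for (nb in list(c(rw[i], cl[i] + 1L), c(rw[i] + 1L, cl[i]))) {
        j <- which(rw == nb[1] & cl == nb[2])
        if (length(j) == 1) {
          pairs[[length(pairs) + 1L]] <- c(idx[i], idx[j])
        }
      }
    }
  }
  stop_if_not(length(pairs) > 0, "no adjacent contact pairs found")
  m <- do.call(rbind, pairs)
  anode <- m[, 1]; cathode <- m[, 2]
  montage <- data.frame(
    anode = anode, cathode = cathode,
    label = paste(channels$label[anode], channels$label[cathode], sep = "-"),
    region = channels$region[anode],
    grid_id = channels$grid_id[anode],
    straddles = channels$region[anode] != channels$region[cathode],
    stringsAsFactors = FALSE)
  unpaired <- setdiff(seq_len(nrow(channels)), unique(c(anode, cathode)))
  attr(montage, "unpaired") <- channels$label[unpaired]
  class(montage) <- c("bipolar_montage", "data.frame")
  montage
}

#' Apply a bipolar montage to a recording
#'
#' Each virtual trace is the sample-aligned difference anode minus cathode;
#' virtual channel coordinates are the pair midpoints when coordinates are
#' present.
#'
#' @param rec an `ieeg_recording`.
#' @param montage a [build_bipolar()] result.
#' @return an `ieeg_recording` of virtual channels.
#' @export
apply_bipolar <- function(rec, montage) {
  stop_if_not(inherits(rec, "ieeg_recording"), "rec must be an ieeg_recording")
  stop_if_not(max(montage$anode, montage$cathode) <= ncol(rec$traces),
              "montage references channels absent from the recording")
  traces <- rec$traces[, montage$anode, drop = FALSE] -
    rec$traces[, montage$cathode, drop = FALSE]
  meta <- data.frame(label = montage$label, region = montage$region,
                     grid_id = montage$grid_id,
                     grid_row = rec$channels$grid_row[montage$anode],
                     grid_col = rec$channels$grid_col[montage$anode],
                     is_depth = rec$channels$is_depth[montage$anode] %||% FALSE,
                     stringsAsFactors = FALSE)
  if (all(c("x", "y", "z") %in% names(rec$channels))) {
    meta$x <- (rec$channels$x[montage$anode] + rec$channels$x[montage$cathode]) / 2
    meta$y <- (rec$channels$y[montage$anode] + rec$channels$y[montage$cathode]) / 2
    meta$z <- (rec$channels$z[montage$anode] + rec$channels$z[montage$cathode]) / 2
  }
  new_recording(traces, rec$fs, meta, session_id = rec$session_id)
}

#' Re-reference to the global common average
#'
#' Subtracts the instantaneous mean across all channels from every channel.
#' Used before coherence estimation, which operates on original contacts
#' (bipolar referencing removes the low-frequency coherence of interest).
#'
#' @param rec an `ieeg_recording`.
#' @return an `ieeg_recording`.
#' @export
common_average_reference <- function(rec) {
  stop_if_not(inherits(rec, "ieeg_recording"), "rec must be an ieeg_recording")
  rec$traces <- rec$traces - rowMeans(rec$traces)
  rec
}

#' Resample to 1000 Hz and notch out line noise
#'
#' Accepts recordings at 1000 or 2000 Hz. 2000 Hz input is low-pass filtered
#' (zero phase) and decimated by two. A fourth-order Butterworth band-stop
#' (2 Hz wide, centred on `notch`) is then applied forward-backward, so no
#' event latency is shifted by filter delay.
#'
#' @param rec an `ieeg_recording` at 1000 or 2000 Hz.
#' @param notch line frequency to suppress (Hz); NULL skips the notch.
#' @param target_fs output rate (Hz), fixed at 1000.
#' @return conditioned `ieeg_recording` at `target_fs`.
#' @export
condition_signal <- function(rec, notch = 60, target_fs = 1000) {
  stop_if_not(inherits(rec, "ieeg_recording"), "rec must be an ieeg_recording")
  stop_if_not(rec$fs %in% c(1000, 2000),
              "condition_signal() accepts fs of 1000 or 2000 Hz, got %g", rec$fs)
  traces <- rec$traces
  fs <- rec$fs
  if (fs == 2000 && target_fs == 1000) {
    aa <- signal::butter(4, (0.8 * target_fs / 2) / (fs / 2), type = "low")
    traces <- apply(traces, 2, function(x) signal::filtfilt(aa, x))
    traces <- traces[seq(1, nrow(traces), by = 2L), , drop = FALSE]
    fs <- 1000
  }
  if (!is.null(notch)) {
    bs <- signal::butter(2, c(notch - 1, notch + 1) / (fs / 2), type = "stop")
    traces <- apply(traces, 2, function(x) signal::filtfilt(bs, x))
  }
  new_recording(traces, fs, rec$channels, session_id = rec$session_id)
}

#' Quartile-based outlier rejection
#'
#' Drops any value strictly above `Q3 + w * (Q3 - Q1)`, the screening rule
#' used for both trial-level and electrode-level rejection with an
#' empirically set weight of 2.3. Quartiles use linear interpolation
#' (`stats::quantile` type 7). With fewer than four values no rejection is
#' performed and a warning is raised. The rule applies to any screening
#' statistic: mean absolute voltage is the standard input, but per-trial
#' variance or kurtosis can be screened with the same form.
#'
#' @param values numeric vector of per-trial (or per-electrode) statistics,
#'   conventionally mean absolute voltage.
#' @param w IQR multiplier (default 2.3).
#' @return list of class `quartile_rejection`: `keep` (logical), `threshold`,
#'   `q1`, `q3`, `w`, `n_dropped`.
#' @export
reject_by_quartile <- function(values, w = 2.3) {
  stop_if_not(is.numeric(values), "values must be numeric")
  if (length(values) < 4) {
    warning("fewer than 4 values: quartiles undefined, nothing rejected")
    return(structure(list(keep = rep(TRUE, length(values)),
                          threshold = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          w = w, n_dropped = 0L),
                     class = "quartile_rejection"))
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- q[2] + w * (q[2] - q[1])
  keep <- !(values > thr)  # strict inequality: IQR 0 drops nothing
  structure(list(keep = keep, threshold = thr, q1 = q[1], q3 = q[2], w = w,
                 n_dropped = sum(!keep)),
            class = "quartile_rejection")
}

#' Two-tier quartile screening of trials then electrodes
#'
#' Computes the mean absolute voltage of each trial on each electrode,
#' screens trials on their across-electrode mean, then screens electrodes on
#' their session mean over the surviving trials, both with the same
#' quartile rule. Mean absolute voltage is the default statistic (a signed
#' mean of a zero-centred trace would make the rule vacuous); `stat =
#' "mean"` applies the rule to the signed mean instead.
#'
#' @param rec an `ieeg_recording`.
#' @param trials trial table.
#' @param w IQR multiplier.
#' @param stat "abs_mean" (default) or "mean".
#' @return list with `trial_keep` (named by trial_id), `electrode_keep`,
#'   `log` (data frame of decisions).
#' @export
reject_trials_electrodes <- function(rec, trials, w = 2.3,
                                     stat = c("abs_mean", "mean")) {
  stat <- match.arg(stat)
  fs <- rec$fs
  n <- nrow(rec$traces)
  per_te <- sapply(seq_len(nrow(trials)), function(r) {
    i0 <- max(1L, floor(trials$image_onset_s[r] * fs) + 1L)
    i1 <- min(n, ceiling(trials$image_offset_s[r] * fs))
    seg <- rec$traces[i0:i1, , drop = FALSE]
    if (stat == "abs_mean") colMeans(abs(seg)) else colMeans(seg)
  })  # channels x trials
  if (is.null(dim(per_te))) per_te <- matrix(per_te, nrow = 1L)
  trial_stat <- colMeans(per_te)
  qt_trial <- reject_by_quartile(trial_stat, w)
  elec_stat <- rowMeans(per_te[, qt_trial$keep, drop = FALSE])
  qt_elec <- reject_by_quartile(elec_stat, w)
  log <- rbind(
    data.frame(entity = paste0("trial_", trials$trial_id), rule = "quartile",
               statistic = trial_stat, threshold = qt_trial$threshold,
               decision = ifelse(qt_trial$keep, "keep", "drop")),
    data.frame(entity = rec$channels$label, rule = "quartile",
               statistic = elec_stat, threshold = qt_elec$threshold,
               decision = ifelse(qt_elec$keep, "keep", "drop")))
  list(trial_keep = stats::setNames(qt_trial$keep, trials$trial_id),
       electrode_keep = stats::setNames(qt_elec$keep, rec$channels$label),
       log = log)
}

#' Event-level artifact detection
#'
#' Marks every sample whose z-scored gradient (first difference) or z-scored
#' amplitude after a 250 Hz high-pass filter exceeds 5 in absolute value,
#' standardised over the whole trace, then extends each marked point by
#' 100 ms on both sides and merges overlapping spans. Catches sharp
#' transients and interictal discharges.
#'
#' @param trace numeric vector (one conditioned channel).
#' @param fs sampling rate (Hz).
#' @param z_thresh z-score threshold (default 5).
#' @param pad_s half-width of the mask around each detection (s).
#' @param hp_freq high-pass edge for the spike-band amplitude (Hz).
#' @return list of class `artifact_mask`: `mask` (logical per sample, TRUE =
#'   artifactual), `events` (data frame of merged spans in seconds),
#'   `n_events`, and the rule parameters.
#' @export
detect_artifact_events <- function(trace, fs, z_thresh = 5, pad_s = 0.1,
                                   hp_freq = 250) {
  stop_if_not(length(trace) >= 0.2 * fs,
              "trace shorter than 200 ms: cannot estimate artifact statistics")
  grad <- c(diff(trace), 0)
  zg <- (grad - mean(grad)) / sd(grad)
  hp <- signal::butter(4, hp_freq / (fs / 2), type = "high")
  # reflect-pad before filtering so filter start-up transients at the trace
  # boundaries are not themselves flagged as artifacts
  npad <- round(0.5 * fs)
  padded <- c(rev(trace[seq_len(npad)]), trace,
              rev(trace[(length(trace) - npad + 1L):length(trace)]))
  hf <- as.numeric(signal::filtfilt(hp, padded))[(npad + 1L):(npad + length(trace))]
  zh <- (hf - mean(hf)) / sd(hf)
  hits <- which(abs(zg) > z_thresh | abs(zh) > z_thresh)
  n <- length(trace)
  mask <- rep(FALSE, n)
  events <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(hits)) {
    pad <- round(pad_s * fs)
    spans <- cbind(pmax(1L, hits - pad), pmin(n, hits + pad))
    spans <- merge_spans(spans)
    for (i in seq_len(nrow(spans))) mask[spans[i, 1]:spans[i, 2]] <- TRUE
    events <- data.frame(start_s = (spans[, 1] - 1L) / fs,
                         end_s = (spans[, 2] - 1L) / fs)
  }
  structure(list(mask = mask, events = events, n_events = nrow(events),
                 z_thresh = z_thresh, pad_s = pad_s, hp_freq = hp_freq),
            class = "artifact_mask")
}
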