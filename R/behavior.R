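# Gaze fixation detection, critical-region scoring, and behavioural
# summaries including Cowan's K.

#' Dispersion-based fixation detection (I-DT)
#'
#' Grows a window of consecutive gaze samples while its spatial dispersion
#' stays within `dispersion_deg`, and emits a fixation when the window
#' spans at least `min_dur_s` (gaze continually within 2 degrees for >= 100
#' ms under the defaults). The dispersion metric is the maximum pairwise
#' Euclidean distance by default; `metric = "bbox"` uses the bounding-box
#' diagonal extent `(max x - min x) + (max y - min y)` instead. Sampling
#' gaps longer than two sample periods split the window.
#'
#' @param gaze data frame with `t_s`, `x_deg`, `y_deg`, time-ordered.
#' @param dispersion_deg dispersion threshold (deg).
#' @param min_dur_s minimum fixation duration (s).
#' @param metric "pairwise" or "bbox".
#' @return data frame of class `fixation_set`: `onset_s`, `offset_s`,
#'   `x_deg`, `y_deg` (centroid), `dispersion_deg`, `n_samples`.
#' @export
detect_fixations <- function(gaze, dispersion_deg = 2, min_dur_s = 0.1,
                             metric = c("pairwise", "bbox")) {
  metric <- match.arg(metric)
  stop_if_not(all(c("t_s", "x_deg", "y_deg") %in% names(gaze)),
              "gaze needs t_s, x_deg, y_deg columns")
  stop_if_not(!is.unsorted(gaze$t_s), "gaze samples must be time-ordered")
  t <- gaze$t_s; x <- gaze$x_deg; y <- gaze$y_deg
  n <- length(t)
  dt_med <- median(diff(t))
  gap_thr <- 2.5 * dt_med

  disp <- function(i0, i1) {
    xs <- x[i0:i1]; ys <- y[i0:i1]
    if (metric == "bbox") {
      (max(xs) - min(xs)) + (max(ys) - min(ys))
    } else {
      max(stats::dist(cbind(xs, ys)))
    }
  }

  fix <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    # extend while dispersion holds and sampling is contiguous
    while (j < n && t[j + 1] - t[j] <= gap_thr) {
      if (disp(i, j + 1) > dispersion_deg) break
      j <- j + 1L
    }
    if (t[j] - t[i] + dt_med >= min_dur_s) {
      fix[[length(fix) + 1L]] <- data.frame(
        onset_s = t[i], offset_s = t[j],
        x_deg = mean(x[i:j]), y_deg = mean(y[i:j]),
        dispersion_deg = if (j > i) disp(i, j) else 0,
        n_samples = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- if (length(fix)) do.call(rbind, fix) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               x_deg = numeric(0), y_deg = numeric(0),
               dispersion_deg = numeric(0), n_samples = integer(0))
  class(out) <- c("fixation_set", "data.frame")
  out
}

in_rect <- function(x, y, rect) {
  x >= rect$x0 & x <= rect$x1 & y >= rect$y0 & y <= rect$y1
}

#' Critical-region gaze and click metrics
#'
#' Scores each recognition trial against its critical-region rectangle:
#' whether at least one fixation fell inside, the fraction of total
#' fixation time spent inside (0 when there are no fixations, not
#' missing), and whether the localisation click fell inside. Trials
#' without a rectangle are excluded with a log attribute. Metrics are
#' aggregated per condition and correctness.
#'
#' @param fixations a [detect_fixations()] result.
#' @param regions data frame `image_id`, `x0`, `y0`, `x1`, `y1`.
#' @param trials trial table (recognition rows are scored).
#' @param clicks optional data frame `trial_id`, `x_deg`, `y_deg`.
#' @return list with `per_trial` (data frame) and `by_condition` (data
#'   frame with `p_fixation_in`, `time_fraction_in`, `p_click_in`).
#' @export
critical_region_metrics <- function(fixations, regions, trials, clicks = NULL) {
  rec <- trials[trials$phase == "recognition", , drop = FALSE]
  excluded <- integer(0)
  rows <- list()
  for (r in seq_len(nrow(rec))) {
    rect <- regions[regions$image_id == rec$image_id[r], , drop = FALSE]
    if (nrow(rect) != 1) { excluded <- c(excluded, rec$trial_id[r]); next }
    fx <- fixations[fixations$onset_s >= rec$image_onset_s[r] &
                      fixations$onset_s < rec$image_offset_s[r], , drop = FALSE]
    if (nrow(fx)) {
      inside <- in_rect(fx$x_deg, fx$y_deg, rect)
      dur <- fx$offset_s - fx$onset_s
      p_in <- any(inside)
      tf <- if (sum(dur) > 0) sum(dur[inside]) / sum(dur) else 0
    } else {
      p_in <- FALSE; tf <- 0
    }
    click_in <- NA
    if (!is.null(clicks)) {
      ck <- clicks[clicks$trial_id == rec$trial_id[r], , drop = FALSE]
      if (nrow(ck) == 1) click_in <- in_rect(ck$x_deg, ck$y_deg, rect)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = rec$trial_id[r], condition = rec$condition[r],
      correct = rec$correct[r], fixation_in = p_in, time_fraction = tf,
      click_in = click_in)
  }
  per_trial <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = integer(0), condition = character(0),
               correct = logical(0), fixation_in = logical(0),
               time_fraction = numeric(0), click_in = logical(0))
  by_condition <- if (nrow(per_trial)) {
    agg <- stats::aggregate(cbind(fixation_in, time_fraction) ~ condition + correct,
                            per_trial, mean)
    names(agg)[names(agg) == "fixation_in"] <- "p_fixation_in"
    names(agg)[names(agg) == "time_fraction"] <- "time_fraction_in"
    if (any(!is.na(per_trial$click_in))) {
      ck <- stats::aggregate(click_in ~ condition + correct, per_trial, mean,
                             na.action = stats::na.omit)
      names(ck)[3] <- "p_click_in"
      agg <- merge(agg, ck, all.x = TRUE)
    } else agg$p_click_in <- NA_real_
    agg
  } else NULL
  out <- list(per_trial = per_trial, by_condition = by_condition)
  attr(out, "excluded_trials") <- excluded
  out
}

#' Cowan's K working-memory capacity estimate
#'
#' `K = (HitRate + CorrectRejectionRate - 1) * N`, where `N` is the memory
#' set size (a four-image list holds roughly 8-20 items at 2-5 items per
#' image). A hit is correct recognition of a manipulated image; a correct
#' rejection is correct recognition of a repeated image. Negative estimates
#' are returned as-is with a flag.
#'
#' @param hit_rate,correct_rejection_rate rates in `[0, 1]`.
#' @param set_size_n memory set size N (> 0).
#' @return numeric K with attribute `flag = "negative"` when below zero.
#' @export
cowans_k <- function(hit_rate, correct_rejection_rate, set_size_n) {
  stop_if_not(all(set_size_n > 0), "set size N must be positive")
  stop_if_not(all(hit_rate >= 0 & hit_rate <= 1) &&
                all(correct_rejection_rate >= 0 & correct_rejection_rate <= 1),
              "rates must lie in [0, 1]")
  k <- (hit_rate + correct_rejection_rate - 1) * set_size_n
  if (any(k < 0)) attr(k, "flag") <- "negative"
  k
}

#' Behavioural summary of a session
#'
#' Recognition probability and mean response times per condition, plus
#' Cowan's K computed from the observed hit rate (mean of the added and
#' removed correct-recognition rates) and correct rejection rate (repeated
#' condition), at the given set sizes.
#'
#' @param trials trial table.
#' @param set_sizes memory set sizes at which to evaluate K.
#' @param hit_rate_pooling "mean" (average of added and removed rates,
#'   default) or "pooled" (trial-weighted).
#' @param max_rt responses slower than this are excluded (s).
#' @return list with `by_condition` data frame, `hit_rate`,
#'   `correct_rejection_rate` and `cowans_k` (named by set size).
#' @export
summarize_behavior <- function(trials, set_sizes = c(8, 20),
                               hit_rate_pooling = c("mean", "pooled"),
                               max_rt = 10) {
  hit_rate_pooling <- match.arg(hit_rate_pooling)
  rec <- trials[trials$phase == "recognition", , drop = FALSE]
  rec <- rec[is.na(rec$response_time_s) | rec$response_time_s <= max_rt, ,
             drop = FALSE]
  stop_if_not(nrow(rec) > 0, "no recognition trials")
  by_condition <- stats::aggregate(
    cbind(p_correct = correct, rt = response_time_s) ~ condition, rec, mean)
  rate <- function(cond) {
    sub <- rec[rec$condition %in% cond, ]
    if (!nrow(sub)) return(NA_real_)
    mean(sub$correct)
  }
  hr <- if (hit_rate_pooling == "mean") {
    mean(c(rate("added"), rate("removed")), na.rm = TRUE)
  } else rate(c("added", "removed"))
  cr <- rate("repeated")
  k <- vapply(set_sizes, function(n) as.numeric(cowans_k(hr, cr, n)), numeric(1))
  list(by_condition = by_condition, hit_rate = hr,
       correct_rejection_rate = cr,
       cowans_k = stats::setNames(k, paste0("N", set_sizes)))
}
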