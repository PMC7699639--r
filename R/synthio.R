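# Synthetic session generator with known ground truth.
#
# The generator emulates the structure of a visuospatial recognition task:
# lists of four natural-scene images are encoded (5 s each, 1 s fixation
# cross) and then tested in the same order, with 28/36/36% of test images
# repeated / item-added / item-removed. Neural structure is injected on top
# of a 1/f background: a high-gamma burst with image-specific per-channel
# gains that recurs between encoding and recognition (the substrate of
# reinstatement), an excess burst on correctly recognised manipulated trials
# with region-specific onsets, a fixed envelope lag of the MTL relative to
# cortical regions, and phase-lagged alpha coupling between PT and MTL.

REGIONS <- c("LOC", "PAR", "PT", "MTL", "OTHER")

#' Configuration for the synthetic session generator
#'
#' Defaults follow the recognition-memory task design: four-image lists,
#' 5 s encoding presentations preceded by a 1 s fixation cross, test images
#' repeated / added / removed in 28/36/36% proportions with per-condition
#' accuracy of 88/65/68%, and signals sampled at 1000 Hz. Injected effects
#' default to a 40 ms PT-to-MTL envelope lag and condition-difference onsets
#' of 250/295/270/480 ms in LOC/PAR/PT/MTL. Artifact injections (60 Hz line
#' noise, spike transients, outlier trials) default to off.
#'
#' @param fs sampling rate (Hz).
#' @param n_lists number of four-image lists in the session.
#' @param images_per_list images per list (the task uses 4).
#' @param n_channels named integer vector of channels per region.
#' @param background_sd standard deviation of the 1/f background (uV).
#' @param pink_slope exponent of the 1/f^slope background power spectrum.
#' @param line_amp amplitude of 60 Hz line noise (uV); 0 disables.
#' @param encoding_dur,fix_dur encoding image and fixation durations (s).
#' @param rt_mean,rt_sd,rt_min recognition response-time distribution (s).
#' @param p_condition condition proportions (repeated/added/removed).
#' @param p_correct per-condition probability of a correct response.
#' @param burst_amp carrier amplitude of the image-evoked high-gamma burst (uV).
#' @param burst_onset,burst_dur onset and duration of the burst envelope (s,
#'   relative to image onset).
#' @param env_mod depth of the trial-specific low-frequency modulation of
#'   the burst envelope (0 disables). The modulation series is shared by
#'   all channels of a trial and time-shifted by `lag_ms` in the MTL, so it
#'   carries the trial-specific envelope coupling that cross-correlograms
#'   measure over and above the stimulus-locked response.
#' @param env_bw bandwidth of the envelope modulation (Hz, low-pass edge).
#' @param carrier_freq carrier frequency of injected bursts (Hz).
#' @param gain_sd log-scale SD of the per-image, per-channel spatial gains.
#' @param pattern_noise log-scale SD of trial-to-trial multiplicative jitter
#'   on the spatial pattern (inter-trial variability of the reinstated
#'   pattern is not characterised empirically, so it is exposed as a knob).
#' @param lag_ms envelope delay of MTL channels relative to other regions (ms).
#' @param effect_amp carrier amplitude of the excess burst on correctly
#'   recognised manipulated trials (uV).
#' @param effect_onsets named vector of condition-difference onsets per
#'   region (s after image onset).
#' @param effect_dur duration of the excess burst envelope (s).
#' @param alpha_amp amplitude of injected alpha coupling (uV); 0 disables.
#' @param alpha_freq alpha frequency (Hz).
#' @param alpha_phase_lag phase of MTL alpha relative to PT (radians).
#' @param alpha_window time window of alpha coupling (s after image onset).
#' @param spike_rate rate of biphasic spike transients per channel (Hz);
#'   0 disables.
#' @param spike_amp_sds spike amplitude in multiples of `background_sd`.
#' @param spike_dur spike transient duration (s).
#' @param outlier_frac fraction of trials amplified into outliers; 0 disables.
#' @param outlier_gain multiplicative gain applied to outlier trials.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(fs = 1000,
                       n_lists = 12,
                       images_per_list = 4,
                       n_channels = c(LOC = 2, PAR = 4, PT = 6, MTL = 4),
                       background_sd = 10,
                       pink_slope = 1,
                       line_amp = 0,
                       encoding_dur = 5,
                       fix_dur = 1,
                       rt_mean = 2.5,
                       rt_sd = 0.4,
                       rt_min = 1.2,
                       p_condition = c(repeated = 0.28, added = 0.36, removed = 0.36),
                       p_correct = c(repeated = 0.88, added = 0.65, removed = 0.68),
                       burst_amp = 6,
                       burst_onset = 0.05,
                       burst_dur = 1.0,
                       env_mod = 0.5,
                       env_bw = 8,
                       carrier_freq = 100,
                       gain_sd = 0.5,
                       pattern_noise = 0.2,
                       lag_ms = 40,
                       effect_amp = 6,
                       effect_onsets = c(LOC = 0.25, PAR = 0.295, PT = 0.27, MTL = 0.48),
                       effect_dur = 0.6,
                       alpha_amp = 4,
                       alpha_freq = 10,
                       alpha_phase_lag = pi / 4,
                       alpha_window = c(0.3, 1.8),
                       spike_rate = 0,
                       spike_amp_sds = 8,
                       spike_dur = 0.02,
                       outlier_frac = 0,
                       outlier_gain = 5) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$n_lists >= 1 && cfg$images_per_list >= 1,
              "config would generate zero trials")
  max_f <- max(cfg$carrier_freq,
               if (cfg$line_amp > 0) 60 else 0,
               if (cfg$alpha_amp > 0) cfg$alpha_freq else 0)
  stop_if_not(cfg$fs >= 2 * max_f,
              "fs = %g is below twice the maximum synthesis frequency (%g Hz)",
              cfg$fs, max_f)
  amps <- c(cfg$burst_amp, cfg$effect_amp, cfg$alpha_amp, cfg$line_amp,
            cfg$background_sd, cfg$spike_rate, cfg$outlier_frac)
  stop_if_not(all(amps >= 0), "effect sizes and amplitudes must be non-negative")
  invisible(cfg)
}

#' 1/f ("pink") noise
#'
#' Spectral-synthesis noise with amplitude spectrum proportional to
#' `f^(-slope/2)` (power `1/f^slope`), unit standard deviation.
#'
#' @param n number of samples.
#' @param slope spectral exponent of the power spectrum.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, slope = 1) {
  stop_if_not(n >= 4, "pink_noise() needs n >= 4")
  n_out <- n
  n <- stats::nextn(n, c(2L, 3L, 5L))  # 5-smooth FFT length, then truncate
  nf <- (n - 1L) %/% 2L
  amp <- seq_len(nf)^(-slope / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n), imaginary = numeric(n))
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 1L)] <- Conj(spec)
  if (n %% 2 == 0) full[n / 2 + 1L] <- (nf + 1)^(-slope / 2)
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n_out)]
  x / sd(x)
}

# Raised-sine burst envelope: sin(pi * s)^2 on [t0, t0 + dur), zero outside.
burst_envelope <- function(t, t0, dur) {
  s <- (t - t0) / dur
  e <- numeric(length(t))
  ok <- s >= 0 & s < 1
  e[ok] <- sin(pi * s[ok])^2
  e
}

make_channel_meta <- function(n_channels) {
  n_channels <- n_channels[n_channels > 0]
  meta <- do.call(rbind, lapply(names(n_channels), function(rg) {
    n <- n_channels[[rg]]
    data.frame(label = sprintf("%s%d", rg, seq_len(n)),
               region = rg,
               grid_id = paste0("strip_", rg),
               grid_row = 1L,
               grid_col = seq_len(n),
               is_depth = rg == "MTL",
               x = stats::runif(n, -60, 60),
               y = stats::runif(n, -80, 40),
               z = stats::runif(n, -30, 60),
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  meta
}

assign_conditions <- function(n_images, p_condition) {
  # largest-remainder apportionment keeps the session composition at the
  # configured proportions exactly (up to integer rounding)
  p <- p_condition / sum(p_condition)
  raw <- n_images * p
  counts <- floor(raw)
  rem <- n_images - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1L
  }
  sample(rep(names(p), times = counts))
}

build_trial_table <- function(cfg) {
  n_images <- cfg$n_lists * cfg$images_per_list
  condition <- assign_conditions(n_images, cfg$p_condition)
  correct <- rbinom(n_images, 1, cfg$p_correct[condition]) == 1
  rt <- pmax(cfg$rt_min, rnorm(n_images, cfg$rt_mean, cfg$rt_sd))

  rows <- vector("list", 2L * n_images)
  t_cur <- 2.0  # lead-in
  k <- 0L
  trial_id <- 0L
  for (l in seq_len(cfg$n_lists)) {
    imgs <- ((l - 1L) * cfg$images_per_list + 1L):(l * cfg$images_per_list)
    for (i in imgs) {
      t_cur <- t_cur + cfg$fix_dur
      trial_id <- trial_id + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(trial_id = trial_id, list_id = l, image_id = i,
                              phase = "encoding", condition = condition[i],
                              correct = NA,
                              image_onset_s = t_cur,
                              image_offset_s = t_cur + cfg$encoding_dur,
                              response_time_s = NA_real_)
      t_cur <- t_cur + cfg$encoding_dur
    }
    for (i in imgs) {
      t_cur <- t_cur + cfg$fix_dur
      trial_id <- trial_id + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(trial_id = trial_id, list_id = l, image_id = i,
                              phase = "recognition", condition = condition[i],
                              correct = correct[i],
                              image_onset_s = t_cur,
                              image_offset_s = t_cur + rt[i],
                              response_time_s = rt[i])
      t_cur <- t_cur + rt[i] + 0.5
    }
    t_cur <- t_cur + 1.0  # inter-list pause
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  trials
}

#' Generate a synthetic iEEG session with known ground truth
#'
#' Builds a trial table for one session of the recognition task and
#' synthesises multichannel voltage traces: 1/f background, optional 60 Hz
#' line noise, an image-evoked high-gamma burst whose per-channel amplitude
#' follows an image-specific spatial gain pattern shared between encoding
#' and recognition, an excess burst on correctly recognised manipulated
#' trials with region-specific onsets, an MTL envelope delayed by
#' `lag_ms`, alpha-band PT-MTL coupling on manipulated-correct trials, and
#' optional spike transients and outlier trials. All injections are
#' recorded in the returned ground truth.
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @return list with elements `recording` (class `ieeg_recording`: `traces`
#'   samples x channels matrix in uV, `fs`, `channels` metadata data frame,
#'   `session_id`), `trials` (trial table data frame) and `truth` (class
#'   `sim_ground_truth`).
#' @export
generate_recording <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  cfg <- config
  set.seed(seed)

  meta <- make_channel_meta(cfg$n_channels)
  trials <- build_trial_table(cfg)
  n_ch <- nrow(meta)
  n_images <- cfg$n_lists * cfg$images_per_list
  dur <- max(trials$image_offset_s) + 2.0
  n <- ceiling(dur * cfg$fs)
  tvec <- (seq_len(n) - 1L) / cfg$fs

  # image-specific spatial gains, shared between encoding and recognition
  gains <- matrix(exp(rnorm(n_ch * n_images, -cfg$gain_sd^2 / 2, cfg$gain_sd)),
                  nrow = n_ch, ncol = n_images)

  rec_rows <- trials[trials$phase == "recognition", ]
  effect_trials <- rec_rows$trial_id[rec_rows$condition != "repeated" &
                                       rec_rows$correct %in% TRUE]
  alpha_trials <- if (cfg$alpha_amp > 0) effect_trials else integer(0)
  out_pool <- trials$trial_id
  outlier_trials <- if (cfg$outlier_frac > 0) {
    sort(sample(out_pool, max(1L, round(cfg$outlier_frac * length(out_pool)))))
  } else integer(0)

  traces <- matrix(0, nrow = n, ncol = n_ch)
  spike_times <- vector("list", n_ch)
  pat_jit <- matrix(exp(rnorm(nrow(trials) * n_ch,
                              -cfg$pattern_noise^2 / 2, cfg$pattern_noise)),
                    nrow = nrow(trials), ncol = n_ch)
  alpha_ph <- runif(nrow(trials), 0, 2 * pi)  # shared by PT and MTL per trial

  # trial-specific envelope modulation, shared across channels (the MTL
  # reads it through the same series shifted by lag_ms)
  nb <- round(cfg$burst_dur * cfg$fs)
  env_lp <- if (cfg$env_mod > 0) signal::butter(2, min(0.99, cfg$env_bw / (cfg$fs / 2)),
                                                type = "low") else NULL
  env_f <- lapply(seq_len(nrow(trials)), function(r) {
    if (cfg$env_mod == 0) return(NULL)
    f <- as.numeric(signal::filtfilt(env_lp, rnorm(nb + 2L * round(cfg$fs * 0.2))))
    f <- f[(round(cfg$fs * 0.2) + 1L):(round(cfg$fs * 0.2) + nb)]
    f / max(sd(f), 1e-12)
  })

  # index range of samples with t0 <= t < t1 (0-based time, 1-based index)
  span_idx <- function(t0, t1) {
    i0 <- max(1L, ceiling(t0 * cfg$fs - 1e-9) + 1L)
    i1 <- min(n, ceiling(t1 * cfg$fs - 1e-9))
    if (i0 > i1) integer(0) else i0:i1
  }

  for (ch in seq_len(n_ch)) {
    rg <- meta$region[ch]
    x <- pink_noise(n, cfg$pink_slope) * cfg$background_sd
    if (cfg$line_amp > 0)
      x <- x + cfg$line_amp * sin(2 * pi * 60 * tvec + runif(1, 0, 2 * pi))

    lag_s <- if (rg == "MTL") cfg$lag_ms / 1000 else 0
    for (r in seq_len(nrow(trials))) {
      on <- trials$image_onset_s[r]
      img <- trials$image_id[r]
      t0 <- on + cfg$burst_onset + lag_s
      idx <- span_idx(t0, t0 + cfg$burst_dur)
      if (length(idx)) {
        amp <- cfg$burst_amp * gains[ch, img] * pat_jit[r, ch]
        env <- burst_envelope(tvec[idx], t0, cfg$burst_dur)
        if (cfg$env_mod > 0) {
          fi <- pmin(nb, pmax(1L, round((tvec[idx] - t0) * cfg$fs) + 1L))
          env <- env * pmax(0, 1 + cfg$env_mod * env_f[[r]][fi])
        }
        x[idx] <- x[idx] + amp * env *
          sin(2 * pi * cfg$carrier_freq * (tvec[idx] - t0) + runif(1, 0, 2 * pi))
      }
      if (trials$trial_id[r] %in% effect_trials && cfg$effect_amp > 0 &&
            rg %in% names(cfg$effect_onsets)) {
        t0e <- on + cfg$effect_onsets[[rg]]
        idx <- span_idx(t0e, t0e + cfg$effect_dur)
        if (length(idx)) {
          env <- burst_envelope(tvec[idx], t0e, cfg$effect_dur)
          x[idx] <- x[idx] + cfg$effect_amp * env *
            sin(2 * pi * cfg$carrier_freq * (tvec[idx] - t0e) + runif(1, 0, 2 * pi))
        }
      }
      if (trials$trial_id[r] %in% alpha_trials && rg %in% c("PT", "MTL")) {
        aw <- cfg$alpha_window
        idx <- span_idx(on + aw[1], on + aw[2])
        if (length(idx)) {
          ph <- if (rg == "MTL") alpha_ph[r] - cfg$alpha_phase_lag else alpha_ph[r]
          taper <- burst_envelope(tvec[idx], on + aw[1], aw[2] - aw[1])
          x[idx] <- x[idx] + cfg$alpha_amp * taper *
            sin(2 * pi * cfg$alpha_freq * (tvec[idx] - on) + ph)
        }
      }
    }

    if (cfg$spike_rate > 0) {
      nsp <- rpois(1, cfg$spike_rate * dur)
      st <- sort(runif(nsp, 1, dur - 1))
      spike_times[[ch]] <- st
      # biphasic transient with a sharp (~2 ms) leading edge, as in
      # interictal discharges: fast rise to +A, overshoot to -A, recovery
      for (s0 in st) {
        idx <- span_idx(s0, s0 + cfg$spike_dur)
        A <- cfg$spike_amp_sds * cfg$background_sd
        frac <- (tvec[idx] - s0) / cfg$spike_dur
        shape <- approx(x = c(0, 0.1, 0.4, 1), y = c(0, 1, -1, 0),
                        xout = frac, rule = 2)$y
        x[idx] <- x[idx] + A * shape
      }
    } else {
      spike_times[[ch]] <- numeric(0)
    }
    traces[, ch] <- x
  }

  for (tid in outlier_trials) {
    r <- which(trials$trial_id == tid)
    idx <- span_idx(trials$image_onset_s[r], trials$image_offset_s[r])
    traces[idx, ] <- traces[idx, ] * cfg$outlier_gain
  }

  recording <- new_recording(traces, cfg$fs, meta,
                             session_id = sprintf("sim_seed%d", seed))
  truth <- structure(list(seed = seed,
                          config = cfg,
                          gains = gains,
                          lag_ms = cfg$lag_ms,
                          effect = list(amp = cfg$effect_amp,
                                        onsets = cfg$effect_onsets,
                                        dur = cfg$effect_dur,
                                        trials = effect_trials),
                          alpha = list(amp = cfg$alpha_amp,
                                       freq = cfg$alpha_freq,
                                       phase_lag = cfg$alpha_phase_lag,
                                       window = cfg$alpha_window,
                                       trials = alpha_trials),
                          spike_times = spike_times,
                          outlier_trials = outlier_trials,
                          background = list(sd = cfg$background_sd,
                                            slope = cfg$pink_slope)),
                     class = "sim_ground_truth")
  list(recording = recording, trials = trials, truth = truth)
}

#' Construct an iEEG recording object
#'
#' @param traces samples x channels numeric matrix (uV); sample `k` (1-based)
#'   occurs at time `(k - 1) / fs` seconds.
#' @param fs sampling rate (Hz), shared by all channels.
#' @param channels per-channel metadata data frame with at least `label` and
#'   `region` columns.
#' @param session_id character scalar.
#' @return object of class `ieeg_recording`.
#' @export
new_recording <- function(traces, fs, channels, session_id = "session") {
  stop_if_not(is.matrix(traces), "traces must be a samples x channels matrix")
  stop_if_not(ncol(traces) == nrow(channels),
              "channel metadata rows (%d) must match trace columns (%d)",
              nrow(channels), ncol(traces))
  stop_if_not(all(c("label", "region") %in% names(channels)),
              "channel metadata needs label and region columns")
  stop_if_not(all(channels$region %in% REGIONS),
              "channel regions must be one of %s", paste(REGIONS, collapse = ", "))
  structure(list(traces = traces, fs = fs, channels = channels,
                 session_id = session_id),
            class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$session_id, ncol(x$traces), nrow(x$traces), x$fs,
              nrow(x$traces) / x$fs))
  print(table(x$channels$region))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gaze generation

#' Configuration for the synthetic gaze generator
#'
#' @param sample_rate gaze sampling rate (Hz); the eye tracker samples at 120.
#' @param screen_deg half-extents of the screen (x, y) in degrees of visual
#'   angle; gaze and critical regions live in `[-x, x] x [-y, y]`.
#' @param rect_deg width and height of critical-region rectangles (deg).
#' @param jitter_sd within-dwell positional jitter SD (deg).
#' @param dwell_range min and max dwell duration (s).
#' @param n_dwell_range min and max number of dwells per recognition trial.
#' @param p_in per-condition probability that a dwell lands inside the
#'   critical region; defaults mirror observed fixation rates (added items
#'   attract gaze, removed-item regions much less, repeated images at a
#'   baseline level).
#' @param dwell_plan optional data frame (`trial_id`, `dur_s`, `inside`,
#'   optionally `x`, `y`) that overrides random dwell placement.
#' @return list of class `gaze_config`.
#' @export
gaze_config <- function(sample_rate = 120,
                        screen_deg = c(16, 12),
                        rect_deg = c(4, 3),
                        jitter_sd = 0.15,
                        dwell_range = c(0.15, 0.40),
                        n_dwell_range = c(3, 6),
                        p_in = c(added = 0.80, removed = 0.35, repeated = 0.20),
                        dwell_plan = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "gaze_config"
  cfg
}

#' Generate a synthetic gaze stream for recognition trials
#'
#' Produces a continuous 120 Hz gaze stream covering the session: random
#' scanning between trials and piecewise-stationary dwells (with sub-degree
#' jitter) during recognition trials. Each recognition image receives a
#' critical-region rectangle; dwells land inside it with a per-condition
#' probability. All dwells are recorded as ground truth.
#'
#' @param trials trial table from [generate_recording()].
#' @param config a [gaze_config()].
#' @param seed integer seed.
#' @return list with `gaze` (data frame `t_s`, `x_deg`, `y_deg`), `regions`
#'   (data frame `image_id`, `x0`, `y0`, `x1`, `y1`) and `truth` (data frame
#'   of injected dwells).
#' @export
generate_gaze <- function(trials, config = gaze_config(), seed = 1) {
  cfg <- config
  set.seed(seed)
  sx <- cfg$screen_deg[1]; sy <- cfg$screen_deg[2]
  rw <- cfg$rect_deg[1];  rh <- cfg$rect_deg[2]
  stop_if_not(rw <= 2 * sx && rh <= 2 * sy,
              "critical-region rectangle exceeds the screen extent")

  rec <- trials[trials$phase == "recognition", ]
  stop_if_not(nrow(rec) > 0, "trial table contains no recognition trials")

  # one rectangle per recognition image (repeated images get a random one)
  cx <- runif(nrow(rec), -sx + rw / 2, sx - rw / 2)
  cy <- runif(nrow(rec), -sy + rh / 2, sy - rh / 2)
  regions <- data.frame(image_id = rec$image_id,
                        x0 = cx - rw / 2, y0 = cy - rh / 2,
                        x1 = cx + rw / 2, y1 = cy + rh / 2)

  dt <- 1 / cfg$sample_rate
  t_end <- max(trials$image_offset_s) + 1
  t_s <- seq(0, t_end, by = dt)
  # background scanning: a fresh point every ~80 ms, each at least 5 deg
  # from the previous one, so no spurious fixations form outside planned
  # dwells
  hop <- max(1L, round(0.08 / dt))
  n_hop <- ceiling(length(t_s) / hop)
  hx <- numeric(n_hop); hy <- numeric(n_hop)
  hx[1] <- runif(1, -sx, sx); hy[1] <- runif(1, -sy, sy)
  for (k in 2:n_hop) {
    repeat {
      hx[k] <- runif(1, -sx, sx); hy[k] <- runif(1, -sy, sy)
      if ((hx[k] - hx[k - 1])^2 + (hy[k] - hy[k - 1])^2 > 25) break
    }
  }
  x <- rep(hx, each = hop)[seq_along(t_s)]
  y <- rep(hy, each = hop)[seq_along(t_s)]

  dwells <- list()
  for (r in seq_len(nrow(rec))) {
    tid <- rec$trial_id[r]
    on <- rec$image_onset_s[r]; off <- rec$image_offset_s[r]
    rect <- regions[r, ]
    if (!is.null(cfg$dwell_plan)) {
      plan <- cfg$dwell_plan[cfg$dwell_plan$trial_id == tid, , drop = FALSE]
      if (nrow(plan) == 0) next
      durs <- plan$dur_s
      inside <- plan$inside
      px <- if ("x" %in% names(plan)) plan$x else rep(NA_real_, nrow(plan))
      py <- if ("y" %in% names(plan)) plan$y else rep(NA_real_, nrow(plan))
    } else {
      nd <- sample(cfg$n_dwell_range[1]:cfg$n_dwell_range[2], 1)
      durs <- runif(nd, cfg$dwell_range[1], cfg$dwell_range[2])
      p <- cfg$p_in[[rec$condition[r]]] %||% 0.2
      inside <- runif(nd) < p
      px <- py <- rep(NA_real_, nd)
    }
    t_cur <- on + 0.05
    for (d in seq_along(durs)) {
      if (t_cur + durs[d] > off) break
      if (is.na(px[d])) {
        if (inside[d]) {
          px[d] <- runif(1, rect$x0, rect$x1); py[d] <- runif(1, rect$y0, rect$y1)
        } else {
          repeat {
            px[d] <- runif(1, -sx, sx); py[d] <- runif(1, -sy, sy)
            if (px[d] < rect$x0 - 3 || px[d] > rect$x1 + 3 ||
                  py[d] < rect$y0 - 3 || py[d] > rect$y1 + 3) break
          }
        }
      }
      idx <- which(t_s >= t_cur & t_s < t_cur + durs[d])
      x[idx] <- px[d] + rnorm(length(idx), 0, cfg$jitter_sd)
      y[idx] <- py[d] + rnorm(length(idx), 0, cfg$jitter_sd)
      dwells[[length(dwells) + 1L]] <-
        data.frame(trial_id = tid, start_s = t_cur, dur_s = durs[d],
                   x = px[d], y = py[d], inside = inside[d])
      t_cur <- t_cur + durs[d] + 0.1  # saccade/scatter gap
    }
  }
  truth <- if (length(dwells)) do.call(rbind, dwells) else
    data.frame(trial_id = integer(0), start_s = numeric(0), dur_s = numeric(0),
               x = numeric(0), y = numeric(0), inside = logical(0))
  list(gaze = data.frame(t_s = t_s, x_deg = x, y_deg = y),
       regions = regions, truth = truth)
}
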