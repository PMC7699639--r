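test_that("generation is bit-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_recording(cfg, seed = 7)
  b <- generate_recording(cfg, seed = 7)
  expect_identical(a$recording$traces, b$recording$traces)
  expect_identical(a$trials, b$trials)
  c <- generate_recording(cfg, seed = 8)
  expect_false(identical(a$recording$traces, c$recording$traces))
})

test_that("trial table respects task structure and condition proportions", {
  cfg <- sim_config(n_lists = 25, n_channels = c(PT = 1))
  sim <- generate_recording(cfg, seed = 1)
  tr <- sim$trials
  # each (image, phase) pair occurs exactly once
  expect_false(any(duplicated(tr[c("image_id", "phase")])))
  # recognition onset follows encoding onset for every image
  enc <- tr[tr$phase == "encoding", ]
  rec <- tr[tr$phase == "recognition", ]
  expect_true(all(rec$image_onset_s[match(enc$image_id, rec$image_id)] >
                    enc$image_onset_s))
  # 28/36/36% repeated/added/removed up to integer rounding
  frac <- table(enc$condition) / nrow(enc)
  expect_equal(as.numeric(frac[c("repeated", "added", "removed")]),
               c(0.28, 0.36, 0.36), tolerance = 0.02)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_lists = 0), "zero trials")
  expect_error(sim_config(fs = 150), "maximum synthesis frequency")
  expect_error(sim_config(effect_amp = -1), "non-negative")
})

test_that("zero effect amplitude leaves conditions exchangeable", {
  # band-power difference between manipulated-correct and repeated-correct
  # trials should be centred on zero when no effect is injected: two-sample
  # t over regenerated sessions must not reject
  diffs <- sapply(1:60, function(s) {
    cfg <- sim_config(n_lists = 2, n_channels = c(PT = 1), encoding_dur = 1,
                      effect_amp = 0, alpha_amp = 0)
    sim <- generate_recording(cfg, seed = 1000 + s)
    rec <- sim$recording
    bp <- bandpass_filter(rec$traces[, 1], rec$fs, c(80, 120))
    tr <- sim$trials
    cls <- condition_class(tr)
    pw <- function(rows) {
      mean(sapply(rows, function(r) {
        i0 <- floor(tr$image_onset_s[r] * rec$fs) + 1
        mean(bp[i0:(i0 + 999)]^2)
      }))
    }
    a <- which(cls == "manip_correct"); b <- which(cls == "repeated_correct")
    if (!length(a) || !length(b)) return(NA)
    pw(a) - pw(b)
  })
  tt <- t.test(diffs[!is.na(diffs)])
  expect_gt(tt$p.value, 0.01)
})

test_that("injected effect amplitude scales the measured condition difference", {
  amps <- c(0, 2, 4, 6, 8)
  med <- sapply(amps, function(a) {
    d <- sapply(1:6, function(s) {
      cfg <- sim_config(n_lists = 2, n_channels = c(PT = 1), encoding_dur = 1,
                        effect_amp = a, alpha_amp = 0, p_correct = c(
                          repeated = 1, added = 1, removed = 1))
      sim <- generate_recording(cfg, seed = 300 * s + round(a))
      rec <- sim$recording
      bp <- bandpass_filter(rec$traces[, 1], rec$fs, c(80, 120))
      tr <- sim$trials
      cls <- condition_class(tr)
      pw <- function(rows) mean(sapply(rows, function(r) {
        i0 <- floor(tr$image_onset_s[r] * rec$fs) + 1
        mean(bp[i0:(i0 + 999)]^2)
      }))
      pw(which(cls == "manip_correct")) - pw(which(cls == "repeated_correct"))
    })
    mean(d)
  })
  expect_gt(cor(amps, med, method = "spearman"), 0)
  expect_gt(med[5], med[1])
})

test_that("background spectrum recovers the configured 1/f slope", {
  for (slope in c(0.5, 1, 1.5)) {
    set.seed(42)
    x <- pink_noise(2^16, slope = slope)
    sp <- spec.pgram(ts(x, frequency = 1000), spans = 31, plot = FALSE,
                     taper = 0, detrend = TRUE)
    keep <- sp$freq > 1 & sp$freq < 100
    fit <- lm(log(sp$spec[keep]) ~ log(sp$freq[keep]))
    expect_equal(unname(-coef(fit)[2]), slope, tolerance = 0.3)
  }
})

test_that("ground truth records every injection", {
  cfg <- tiny_config(spike_rate = 0.05, outlier_frac = 0.1)
  sim <- generate_recording(cfg, seed = 3)
  gt <- sim$truth
  expect_equal(gt$lag_ms, 40)
  expect_equal(dim(gt$gains), c(4, 8))  # channels x images
  cls <- condition_class(sim$trials)
  expect_setequal(gt$effect$trials,
                  sim$trials$trial_id[which(cls == "manip_correct")])
  expect_true(length(gt$outlier_trials) >= 1)
  expect_equal(length(gt$spike_times), 4)
})

test_that("noiseless injected envelopes cross-covary at the configured lag", {
  # the injected MTL envelope is the PT envelope delayed by lag_ms: the
  # cross-covariance of the noiseless components must peak at exactly that
  # shift
  cfg <- sim_config(lag_ms = 40)
  fs <- cfg$fs
  t <- seq(0, 3, by = 1 / fs)
  env_pt <- burst_env <- sin(pi * pmin(pmax((t - 0.05) / cfg$burst_dur, 0), 1))^2
  env_mtl <- sin(pi * pmin(pmax((t - 0.05 - cfg$lag_ms / 1000) / cfg$burst_dur, 0), 1))^2
  lags <- -100:100  # samples = ms at 1 kHz
  xcov <- sapply(lags, function(k) {
    if (k >= 0) sum(env_pt[1:(length(t) - k)] * env_mtl[(1 + k):length(t)])
    else sum(env_pt[(1 - k):length(t)] * env_mtl[1:(length(t) + k)])
  })
  expect_equal(lags[which.max(xcov)], 40)
})

test_that("session containers roundtrip bit-exactly", {
  dir <- withr::local_tempdir()
  sim <- generate_recording(tiny_config(), seed = 5)
  p1 <- file.path(dir, "a")
  write_recording(sim$recording, p1)
  back <- read_recording(p1)
  expect_identical(back$traces, sim$recording$traces)
  expect_identical(back$fs, sim$recording$fs)
  expect_identical(back$channels$label, sim$recording$channels$label)
  # write(read(write(x))) == write(x) byte-for-byte for the array payload
  p2 <- file.path(dir, "b")
  write_recording(back, p2)
  expect_identical(readBin(file.path(p1, "traces.bin"), "raw",
                           file.size(file.path(p1, "traces.bin"))),
                   readBin(file.path(p2, "traces.bin"), "raw",
                           file.size(file.path(p2, "traces.bin"))))
  # trial table roundtrip
  tp <- file.path(dir, "events.tsv")
  write_trials(sim$trials, tp)
  tr <- read_trials(tp)
  expect_equal(tr$image_onset_s, sim$trials$image_onset_s)
  expect_identical(tr$condition, sim$trials$condition)
})

test_that("2000 Hz recordings roundtrip with fs preserved", {
  dir <- withr::local_tempdir()
  meta <- data.frame(label = "PT1", region = "PT")
  rec <- new_recording(matrix(rnorm(4000), ncol = 1), 2000, meta)
  write_recording(rec, dir)
  expect_equal(read_recording(dir)$fs, 2000)
})

test_that("container validation fails loudly", {
  dir <- withr::local_tempdir()
  sim <- generate_recording(tiny_config(), seed = 5)
  # missing mandatory column named in the error
  tr <- sim$trials
  write_tsv_path <- file.path(dir, "bad.tsv")
  write.table(tr[setdiff(names(tr), "condition")], write_tsv_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_trials(write_tsv_path), "condition")
  # sidecar / payload size mismatch
  p <- file.path(dir, "rec")
  write_recording(sim$recording, p)
  meta <- jsonlite::read_json(file.path(p, "meta.json"), simplifyVector = TRUE)
  meta$n_samples <- meta$n_samples - 1
  jsonlite::write_json(meta, file.path(p, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_recording(p), "declares")
  # NaN in traces refused
  p3 <- file.path(dir, "nan")
  bad <- sim$recording
  bad$traces[1, 1] <- NaN
  write_recording(bad, p3)
  expect_error(read_recording(p3), "NaN")
})

test_that("gaze generation honours dwell plans and seeds", {
  sim <- generate_recording(tiny_config(), seed = 2)
  rec_trials <- sim$trials[sim$trials$phase == "recognition", ]
  plan <- data.frame(trial_id = rec_trials$trial_id[1], dur_s = 0.15,
                     inside = TRUE)
  gz <- generate_gaze(sim$trials, gaze_config(dwell_plan = plan), seed = 1)
  fx <- detect_fixations(gz$gaze)
  rect <- gz$regions[gz$regions$image_id == rec_trials$image_id[1], ]
  hit <- fx$x_deg >= rect$x0 & fx$x_deg <= rect$x1 &
    fx$y_deg >= rect$y0 & fx$y_deg <= rect$y1
  expect_gte(sum(hit), 1)
  # zero dwells of >= 100 ms -> no fixations at all
  plan2 <- data.frame(trial_id = rec_trials$trial_id, dur_s = 0.05,
                      inside = TRUE)
  gz2 <- generate_gaze(sim$trials, gaze_config(dwell_plan = plan2), seed = 1)
  expect_equal(nrow(detect_fixations(gz2$gaze)), 0)
  # determinism
  gz3 <- generate_gaze(sim$trials, gaze_config(dwell_plan = plan), seed = 1)
  expect_identical(gz$gaze, gz3$gaze)
  # oversized rectangle rejected
  expect_error(generate_gaze(sim$trials, gaze_config(rect_deg = c(40, 3))),
               "screen")
})
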