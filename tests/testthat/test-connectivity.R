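test_that("cross-correlogram recovers a pure shift exactly", {
  set.seed(61)
  n_tr <- 8; n_bins <- 100
  A <- matrix(rnorm(n_tr * n_bins), n_tr, n_bins)
  A <- t(apply(A, 1, function(x) stats::filter(x, rep(1/5, 5), circular = TRUE)))
  shift <- 4  # bins = 40 ms at 10 ms bins
  B <- cbind(matrix(0, n_tr, shift), A[, 1:(n_bins - shift)])
  cc <- crosscorrelogram(A, B)
  expect_equal(peak_lag(cc), 40)
  # A against itself: peak 1.0 at lag 0
  cc0 <- crosscorrelogram(A, A)
  expect_equal(peak_lag(cc0), 0)
  expect_equal(cc0$r[cc0$lags_ms == 0], 1)
})

test_that("independent series give a flat correlogram", {
  set.seed(62)
  n_tr <- 20; n_bins <- 100
  A <- matrix(rnorm(n_tr * n_bins), n_tr, n_bins)
  B <- matrix(rnorm(n_tr * n_bins), n_tr, n_bins)
  cc <- crosscorrelogram(A, B)
  expect_true(all(abs(cc$r) < 3 / sqrt(n_bins * n_tr) + 0.02))
})

test_that("swapping channel roles reflects the lag axis", {
  set.seed(63)
  A <- matrix(rnorm(6 * 80), 6, 80)
  B <- matrix(rnorm(6 * 80), 6, 80) + 0.5 * A
  ab <- crosscorrelogram(A, B)
  ba <- crosscorrelogram(B, A)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)
})

test_that("chance correlogram is seeded and near zero for iid trials", {
  set.seed(64)
  A <- matrix(rnorm(10 * 100), 10, 100)
  B <- matrix(rnorm(10 * 100), 10, 100)
  c1 <- chance_crosscorrelogram(A, B, seed = 3)
  c2 <- chance_crosscorrelogram(A, B, seed = 3)
  expect_identical(c1$r, c2$r)
  expect_lt(max(abs(c1$r)), 0.15)
  expect_error(chance_crosscorrelogram(A, B, n_perm = 0), "at least 1")
})

test_that("chance correlogram absorbs the stimulus-locked component", {
  # a shared stimulus-locked bump appears in both true and chance
  # correlograms; trial-specific coupling appears only in the true one
  set.seed(65)
  n_tr <- 24; n_bins <- 100
  bump <- sin(pi * (1:n_bins) / n_bins)^2
  mk_noise <- function() t(apply(matrix(rnorm(n_tr * n_bins), n_tr), 1,
                                 function(x) stats::filter(x, rep(1/7, 7),
                                                           circular = TRUE)))
  shared <- mk_noise()   # trial-specific, common to both channels
  A <- matrix(bump, n_tr, n_bins, byrow = TRUE) + shared + 0.3 * mk_noise()
  B <- matrix(bump, n_tr, n_bins, byrow = TRUE) + shared + 0.3 * mk_noise()
  tru <- crosscorrelogram(A, B)
  cha <- chance_crosscorrelogram(A, B, n_perm = 200, seed = 1)
  i0 <- which(tru$lags_ms == 0)
  # both capture the stimulus-locked correlation
  expect_gt(cha$r[i0], 0.3)
  # true exceeds chance at lag 0 because of the trial-specific component
  expect_gt(tru$r[i0] - cha$r[i0], 0.2)
})

test_that("peak lag statistics summarise pairs and participants", {
  # symmetric triangular correlogram peaks at its apex
  lags <- seq(-200, 200, by = 10)
  tri <- pmax(0, 1 - abs(lags - 30) / 100)
  ccg <- structure(list(lags_ms = lags, r = tri, n_trials = 10, kind = "true"),
                   class = "crosscorrelogram")
  expect_equal(peak_lag(ccg), 30)
  # flat correlogram resolves toward the lag nearest zero
  flat <- structure(list(lags_ms = lags, r = rep(0.5, length(lags)),
                         n_trials = 10, kind = "true"),
                    class = "crosscorrelogram")
  expect_equal(peak_lag(flat), 0)
  # across participants
  mk_pair <- function(p, peak) {
    r <- pmax(0, 1 - abs(lags - peak) / 150) + rnorm(length(lags), 0, 0.01)
    list(participant = p,
         true = structure(list(lags_ms = lags, r = r, n_trials = 10,
                               kind = "true"), class = "crosscorrelogram"),
         chance = structure(list(lags_ms = lags, r = rep(0, length(lags)),
                                 n_trials = 10, kind = "chance"),
                            class = "crosscorrelogram"))
  }
  set.seed(66)
  pairs <- c(lapply(1:3, mk_pair, peak = 40), lapply(4:6, mk_pair, peak = 50))
  st <- peak_lag_stats(pairs)
  expect_equal(nrow(st$pair_stats), 6)
  expect_equal(st$mean_lag_ms, 45, tolerance = 6)
  expect_lt(st$lag_test$p.value, 0.05)
})

test_that("PLV identities hold", {
  set.seed(67)
  ph <- matrix(runif(50 * 20, -pi, pi), 50, 20)
  # constant phase lag -> PLV 1 everywhere
  expect_equal(plv(ph, ph - 1.1)$plv, rep(1, 20), tolerance = 1e-12)
  # antipodal phasors over two trials -> PLV 0
  p2 <- rbind(rep(0, 5), rep(pi, 5))
  expect_equal(plv(p2, matrix(0, 2, 5))$plv, rep(0, 5), tolerance = 1e-12)
  # common offset invariance
  v1 <- plv(ph, 0.3 * ph)$plv
  v2 <- plv(ph + 2, 0.3 * ph + 2)$plv
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_error(plv(ph[1, , drop = FALSE], ph[1, , drop = FALSE]), "2 trials")
})

test_that("PLV under uniform phases matches the Rayleigh expectation", {
  set.seed(68)
  sims <- replicate(1000, plv(matrix(runif(100, -pi, pi), 100, 1),
                              matrix(runif(100, -pi, pi), 100, 1),
                              zscore = FALSE)$plv)
  expect_equal(mean(sims), sqrt(pi / (4 * 100)), tolerance = 0.15 * sqrt(pi / 400))
})

test_that("coherence equals 1 for identical signals and ~1/K for noise", {
  set.seed(69)
  x <- rnorm(4000)
  cs <- msc_coherence(x, x, 1000)
  expect_true(all(abs(cs$coherence - 1) < 1e-8))
  # K = 8 independent rectangular segments: E[C] ~ 1/K
  m <- replicate(200, {
    mean(msc_coherence(rnorm(4000), rnorm(4000), 1000, seg_s = 0.5,
                       overlap = 0, window = "rect")$coherence)
  })
  expect_equal(mean(m), 1 / 8, tolerance = 0.2 * (1 / 8))
  expect_error(msc_coherence(rnorm(400), rnorm(400), 1000, seg_s = 0.5),
               "2 segments")
})

test_that("coherence is invariant to per-channel scaling and sees delays", {
  set.seed(70)
  x <- rnorm(4000)
  y <- c(rep(0, 25), x[1:3975]) + 0.2 * rnorm(4000)
  c1 <- msc_coherence(x, y, 1000)
  c2 <- msc_coherence(5 * x, 0.1 * y, 1000)
  expect_equal(c1$coherence, c2$coherence, tolerance = 1e-10)
  low <- c1$freq <= 20
  expect_gt(mean(c1$coherence[low]), 0.8)
})

test_that("injected alpha coupling raises alpha coherence and synchrony", {
  hit_coh <- logical(0); hit_plv <- logical(0)
  for (s in 1:3) {
    cfg <- sim_config(n_lists = 3, n_channels = c(PT = 1, MTL = 1),
                      effect_amp = 0, alpha_amp = 6,
                      p_correct = c(repeated = 1, added = 1, removed = 1))
    sim <- generate_recording(cfg, seed = 500 + s)
    rec <- sim$recording
    tr <- sim$trials
    cls <- condition_class(tr)
    fs <- rec$fs
    phP <- hilbert_phase(rec$traces[, 1], fs, c(8, 12))
    phM <- hilbert_phase(rec$traces[, 2], fs, c(8, 12))
    seg <- function(r, ph) {
      i0 <- floor((tr$image_onset_s[r] + 0.3) * fs) + 1
      ph[i0:(i0 + 1499)]
    }
    coh_of <- function(rows) {
      mean(sapply(rows, function(r) {
        i0 <- floor((tr$image_onset_s[r] + 0.3) * fs) + 1
        band_coherence(msc_coherence(rec$traces[i0:(i0 + 999), 1],
                                     rec$traces[i0:(i0 + 999), 2], fs))
      }))
    }
    a <- which(cls == "manip_correct")       # alpha-coupled trials
    b <- which(cls == "repeated_correct")    # uncoupled trials
    hit_coh <- c(hit_coh, coh_of(a) > coh_of(b))
    pa <- plv(t(sapply(a, seg, ph = phP)), t(sapply(a, seg, ph = phM)),
              zscore = FALSE)
    pb <- plv(t(sapply(b, seg, ph = phP)), t(sapply(b, seg, ph = phM)),
              zscore = FALSE)
    hit_plv <- c(hit_plv, mean(pa$plv) > mean(pb$plv))
  }
  expect_gte(mean(hit_coh), 2 / 3)
  expect_gte(mean(hit_plv), 2 / 3)
})
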