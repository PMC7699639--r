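# Feature construction and cosine reinstatement on small hand-built inputs.

fake_bp <- function(values, centers, trials) {
  structure(list(values = values, centers = centers, trials = trials,
                 skipped = integer(0), width = 0.2, step = 0.1,
                 band = c(80, 120), freqs = c(90.6, 107.7),
                 channels = NULL),
            class = "binned_power")
}

fake_feats <- function(E, R, list_id = rep(1L, dim(E)[1])) {
  structure(list(E = E, R = R, image_id = seq_len(dim(E)[1]),
                 list_id = list_id,
                 enc_centers = seq_len(dim(E)[2]) / 10,
                 ret_centers = seq_len(dim(R)[2]) / 10),
            class = "feature_set")
}

test_that("feature vectors have K = L * F entries and honour scoping", {
  tr <- data.frame(trial_id = 1:2, list_id = 1L, image_id = 1:2,
                   phase = "x", condition = "added", correct = TRUE)
  # band-averaged: trials x channels x bins -> K = L = 3
  v_enc <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  v_ret <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  f1 <- build_features(fake_bp(v_enc, 1:4, tr), fake_bp(v_ret, 1:4, tr))
  expect_equal(dim(f1$E), c(2, 4, 3))
  # multi-band: trials x channels x freqs x bins -> K = L * F = 2 * 4 = 8
  v_enc2 <- array(rnorm(2 * 2 * 4 * 5), dim = c(2, 2, 4, 5))
  v_ret2 <- array(rnorm(2 * 2 * 4 * 5), dim = c(2, 2, 4, 5))
  f2 <- build_features(fake_bp(v_enc2, 1:5, tr), fake_bp(v_ret2, 1:5, tr))
  expect_equal(dim(f2$E)[3], 8)
  # scoping to a channel subset keeps only those channels' features
  f3 <- build_features(fake_bp(v_enc, 1:4, tr), fake_bp(v_ret, 1:4, tr),
                       scope = c(1, 3))
  expect_equal(dim(f3$E)[3], 2)
  expect_equal(f3$E[1, , 1], f1$E[1, , 1])
  expect_equal(f3$E[1, , 2], f1$E[1, , 3])
  expect_error(build_features(fake_bp(v_enc, 1:4, tr),
                              fake_bp(v_ret, 1:4, tr), scope = integer(0)),
               "empty")
})

test_that("cosine similarity matches closed forms", {
  E <- array(0, dim = c(1, 3, 2))
  R <- array(0, dim = c(1, 3, 2))
  E[1, 1, ] <- c(1, 0); R[1, 1, ] <- c(1, 0)   # identical -> 1
  E[1, 2, ] <- c(1, 0); R[1, 2, ] <- c(0, 1)   # orthogonal -> 0
  E[1, 3, ] <- c(1, 0); R[1, 3, ] <- c(1, 1)   # 45 degrees -> 1/sqrt(2)
  C <- cosine_map(fake_feats(E, R))
  expect_equal(C[1, 1, 1], 1)
  expect_equal(C[1, 2, 2], 0)
  expect_equal(C[1, 3, 3], 1 / sqrt(2), tolerance = 1e-12)
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
})

test_that("cosine maps are invariant to positive rescaling of vectors", {
  set.seed(51)
  E <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  R <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  C1 <- cosine_map(fake_feats(E, R))
  C2 <- cosine_map(fake_feats(E * 3.7, R * 0.2))
  expect_equal(unclass(C1), unclass(C2), tolerance = 1e-12)
})

test_that("zero-norm vectors yield missing cells, not errors", {
  E <- array(1, dim = c(1, 2, 3))
  R <- array(1, dim = c(1, 2, 3))
  E[1, 2, ] <- 0
  C <- cosine_map(fake_feats(E, R))
  expect_true(all(is.na(C[1, 2, ])))
  expect_false(anyNA(C[1, 1, ]))
})

test_that("cellwise normalisation standardises across trials", {
  set.seed(52)
  maps <- array(rnorm(6 * 3 * 3), dim = c(6, 3, 3))
  nm <- normalize_maps(maps)
  expect_equal(apply(nm, c(2, 3), mean), matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(apply(nm, c(2, 3), sd), matrix(1, 3, 3), tolerance = 1e-12)
  # identical maps across trials -> zero variance -> NA cells
  same <- array(rep(0.5, 4 * 2 * 2), dim = c(4, 2, 2))
  expect_true(all(is.na(normalize_maps(same))))
  # shift invariance
  nm2 <- normalize_maps(maps + 10)
  expect_equal(unclass(nm), unclass(nm2), tolerance = 1e-12)
  # 2-trial, 1-cell hand example: (x - mean) / sd
  two <- array(c(1, 3), dim = c(2, 1, 1))
  expect_equal(as.numeric(normalize_maps(two)), (c(1, 3) - 2) / sd(c(1, 3)))
})

test_that("derangement enumeration is exact", {
  expect_equal(nrow(derangements(2)), 1)  # the swap
  expect_equal(derangements(2), matrix(c(2, 1), 1, 2), ignore_attr = TRUE)
  expect_equal(nrow(derangements(3)), 2)
  expect_equal(nrow(derangements(4)), 9)  # four-image list
  d4 <- derangements(4)
  expect_true(all(apply(d4, 1, function(r) all(r != 1:4))))
  expect_equal(nrow(unique(d4)), 9)
})

test_that("shuffled maps subtract out pattern structure shared across images", {
  set.seed(53)
  # image-specific patterns: each image a distinct direction
  n_img <- 4
  K <- 12
  pats <- matrix(rnorm(n_img * K, sd = 1), n_img, K)
  mk <- function(pats, noise = 0.1) {
    E <- array(0, dim = c(n_img, 3, K))
    R <- array(0, dim = c(n_img, 3, K))
    for (i in seq_len(n_img)) {
      for (e in 1:3) {
        E[i, e, ] <- pats[i, ] + rnorm(K, 0, noise)
        R[i, e, ] <- pats[i, ] + rnorm(K, 0, noise)
      }
    }
    fake_feats(E, R)
  }
  f_specific <- mk(pats)
  true_m <- mean(cosine_map(f_specific), na.rm = TRUE)
  null_m <- mean(shuffle_null(f_specific), na.rm = TRUE)
  expect_gt(true_m - null_m, 0.3)
  # patterns shared across all images: true - shuffled ~ 0
  shared <- mk(matrix(rep(pats[1, ], n_img), n_img, K, byrow = TRUE))
  d <- mean(cosine_map(shared), na.rm = TRUE) -
    mean(shuffle_null(shared), na.rm = TRUE)
  expect_lt(abs(d), 0.02)
})

test_that("a two-image list shuffles by swapping", {
  set.seed(54)
  E <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  R <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  f <- fake_feats(E, R, list_id = c(1L, 1L))
  null <- shuffle_null(f)
  # trial 1's null pairs R_1 with E_2 and vice versa
  expect_equal(null[1, , ],
               cosine_map(fake_feats(E[c(2, 1), , , drop = FALSE], R))[1, , ],
               tolerance = 1e-12)
})

test_that("single-image lists are excluded from the null", {
  set.seed(55)
  E <- array(rnorm(3 * 2 * 3), dim = c(3, 2, 3))
  R <- array(rnorm(3 * 2 * 3), dim = c(3, 2, 3))
  f <- fake_feats(E, R, list_id = c(1L, 1L, 2L))
  null <- shuffle_null(f)
  expect_true(all(is.na(null[3, , ])))
  expect_false(anyNA(null[1, , ]))
})

test_that("region-scoped maps equal maps from scoped features", {
  sim <- generate_recording(tiny_config(), seed = 9)
  tfr <- hg_power(sim$recording)
  bp_enc <- bin_power(tfr, sim$trials, phase = "encoding", window = c(0, 1),
                      band = c(80, 120))
  bp_ret <- bin_power(tfr, sim$trials, phase = "recognition", window = c(0, 1),
                      band = c(80, 120))
  pt <- region_channels(tfr$channels, "PT")
  f_scoped <- build_features(bp_enc, bp_ret, scope = pt)
  C1 <- cosine_map(f_scoped)
  # restrict the binned arrays first, then build features
  bp_enc2 <- bp_enc; bp_enc2$values <- bp_enc$values[, pt, , drop = FALSE]
  bp_ret2 <- bp_ret; bp_ret2$values <- bp_ret$values[, pt, , drop = FALSE]
  C2 <- cosine_map(build_features(bp_enc2, bp_ret2))
  expect_equal(unclass(C1), unclass(C2), tolerance = 1e-12)
})

test_that("reinstatement time series extracts masked encoding epochs", {
  set.seed(56)
  map <- matrix(rnorm(5 * 7), 5, 7)
  # full mask -> column means
  expect_equal(reinstatement_timeseries(map, rep(TRUE, 5)), colMeans(map))
  # single-epoch mask -> that row
  expect_equal(reinstatement_timeseries(map, c(FALSE, TRUE, FALSE, FALSE, FALSE)),
               map[2, ])
  expect_error(reinstatement_timeseries(map, rep(FALSE, 5)), "mask")
  # participant stack averaging
  stack <- array(rnorm(3 * 5 * 7), dim = c(3, 5, 7))
  ts3 <- reinstatement_timeseries(stack, rep(TRUE, 5))
  expect_equal(ts3, colMeans(apply(stack, c(1, 3), mean)))
})
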