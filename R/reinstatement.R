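# Encoding-retrieval representational similarity: feature vectors, cosine
# similarity maps, cell-wise normalisation, within-list shuffle nulls, and
# retrieval-locked reinstatement time series.

#' Build encoding and retrieval feature vectors
#'
#' For every temporal epoch of every trial, stacks the z-scored power of the
#' scoped electrodes (and frequency bands) into a feature vector of length
#' `K = L * F`; with the single high-gamma band, `K = L`. Encoding and
#' retrieval vectors of the same image share an identical entry order.
#'
#' @param bp_enc,bp_ret [bin_power()] results for the encoding and
#'   recognition phases of one session (band-averaged: trials x channels x
#'   bins, or full: trials x channels x freqs x bins).
#' @param scope optional integer or logical index of electrodes to keep
#'   (e.g. one region); default all.
#' @return list of class `feature_set`: `E` (trials x enc epochs x K), `R`
#'   (trials x ret epochs x K), `image_id`, `list_id`, `enc_centers`,
#'   `ret_centers`.
#' @export
build_features <- function(bp_enc, bp_ret, scope = NULL) {
  stop_if_not(inherits(bp_enc, "binned_power") && inherits(bp_ret, "binned_power"),
              "inputs must come from bin_power()")
  imgs <- intersect(bp_enc$trials$image_id, bp_ret$trials$image_id)
  stop_if_not(length(imgs) > 0, "no images shared between encoding and retrieval")
  flat <- function(bp, rows) {
    v <- bp$values
    if (length(dim(v)) == 4) {
      # trials x channels x freqs x bins -> trials x bins x (ch*freq)
      v <- aperm(v, c(1, 4, 2, 3))
      dim(v) <- c(dim(v)[1], dim(v)[2], dim(v)[3] * dim(v)[4])
    } else {
      v <- aperm(v, c(1, 3, 2))
    }
    v[rows, , , drop = FALSE]
  }
  e_rows <- match(imgs, bp_enc$trials$image_id)
  r_rows <- match(imgs, bp_ret$trials$image_id)
  E <- flat(bp_enc, e_rows)
  R <- flat(bp_ret, r_rows)
  if (!is.null(scope)) {
    n_ch <- dim(bp_enc$values)[2]
    if (is.logical(scope)) scope <- which(scope)
    stop_if_not(length(scope) > 0, "empty electrode scope")
    n_f <- dim(E)[3] / n_ch
    keep <- as.vector(outer(scope, (seq_len(n_f) - 1) * n_ch, `+`))
    E <- E[, , keep, drop = FALSE]
    R <- R[, , keep, drop = FALSE]
  }
  structure(list(E = E, R = R,
                 image_id = imgs,
                 list_id = bp_enc$trials$list_id[e_rows],
                 enc_centers = bp_enc$centers,
                 ret_centers = bp_ret$centers),
            class = "feature_set")
}

# Extract trial `tr` from a trials x epochs x K array as an epochs x K matrix
trial_slice <- function(a, tr) {
  m <- a[tr, , , drop = FALSE]
  dim(m) <- dim(a)[-1]
  m
}

cosine_pairs <- function(Ei, Rj) {
  # Ei: enc epochs x K, Rj: ret epochs x K -> enc x ret cosine matrix,
  # NA rows (missing epochs) and zero-norm vectors propagate as NA
  ne <- sqrt(rowSums(Ei^2))
  nr <- sqrt(rowSums(Rj^2))
  ne[ne == 0] <- NA_real_
  nr[nr == 0] <- NA_real_
  (Ei %*% t(Rj)) / outer(ne, nr)
}

#' Trial-wise cosine reinstatement maps
#'
#' For each trial `n`, computes `C_n(i, j)`, the cosine similarity between
#' the encoding feature vector at epoch `i` and the retrieval feature vector
#' at epoch `j`. Cosine (not Pearson) is used so that a shared broadband
#' power increase across electrodes registers as reinstatement.
#'
#' @param feat a [build_features()] result.
#' @return array of class `reinstatement_map`, trials x enc epochs x ret
#'   epochs, raw entries in `[-1, 1]` (NA where an epoch is missing or a
#'   vector has zero norm).
#' @export
cosine_map <- function(feat) {
  stop_if_not(inherits(feat, "feature_set"), "feat must come from build_features()")
  n_tr <- dim(feat$E)[1]
  C <- array(NA_real_, dim = c(n_tr, dim(feat$E)[2], dim(feat$R)[2]))
  for (tr in seq_len(n_tr)) {
    C[tr, , ] <- cosine_pairs(trial_slice(feat$E, tr),
                              trial_slice(feat$R, tr))
  }
  structure(C, class = "reinstatement_map",
            enc_centers = feat$enc_centers, ret_centers = feat$ret_centers)
}

#' Normalise reinstatement maps across trials
#'
#' Default (`cellwise`) standardises each (encoding, retrieval) cell by the
#' mean and SD of that cell over all trials of the session; `global` centres
#' and scales by the grand mean and SD of all cells over all trials. Cells
#' with zero variance become NA.
#'
#' @param maps trials x enc x ret array from [cosine_map()].
#' @param method "cellwise" (default) or "global".
#' @return array of the same shape.
#' @export
normalize_maps <- function(maps, method = c("cellwise", "global")) {
  method <- match.arg(method)
  stop_if_not(dim(maps)[1] >= 2, "need at least 2 trials to normalise")
  if (method == "global") {
    mu <- mean(maps, na.rm = TRUE)
    sg <- sd(as.vector(maps), na.rm = TRUE)
    out <- (maps - mu) / sg
  } else {
    mu <- apply(maps, c(2, 3), mean, na.rm = TRUE)
    sg <- apply(maps, c(2, 3), sd, na.rm = TRUE)
    sg[sg == 0] <- NA_real_
    out <- sweep(sweep(maps, c(2, 3), mu), c(2, 3), sg, "/")
  }
  attributes(out) <- attributes(maps)
  out
}

#' Enumerate derangements
#'
#' All permutations of `1:n` with no fixed point. Used to pair each
#' retrieval trial with a non-matching encoding trial of the same list.
#'
#' @param n set size (a four-image list has 9 derangements).
#' @return matrix, one derangement per row.
#' @export
derangements <- function(n) {
  stop_if_not(n >= 2, "derangements need n >= 2")
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  p <- perms(seq_len(n))
  p[apply(p, 1, function(r) all(r != seq_len(n))), , drop = FALSE]
}

#' Within-list shuffled reinstatement maps (null)
#'
#' Pairs the retrieval epochs of each trial with the encoding epochs of a
#' *different* image from the same four-image list (a strict derangement:
#' no self-pairing), and averages the resulting cosine maps over all
#' derangements of the list. With lists of up to `exact_max` images all
#' derangements are enumerated exactly, removing Monte Carlo noise;
#' otherwise `n_shuffles` random derangements are sampled. Lists with a
#' single image cannot be shuffled and yield NA with a log attribute.
#'
#' @param feat a [build_features()] result.
#' @param n_shuffles random derangements per list when enumeration is not
#'   used.
#' @param seed integer seed (used only when sampling).
#' @param exact_max largest list size enumerated exactly.
#' @return trials x enc x ret array: per-trial average shuffled map.
#' @export
shuffle_null <- function(feat, n_shuffles = 100, seed = 1, exact_max = 5) {
  stop_if_not(inherits(feat, "feature_set"), "feat must come from build_features()")
  n_tr <- dim(feat$E)[1]
  C0 <- array(NA_real_, dim = c(n_tr, dim(feat$E)[2], dim(feat$R)[2]))
  acc <- C0
  cnt <- array(0L, dim = dim(C0))
  excluded <- integer(0)
  set.seed(seed)
  for (l in unique(feat$list_id)) {
    members <- which(feat$list_id == l)
    m <- length(members)
    if (m < 2) { excluded <- c(excluded, members); next }
    D <- if (m <= exact_max) derangements(m) else {
      t(replicate(n_shuffles, {
        repeat {
          p <- sample.int(m)
          if (all(p != seq_len(m))) break
        }
        p
      }))
    }
    for (d in seq_len(nrow(D))) {
      for (k in seq_len(m)) {
        tr <- members[k]
        src <- members[D[d, k]]
        cm <- cosine_pairs(trial_slice(feat$E, src),
                           trial_slice(feat$R, tr))
        ok <- !is.na(cm)
        prev <- acc[tr, , ]
        prev[is.na(prev) & ok] <- 0
        prev[ok] <- prev[ok] + cm[ok]
        acc[tr, , ] <- prev
        cnt[tr, , ] <- cnt[tr, , ] + ok
      }
    }
  }
  out <- acc / ifelse(cnt > 0, cnt, NA_real_)
  attributes(out) <- c(attributes(C0),
                       list(excluded_trials = excluded))
  class(out) <- "reinstatement_map"
  attr(out, "enc_centers") <- feat$enc_centers
  attr(out, "ret_centers") <- feat$ret_centers
  out
}

#' Retrieval-locked reinstatement time series
#'
#' Given a participant-level reinstatement map (or a stack of them) and a
#' mask of encoding epochs showing significant image-specific reinstatement,
#' returns the mean reinstatement over the masked encoding epochs at every
#' retrieval epoch.
#'
#' @param map enc x ret matrix, or participants x enc x ret array.
#' @param enc_mask logical vector over encoding epochs; must select at least
#'   one.
#' @return numeric vector over retrieval epochs (participant average if a
#'   stack was given).
#' @export
reinstatement_timeseries <- function(map, enc_mask) {
  stop_if_not(any(enc_mask), "encoding-epoch mask selects nothing")
  if (length(dim(map)) == 3) {
    per <- apply(map[, enc_mask, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
    return(colMeans(per, na.rm = TRUE))
  }
  colMeans(map[enc_mask, , drop = FALSE], na.rm = TRUE)
}
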