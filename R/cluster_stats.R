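# Nonparametric cluster-based permutation testing in 1-D (time) and 2-D
# (time x time, time x frequency), with participant-level sign-flip and
# trial-level label-shuffle null constructions.

BIG_T <- 1e12  # stand-in statistic for zero-variance (degenerate) bins

#' Pointwise paired t statistics across participants
#'
#' Paired t statistic and two-sided p value at every bin of a
#' participants x bins matrix of condition differences (each row one
#' participant's average over their visually responsive electrodes).
#' Zero-variance bins with a nonzero mean are flagged as degenerate and
#' assigned the largest representable statistic.
#'
#' @param diffs participants x bins matrix (or participants x rows x cols
#'   array) of paired condition differences.
#' @return list with `t`, `p` (same shape as one participant's data), `df`,
#'   `degenerate` (logical, same shape).
#' @export
pointwise_tstats <- function(diffs) {
  d <- if (is.matrix(diffs)) diffs else matrix(diffs, nrow = dim(diffs)[1])
  n <- nrow(d)
  stop_if_not(n >= 2, "need at least 2 participants")
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  degen <- s == 0 & m != 0
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * BIG_T))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  shape <- function(v) {
    if (is.matrix(diffs)) v else array(v, dim = dim(diffs)[-1])
  }
  list(t = shape(t_stat), p = shape(p), df = n - 1, degenerate = shape(degen))
}

# Unpaired (pooled-variance) t per bin between two groups of trials.
unpaired_tstats <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t_stat <- ifelse(se > 0, (ma - mb) / se,
                   ifelse(ma == mb, 0, sign(ma - mb) * BIG_T))
  list(t = t_stat, df = na + nb - 2)
}

# Label connected components of a logical mask. 1-D: contiguous runs.
# 2-D: flood fill with 4- or 8-connectivity.
label_components <- function(mask, connectivity = 4) {
  if (is.null(dim(mask)) || length(dim(mask)) == 1) {
    lab <- integer(length(mask))
    r <- rle(as.vector(mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- 0L
    for (i in seq_along(r$values)) {
      if (r$values[i]) { k <- k + 1L; lab[starts[i]:ends[i]] <- k }
    }
    return(lab)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
  }
  k <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    k <- k + 1L
    queue <- matrix(c(i, j), 1, 2)
    lab[i, j] <- k
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (q in seq_len(nrow(nbr))) {
        ii <- cur[1] + nbr[q, 1]; jj <- cur[2] + nbr[q, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- k
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# Clusters of suprathreshold bins sharing a sign. Returns a list of
# clusters: members (indices into the flattened map), stat (sum of t), sign.
form_clusters <- function(t_map, t_crit, tail, connectivity = 4) {
  clusters <- list()
  signs <- if (tail == "two") c(1, -1) else if (tail == "pos") 1 else -1
  for (sgn in signs) {
    mask <- if (sgn > 0) t_map > t_crit else t_map < -t_crit
    if (!any(mask, na.rm = TRUE)) next
    mask[is.na(mask)] <- FALSE
    lab <- label_components(mask, connectivity)
    for (k in seq_len(max(lab))) {
      members <- which(lab == k)
      clusters[[length(clusters) + 1L]] <-
        list(members = members, stat = sum(t_map[members]), sign = sgn)
    }
  }
  clusters
}

max_cluster_stat <- function(t_map, t_crit, tail, connectivity) {
  cl <- form_clusters(t_map, t_crit, tail, connectivity)
  if (!length(cl)) return(0)
  max(vapply(cl, function(c) abs(c$stat), numeric(1)))
}

new_cluster_result <- function(clusters, p_values, t_map, t_crit, null_max,
                               n_perm, exact, tail, connectivity) {
  df <- if (length(clusters)) {
    data.frame(cluster = seq_along(clusters),
               n_bins = vapply(clusters, function(c) length(c$members), 1L),
               stat = vapply(clusters, function(c) c$stat, 1),
               sign = vapply(clusters, function(c) c$sign, 1),
               p_value = p_values)
  } else {
    data.frame(cluster = integer(0), n_bins = integer(0), stat = numeric(0),
               sign = numeric(0), p_value = numeric(0))
  }
  structure(list(clusters = df,
                 members = lapply(clusters, function(c) c$members),
                 t = t_map, t_crit = t_crit, null_max = null_max,
                 n_perm = n_perm, exact = exact, tail = tail,
                 connectivity = connectivity),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s null of %d %s draws, |t| threshold %.3f\n",
              if (x$exact) "exact" else "sampled", x$n_perm,
              if (x$exact) "enumerated" else "permutation", x$t_crit))
  print(x$clusters)
  invisible(x)
}

#' Significance mask from a cluster result
#'
#' @param cr a `cluster_result`.
#' @param alpha cluster-level significance threshold.
#' @return logical array shaped like the statistic map, TRUE inside
#'   significant clusters.
#' @export
cluster_mask <- function(cr, alpha = 0.05) {
  out <- array(FALSE, dim = if (is.null(dim(cr$t))) length(cr$t) else dim(cr$t))
  sig <- which(cr$clusters$p_value < alpha)
  for (k in sig) out[cr$members[[k]]] <- TRUE
  out
}

#' Participant-level sign-flip cluster permutation test
#'
#' Forms clusters of contiguous bins (1-D) or 4-connected cells (2-D) whose
#' pointwise paired t statistic exceeds the cluster-forming threshold with
#' a common sign, scores each by the sum of its t statistics, and compares
#' to the permutation null obtained by randomly reversing the sign of each
#' participant's difference — the empiric distribution of the 2^n equally
#' probable mean differences under the null. The maximum cluster statistic
#' of each permutation corrects for multiple comparisons. For `n <=
#' exact_n_max` participants all 2^n sign patterns are enumerated and the
#' p value is exact (`count / 2^n`, identity pattern included); otherwise
#' `n_perm` random draws are used with the `(1 + count) / (1 + n_perm)`
#' convention.
#'
#' @param diffs participants x bins matrix, or participants x rows x cols
#'   array, of paired condition differences.
#' @param n_perm permutation draws when not enumerating.
#' @param seed integer seed.
#' @param threshold_p pointwise cluster-forming p threshold (in (0, 1)).
#' @param tail "two" (clusters of both signs, compared to the null of
#'   maximum absolute cluster statistics), "pos" or "neg".
#' @param connectivity 4 or 8 (2-D only).
#' @param exact_n_max largest n for exact enumeration.
#' @return a `cluster_result`.
#' @export
signflip_cluster_test <- function(diffs, n_perm = 1000, seed = 1,
                                  threshold_p = 0.05, tail = c("two", "pos", "neg"),
                                  connectivity = 4, exact_n_max = 10) {
  tail <- match.arg(tail)
  stop_if_not(threshold_p > 0 && threshold_p < 1, "threshold_p must be in (0, 1)")
  d <- if (is.matrix(diffs)) diffs else matrix(diffs, nrow = dim(diffs)[1])
  n <- nrow(d)
  stop_if_not(n >= 2, "need at least 2 participants")
  map_dim <- if (is.matrix(diffs)) NULL else dim(diffs)[-1]

  t_crit <- if (tail == "two") qt(1 - threshold_p / 2, n - 1) else
    qt(1 - threshold_p, n - 1)
  # t statistics for arbitrary sign patterns need only the flipped mean:
  # squares are sign-invariant, so var = (q/n - m^2) * n/(n-1)
  q <- colSums(d^2)
  t_from_signs <- function(s) {
    m <- colMeans(s * d)
    v <- pmax(0, (q / n - m^2)) * n / (n - 1)
    ifelse(v > 0, m / sqrt(v / n), ifelse(m == 0, 0, sign(m) * BIG_T))
  }
  shape <- function(v) if (is.null(map_dim)) v else array(v, dim = map_dim)

  t_obs <- shape(t_from_signs(rep(1, n)))
  clusters <- form_clusters(t_obs, t_crit, tail, connectivity)

  exact <- n <= exact_n_max
  if (exact) {
    n_pat <- 2L^n
    null_max <- numeric(n_pat)
    for (i in seq_len(n_pat)) {
      bits <- as.integer(intToBits(i - 1L))[seq_len(n)]
      s <- 1 - 2 * bits
      null_max[i] <- max_cluster_stat(shape(t_from_signs(s)), t_crit, tail,
                                      connectivity)
    }
    n_eff <- n_pat
    p_fun <- function(stat) mean(null_max >= abs(stat) - 1e-12)
  } else {
    set.seed(seed)
    null_max <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      null_max[i] <- max_cluster_stat(shape(t_from_signs(s)), t_crit, tail,
                                      connectivity)
    }
    n_eff <- n_perm
    p_fun <- function(stat) (1 + sum(null_max >= abs(stat) - 1e-12)) / (1 + n_perm)
  }
  p_values <- vapply(clusters, function(c) p_fun(c$stat), numeric(1))
  new_cluster_result(clusters, p_values, t_obs, t_crit, null_max, n_eff,
                     exact, tail, connectivity)
}

#' Trial-level condition-shuffle cluster permutation test
#'
#' The same clustering machinery applied within a single electrode: the
#' pointwise statistic is an unpaired t between the two conditions across
#' trials, and the null permutes condition labels over trials (label counts
#' preserved, so no permutation can empty a condition).
#'
#' @param values trials x bins matrix (or trials x rows x cols array).
#' @param labels factor or vector with exactly two levels, one per trial.
#' @param n_perm permutation draws.
#' @param seed integer seed.
#' @param threshold_p pointwise cluster-forming p threshold.
#' @param tail,connectivity as in [signflip_cluster_test()].
#' @return a `cluster_result`.
#' @export
trialshuffle_cluster_test <- function(values, labels, n_perm = 1000, seed = 1,
                                      threshold_p = 0.05,
                                      tail = c("two", "pos", "neg"),
                                      connectivity = 4) {
  tail <- match.arg(tail)
  stop_if_not(threshold_p > 0 && threshold_p < 1, "threshold_p must be in (0, 1)")
  v <- if (is.matrix(values)) values else matrix(values, nrow = dim(values)[1])
  labels <- as.factor(labels)
  lv <- levels(labels)
  stop_if_not(length(lv) == 2, "labels must have exactly two levels")
  stop_if_not(min(table(labels)) >= 2, "need at least 2 trials per condition")
  map_dim <- if (is.matrix(values)) NULL else dim(values)[-1]
  shape <- function(x) if (is.null(map_dim)) x else array(x, dim = map_dim)

  ia <- labels == lv[1]
  n1 <- sum(ia); n2 <- sum(!ia)
  t_crit <- if (tail == "two") qt(1 - threshold_p / 2, n1 + n2 - 2) else
    qt(1 - threshold_p, n1 + n2 - 2)
  t_obs <- shape(unpaired_tstats(v[ia, , drop = FALSE],
                                 v[!ia, , drop = FALSE])$t)
  clusters <- form_clusters(t_obs, t_crit, tail, connectivity)

  set.seed(seed)
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pa <- sample(seq_len(n1 + n2), n1)
    sel <- seq_len(n1 + n2) %in% pa
    t_p <- shape(unpaired_tstats(v[sel, , drop = FALSE],
                                 v[!sel, , drop = FALSE])$t)
    null_max[i] <- max_cluster_stat(t_p, t_crit, tail, connectivity)
  }
  p_values <- vapply(clusters, function(c)
    (1 + sum(null_max >= abs(c$stat) - 1e-12)) / (1 + n_perm), numeric(1))
  new_cluster_result(clusters, p_values, t_obs, t_crit, null_max, n_perm,
                     FALSE, tail, connectivity)
}

#' Two-dimensional cluster test
#'
#' Convenience wrapper for time x time (reinstatement) and time x frequency
#' (coherence) maps: a participant-level sign-flip test on a stack of paired
#' difference maps (e.g. true minus shuffled reinstatement), with
#' 4-connected clusters.
#'
#' @param map_true,map_null participants x rows x cols arrays; `map_null`
#'   may be NULL if `map_true` already holds differences.
#' @param ... passed to [signflip_cluster_test()].
#' @return a `cluster_result`.
#' @export
cluster_2d <- function(map_true, map_null = NULL, ...) {
  stop_if_not(length(dim(map_true)) == 3, "expected participants x rows x cols")
  if (!is.null(map_null)) {
    stop_if_not(all(dim(map_true) == dim(map_null)), "dimension mismatch")
    map_true <- map_true - map_null
  }
  signflip_cluster_test(map_true, ...)
}
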