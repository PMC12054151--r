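# Sub-group (sub-species) structure: Ward clustering of genomes on a
# numeric feature matrix (gene-cluster frequencies, or the rows of a
# symmetrized ANI similarity matrix), with k selected by the gap statistic
# or inspected on a within-cluster sum-of-squares curve.

check_features <- function(features) {
  features <- as.matrix(features)
  if (!is.numeric(features) || anyNA(features)) {
    stop_input("feature matrix must be numeric with no missing values")
  }
  if (nrow(features) < 2L) {
    stop_input("feature matrix needs at least 2 rows (genomes)")
  }
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("row", seq_len(nrow(features)))
  }
  features
}

#' Ward clustering of genomes into k groups
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion on Euclidean distances (`hclust` method `ward.D2`, which
#' applies Ward's criterion to raw Euclidean distances), cut at k
#' clusters.
#'
#' @param features Numeric matrix, rows = genomes, columns = features.
#' @param k Number of clusters, 1 <= k <= nrow(features).
#' @return Named integer vector of cluster labels (1..k), one per row.
#' @export
ward_cluster <- function(features, k) {
  features <- check_features(features)
  n <- nrow(features)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    stop_input("k must lie in [1, %d]", n)
  }
  hc <- stats::hclust(stats::dist(features, method = "euclidean"),
                      method = "ward.D2")
  stats::cutree(hc, k = k)
}

# Total within-cluster sum of squared Euclidean deviations from centroids.
within_ss <- function(features, labels) {
  sum(vapply(split(seq_len(nrow(features)), labels), function(idx) {
    block <- features[idx, , drop = FALSE]
    sum(sweep(block, 2, colMeans(block))^2)
  }, numeric(1)))
}

#' Within-cluster sum-of-squares curve
#'
#' Total within-cluster sum of squares W_k of the Ward partition for each
#' k from 1 to `k_max`. W_k is non-increasing in k and reaches 0 at
#' k = number of rows; an elbow in the curve is the usual visual guide to
#' the number of sub-groups.
#'
#' @inheritParams ward_cluster
#' @param k_max Largest k to evaluate; must be < nrow(features).
#' @return data.frame with columns `k`, `wss`.
#' @export
wss_curve <- function(features, k_max) {
  features <- check_features(features)
  if (k_max < 1L || k_max >= nrow(features)) {
    stop_input("k_max must lie in [1, %d]", nrow(features) - 1L)
  }
  hc <- stats::hclust(stats::dist(features, method = "euclidean"),
                      method = "ward.D2")
  wss <- vapply(seq_len(k_max), function(k) {
    within_ss(features, stats::cutree(hc, k = k))
  }, numeric(1))
  data.frame(k = seq_len(k_max), wss = wss)
}

#' Optimal cluster number by the gap statistic
#'
#' Computes the gap statistic of Tibshirani, Walther and Hastie for Ward
#' partitions at k = 1..k_max: Gap(k) is the mean over `n_reference`
#' uniform reference data sets of log(W*_k) minus the observed log(W_k),
#' with references drawn uniformly over the observed per-feature range.
#' The optimal k is the smallest k with
#' Gap(k) >= Gap(k+1) - s_{k+1}, where s_k is the reference standard
#' deviation scaled by sqrt(1 + 1/B); when no k satisfies the rule, k_max
#' is returned.
#'
#' @inheritParams wss_curve
#' @param n_reference Number of uniform reference data sets (B); at
#'   least 10.
#' @param seed Integer seed; the computation is bit-for-bit reproducible
#'   for a fixed seed.
#' @return A list with `k` (the selected number of clusters) and `curve`,
#'   a data.frame with columns `k`, `log_w`, `log_w_ref`, `gap`, `se`.
#' @export
gap_statistic_k <- function(features, k_max, n_reference = 100, seed = 1L) {
  features <- check_features(features)
  if (k_max < 1L || k_max >= nrow(features)) {
    stop_input("k_max must lie in [1, %d]", nrow(features) - 1L)
  }
  if (n_reference < 10L) {
    stop_input("n_reference must be at least 10")
  }
  lo <- apply(features, 2, min)
  hi <- apply(features, 2, max)
  if (all(hi - lo == 0)) {
    stop_input("degenerate feature matrix: every feature has zero range")
  }
  n <- nrow(features)
  p <- ncol(features)

  log_w_of <- function(mat) {
    hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "ward.D2")
    vapply(seq_len(k_max), function(k) {
      w <- within_ss(mat, stats::cutree(hc, k = k))
      log(max(w, .Machine$double.xmin)) # guard k with W_k == 0
    }, numeric(1))
  }

  log_w <- log_w_of(features)
  log_w_ref <- with_seed(seed, {
    vapply(seq_len(n_reference), function(b) {
      ref <- matrix(stats::runif(n * p, rep(lo, each = n), rep(hi, each = n)),
                    nrow = n, ncol = p)
      log_w_of(ref)
    }, numeric(k_max))
  })
  log_w_ref <- matrix(log_w_ref, nrow = k_max)
  gap <- rowMeans(log_w_ref) - log_w
  sd_ref <- sqrt(rowMeans((log_w_ref - rowMeans(log_w_ref))^2))
  se <- sd_ref * sqrt(1 + 1 / n_reference)

  k_opt <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) {
      k_opt <- k
      break
    }
  }
  list(
    k = k_opt,
    curve = data.frame(
      k = seq_len(k_max), log_w = log_w, log_w_ref = rowMeans(log_w_ref),
      gap = gap, se = se
    )
  )
}
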