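#' Log transform and double centering
#'
#' The scaled-subprofile-model residual step: take the natural log of the
#' normalized data matrix, remove each subject's (row) mean, then remove each
#' voxel's (column) mean of the row-centered matrix. Both row and column
#' means of the result are exactly zero; any per-subject multiplicative
#' factor in the raw data and any additive voxel profile shared by all
#' subjects are fully absorbed.
#'
#' @param dm A normalized [vectorize()] data matrix with all in-mask values
#'   positive.
#' @param log_transform Apply the natural log before centering (default
#'   `TRUE`, the scaled-subprofile-model convention); `FALSE` double-centers
#'   the raw values for sensitivity checks.
#' @return An object of class `residual_matrix` with fields `values` (N x V,
#'   doubly centered), `group_profile` (V), `subject_offsets` (N), plus the
#'   voxel bookkeeping of `dm`.
#' @export
log_and_center <- function(dm, log_transform = TRUE) {
  stopifnot(inherits(dm, "data_matrix"))
  if (!isTRUE(dm$normalized))
    stop("data matrix must be globally normalized before centering")
  vals <- dm$values
  if (log_transform) {
    bad <- which(vals <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("nonpositive in-mask value for subject %d at voxel %d",
                   bad[1L, 1L], bad[1L, 2L]))
    vals <- log(vals)
  }
  cen <- double_center(vals)
  structure(
    list(values = cen$residuals, group_profile = cen$col_means,
         subject_offsets = cen$row_means, voxel_index = dm$voxel_index,
         voxel_linear = dm$voxel_linear, affine = dm$affine,
         grid_shape = dm$grid_shape, subject_ids = dm$subject_ids),
    class = "residual_matrix"
  )
}

# Row means first, then column means of the row-centered matrix; both means
# of the output are exactly zero (the reverse order yields the same matrix,
# this order is fixed so intermediates are reproducible).
double_center <- function(m) {
  rm_ <- rowMeans(m)
  m1 <- m - rm_
  cm_ <- colMeans(m1)
  list(residuals = sweep(m1, 2L, cm_), row_means = rm_, col_means = cm_)
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("<residual_matrix> %d subjects x %d voxels (doubly centered)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Covariant-pattern decomposition
#'
#' Thin singular value decomposition of the residual matrix,
#' `res = U S V'`. Component k's eigenimage is the k-th right singular
#' vector (unit norm, mean zero), its subject scaling factors are
#' `U[, k] * S[k]`, and its variance fraction is `S[k]^2 / sum(S^2)`.
#' Components are ordered by decreasing variance. Each component's sign is
#' fixed so the skewness of its voxel weights is nonnegative (falling back
#' to making the largest-magnitude weight positive when the weights are
#' symmetric), making the orientation deterministic and data driven.
#'
#' @param res A [log_and_center()] residual matrix with at least 3 subjects.
#' @return A list with `patterns` (list of `covariance_pattern`: fields `k`,
#'   `weights`, `variance_fraction`, `singular_value`, `zmap` initially
#'   `NULL`) and `ssf` (an `ssf_table`: `scores` N x K, `subject_ids`,
#'   `components`). All-zero residuals yield zero components.
#' @export
ssm_decompose <- function(res) {
  stopifnot(inherits(res, "residual_matrix"))
  n <- nrow(res$values)
  if (n < 3L) stop("at least 3 subjects are required for the decomposition")
  sv <- svd(res$values)
  tot <- sum(sv$d^2)
  if (tot == 0) {
    return(structure(list(
      patterns = list(),
      ssf = ssf_table(matrix(0, n, 0), res$subject_ids, integer(0)),
      total_ss = 0, voxel_index = res$voxel_index,
      voxel_linear = res$voxel_linear, affine = res$affine,
      grid_shape = res$grid_shape), class = "ssm_decomposition"))
  }
  keep <- which(sv$d > max(dim(res$values)) * .Machine$double.eps * sv$d[1L])
  patterns <- vector("list", length(keep))
  scores <- matrix(0, n, length(keep))
  for (idx in seq_along(keep)) {
    k <- keep[idx]
    w <- sv$v[, k]
    flip <- weight_orientation(w)
    w <- w * flip
    patterns[[idx]] <- structure(
      list(k = idx, weights = w, variance_fraction = sv$d[k]^2 / tot,
           singular_value = sv$d[k], zmap = NULL),
      class = "covariance_pattern")
    scores[, idx] <- sv$u[, k] * sv$d[k] * flip
  }
  structure(list(
    patterns = patterns,
    ssf = ssf_table(scores, res$subject_ids, seq_along(keep)),
    total_ss = tot, voxel_index = res$voxel_index,
    voxel_linear = res$voxel_linear, affine = res$affine,
    grid_shape = res$grid_shape), class = "ssm_decomposition")
}

# +1 / -1 so that the skewness of the weight vector is >= 0; symmetric
# weight vectors fall back to the sign of the largest-magnitude weight.
weight_orientation <- function(w) {
  wc <- w - mean(w)
  s2 <- mean(wc^2)
  if (s2 == 0) return(1)
  skew <- mean(wc^3) / s2^1.5
  if (abs(skew) > 1e-12) {
    if (skew >= 0) 1 else -1
  } else {
    if (w[which.max(abs(w))] >= 0) 1 else -1
  }
}

ssf_table <- function(scores, subject_ids, components) {
  rownames(scores) <- subject_ids
  structure(list(scores = scores, subject_ids = subject_ids,
                 components = components), class = "ssf_table")
}

#' @export
print.ssm_decomposition <- function(x, ...) {
  vf <- vapply(x$patterns, `[[`, numeric(1), "variance_fraction")
  cat(sprintf("<ssm_decomposition> %d components; variance fractions: %s\n",
              length(x$patterns),
              paste(sprintf("%.1f%%", 100 * vf[seq_len(min(6, length(vf)))]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.ssf_table <- function(x, ...) {
  cat(sprintf("<ssf_table> %d subjects x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Retain components above a variance threshold
#'
#' Keeps exactly the components whose variance fraction strictly exceeds the
#' threshold (default 10%), preserving order.
#'
#' @param patterns List of `covariance_pattern`, ordered by decreasing
#'   variance fraction.
#' @param threshold Variance-fraction cut (default 0.10).
#' @return The retained sub-list (possibly empty).
#' @export
retain_major <- function(patterns, threshold = 0.10) {
  vf <- vapply(patterns, `[[`, numeric(1), "variance_fraction")
  if (is.unsorted(rev(vf), strictly = FALSE))
    stop("patterns must be ordered by decreasing variance fraction")
  patterns[vf > threshold]
}

#' Z-score an eigenimage
#'
#' Standardizes the voxel weights over in-mask voxels using the population
#' (1/n) standard deviation, so the Z map is reproducible bit-for-bit. The
#' weights are mean zero by construction, so the Z map is
#' `weights / sd(weights)`.
#'
#' @param p A `covariance_pattern`.
#' @return The pattern with its `zmap` field filled (mean 0, sd 1).
#' @export
zscore_pattern <- function(p) {
  stopifnot(inherits(p, "covariance_pattern"))
  w <- p$weights
  if (length(w) < 2L) stop("Z-scoring needs at least 2 voxels")
  mu <- mean(w)
  sdp <- sqrt(mean((w - mu)^2))
  if (sdp == 0) stop("degenerate pattern: zero weight standard deviation")
  p$zmap <- (w - mu) / sdp
  p
}

#' Threshold a Z map into positive and negative voxel sets
#'
#' @param zmap Numeric voxel vector of Z values.
#' @param z Positive threshold; default 1.64, the standard normal upper-0.05
#'   quantile rounded to two decimals.
#' @return List with logical vectors `positive` (`zmap >= z`) and `negative`
#'   (`zmap <= -z`); the two are disjoint.
#' @export
threshold_zmap <- function(zmap, z = 1.64) {
  if (length(z) != 1L || is.na(z) || z <= 0) stop("`z` must be positive")
  list(positive = zmap >= z, negative = zmap <= -z)
}

#' Project a subject's log profile onto a fixed pattern
#'
#' Computes the subject scaling factor of a (possibly held-out) subject on a
#' previously derived eigenimage: the subject's log profile is centered by
#' its own mean, the training group profile is subtracted, and the residual
#' is projected onto the pattern weights. Projecting a training subject
#' reproduces its stored score.
#'
#' @param log_profile Length-V vector of the subject's log-transformed,
#'   globally normalized in-mask intensities.
#' @param group_profile Length-V training group profile (from
#'   [log_and_center()]).
#' @param pattern A `covariance_pattern`.
#' @return Scalar SSF score.
#' @export
project_subject <- function(log_profile, group_profile, pattern) {
  stopifnot(inherits(pattern, "covariance_pattern"))
  v <- length(pattern$weights)
  if (length(log_profile) != v || length(group_profile) != v)
    stop("profile lengths do not match the pattern voxel count")
  sum((log_profile - mean(log_profile) - group_profile) * pattern$weights)
}
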