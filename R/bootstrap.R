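#' Bootstrap configuration
#'
#' @param n_boot Number of replicates (>= 50 recommended for reported maps;
#'   smaller values are accepted for quick checks).
#' @param seed Integer seed; the whole resampling schedule is deterministic
#'   given the seed.
#' @param match_threshold Minimum |Pearson correlation| between a replicate
#'   component's weights and the target weights for the replicate to be
#'   accepted (default 0.5).
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 500L, seed = 1L, match_threshold = 0.5) {
  if (n_boot < 1L) stop("n_boot must be positive")
  if (match_threshold < 0 || match_threshold >= 1)
    stop("match_threshold must lie in [0, 1)")
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 match_threshold = match_threshold),
            class = "bootstrap_config")
}

#' Subject-resampling bootstrap stability map for one pattern
#'
#' For each replicate, N subjects are drawn with replacement (redrawn, not
#' counted, if fewer than 3 distinct subjects appear), the log transform and
#' double centering are recomputed on the resample (the group profile changes
#' with the resample), and the residuals are re-decomposed. The replicate
#' component whose weights have the largest |Pearson correlation| with the
#' target pattern is selected; replicates whose best match falls below
#' `match_threshold` are rejected, otherwise the matched weights are
#' sign-aligned to the target and accumulated. The per-voxel stability
#' statistic is the mean over accepted replicates divided by the sample
#' standard deviation over accepted replicates (an inverse coefficient of
#' variation Z).
#'
#' Voxels whose replicate weights are exactly constant and nonzero have no
#' numeric Z; they are flagged in the `stable` field instead (and treated as
#' suprathreshold by [significant_voxels()]).
#'
#' @param dm The normalized [vectorize()] data matrix the target pattern was
#'   derived from.
#' @param target A `covariance_pattern` from [ssm_decompose()] on `dm`'s
#'   residuals.
#' @param cfg A [bootstrap_config()].
#' @param log_transform Passed through to the within-replicate centering.
#' @return An object of class `stability_map` with fields `z_stab` (V),
#'   `mean_w`, `sd_w`, `stable` (logical V), `n_accepted`, `n_rejected`
#'   (`n_accepted + n_rejected == n_boot`), plus voxel bookkeeping.
#' @export
bootstrap_pattern <- function(dm, target, cfg = bootstrap_config(),
                              log_transform = TRUE) {
  stopifnot(inherits(dm, "data_matrix"), inherits(target, "covariance_pattern"),
            inherits(cfg, "bootstrap_config"))
  n <- nrow(dm$values)
  v <- ncol(dm$values)
  if (length(target$weights) != v)
    stop("target pattern voxel count does not match the data matrix")
  vals <- if (log_transform) {
    if (any(dm$values <= 0)) stop("nonpositive in-mask value; cannot log")
    log(dm$values)
  } else dm$values
  tw <- target$weights
  tw_c <- tw - mean(tw)
  tw_n <- sqrt(sum(tw_c^2))

  set.seed(cfg$seed)
  sum_w <- numeric(v)
  sum_w2 <- numeric(v)
  n_acc <- 0L
  n_rej <- 0L
  for (b in seq_len(cfg$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 3L) break
    }
    resid <- double_center(vals[idx, , drop = FALSE])$residuals
    sv <- svd(resid, nu = 0L)
    keep <- sv$d > max(dim(resid)) * .Machine$double.eps * max(sv$d[1L], 0)
    if (!any(keep)) { n_rej <- n_rej + 1L; next }
    vmat <- sv$v[, keep, drop = FALSE]
    # columns of V are mean-zero unit vectors (residuals are doubly
    # centered), so Pearson correlation reduces to a dot product
    cors <- drop(crossprod(vmat, tw_c)) / tw_n
    kb <- which.max(abs(cors))
    if (abs(cors[kb]) < cfg$match_threshold) { n_rej <- n_rej + 1L; next }
    wb <- sign(cors[kb]) * vmat[, kb]
    sum_w <- sum_w + wb
    sum_w2 <- sum_w2 + wb^2
    n_acc <- n_acc + 1L
  }
  if (n_acc == 0L)
    stop("all bootstrap replicates were rejected; lower match_threshold or check the pattern")
  mean_w <- sum_w / n_acc
  var_w <- if (n_acc > 1L) pmax(0, (sum_w2 - n_acc * mean_w^2) / (n_acc - 1L))
           else rep(0, v)
  sd_w <- sqrt(var_w)
  # zero replicate variability is judged relative to the weight scale, so
  # that SVD round-off jitter on a deterministic pattern still reads as
  # "stable" rather than as an astronomically large Z
  tol <- 1e-6 * sqrt(mean(mean_w^2))
  stable <- sd_w <= tol & abs(mean_w) > tol
  z <- ifelse(sd_w > tol, mean_w / sd_w, ifelse(stable, NA_real_, 0))
  structure(list(
    z_stab = z, mean_w = mean_w, sd_w = sd_w, stable = stable,
    n_accepted = n_acc, n_rejected = n_rej, n_boot = cfg$n_boot,
    voxel_index = dm$voxel_index, voxel_linear = dm$voxel_linear,
    affine = dm$affine, grid_shape = dm$grid_shape),
    class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  cat(sprintf("<stability_map> %d voxels; %d/%d replicates accepted\n",
              length(x$z_stab), x$n_accepted, x$n_boot))
  invisible(x)
}

#' Threshold a stability map into positive and negative voxel sets
#'
#' Same contract as [threshold_zmap()] applied to the stability Z; voxels
#' flagged `stable` (zero replicate variability with a nonzero mean) count
#' as suprathreshold on the side of their mean.
#'
#' @param stab A [bootstrap_pattern()] stability map.
#' @param z Positive threshold (default 1.64).
#' @return List of logical vectors `positive` and `negative` (disjoint).
#' @export
significant_voxels <- function(stab, z = 1.64) {
  stopifnot(inherits(stab, "stability_map"))
  if (length(z) != 1L || is.na(z) || z <= 0) stop("`z` must be positive")
  zs <- stab$z_stab
  pos <- (!is.na(zs) & zs >= z) | (stab$stable & stab$mean_w > 0)
  neg <- (!is.na(zs) & zs <= -z) | (stab$stable & stab$mean_w < 0)
  list(positive = pos, negative = neg)
}

#' Connected suprathreshold clusters
#'
#' Labels connected components of a binary 3D map (breadth-first search
#' under the chosen voxel connectivity), drops components smaller than
#' `min_size`, and reports each surviving cluster with its peak: the voxel
#' of maximum |value|, ties resolved by canonical (ascending linear) index.
#' Clusters are sorted by size descending, then peak |value| descending,
#' then canonical peak index.
#'
#' @param binary_map Logical 3D array of suprathreshold voxels.
#' @param values Numeric 3D array of the statistic (e.g. stability Z) on the
#'   same grid; `NA` entries are treated as infinitely strong (sentinel
#'   "stable" voxels).
#' @param min_size Minimum cluster extent in voxels (default 10).
#' @param connectivity `"face"` (6 neighbours, default), `"face-edge"` (18)
#'   or `"face-edge-corner"` (26).
#' @param affine Optional 4x4 affine; when given, each cluster also carries
#'   `peak_mm`.
#' @param sign Optional `"positive"`/`"negative"` label stored on each
#'   cluster; default derives the label from the peak value's sign.
#' @return List of `cluster` objects with fields `voxels` (m x 3, 1-based),
#'   `size`, `sign`, `peak_voxel`, `peak_mm` (or `NULL`), `peak_value`.
#' @export
extract_clusters <- function(binary_map, values, min_size = 10L,
                             connectivity = c("face", "face-edge",
                                              "face-edge-corner"),
                             affine = NULL, sign = NULL) {
  connectivity <- match.arg(connectivity)
  d <- dim(binary_map)
  if (length(d) != 3L || !all(d == dim(values)))
    stop("binary map and values must be 3D arrays on the same grid")
  offsets <- connectivity_offsets(connectivity)
  inmap <- which(binary_map)
  if (!length(inmap)) return(list())
  labels <- array(0L, dim = d)
  comp <- 0L
  members <- list()
  queue <- integer(length(inmap))
  for (start in inmap) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    labels[start] <- comp
    queue[1L] <- start
    qlo <- 1L; qhi <- 1L
    while (qlo <= qhi) {
      cur <- queue[qlo]; qlo <- qlo + 1L
      ci <- arrayInd(cur, d)
      for (o in seq_len(nrow(offsets))) {
        nb <- ci + offsets[o, ]
        if (any(nb < 1L) || any(nb > d)) next
        nl <- nb[1L] + (nb[2L] - 1L) * d[1L] + (nb[3L] - 1L) * d[1L] * d[2L]
        if (binary_map[nl] && labels[nl] == 0L) {
          labels[nl] <- comp
          qhi <- qhi + 1L
          queue[qhi] <- nl
        }
      }
    }
    members[[comp]] <- sort(queue[seq_len(qhi)])
  }
  clusters <- list()
  for (m in members) {
    if (length(m) < min_size) next
    vals <- values[m]
    mag <- abs(vals)
    mag[is.na(mag)] <- Inf  # sentinel "stable" voxels dominate
    peak_pos <- which(mag == max(mag))[1L]  # m is sorted: canonical tiebreak
    pk <- m[peak_pos]
    pk_ijk <- drop(arrayInd(pk, d))
    pv <- values[pk]
    lab <- if (!is.null(sign)) sign
           else if (is.na(pv) || pv >= 0) "positive" else "negative"
    clusters[[length(clusters) + 1L]] <- structure(list(
      voxels = arrayInd(m, d), size = length(m), sign = lab,
      peak_voxel = pk_ijk,
      peak_mm = if (is.null(affine)) NULL else voxel_to_mm(pk_ijk - 1L, affine),
      peak_value = pv, peak_linear = pk),
      class = "cluster")
  }
  if (!length(clusters)) return(clusters)
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  pmag <- vapply(clusters, function(cl)
    if (is.na(cl$peak_value)) Inf else abs(cl$peak_value), numeric(1))
  plin <- vapply(clusters, `[[`, numeric(1), "peak_linear")
  clusters[order(-sizes, -pmag, plin)]
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(connectivity,
    "face" = nz == 1,
    "face-edge" = nz >= 1 & nz <= 2,
    "face-edge-corner" = nz >= 1)
  unname(g[keep, , drop = FALSE])
}

#' Cluster table
#'
#' Flattens a cluster list into the reporting table written next to the
#' pattern maps.
#'
#' @param clusters List of `cluster` objects.
#' @return data.frame with columns sign, size, peak_i, peak_j, peak_k
#'   (1-based voxel indices), peak_x_mm, peak_y_mm, peak_z_mm, peak_z_stab.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(sign = character(0), size = integer(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_z_stab = numeric(0)))
  do.call(rbind, lapply(clusters, function(cl) {
    mm <- if (is.null(cl$peak_mm)) c(NA_real_, NA_real_, NA_real_) else cl$peak_mm
    data.frame(sign = cl$sign, size = cl$size,
               peak_i = cl$peak_voxel[1L], peak_j = cl$peak_voxel[2L],
               peak_k = cl$peak_voxel[3L],
               peak_x_mm = mm[1L], peak_y_mm = mm[2L], peak_z_mm = mm[3L],
               peak_z_stab = cl$peak_value)
  }))
}
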