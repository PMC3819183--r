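#' Isotropic Gaussian smoothing of a volume stack
#'
#' Convolves every subject's volume with a separable 3D Gaussian kernel of
#' the given full width at half maximum. The per-axis kernel standard
#' deviation in voxels is `fwhm / (sqrt(8 * log(2)) * voxel_size(axis))`.
#' Boundaries use nearest-edge replication, which preserves constant volumes
#' exactly and conserves the sum of interior blobs.
#'
#' @param stack A [volume_stack()].
#' @param fwhm Kernel full width at half maximum in mm; 0 is the identity.
#' @return A smoothed [volume_stack()].
#' @export
smooth_gaussian <- function(stack, fwhm) {
  stopifnot(inherits(stack, "volume_stack"))
  if (length(fwhm) != 1L || is.na(fwhm) || fwhm < 0)
    stop("`fwhm` must be a single nonnegative number (mm)")
  if (fwhm == 0) return(stack)
  vs <- axis_voxel_sizes(stack$affine)
  sigma_vox <- fwhm / (sqrt(8 * log(2)) * vs)
  d <- dim(stack$data)
  cmats <- lapply(1:3, function(a) gauss_conv_matrix(d[a], sigma_vox[a]))
  out <- stack$data
  for (s in seq_len(d[4L])) {
    vol <- out[, , , s]
    for (a in 1:3) vol <- apply_along_axis(vol, a, cmats[[a]])
    out[, , , s] <- vol
  }
  volume_stack(out, stack$affine, stack$subject_ids)
}

# Voxel sizes of an axis-aligned affine; oblique affines are rejected rather
# than approximated (a rotated grid would need a rotated kernel).
axis_voxel_sizes <- function(affine) {
  rot <- affine[1:3, 1:3]
  off <- rot; diag(off) <- 0
  if (max(abs(off)) > 1e-6 * max(abs(diag(rot))))
    stop("oblique affine: smoothing requires an axis-aligned voxel grid")
  vs <- abs(diag(rot))
  if (any(vs <= 0)) stop("affine has a zero voxel size")
  vs
}

# Dense n x n convolution matrix for a 1D Gaussian, truncated at 4 sigma,
# with out-of-range taps clamped to the edge (replicate padding). Rows sum
# to 1 exactly.
gauss_conv_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  cm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-r:r), 1L), n)
    for (t in seq_along(j)) cm[i, j[t]] <- cm[i, j[t]] + k[t]
  }
  cm
}

apply_along_axis <- function(vol, axis, cm) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- cm %*% matrix(v, nrow = d[axis])
  v <- array(m, dim = d[perm])
  aperm(v, order(perm))
}

#' Global-mean intensity normalization
#'
#' Scales each subject's volume to its own mean in-mask ("whole-brain")
#' uptake, so that every subject's in-mask mean becomes exactly 1. Voxels
#' outside the mask never enter the mean. Idempotent.
#'
#' @param stack A [volume_stack()].
#' @param mask A [brain_mask()] on the same grid.
#' @return A normalized [volume_stack()] with attribute `normalized = TRUE`.
#' @export
normalize_global <- function(stack, mask) {
  check_grid_match(stack, mask)
  idx <- which(mask$grid)
  out <- stack$data
  for (s in seq_len(n_subjects(stack))) {
    vol <- out[, , , s]
    m <- mean(vol[idx])
    if (!is.finite(m) || m <= 0)
      stop(sprintf("subject '%s' has nonpositive in-mask mean (%g)",
                   stack$subject_ids[s], m))
    out[, , , s] <- vol / m
  }
  res <- volume_stack(out, stack$affine, stack$subject_ids)
  attr(res, "normalized") <- TRUE
  res
}

check_grid_match <- function(stack, mask) {
  stopifnot(inherits(stack, "volume_stack"), inherits(mask, "brain_mask"))
  if (!all(grid_shape(stack) == dim(mask$grid)))
    stop("stack and mask grid shapes differ")
  if (max(abs(stack$affine - mask$affine)) > 1e-4)
    stop("stack and mask affines differ by more than 1e-4 mm")
  invisible(TRUE)
}

#' Subjects-by-voxels data matrix
#'
#' Extracts in-mask intensities into an N x V matrix in canonical voxel
#' order (ascending linear array index, first axis fastest). Round-trips
#' losslessly with [devectorize()] for in-mask voxels.
#'
#' @param stack A [volume_stack()].
#' @param mask A [brain_mask()] on the same grid.
#' @return An object of class `data_matrix` with fields `values` (N x V),
#'   `voxel_index` (V x 3, 1-based), `voxel_linear`, `affine`, `grid_shape`,
#'   `subject_ids` and `normalized`.
#' @export
vectorize <- function(stack, mask) {
  check_grid_match(stack, mask)
  lin <- which(mask$grid)
  vi <- arrayInd(lin, dim(mask$grid))
  n <- n_subjects(stack)
  vals <- matrix(0, n, length(lin))
  for (s in seq_len(n)) vals[s, ] <- stack$data[, , , s][lin]
  rownames(vals) <- stack$subject_ids
  structure(
    list(values = vals, voxel_index = vi, voxel_linear = lin,
         affine = stack$affine, grid_shape = dim(mask$grid),
         subject_ids = stack$subject_ids,
         normalized = isTRUE(attr(stack, "normalized"))),
    class = "data_matrix"
  )
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d subjects x %d in-mask voxels%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) " (globally normalized)" else ""))
  invisible(x)
}

#' Scatter a voxel vector back into a 3D map
#'
#' Inverse of one row of [vectorize()]: in-mask voxels receive the vector
#' values in canonical order, all others the fill value.
#'
#' @param vector Numeric vector of length `sum(mask$grid)`.
#' @param mask A [brain_mask()].
#' @param fill Value assigned outside the mask (default 0).
#' @return 3D numeric array on the mask grid.
#' @export
devectorize <- function(vector, mask, fill = 0) {
  stopifnot(inherits(mask, "brain_mask"))
  lin <- which(mask$grid)
  if (length(vector) != length(lin))
    stop(sprintf("vector length %d does not match mask voxel count %d",
                 length(vector), length(lin)))
  out <- array(fill, dim = dim(mask$grid))
  out[lin] <- vector
  out
}
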