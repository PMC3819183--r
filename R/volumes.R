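#' Multi-subject volume stack
#'
#' Bundle N co-registered nonnegative 3D intensity volumes sharing one grid
#' and one voxel-to-mm affine.
#'
#' @param data Numeric 4D array, dimensions `c(nx, ny, nz, n_subjects)`, all
#'   values nonnegative.
#' @param affine 4x4 voxel-to-mm matrix (NIfTI convention: maps zero-based
#'   voxel indices to mm).
#' @param subject_ids Character vector of length `n_subjects`.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, affine, subject_ids = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, subject)")
  if (any(data < 0, na.rm = TRUE))
    stop("volume intensities must be nonnegative")
  affine <- check_affine(affine)
  n <- dim(data)[4L]
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(n))
  if (length(subject_ids) != n)
    stop("`subject_ids` must have one entry per subject")
  structure(
    list(data = data, affine = affine, subject_ids = as.character(subject_ids)),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %d subjects on a %d x %d x %d grid\n",
              d[4L], d[1L], d[2L], d[3L]))
  invisible(x)
}

n_subjects <- function(stack) dim(stack$data)[4L]
grid_shape <- function(stack) dim(stack$data)[1:3]

#' Binary brain mask
#'
#' @param grid Logical 3D array marking in-brain voxels.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param min_voxels Minimum number of TRUE voxels required (default 100,
#'   relaxed in unit tests through this argument).
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(grid, affine, min_voxels = 100L) {
  if (length(dim(grid)) != 3L) stop("mask grid must be a 3D array")
  grid <- array(as.logical(grid), dim = dim(grid))
  if (anyNA(grid)) stop("mask grid must not contain NA")
  nv <- sum(grid)
  if (nv < min_voxels)
    stop(sprintf("mask has %d voxels; at least %d required", nv, min_voxels))
  affine <- check_affine(affine)
  structure(list(grid = grid, affine = affine, n_voxels = nv),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<brain_mask> %d / %d voxels on a %d x %d x %d grid\n",
              x$n_voxels, prod(d), d[1L], d[2L], d[3L]))
  invisible(x)
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  storage.mode(affine) <- "double"
  affine
}

#' Build a simple axis-aligned affine
#'
#' Diagonal voxel scaling plus a translation, in the NIfTI zero-based index
#' convention.
#'
#' @param voxel_size Voxel edge length(s) in mm (length 1 or 3).
#' @param origin mm coordinate of voxel (0, 0, 0); defaults to placing the
#'   grid center at the origin when `grid_shape` is given.
#' @param grid_shape Optional voxel grid dimensions used to center the origin.
#' @return 4x4 affine matrix.
#' @export
make_affine <- function(voxel_size, origin = NULL, grid_shape = NULL) {
  vs <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(origin)) {
    origin <- if (is.null(grid_shape)) c(0, 0, 0)
              else -vs * (grid_shape - 1) / 2
  }
  aff <- diag(c(vs, 1))
  aff[1:3, 4] <- origin
  aff
}

#' Ellipsoidal brain mask phantom
#'
#' Build a centered ellipsoid mask on a regular grid: voxel (i, j, k) is in
#' the mask when `sum(((index - center) * voxel_size / semi_axes)^2) <= 1`,
#' with the center at the grid midpoint.
#'
#' @param grid_shape Integer voxel triple.
#' @param semi_axes Ellipsoid semi-axes in mm (length 3).
#' @param voxel_size Voxel edge length in mm (scalar or length 3).
#' @param allow_partial If `FALSE` (default) an ellipsoid extending beyond
#'   the grid is an error naming the offending axis; if `TRUE` the mask is
#'   silently truncated at the grid boundary.
#' @param min_voxels Passed to [brain_mask()].
#' @return A [brain_mask()].
#' @export
make_ellipsoid_mask <- function(grid_shape, semi_axes, voxel_size,
                                allow_partial = FALSE, min_voxels = 100L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three positive integers")
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  vs <- rep_len(as.numeric(voxel_size), 3L)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (!allow_partial) {
    half_extent <- vs * (grid_shape - 1) / 2
    bad <- which(semi_axes > half_extent + 1e-9)
    if (length(bad))
      stop(sprintf("ellipsoid exceeds the grid along axis %s (semi-axis %g mm > half-extent %g mm)",
                   c("x", "y", "z")[bad[1L]], semi_axes[bad[1L]],
                   half_extent[bad[1L]]))
  }
  center <- (grid_shape + 1) / 2
  ax <- ((seq_len(grid_shape[1L]) - center[1L]) * vs[1L] / semi_axes[1L])^2
  ay <- ((seq_len(grid_shape[2L]) - center[2L]) * vs[2L] / semi_axes[2L])^2
  az <- ((seq_len(grid_shape[3L]) - center[3L]) * vs[3L] / semi_axes[3L])^2
  d2 <- outer(outer(ax, ay, `+`), az, `+`)
  brain_mask(d2 <= 1, make_affine(vs, grid_shape = grid_shape),
             min_voxels = min_voxels)
}

#' Map voxel indices to mm coordinates
#'
#' Applies the homogeneous affine product to zero-based voxel indices, the
#' NIfTI convention. R-side 1-based array indices must be decremented by the
#' caller (cluster reporting does this internally).
#'
#' @param index Numeric length-3 vector or m x 3 matrix of zero-based voxel
#'   indices.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return mm coordinates, same shape as `index`.
#' @export
voxel_to_mm <- function(index, affine) {
  affine <- check_affine(affine)
  if (is.null(dim(index))) {
    drop(affine %*% c(as.numeric(index), 1))[1:3]
  } else {
    ix <- cbind(as.matrix(index), 1)
    t(affine %*% t(ix))[, 1:3, drop = FALSE]
  }
}
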