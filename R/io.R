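#' Read co-registered NIfTI volumes into a stack
#'
#' Files are read in sorted-name order. All volumes must share the grid
#' shape exactly and the affine to within 1e-4 mm.
#'
#' @param paths Character vector of at least 3 NIfTI-1 file paths.
#' @return A [volume_stack()]; subject ids are file names without
#'   extensions.
#' @export
read_volumes <- function(paths) {
  if (length(paths) < 3L) stop("at least 3 subject volumes are required")
  paths <- sort(paths, method = "radix")
  imgs <- lapply(paths, RNifti::readNifti)
  d0 <- dim(imgs[[1L]])
  if (length(d0) != 3L)
    stop(sprintf("'%s' is not a 3D volume", paths[1L]))
  a0 <- unclass(RNifti::xform(imgs[[1L]]))
  for (i in seq_along(imgs)[-1L]) {
    if (!identical(dim(imgs[[i]]), d0))
      stop(sprintf("grid shape of '%s' differs from '%s'",
                   paths[i], paths[1L]))
    ai <- unclass(RNifti::xform(imgs[[i]]))
    if (max(abs(ai - a0)) > 1e-4)
      stop(sprintf("affine of '%s' differs from '%s' by more than 1e-4 mm",
                   paths[i], paths[1L]))
  }
  data <- array(0, dim = c(d0, length(imgs)))
  for (i in seq_along(imgs)) data[, , , i] <- as.array(imgs[[i]])
  ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  volume_stack(data, a0, ids)
}

#' Read a NIfTI mask
#'
#' @param path NIfTI-1 file; nonzero voxels are in-mask.
#' @param min_voxels Passed to [brain_mask()].
#' @return A [brain_mask()].
#' @export
read_mask <- function(path, min_voxels = 100L) {
  img <- RNifti::readNifti(path)
  brain_mask(as.array(img) != 0, unclass(RNifti::xform(img)),
             min_voxels = min_voxels)
}

#' Write a 3D array as NIfTI-1
#'
#' @param vol 3D numeric array.
#' @param affine 4x4 voxel-to-mm matrix, stored as the sform.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(check_affine(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write eigenimage, Z and stability maps plus the cluster table
#'
#' Devectorizes the pattern's weights, Z map and (optionally) stability Z
#' onto the mask grid and writes them as NIfTI-1 volumes, together with the
#' thresholded positive/negative masks and a TSV cluster table. Out-of-mask
#' voxels are 0.
#'
#' @param pattern A `covariance_pattern` (Z-scored via [zscore_pattern()]
#'   if its `zmap` is still `NULL`).
#' @param stab Optional [bootstrap_pattern()] stability map.
#' @param mask The [brain_mask()] the analysis ran on.
#' @param affine 4x4 affine for the output volumes.
#' @param outdir Output directory (created if missing).
#' @param z Threshold for the +/- masks and cluster extraction (default
#'   1.64).
#' @param min_size Minimum cluster extent (default 10).
#' @param connectivity Cluster connectivity (default `"face"`).
#' @param prefix File-name prefix (default `"pci<k>"`).
#' @return Invisibly, a named character vector of files written.
#' @export
write_pattern_maps <- function(pattern, stab = NULL, mask, affine, outdir,
                               z = 1.64, min_size = 10L,
                               connectivity = "face", prefix = NULL) {
  stopifnot(inherits(pattern, "covariance_pattern"), inherits(mask, "brain_mask"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(prefix)) prefix <- sprintf("pci%d", pattern$k)
  if (is.null(pattern$zmap)) pattern <- zscore_pattern(pattern)
  files <- c(
    weights = file.path(outdir, paste0(prefix, "_weights.nii.gz")),
    zmap = file.path(outdir, paste0(prefix, "_zmap.nii.gz")),
    pos = file.path(outdir, paste0(prefix, "_pos_mask.nii.gz")),
    neg = file.path(outdir, paste0(prefix, "_neg_mask.nii.gz")),
    clusters = file.path(outdir, paste0(prefix, "_clusters.tsv")))
  write_volume(devectorize(pattern$weights, mask), affine, files[["weights"]])
  write_volume(devectorize(pattern$zmap, mask), affine, files[["zmap"]])
  if (!is.null(stab)) {
    files[["z_stab"]] <- file.path(outdir, paste0(prefix, "_zstab.nii.gz"))
    zvol <- devectorize(ifelse(is.na(stab$z_stab), 0, stab$z_stab), mask)
    write_volume(zvol, affine, files[["z_stab"]])
    thr <- significant_voxels(stab, z = z)
    stat_vec <- stab$z_stab
  } else {
    thr <- threshold_zmap(pattern$zmap, z = z)
    stat_vec <- pattern$zmap
  }
  write_volume(devectorize(as.numeric(thr$positive), mask), affine,
               files[["pos"]])
  write_volume(devectorize(as.numeric(thr$negative), mask), affine,
               files[["neg"]])
  stat_vol <- devectorize(stat_vec, mask, fill = 0)
  cl <- c(
    extract_clusters(devectorize(thr$positive, mask, fill = FALSE) > 0,
                     stat_vol, min_size = min_size,
                     connectivity = connectivity, affine = affine,
                     sign = "positive"),
    extract_clusters(devectorize(thr$negative, mask, fill = FALSE) > 0,
                     stat_vol, min_size = min_size,
                     connectivity = connectivity, affine = affine,
                     sign = "negative"))
  utils::write.table(cluster_table(cl), files[["clusters"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(files)
}
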