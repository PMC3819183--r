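# Small in-code fixtures shared across test files.

# Minimal data_matrix around an explicit N x V value matrix (bookkeeping
# fields filled with a flat dummy grid), for unit tests of the matrix
# algebra that do not need real volumes.
make_dm <- function(values, normalized = TRUE) {
  v <- ncol(values)
  structure(list(
    values = values,
    voxel_index = cbind(seq_len(v), 1L, 1L),
    voxel_linear = seq_len(v),
    affine = diag(4),
    grid_shape = c(v, 1L, 1L),
    subject_ids = sprintf("sub-%03d", seq_len(nrow(values))),
    normalized = normalized),
    class = "data_matrix")
}

# Small phantom cohort configuration: ~670-voxel ellipsoid mask, quick to
# simulate and decompose.
small_sim_config <- function(seed = 1L, n_subjects = 20L, ...) {
  sim_config(n_subjects = n_subjects, grid_shape = c(15L, 13L, 11L),
             voxel_size = 4, mask_semi_axes = c(26, 22, 18),
             seed = seed, ...)
}

# Decompose a simulated cohort without smoothing: normalize -> vectorize ->
# log + double centering -> SVD.
decompose_sim <- function(sim) {
  dm <- vectorize(normalize_global(sim$stack, sim$mask), sim$mask)
  list(dm = dm, res = log_and_center(dm), dec = ssm_decompose(log_and_center(dm)))
}

# Best-matching estimated component for a true pattern (row of
# truth$patterns), by |correlation| of voxel weights.
match_component <- function(dec, true_pattern) {
  cors <- vapply(dec$patterns, function(p) stats::cor(p$weights, true_pattern),
                 numeric(1))
  k <- which.max(abs(cors))
  list(k = k, cor = cors[k], pattern = dec$patterns[[k]],
       ssf = dec$ssf$scores[, k] * sign(cors[k]))
}

# mm distance from every in-mask voxel to a set of bump centers (1-based
# voxel triples); returns the minimum distance per voxel.
min_bump_distance <- function(mask, centers, voxel_size) {
  vi <- arrayInd(which(mask$grid), dim(mask$grid))
  vs <- rep_len(voxel_size, 3L)
  d <- matrix(Inf, nrow(vi), nrow(centers))
  for (b in seq_len(nrow(centers)))
    d[, b] <- sqrt(colSums((t(vi) - centers[b, ])^2 * vs^2))
  apply(d, 1L, min)
}

# Independent connected-component oracle: iterative minimum-label
# propagation over shifted copies of the label array (a different algorithm
# from the BFS used by extract_clusters). Returns an integer label array.
label_components_oracle <- function(binary_map, connectivity = "face") {
  d <- dim(binary_map)
  labels <- array(0L, dim = d)
  labels[binary_map] <- seq_len(sum(binary_map))
  offs <- ssmpca:::connectivity_offsets(connectivity)
  repeat {
    changed <- FALSE
    for (o in seq_len(nrow(offs))) {
      sh <- shift_array(labels, offs[o, ])
      upd <- binary_map & sh > 0L & (labels == 0L | sh < labels)
      if (any(upd)) { labels[upd] <- sh[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  labels
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0L, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) { dst[[ax]] <- seq_len(d[ax] - o) + o; src[[ax]] <- seq_len(d[ax] - o) }
    else { dst[[ax]] <- seq_len(d[ax] + o); src[[ax]] <- seq_len(d[ax] + o) - o }
    if (!length(dst[[ax]])) return(out)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Partition of a label array into sorted member lists, for comparing two
# labelings up to renaming.
partition_of <- function(labels) {
  m <- split(which(labels > 0L), labels[labels > 0L])
  unname(m[order(vapply(m, min, numeric(1)))])
}
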