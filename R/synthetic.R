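#' Spatial pattern specification
#'
#' One covariant spatial pattern described as a sum of isotropic Gaussian
#' bumps; the generator later mean-removes, orthogonalizes and unit-norms
#' the summed field so PCA can recover it exactly.
#'
#' @param centers m x 3 matrix (or length-3 vector) of 1-based voxel index
#'   triples, one row per bump; every center must fall inside the mask.
#' @param radii Bump standard deviations in mm (length m, recycled).
#' @param amplitudes Signed unitless bump heights (length m, recycled).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(centers, radii, amplitudes) {
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1L)
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L || nrow(centers) < 1L)
    stop("`centers` must be an m x 3 matrix with at least one row")
  m <- nrow(centers)
  radii <- rep_len(as.numeric(radii), m)
  amplitudes <- rep_len(as.numeric(amplitudes), m)
  if (any(radii <= 0)) stop("bump radii must be positive")
  structure(list(centers = centers, radii = radii, amplitudes = amplitudes),
            class = "pattern_spec")
}

#' Simulation configuration
#'
#' Generative model for one synthetic cohort: subject i's in-mask intensity
#' at voxel v is
#' `c_i * exp(m_v + g_i + sum_k s_ik * p_kv + eps_iv)`,
#' with `m` a fixed smooth group profile, `g_i ~ N(0, global_offset_sd)` a
#' subject global offset, `s_ik ~ N(0, ssf_sd[k])` pattern scores (score 2
#' shifted by `-chei_ssf_shift` in subjects on a cholinesterase inhibitor),
#' `eps ~ N(0, noise_sd)` voxel noise, and `c_i ~ U(subject_scale_range)` a
#' per-subject multiplicative scanner factor. The clinical fluctuation
#' outcome is `caf_i = caf_intercept + clinical_beta * s_i2 +
#' clinical_direct_beta * chei_i + N(0, clinical_noise_sd)`; the default
#' `clinical_direct_beta = 0` makes medication act on the outcome only
#' through the pattern score (full mediation), a positive value adds a
#' direct effect for negative-control experiments.
#'
#' @param n_subjects Cohort size (>= 4).
#' @param grid_shape Voxel grid triple.
#' @param voxel_size Voxel edge in mm.
#' @param mask_semi_axes Ellipsoid mask semi-axes in mm.
#' @param pattern_specs List of [pattern_spec()] (default: two bilateral
#'   two-bump patterns).
#' @param ssf_sd Per-pattern score standard deviation.
#' @param noise_sd Voxel log-intensity noise sd.
#' @param global_offset_sd Subject global log offset sd.
#' @param subject_scale_range Multiplicative scanner-factor interval.
#' @param clinical_beta Outcome units per unit of score 2.
#' @param clinical_noise_sd Outcome noise sd.
#' @param clinical_direct_beta Direct medication effect on the outcome
#'   (default 0: full mediation).
#' @param caf_intercept Outcome intercept.
#' @param chei_prob Probability of medication use.
#' @param chei_ssf_shift Downward shift of score 2 under medication.
#' @param seed Integer seed; the whole cohort is drawn from one generator
#'   seeded once, so identical configs give bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 40L,
                       grid_shape = c(27L, 23L, 19L),
                       voxel_size = 4,
                       mask_semi_axes = c(48, 40, 32),
                       pattern_specs = NULL,
                       ssf_sd = c(3.5, 1.6),
                       noise_sd = 0.05,
                       global_offset_sd = 0.15,
                       subject_scale_range = c(0.8, 1.25),
                       clinical_beta = 3,
                       clinical_noise_sd = 7.5,
                       clinical_direct_beta = 0,
                       caf_intercept = 8,
                       chei_prob = 0.5,
                       chei_ssf_shift = 3,
                       seed = 1L) {
  if (n_subjects < 4L) stop("n_subjects must be at least 4")
  if (is.null(pattern_specs))
    pattern_specs <- default_pattern_specs(grid_shape)
  if (!length(pattern_specs)) stop("at least one pattern spec is required")
  if (any(c(ssf_sd, noise_sd, global_offset_sd, clinical_noise_sd) < 0))
    stop("standard deviations must be nonnegative")
  if (chei_prob < 0 || chei_prob > 1) stop("chei_prob must lie in [0, 1]")
  if (length(subject_scale_range) != 2L || any(subject_scale_range <= 0) ||
      diff(subject_scale_range) < 0)
    stop("subject_scale_range must be a positive increasing interval")
  ssf_sd <- rep_len(as.numeric(ssf_sd), length(pattern_specs))
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = as.integer(grid_shape),
    voxel_size = voxel_size, mask_semi_axes = mask_semi_axes,
    pattern_specs = pattern_specs, ssf_sd = ssf_sd, noise_sd = noise_sd,
    global_offset_sd = global_offset_sd,
    subject_scale_range = subject_scale_range,
    clinical_beta = clinical_beta, clinical_noise_sd = clinical_noise_sd,
    clinical_direct_beta = clinical_direct_beta,
    caf_intercept = caf_intercept, chei_prob = chei_prob,
    chei_ssf_shift = chei_ssf_shift, seed = as.integer(seed)),
    class = "sim_config")
}

# Two orthogonal-by-construction topographies: a deep "relative increase
# plus posterior decrease" pattern and a lateral left/right pattern, placed
# relative to the grid center so they scale with the grid. Bump amplitudes
# are volume-balanced (amplitude x radius^3 sums to zero within a pattern)
# so each bump sum integrates to ~0 and the mean-removal step leaves no
# diffuse offset: the embedded pattern is genuinely null away from the
# bumps.
default_pattern_specs <- function(grid_shape) {
  ctr <- round((grid_shape + 1) / 2)
  h <- (grid_shape - 1) / 2  # offsets scale with the grid half-extent
  off <- function(f) round(f * h)
  list(
    pattern_spec(rbind(ctr + off(c(0, 0, 0.12)), ctr + off(c(0, -0.55, 0.2))),
                 radii = c(12, 10), amplitudes = c(1, -(12 / 10)^3)),
    pattern_spec(rbind(ctr + off(c(0.5, 0.27, -0.2)),
                       ctr + off(c(-0.5, 0.27, -0.2))),
                 radii = c(10, 10), amplitudes = c(1, -1))
  )
}

#' Build orthonormal spatial patterns from bump specs
#'
#' Each spec's bump-sum field is restricted to the mask, mean-removed,
#' Gram-Schmidt-orthogonalized against all earlier patterns, and scaled to
#' unit norm, so the pattern set is exactly orthonormal over in-mask voxels
#' with exact zero voxel mean.
#'
#' @param mask A [brain_mask()].
#' @param specs List of [pattern_spec()].
#' @param voxel_size Voxel edge in mm.
#' @return K x V numeric matrix of pattern weights.
#' @export
make_patterns <- function(mask, specs, voxel_size) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!length(specs)) stop("at least one pattern spec is required")
  vs <- rep_len(as.numeric(voxel_size), 3L)
  vi <- arrayInd(which(mask$grid), dim(mask$grid))
  v <- nrow(vi)
  if (v <= length(specs))
    stop("mask must contain more voxels than there are patterns")
  pats <- matrix(0, length(specs), v)
  lin <- which(mask$grid)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    for (b in seq_len(nrow(sp$centers))) {
      cl <- lin_index(sp$centers[b, ], dim(mask$grid))
      if (is.na(cl) || !mask$grid[cl])
        stop(sprintf("pattern %d bump %d center is outside the mask", k, b))
    }
    f <- numeric(v)
    for (b in seq_len(nrow(sp$centers))) {
      d2 <- colSums((t(vi) - sp$centers[b, ])^2 * vs^2)
      f <- f + sp$amplitudes[b] * exp(-d2 / (2 * sp$radii[b]^2))
    }
    f <- f - mean(f)
    if (k > 1L)
      for (j in seq_len(k - 1L)) f <- f - sum(f * pats[j, ]) * pats[j, ]
    f <- f - mean(f)  # earlier patterns are mean-zero, kept exact
    nrm <- sqrt(sum(f^2))
    if (nrm < 1e-10)
      stop(sprintf("pattern %d is numerically zero after orthogonalization (specs too collinear)", k))
    pats[k, ] <- f / nrm
  }
  pats
}

lin_index <- function(ijk, d) {
  if (any(ijk < 1L) || any(ijk > d)) return(NA_integer_)
  as.integer(ijk[1L] + (ijk[2L] - 1L) * d[1L] + (ijk[3L] - 1L) * d[1L] * d[2L])
}

#' Simulate a phantom perfusion cohort with known ground truth
#'
#' Draws a full multi-subject cohort from the generative model of
#' [sim_config()]: volumes with embedded orthonormal covariant patterns,
#' a clinical table whose fluctuation outcome is a linear function of the
#' score on pattern 2 (the "cognitive-motor" component), and a medication
#' indicator that shifts that score, giving a known full-mediation pathway.
#'
#' @param config A [sim_config()].
#' @return List with `stack` ([volume_stack()]), `mask` ([brain_mask()]),
#'   `clinical` (data.frame: subject_id, group, caf, crt_ms, crt_sd_ms,
#'   mmse, camcog, updrs3, bradykinesia, age, sex, duration_yr, chei) and
#'   `truth` (class `ground_truth`: `patterns` K x V, `true_ssf` N x K,
#'   `group_profile`, `clinical_coefficients`, `pattern_specs`,
#'   `mediator_component`, plus the realized `chei`, `global_offsets` and
#'   `subject_scales`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mask <- make_ellipsoid_mask(config$grid_shape, config$mask_semi_axes,
                              config$voxel_size)
  pats <- make_patterns(mask, config$pattern_specs, config$voxel_size)
  k <- nrow(pats)
  v <- ncol(pats)
  n <- config$n_subjects
  mk <- min(2L, k)  # component carrying the clinical signal

  # fixed smooth group profile: perfusion-like, higher toward the center
  vi <- arrayInd(which(mask$grid), dim(mask$grid))
  ctr <- (config$grid_shape + 1) / 2
  rho2 <- colSums(((t(vi) - ctr) * config$voxel_size / config$mask_semi_axes)^2)
  group_profile <- log(60 * (1 - 0.3 * pmin(rho2, 1)))

  g <- stats::rnorm(n, 0, config$global_offset_sd)
  s <- matrix(stats::rnorm(n * k), n, k) %*% diag(config$ssf_sd, k)
  chei <- stats::rbinom(n, 1L, config$chei_prob)
  s[, mk] <- s[, mk] - config$chei_ssf_shift * chei
  ci <- stats::runif(n, config$subject_scale_range[1L],
                     config$subject_scale_range[2L])

  lin <- which(mask$grid)
  data <- array(0, dim = c(config$grid_shape, n))
  for (i in seq_len(n)) {
    eps <- stats::rnorm(v, 0, config$noise_sd)
    logint <- group_profile + g[i] + drop(s[i, , drop = FALSE] %*% pats) + eps
    vol <- array(0, dim = config$grid_shape)
    vol[lin] <- ci[i] * exp(logint)
    data[, , , i] <- vol
  }
  ids <- sprintf("sub-%03d", seq_len(n))
  stack <- volume_stack(data, mask$affine, ids)

  s2 <- s[, mk]
  caf <- config$caf_intercept + config$clinical_beta * s2 +
    config$clinical_direct_beta * chei +
    stats::rnorm(n, 0, config$clinical_noise_sd)
  clinical <- data.frame(
    subject_id = ids,
    group = "DLB",
    caf = caf,
    crt_ms = exp(6.55 + 0.06 * s2 + stats::rnorm(n, 0, 0.15)),
    crt_sd_ms = exp(5.20 + 0.08 * s2 + stats::rnorm(n, 0, 0.25)),
    mmse = pmax(0, pmin(30, round(16 - 0.8 * s2 + stats::rnorm(n, 0, 4)))),
    camcog = pmax(0, pmin(107, round(60 - 2 * s2 + stats::rnorm(n, 0, 10)))),
    updrs3 = pmax(0, round(27 + stats::rnorm(n, 0, 12))),
    bradykinesia = pmax(0, round(8 + 0.6 * s2 + stats::rnorm(n, 0, 3))),
    age = round(stats::rnorm(n, 76, 6)),
    sex = stats::rbinom(n, 1L, 0.5),
    duration_yr = round(exp(stats::rnorm(n, 1.2, 0.5)), 1),
    chei = chei,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    patterns = pats, true_ssf = s, group_profile = group_profile,
    clinical_coefficients = list(
      caf_intercept = config$caf_intercept, beta_ssf = config$clinical_beta,
      beta_direct = config$clinical_direct_beta,
      noise_sd = config$clinical_noise_sd),
    pattern_specs = config$pattern_specs, mediator_component = mk,
    chei = chei, global_offsets = g, subject_scales = ci),
    class = "ground_truth")

  list(stack = stack, mask = mask, clinical = clinical, truth = truth,
       config = config)
}

#' Clinical noise level for a target score-outcome correlation
#'
#' Given the outcome slope and the score standard deviation, returns the
#' outcome noise sd that makes the population correlation between pattern
#' score and outcome equal `rho`.
#'
#' @param beta Outcome units per score unit.
#' @param ssf_sd Score standard deviation.
#' @param rho Target correlation in (0, 1).
#' @return Noise standard deviation.
#' @export
clinical_noise_for_rho <- function(beta, ssf_sd, rho) {
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly in (0, 1)")
  abs(beta) * ssf_sd * sqrt(1 / rho^2 - 1)
}

#' Write a simulated cohort to disk
#'
#' One NIfTI-1 volume per subject, the mask NIfTI, the clinical CSV and a
#' JSON sidecar holding the configuration and ground truth.
#'
#' @param sim Result of [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_len(n_subjects(sim$stack))) {
    f <- file.path(outdir, paste0(sim$stack$subject_ids[i], ".nii.gz"))
    write_volume(sim$stack$data[, , , i], sim$stack$affine, f)
    files <- c(files, f)
  }
  fm <- file.path(outdir, "mask.nii.gz")
  write_volume(sim$mask$grid * 1, sim$mask$affine, fm)
  fc <- file.path(outdir, "clinical.csv")
  utils::write.csv(sim$clinical, fc, row.names = FALSE)
  fj <- file.path(outdir, "ground_truth.json")
  gt <- sim$truth
  side <- list(
    config = sim$config[setdiff(names(sim$config), "pattern_specs")],
    pattern_specs = lapply(sim$config$pattern_specs, unclass),
    true_ssf = gt$true_ssf, patterns = gt$patterns,
    group_profile = gt$group_profile,
    clinical_coefficients = gt$clinical_coefficients,
    mediator_component = gt$mediator_component)
  jsonlite::write_json(side, fj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fm, fc, fj))
}
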