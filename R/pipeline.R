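#' End-to-end run configuration
#'
#' Defaults are the reference analysis settings: 16-mm FWHM smoothing, global-mean
#' normalization, >10% variance retention, |Z| >= 1.64 thresholding,
#' subject-resampling bootstrap, and clusters of at least ten voxels under
#' face connectivity. Inputs are either a [sim_config()] (synthetic run) or
#' paths to volumes, a mask and a clinical CSV.
#'
#' @param simulate Optional [sim_config()].
#' @param volume_paths,mask_path,clinical_path File inputs, used when
#'   `simulate` is `NULL`.
#' @param fwhm Smoothing kernel FWHM in mm (default 16).
#' @param variance_threshold Component retention cut (default 0.10).
#' @param z_threshold Eigenimage/stability threshold (default 1.64).
#' @param n_boot Bootstrap replicates (default 500).
#' @param min_cluster_size Minimum cluster extent in voxels (default 10).
#' @param connectivity Cluster connectivity (default `"face"`).
#' @param match_threshold Bootstrap component-matching threshold (default
#'   0.5).
#' @param log_transform Log-transform before double centering (default
#'   `TRUE`).
#' @param seed Integer seed driving every random stage.
#' @param outdir Optional output directory; when set, pattern maps, the
#'   cluster tables and the JSON report are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, volume_paths = NULL,
                       mask_path = NULL, clinical_path = NULL,
                       fwhm = 16, variance_threshold = 0.10,
                       z_threshold = 1.64, n_boot = 500L,
                       min_cluster_size = 10L, connectivity = "face",
                       match_threshold = 0.5, log_transform = TRUE,
                       seed = 1L, outdir = NULL) {
  if (is.null(simulate) &&
      (is.null(volume_paths) || is.null(mask_path) || is.null(clinical_path)))
    stop("provide either `simulate` or volume, mask and clinical paths")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(simulate = simulate, volume_paths = volume_paths,
                 mask_path = mask_path, clinical_path = clinical_path,
                 fwhm = fwhm, variance_threshold = variance_threshold,
                 z_threshold = z_threshold, n_boot = as.integer(n_boot),
                 min_cluster_size = as.integer(min_cluster_size),
                 connectivity = connectivity,
                 match_threshold = match_threshold,
                 log_transform = isTRUE(log_transform),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the full spatial covariance analysis
#'
#' Orchestrates the full analysis: (simulate or read) -> smooth -> global-mean
#' normalize -> vectorize -> log + double centering -> SVD decomposition ->
#' retain components above the variance threshold -> per retained pattern:
#' Z-scoring, thresholding, bootstrap stability and cluster extraction ->
#' clinical associations, confounder screening, stepwise regression with
#' the pattern expression forced in, and partial-correlation mediation of
#' medication use through pattern expression. Fully deterministic given the
#' seed.
#'
#' @param cfg A [run_config()].
#' @param verbose Emit per-stage progress messages (default `TRUE`).
#' @return A `pipeline_report` list: `config` echo, `status`, per-component
#'   `variance_fractions`, `retained`, `patterns` (Z maps, stability,
#'   clusters), `associations`, `confounders`, `stepwise`, `mediation`,
#'   `normality`, `timings_sec` and `versions`. When `cfg$outdir` is set the
#'   report is also written as JSON alongside the NIfTI/TSV maps.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    say("stage %-12s %.2fs", name, timings[[name]])
    out
  }

  inputs <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_cohort(cfg$simulate)
      list(stack = sim$stack, mask = sim$mask, clinical = sim$clinical,
           truth = sim$truth)
    } else {
      stack <- read_volumes(cfg$volume_paths)
      mask <- read_mask(cfg$mask_path)
      clin <- utils::read.csv(cfg$clinical_path, stringsAsFactors = FALSE)
      ord <- match(stack$subject_ids, clin$subject_id)
      if (anyNA(ord))
        stop("clinical table is missing subjects: ",
             paste(stack$subject_ids[is.na(ord)], collapse = ", "))
      list(stack = stack, mask = mask, clinical = clin[ord, ], truth = NULL)
    }
  })

  smoothed <- stage("smooth", smooth_gaussian(inputs$stack, cfg$fwhm))
  normed <- stage("normalize", normalize_global(smoothed, inputs$mask))
  dm <- stage("vectorize", vectorize(normed, inputs$mask))
  res <- stage("center", log_and_center(dm, log_transform = cfg$log_transform))
  dec <- stage("decompose", ssm_decompose(res))

  report <- list(
    config = cfg[setdiff(names(cfg), "simulate")],
    seed = cfg$seed,
    versions = list(ssmpca = as.character(utils::packageVersion("ssmpca")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    n_subjects = nrow(dm$values), n_voxels = ncol(dm$values))

  if (!length(dec$patterns)) {
    report$status <- "no-components"
    report$variance_fractions <- numeric(0)
    say("no non-degenerate components; stopping early")
    report$timings_sec <- timings
    return(structure(report, class = "pipeline_report"))
  }

  vf <- vapply(dec$patterns, `[[`, numeric(1), "variance_fraction")
  retained <- retain_major(dec$patterns, cfg$variance_threshold)
  report$status <- if (length(retained)) "ok" else "no-retained-components"
  report$variance_fractions <- vf
  report$retained <- vapply(retained, `[[`, integer(1), "k")
  say("%d/%d components retained (>%.0f%% variance)", length(retained),
      length(dec$patterns), 100 * cfg$variance_threshold)

  pat_reports <- list()
  for (p in retained) {
    p <- zscore_pattern(p)
    bs <- stage(sprintf("bootstrap_k%d", p$k), bootstrap_pattern(
      dm, p, bootstrap_config(n_boot = cfg$n_boot,
                              seed = cfg$seed + 1000L + p$k,
                              match_threshold = cfg$match_threshold),
      log_transform = cfg$log_transform))
    say("component %d: %d/%d bootstrap replicates accepted", p$k,
        bs$n_accepted, bs$n_boot)
    thr <- significant_voxels(bs, z = cfg$z_threshold)
    stat_vol <- devectorize(ifelse(is.na(bs$z_stab), Inf * sign(bs$mean_w),
                                   bs$z_stab), inputs$mask, fill = 0)
    cl <- c(
      extract_clusters(devectorize(thr$positive, inputs$mask, fill = FALSE) > 0,
                       stat_vol, min_size = cfg$min_cluster_size,
                       connectivity = cfg$connectivity,
                       affine = dm$affine, sign = "positive"),
      extract_clusters(devectorize(thr$negative, inputs$mask, fill = FALSE) > 0,
                       stat_vol, min_size = cfg$min_cluster_size,
                       connectivity = cfg$connectivity,
                       affine = dm$affine, sign = "negative"))
    pat_reports[[as.character(p$k)]] <- list(
      k = p$k, variance_fraction = p$variance_fraction,
      pattern = p, stability = bs, clusters = cl,
      cluster_table = cluster_table(cl),
      n_boot_accepted = bs$n_accepted, n_boot_rejected = bs$n_rejected)
  }
  report$patterns <- pat_reports

  clin <- inputs$clinical
  report <- c(report, stage("clinical", clinical_block(
    dec, retained, clin, verbose = verbose)))
  report$timings_sec <- timings
  report$total_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    for (pr in pat_reports)
      write_pattern_maps(pr$pattern, pr$stability, inputs$mask, dm$affine,
                         cfg$outdir, z = cfg$z_threshold,
                         min_size = cfg$min_cluster_size,
                         connectivity = cfg$connectivity)
    write_report_json(report,
                      file.path(cfg$outdir, "report.json"))
  }
  structure(report, class = "pipeline_report")
}

# Clinical association block: correlations of each retained component's
# expression with the primary variables, selection of the clinical pattern
# (smallest p against the fluctuation score), confounder screening,
# stepwise models and the medication mediation analysis.
clinical_block <- function(dec, retained, clin, verbose = TRUE) {
  scores <- dec$ssf$scores
  primary <- list(caf = clin$caf, log_crt = log_rt(clin$crt_ms),
                  log_crt_sd = log_rt(clin$crt_sd_ms),
                  camcog = clin$camcog, updrs3 = clin$updrs3)
  assoc <- do.call(rbind, lapply(retained, function(p) {
    do.call(rbind, lapply(names(primary), function(vn) {
      pc <- pearson_corr(scores[, p$k], primary[[vn]])
      data.frame(component = p$k, variable = vn, r = pc$r, n = pc$n,
                 p = pc$p)
    }))
  }))

  normality <- lapply(primary, function(v)
    tryCatch(shapiro_wilk(v), error = function(e) list(W = NA, p = NA)))
  non_normal <- names(normality)[vapply(normality, function(x)
    is.finite(x$p) && x$p < 0.05, logical(1))]
  if (length(non_normal) && verbose)
    message("normality warning (Shapiro-Wilk p < 0.05): ",
            paste(non_normal, collapse = ", "))

  caf_rows <- assoc[assoc$variable == "caf", , drop = FALSE]
  sel_k <- caf_rows$component[which.min(caf_rows$p)]
  ssf <- scores[, sel_k]

  candidates <- list(age = clin$age, sex = clin$sex, chei = clin$chei,
                     duration_yr = clin$duration_yr, mmse = clin$mmse)
  conf <- screen_confounders(ssf, clin$caf, candidates)
  # degenerate cohorts (e.g. single-level medication, too few subjects for
  # the candidate count) skip the affected model with a recorded reason
  # instead of aborting the whole run
  or_skip <- function(expr) tryCatch(expr, error = function(e)
    list(skipped = conditionMessage(e)))
  step <- or_skip(stepwise_regress(clin$caf, ssf, candidates[conf]))
  med <- list(
    caf = or_skip(mediation_analysis(clin$chei, ssf, clin$caf)),
    log_crt = or_skip(mediation_analysis(clin$chei, ssf,
                                         log_rt(clin$crt_ms))),
    log_crt_sd = or_skip(mediation_analysis(clin$chei, ssf,
                                            log_rt(clin$crt_sd_ms))))

  list(associations = assoc, clinical_component = sel_k,
       confounders = conf, stepwise = step, mediation = med,
       normality = normality)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> status: %s\n", x$status))
  if (length(x$variance_fractions))
    cat("variance fractions:",
        paste(sprintf("%.1f%%", 100 * x$variance_fractions[
          seq_len(min(6, length(x$variance_fractions)))]), collapse = ", "),
        "\n")
  if (!is.null(x$retained))
    cat("retained components:", paste(x$retained, collapse = ", "), "\n")
  if (!is.null(x$clinical_component))
    cat("clinical component:", x$clinical_component, "\n")
  invisible(x)
}

# JSON-safe projection of the report (drops voxel-level vectors, keeps
# tables and summaries).
write_report_json <- function(report, path) {
  slim <- report
  slim$patterns <- lapply(report$patterns, function(pr) list(
    k = pr$k, variance_fraction = pr$variance_fraction,
    n_boot_accepted = pr$n_boot_accepted,
    n_boot_rejected = pr$n_boot_rejected,
    clusters = pr$cluster_table))
  slim$stepwise <- list(
    selected_covariates = report$stepwise$selected_covariates,
    coefficients = report$stepwise$coefficients,
    n = report$stepwise$n)
  slim$mediation <- lapply(report$mediation, unclass)
  slim$config <- report$config[!vapply(report$config, is.null, logical(1))]
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
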