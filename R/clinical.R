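#' Natural-log transform of reaction times
#'
#' Reaction-time distributions are positively skewed; analyses use their
#' natural log. Correlation magnitudes are unaffected by the log base.
#'
#' @param values Positive reaction times (ms).
#' @return `log(values)`.
#' @export
log_rt <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("reaction times must be positive and finite")
  log(values)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with positive
#'   variance.
#' @return An object of class `correlation_result`: fields `r`, `n`,
#'   `t_stat`, `df`, `p` (two-sided, from Student t with n - 2 df).
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = n,
                 t_stat = unname(ct$statistic), df = n - 2L,
                 p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, df = %d, t = %.3f, p = %.4g)\n",
              x$r, x$n, x$df, x$t_stat, x$p))
  invisible(x)
}

#' Two-sided p-value for a printed correlation coefficient
#'
#' The t transformation `t = r * sqrt(n - 2) / sqrt(1 - r^2)` applied to a
#' reported r and sample size.
#'
#' @param r Correlation in (-1, 1).
#' @param n Sample size (> 2).
#' @return Two-sided p-value.
#' @export
corr_p_value <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be below 1")
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Partial correlation by residualization
#'
#' Residualizes `x` and `y` on the covariates (plus intercept) by least
#' squares and correlates the residuals; the p-value uses Student t with
#' `n - 2 - c` degrees of freedom. With a single covariate this equals the
#' closed form `(r_xy - r_xm r_ym) / sqrt((1 - r_xm^2)(1 - r_ym^2))`.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data.frame of c covariates.
#' @return A `correlation_result` with `df = n - 2 - c`.
#' @export
partial_corr <- function(x, y, covariates) {
  z <- as.matrix(covariates)
  n <- length(x)
  if (length(y) != n || nrow(z) != n)
    stop("x, y and covariates must have matching lengths")
  nc <- ncol(z)
  if (n < nc + 4L) stop("too few observations for the covariate count")
  design <- cbind(1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("rank-deficient covariate matrix")
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  # residual variance judged relative to the input scale: an exact linear
  # dependence leaves only round-off
  if (stats::sd(rx) <= 1e-12 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= 1e-12 * max(stats::sd(y), 1e-300))
    stop("zero residual variance after adjusting for covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2L - nc
  tval <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, n = n, t_stat = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df = df)),
            class = "correlation_result")
}

#' Screen candidate confounders
#'
#' A candidate is flagged when its Pearson correlation p-value falls below
#' `p_thresh` against the imaging variable and (default) also against the
#' clinical variable -- the classical confounder definition; `rule =
#' "either"` flags on association with either one. Binary candidates are
#' correlated as 0/1 (point-biserial).
#'
#' @param ssf Imaging (pattern-expression) vector.
#' @param outcome Clinical outcome vector.
#' @param candidates Named list or data.frame of candidate vectors.
#' @param p_thresh Screening threshold (default 0.10).
#' @param rule `"both"` (default) or `"either"`.
#' @return Character vector of flagged candidate names.
#' @export
screen_confounders <- function(ssf, outcome, candidates, p_thresh = 0.10,
                               rule = c("both", "either")) {
  rule <- match.arg(rule)
  candidates <- as.list(candidates)
  if (!length(candidates)) return(character(0))
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be named")
  flagged <- vapply(candidates, function(cand) {
    cand <- as.numeric(cand)
    if (stats::sd(cand) == 0) return(FALSE)
    p_img <- pearson_corr(cand, ssf)$p
    p_out <- pearson_corr(cand, outcome)$p
    if (rule == "both") p_img < p_thresh && p_out < p_thresh
    else p_img < p_thresh || p_out < p_thresh
  }, logical(1))
  names(candidates)[flagged]
}

#' Stepwise regression with a forced primary predictor
#'
#' The imaging predictor is always in the model; candidate covariates enter
#' by forward selection (smallest coefficient p-value, if below `entry_p`)
#' and leave by backward elimination (p at or above `removal_p`), iterated
#' to a fixed point. The forced predictor is never removed.
#'
#' @param y Outcome vector.
#' @param forced_x Forced predictor vector.
#' @param candidates Named list or data.frame of candidate covariates (may
#'   be empty).
#' @param entry_p Forward entry threshold (default 0.05).
#' @param removal_p Backward removal threshold (default 0.10).
#' @return An object of class `stepwise_model`: `forced_predictor`,
#'   `selected_covariates`, `coefficients` (estimate, std_error, t, p per
#'   term), `n`, `fit` (the final `lm`).
#' @export
stepwise_regress <- function(y, forced_x, candidates = list(),
                             entry_p = 0.05, removal_p = 0.10) {
  candidates <- as.list(candidates)
  n <- length(y)
  if (length(forced_x) != n) stop("y and forced_x must have equal length")
  if (length(candidates) &&
      (is.null(names(candidates)) || any(!nzchar(names(candidates)))))
    stop("candidates must be named")
  if (n <= length(candidates) + 2L)
    stop("too few observations for the number of potential predictors")
  dat <- data.frame(.y = y, .forced = forced_x)
  for (nm in names(candidates)) dat[[nm]] <- as.numeric(candidates[[nm]])

  fit_with <- function(sel) {
    fml <- stats::reformulate(c(".forced", sel), response = ".y")
    fit <- stats::lm(fml, data = dat)
    if (anyNA(stats::coef(fit))) stop("collinear design matrix")
    fit
  }
  coef_p <- function(fit, term) stats::coef(summary(fit))[term, 4L]

  selected <- character(0)
  for (iter in seq_len(100L)) {
    changed <- FALSE
    # forward: best remaining candidate below entry_p
    remaining <- setdiff(names(candidates), selected)
    if (length(remaining) && entry_p > 0) {
      ps <- vapply(remaining, function(nm)
        coef_p(fit_with(c(selected, nm)), nm), numeric(1))
      if (min(ps) < entry_p) {
        selected <- c(selected, remaining[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward: drop the worst selected covariate at/above removal_p
    if (length(selected)) {
      fit <- fit_with(selected)
      ps <- vapply(selected, function(nm) coef_p(fit, nm), numeric(1))
      if (max(ps) >= removal_p) {
        selected <- setdiff(selected, selected[which.max(ps)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- fit_with(selected)
  cs <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(cs), estimate = cs[, 1L],
                      std_error = cs[, 2L], t = cs[, 3L], p = cs[, 4L],
                      row.names = NULL)
  structure(list(forced_predictor = ".forced",
                 selected_covariates = selected, coefficients = coefs,
                 n = n, fit = fit),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> n = %d; covariates selected: %s\n", x$n,
              if (length(x$selected_covariates))
                paste(x$selected_covariates, collapse = ", ") else "none"))
  print(x$coefficients)
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom
#' (not Welch), two-sided.
#'
#' @param values Numeric vector.
#' @param groups Binary/two-level grouping of the same length, at least 2
#'   observations per group.
#' @return List of class `group_comparison`: `t_stat`, `df`, `p`,
#'   `group_means`, `n`.
#' @export
compare_groups <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  ns <- table(g)
  if (any(ns < 2L)) stop("each group needs at least 2 observations")
  tt <- stats::t.test(values ~ g, var.equal = TRUE)
  structure(list(t_stat = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 group_means = tt$estimate, n = length(values)),
            class = "group_comparison")
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; df = 1 for a 2x2 table. All expected counts
#' must be positive.
#'
#' @param table Matrix of counts.
#' @return List of class `group_comparison`: `chi_sq`, `df`, `p`,
#'   `expected`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("zero expected count in the table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(chi_sq = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = expected),
            class = "group_comparison")
}

#' Shapiro-Wilk normality screen
#'
#' Used to log a normality warning on clinical variables; never branches
#' the analysis automatically.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 observations")
  if (stats::sd(values) == 0) stop("constant vector")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Partial-correlation mediation analysis
#'
#' Tests whether an exposure-outcome association is carried by a mediator:
#' the marginal Pearson correlation between exposure and outcome is
#' compared with their partial correlation controlling for the mediator.
#' The association is flagged as mediated when the marginal correlation is
#' significant (p < alpha) while the partial correlation is not
#' (p >= alpha). When the outcome (or exposure) is an exact linear function
#' of the mediator, the residual variance is zero and the partial
#' correlation is reported as 0 with p = 1 (the complete-mediation limit).
#'
#' @param exposure Binary 0/1 vector with both levels present.
#' @param mediator Numeric vector (e.g. pattern expression).
#' @param outcome Numeric vector.
#' @param alpha Significance level for the mediated flag (default 0.05).
#' @return An object of class `mediation_result`: `r_marginal`,
#'   `p_marginal`, `r_partial`, `p_partial`, `mediated`, `n`.
#' @export
mediation_analysis <- function(exposure, mediator, outcome, alpha = 0.05) {
  if (length(unique(exposure)) < 2L)
    stop("exposure must have both levels present")
  marg <- pearson_corr(exposure, outcome)
  design <- cbind(1, mediator)
  rx <- stats::lm.fit(design, exposure)$residuals
  ry <- stats::lm.fit(design, outcome)$residuals
  eps <- 1e-12 * max(stats::sd(outcome), stats::sd(exposure), 1)
  if (stats::sd(rx) <= eps || stats::sd(ry) <= eps) {
    part <- list(r = 0, p = 1)
  } else {
    part <- partial_corr(exposure, outcome, mediator)
  }
  structure(list(r_marginal = marg$r, p_marginal = marg$p,
                 r_partial = part$r, p_partial = part$p,
                 mediated = marg$p < alpha && part$p >= alpha,
                 n = length(exposure)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("marginal r = %.3f (p = %.3g); partial r = %.3f ",
                     "(p = %.3g); mediated: %s\n"),
              x$r_marginal, x$p_marginal, x$r_partial, x$p_partial,
              x$mediated))
  invisible(x)
}
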