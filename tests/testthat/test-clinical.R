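test_that("reaction-time log transform is the natural log and rejects nonpositives", {
  expect_equal(log_rt(1), 0)
  expect_equal(log_rt(exp(1)), 1)
  expect_equal(log_rt(c(100, 1000)), c(4.60517, 6.90776), tolerance = 1e-5)
  expect_error(log_rt(c(300, 0)), "positive")
  expect_error(log_rt(c(300, -5)), "positive")
})

test_that("Pearson correlation reproduces the t transform and perfect linearity", {
  x <- c(1, 2, 3, 4, 5)
  r1 <- pearson_corr(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-10)
  set.seed(7)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25)
  pc <- pearson_corr(x, y)
  expect_equal(pc$t_stat, pc$r * sqrt(pc$n - 2) / sqrt(1 - pc$r^2),
               tolerance = 1e-10)
  expect_equal(pc$p, 2 * pt(-abs(pc$t_stat), pc$n - 2), tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson_corr(rnorm(2), rnorm(2)), "at least 3")
})

test_that("cohort-size p-values of the printed attention correlations round as reported", {
  # fluctuation vs reaction time, n = 19 subjects
  expect_equal(round(corr_p_value(0.47, 19), 2), 0.04)
  expect_equal(round(corr_p_value(0.54, 19), 2), 0.02)
})

test_that("partial correlation matches the single-covariate closed form", {
  set.seed(13)
  for (rep in 1:100) {
    n <- 30
    m <- rnorm(n)
    x <- 0.5 * m + rnorm(n)
    y <- -0.3 * m + rnorm(n)
    pc <- partial_corr(x, y, m)
    rxy <- cor(x, y); rxm <- cor(x, m); rym <- cor(y, m)
    closed <- (rxy - rxm * rym) / sqrt((1 - rxm^2) * (1 - rym^2))
    expect_equal(pc$r, closed, tolerance = 1e-12)
    expect_equal(pc$df, n - 3)
  }
})

test_that("partial correlation handles orthogonal covariates and degenerate inputs", {
  set.seed(14)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  # covariate orthogonal to both by construction
  cov_ <- rnorm(40)
  cov_ <- resid(lm(cov_ ~ x + y))
  pc <- partial_corr(x, y, cov_)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-10)
  # identical x, y and covariate: zero residual variance
  m <- rnorm(30)
  expect_error(partial_corr(m, m, m), "zero residual variance")
  # rank-deficient covariates
  expect_error(partial_corr(x, y, cbind(cov_, cov_)), "rank")
})

test_that("confounder screening applies the both-test rule", {
  set.seed(15)
  n <- 200
  ssf <- rnorm(n)
  outcome <- 0.7 * ssf + rnorm(n)
  conf <- 0.8 * ssf + 0.5 * outcome + rnorm(n)  # tied to both
  noise <- rnorm(n)                             # tied to neither
  out <- screen_confounders(ssf, outcome, list(conf = conf, noise = noise))
  expect_identical(out, "conf")
  # a candidate equal to the outcome is flagged iff also tied to ssf
  out2 <- screen_confounders(ssf, outcome, list(dup = outcome))
  expect_identical(out2, "dup")
  ssf2 <- rnorm(n)  # ssf independent of outcome
  out3 <- screen_confounders(ssf2, outcome, list(dup = outcome))
  expect_identical(out3, character(0))
  # either-variable reading as a switch
  out4 <- screen_confounders(ssf2, outcome, list(dup = outcome),
                             rule = "either")
  expect_identical(out4, "dup")
  expect_identical(screen_confounders(ssf, outcome, list()), character(0))
})

test_that("stepwise regression forces the imaging predictor and selects real covariates", {
  set.seed(16)
  # no candidate passes entry: simple regression; p equals the correlation p
  n <- 50
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  noise <- rnorm(n)
  sm <- stepwise_regress(y, x, list(c1 = noise), entry_p = 1e-12)
  expect_length(sm$selected_covariates, 0L)
  pc <- pearson_corr(x, y)
  p_forced <- sm$coefficients$p[sm$coefficients$term == ".forced"]
  expect_equal(p_forced, pc$p, tolerance = 1e-10)
  # entry_p = 0: nothing can enter
  sm0 <- stepwise_regress(y, x, list(c1 = noise), entry_p = 0)
  expect_length(sm0$selected_covariates, 0L)
  # collinear design errors
  expect_error(stepwise_regress(y, x, list(c1 = x)), "collinear")

  # real covariate selected, pure noise not, in >= 90% of 100 seeds
  hits <- 0L; false_in <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- 200
    fx <- rnorm(n); c1 <- rnorm(n); c2 <- rnorm(n)
    yy <- 1 * fx + 0.8 * c1 + rnorm(n)
    fit <- stepwise_regress(yy, fx, list(c1 = c1, c2 = c2))
    if ("c1" %in% fit$selected_covariates) hits <- hits + 1L
    if ("c2" %in% fit$selected_covariates) false_in <- false_in + 1L
  }
  expect_gte(hits, 90L)
  expect_lte(false_in, 20L)
})

test_that("pooled-variance t-test matches hand arithmetic and the ANOVA identity", {
  eq <- compare_groups(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p, 1)
  # hand-computed 3 vs 3: groups (1,2,3) and (2,4,6)
  gc <- compare_groups(c(1, 2, 3, 2, 4, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(gc$t_stat, -2 / sqrt(2.5 * (2 / 3)), tolerance = 1e-12)
  expect_equal(gc$df, 4)
  # |t| = sqrt(F) of a two-group one-way ANOVA
  set.seed(17)
  v <- rnorm(30); g <- rep(0:1, 15)
  ct <- compare_groups(v, g)
  f <- anova(lm(v ~ factor(g)))[1, "F value"]
  expect_equal(ct$t_stat^2, f, tolerance = 1e-10)
  # shifting one group by a constant moves t monotonically
  t1 <- compare_groups(c(v[g == 0], v[g == 1] + 1), g)$t_stat
  t2 <- compare_groups(c(v[g == 0], v[g == 1] + 2), g)$t_stat
  expect_lt(t2, t1)
  expect_error(compare_groups(rnorm(4), c(0, 0, 0, 1)), "at least 2")
})

test_that("chi-squared test uses no continuity correction", {
  expect_equal(chi_square(rbind(c(10, 10), c(10, 10)))$chi_sq, 0)
  cs <- chi_square(rbind(c(20, 5), c(5, 20)))
  expect_equal(cs$chi_sq, 18)   # all expected counts 12.5, sum (7.5)^2/12.5
  expect_equal(cs$df, 1)
  cs2 <- chi_square(2 * rbind(c(20, 5), c(5, 20)))
  expect_equal(cs2$chi_sq, 36)  # doubling counts doubles the statistic
  expect_error(chi_square(rbind(c(0, 0), c(5, 5))), "expected")
})

test_that("Shapiro-Wilk screen detects skew and rejects bad input", {
  expect_error(shapiro_wilk(rnorm(2)), "between 3 and 5000")
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
  set.seed(18)
  rej <- mean(replicate(200, shapiro_wilk(rexp(100))$p < 0.05))
  expect_gt(rej, 0.95)
  ok <- mean(replicate(200, shapiro_wilk(rnorm(100))$p < 0.05))
  expect_lt(ok, 0.15)
})

test_that("mediation analysis flags complete mediation and handles the degenerate limit", {
  set.seed(19)
  n <- 60
  chei <- rbinom(n, 1, 0.5)
  med <- -2 * chei + rnorm(n)
  out <- 3 * med + rnorm(n, 0, 1)
  mr <- mediation_analysis(chei, med, out)
  expect_lt(mr$p_marginal, 0.05)
  expect_gt(mr$p_partial, 0.05)
  expect_true(mr$mediated)
  # outcome identical to the mediator: the complete-mediation limit
  mr0 <- mediation_analysis(chei, med, med)
  expect_equal(mr0$r_partial, 0)
  expect_equal(mr0$p_partial, 1)
  expect_error(mediation_analysis(rep(1, n), med, out), "both levels")
})
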