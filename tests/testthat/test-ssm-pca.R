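test_that("double centering zeroes row and column means and absorbs additive structure", {
  # hand-worked 2x3 case: log values [[1,2,3],[2,4,3]], row means (2,3),
  # row-centered [[-1,0,1],[-1,1,0]], column means (-1, 0.5, 0.5)
  dm <- make_dm(exp(rbind(c(1, 2, 3), c(2, 4, 3))))
  res <- log_and_center(dm)
  expect_equal(res$subject_offsets, c(2, 3))
  expect_equal(res$group_profile, c(-1, 0.5, 0.5))
  expect_equal(unname(res$values),
               rbind(c(0, -0.5, 0.5), c(0, 0.5, -0.5)))

  # exp(a_i + b_v) structure is fully absorbed
  a <- c(0.3, -1, 2, 0.5); b <- c(1, 2, 0.5, -0.2, 0)
  dm2 <- make_dm(exp(outer(a, b, `+`)))
  expect_true(max(abs(log_and_center(dm2)$values)) < 1e-12)

  # random matrices: both means vanish to 1e-10 x scale
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(exp(rnorm(8 * 30)), 8, 30)
    r <- log_and_center(make_dm(m))$values
    sc <- max(abs(log(m)))
    expect_true(max(abs(rowMeans(r))) < 1e-10 * sc)
    expect_true(max(abs(colMeans(r))) < 1e-10 * sc)
  }
})

test_that("log step errors name the offending subject and voxel", {
  m <- matrix(1, 3, 4); m[2, 3] <- 0
  expect_error(log_and_center(make_dm(m)), "subject 2 at voxel 3")
  expect_error(log_and_center(make_dm(matrix(1, 3, 4), normalized = FALSE)),
               "normalized")
})

test_that("a subject's global rescaling before normalization changes nothing", {
  sim <- simulate_cohort(small_sim_config(seed = 5, n_subjects = 10))
  st2 <- sim$stack
  st2$data[, , , 4] <- st2$data[, , , 4] * 10
  d1 <- decompose_sim(sim)
  d2 <- decompose_sim(list(stack = st2, mask = sim$mask))
  expect_equal(d1$res$values, d2$res$values, tolerance = 1e-12)
  expect_lt(max(abs(d1$dec$ssf$scores - d2$dec$ssf$scores)), 1e-8)
  for (k in seq_along(d1$dec$patterns)[1:4]) {
    expect_lt(max(abs(d1$dec$patterns[[k]]$weights -
                      d2$dec$patterns[[k]]$weights)), 1e-8)
    expect_lt(abs(d1$dec$patterns[[k]]$variance_fraction -
                  d2$dec$patterns[[k]]$variance_fraction), 1e-8)
  }
})

test_that("decomposition reconstructs the residuals and orders variance", {
  set.seed(31)
  m <- matrix(exp(0.1 * rnorm(6 * 40)), 6, 40)
  res <- log_and_center(make_dm(m))
  dec <- ssm_decompose(res)
  # reconstruction sum_k ssf_k w_k'
  recon <- dec$ssf$scores %*% t(sapply(dec$patterns, `[[`, "weights"))
  expect_lt(max(abs(recon - res$values)), 1e-8)
  vf <- vapply(dec$patterns, `[[`, numeric(1), "variance_fraction")
  expect_true(all(diff(vf) <= 1e-14))
  expect_equal(sum(vf), 1, tolerance = 1e-12)
  expect_lte(length(dec$patterns), nrow(m) - 1L)
  # weights unit norm and mean-zero; SSF columns mean-zero
  for (p in dec$patterns) {
    expect_equal(sqrt(sum(p$weights^2)), 1, tolerance = 1e-12)
    expect_lt(abs(mean(p$weights)), 1e-10)
  }
  expect_lt(max(abs(colMeans(dec$ssf$scores))), 1e-10)
})

test_that("rank-1 residuals give one component with full variance", {
  a <- c(1, -1, 0.5, -0.5)
  b <- rnorm(20)
  b <- b - mean(b)
  vals <- exp(outer(a - mean(a), b))
  dec <- ssm_decompose(log_and_center(make_dm(vals)))
  vf <- vapply(dec$patterns, `[[`, numeric(1), "variance_fraction")
  expect_equal(vf[1], 1, tolerance = 1e-10)
  expect_lt(sum(vf[-1]), 1e-10)
})

test_that("degenerate inputs are handled: N < 3 errors, zero residuals give zero components", {
  expect_error(ssm_decompose(log_and_center(make_dm(matrix(1, 2, 5)))),
               "3 subjects")
  dec <- ssm_decompose(log_and_center(make_dm(matrix(2, 5, 7))))
  expect_length(dec$patterns, 0)
})

test_that("variance fractions and SSFs agree with a Gram-matrix eigendecomposition", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    m <- matrix(exp(0.2 * rnorm(n * 25)), n, 25)
    res <- log_and_center(make_dm(m))
    dec <- ssm_decompose(res)
    eg <- eigen(tcrossprod(res$values), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    keep <- seq_along(dec$patterns)
    expect_equal(vapply(dec$patterns, `[[`, numeric(1), "variance_fraction"),
                 (ev / sum(ev))[keep], tolerance = 1e-8)
    for (k in keep) {
      ssf_o <- eg$vectors[, k] * sqrt(ev[k])
      ssf_i <- dec$ssf$scores[, k]
      expect_lt(min(max(abs(ssf_i - ssf_o)), max(abs(ssf_i + ssf_o))), 1e-8)
    }
  }
})

test_that("component orientation is deterministic and skewness-positive", {
  set.seed(51)
  m <- matrix(exp(0.1 * rnorm(8 * 50)), 8, 50)
  res <- log_and_center(make_dm(m))
  dec <- ssm_decompose(res)
  for (p in dec$patterns) {
    w <- p$weights - mean(p$weights)
    skew <- mean(w^3) / mean(w^2)^1.5
    if (abs(skew) > 1e-12) expect_gte(skew, 0)
    else expect_gte(p$weights[which.max(abs(p$weights))], 0)
  }
  # feeding the negated residuals gives identically oriented weights
  res2 <- res; res2$values <- -res$values
  dec2 <- ssm_decompose(res2)
  expect_equal(dec2$patterns[[1]]$weights, dec$patterns[[1]]$weights,
               tolerance = 1e-10)
})

test_that("variance retention keeps exactly the components above 10%", {
  fake <- function(vfs) lapply(seq_along(vfs), function(k)
    structure(list(k = k, weights = numeric(0), variance_fraction = vfs[k],
                   singular_value = 0, zmap = NULL),
              class = "covariance_pattern"))
  # printed component percentages from the two cohorts retain the first two
  expect_length(retain_major(fake(c(0.187, 0.139, 0.07, 0.05))), 2L)
  expect_length(retain_major(fake(c(0.167, 0.153, 0.09, 0.04))), 2L)
  # strict inequality: 10% exactly is not retained
  expect_length(retain_major(fake(c(0.10, 0.08))), 0L)
  expect_length(retain_major(fake(c(0.05, 0.04))), 0L)
  expect_error(retain_major(fake(c(0.1, 0.3))), "decreasing")
})

test_that("Z-scoring standardizes weights with the population sd", {
  p <- structure(list(k = 1L, weights = c(1, -1) / sqrt(2),
                      variance_fraction = 1, singular_value = 1, zmap = NULL),
                 class = "covariance_pattern")
  pz <- zscore_pattern(p)
  expect_equal(pz$zmap, c(1, -1))
  set.seed(61)
  w <- rnorm(100); w <- w - mean(w); w <- w / sqrt(sum(w^2))
  p2 <- p; p2$weights <- w
  z <- zscore_pattern(p2)$zmap
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  p3 <- p; p3$weights <- rep(0.1, 5)
  expect_error(zscore_pattern(p3), "degenerate")
})

test_that("Z thresholding splits into disjoint positive and negative sets", {
  thr <- threshold_zmap(c(2.0, -1.7, 0.3), 1.64)
  expect_identical(thr$positive, c(TRUE, FALSE, FALSE))
  expect_identical(thr$negative, c(FALSE, TRUE, FALSE))
  thr0 <- threshold_zmap(c(0.5, -1.2, 1.63), 1.64)
  expect_false(any(thr0$positive | thr0$negative))
  expect_false(any(threshold_zmap(rnorm(50))$positive &
                   threshold_zmap(rnorm(50))$negative))
  expect_error(threshold_zmap(c(1, 2), z = -1), "positive")
  # the default threshold is the upper-0.05 standard normal quantile to 2 dp
  expect_equal(round(qnorm(0.95), 2), 1.64)
})

test_that("projection reproduces training scores and recovers held-out scores", {
  sim <- simulate_cohort(small_sim_config(seed = 8, n_subjects = 12,
                                          noise_sd = 0))
  d <- decompose_sim(sim)
  lv <- log(d$dm$values)
  for (i in c(1, 5, 12)) for (k in 1:2) {
    sc <- project_subject(lv[i, ], d$res$group_profile, d$dec$patterns[[k]])
    expect_equal(sc, unname(d$dec$ssf$scores[i, k]), tolerance = 1e-8)
  }
  # profile equal to the group profile plus a constant scores zero
  sc0 <- project_subject(d$res$group_profile + 3, d$res$group_profile,
                         d$dec$patterns[[1]])
  expect_lt(abs(sc0), 1e-8)
  # projecting onto the true generative pattern at zero noise recovers each
  # subject's generative score exactly (up to the cohort mean, which the
  # group profile absorbs)
  p_true <- structure(list(k = 2L, weights = sim$truth$patterns[2, ],
                           variance_fraction = NA, singular_value = NA,
                           zmap = NULL), class = "covariance_pattern")
  s_true <- sim$truth$true_ssf[, 2]
  sc <- vapply(seq_len(nrow(lv)), function(i)
    project_subject(lv[i, ], d$res$group_profile, p_true), numeric(1))
  expect_equal(sc, s_true - mean(s_true), tolerance = 1e-6)
  expect_error(project_subject(lv[1, 1:10], d$res$group_profile,
                               d$dec$patterns[[1]]), "length")
})
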