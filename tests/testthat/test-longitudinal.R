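test_that("GLS on complete balanced data returns visitwise arm means", {
  d <- make_generated_trial(n_per_arm = 25)
  fit <- fit_gls(d)
  Y <- augbin:::y_matrix(d)
  m0 <- colMeans(Y[d$arm == 0, ])
  m1 <- colMeans(Y[d$arm == 1, ])
  expect_equal(unname(fit$beta[1:2]), unname(m0))
  expect_equal(unname(fit$beta[3:4]), unname(m1 - m0))
  expect_true(fit$converged)
  # ML covariance: mean residual outer product
  expect_equal(dim(fit$Sigma), c(2L, 2L))
  expect_true(min(eigen(fit$Sigma, only.values = TRUE)$values) > 0)
})

test_that("single-visit GLS reduces to ordinary least squares", {
  set.seed(11)
  n <- 30
  arm <- rep(0:1, each = n / 2)
  y <- matrix(5 + 3 * arm + rnorm(n, sd = 2), ncol = 1)
  d <- trial_dataset(paste0("P", 1:n), arm, rep(0, n), y,
                     matrix(0L, n, 1), threshold = 6)
  fit <- fit_gls(d)
  ols <- lm(y ~ arm)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(dim(fit$Sigma), c(1L, 1L))
  # ML variance (divisor n) vs OLS residual variance (divisor n - 2)
  expect_equal(fit$Sigma[1, 1], sum(resid(ols)^2) / n, tolerance = 1e-8)
})

test_that("GLS with missing visits matches direct likelihood maximization", {
  set.seed(202)
  n <- 16
  arm <- rep(0:1, each = n / 2)
  L <- chol(matrix(c(4, 2.4, 2.4, 4), 2, 2))
  Y <- matrix(rnorm(n * 2), n, 2) %*% L +
    cbind(1 + arm, 2 + 2 * arm)
  Y[c(2, 9), 2] <- NA
  Y[5, 1] <- NA
  d <- trial_dataset(paste0("P", 1:n), arm, rep(0, n), Y,
                     matrix(0L, n, 2), threshold = 3)
  fit <- fit_gls(d)
  ref <- oracle_gls_fit(Y, arm, 2)
  expect_equal(unname(fit$beta), ref$beta, tolerance = 1e-4)
  # the EM solution should attain at least the oracle's log-likelihood
  em_ll <- oracle_gls_loglik(
    c(fit$beta, local({
      Lc <- t(chol(fit$Sigma)); diag(Lc) <- log(diag(Lc))
      Lc[lower.tri(Lc, diag = TRUE)]
    })), Y, arm, 2)
  expect_gte(em_ll, ref$value - 1e-6)
})

test_that("GEE with independence working correlation equals GLS on complete data", {
  d <- make_generated_trial(n_per_arm = 20)
  g1 <- fit_gls(d)
  g2 <- fit_gee(d, working_corr = "independence")
  expect_equal(g2$beta, g1$beta, tolerance = 1e-8)
  g3 <- fit_gee(d, working_corr = "exchangeable")
  expect_equal(g3$beta, g1$beta, tolerance = 1e-8) # saturated design
  expect_false(is.null(g3$cov_robust))
  expect_true(all(diag(g3$cov_robust) > 0))
})

test_that("degenerate inputs are rejected", {
  d <- make_generated_trial(n_per_arm = 10)
  single <- augbin:::subset_trial(d, c(1, 2, 11))
  expect_error(fit_gee(single), "per arm")
  expect_error(fit_gls(single), "per arm")
})

test_that("GEE sandwich tracks the empirical sampling variance", {
  params <- reference_alternative(n_per_arm = 200)
  set.seed(314)
  reps <- 500
  arm2 <- matrix(NA_real_, reps, 2) # final-visit arm effect + interim
  sand <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    d <- generate_trial(params)
    f <- fit_gee(d)
    arm2[r, ] <- f$beta[c("arm:visit1", "arm:visit2")]
    sand[r, ] <- diag(f$cov_robust)[c("arm:visit1", "arm:visit2")]
  }
  emp <- apply(arm2, 2, var)
  avg_sand <- colMeans(sand)
  expect_true(all(abs(avg_sand / emp - 1) < 0.20))
})

test_that("MBN correction matches an independent evaluation to 1e-10", {
  d <- make_generated_trial(n_per_arm = 10, seed = 55)
  fit <- fit_gee(d)
  corrected <- mbn_correct(fit)
  ref <- oracle_mbn(fit$cov_robust, fit$cov_model, fit$n_clusters, fit$p,
                    fit$n_obs)
  expect_equal(corrected$cov_mbn, ref, tolerance = 1e-10)
  # original fields untouched
  expect_identical(corrected$cov_robust, fit$cov_robust)
  expect_identical(corrected$beta, fit$beta)
})

test_that("MBN inflates every diagonal element on random instances", {
  for (seed in c(1, 2, 3, 4, 5)) {
    d <- make_generated_trial(n_per_arm = sample(8:20, 1), seed = seed)
    fit <- mbn_correct(fit_gee(d))
    expect_true(all(diag(fit$cov_mbn) >= diag(fit$cov_robust) - 1e-14))
  }
})

test_that("MBN correction vanishes for many clusters", {
  d <- make_generated_trial(n_per_arm = 500, seed = 77) # K = 1000
  fit <- mbn_correct(fit_gee(d))
  rel <- abs(fit$cov_mbn - fit$cov_robust) /
    pmax(abs(fit$cov_robust), 1e-12)
  expect_lt(max(diag(rel)), 0.02)
})

test_that("MBN requires more clusters than parameters", {
  d <- make_generated_trial(n_per_arm = 10, seed = 3)
  fit <- fit_gee(d)
  fit$n_clusters <- fit$p # simulate K <= p
  expect_error(mbn_correct(fit), "K <= p")
  expect_error(mbn_correct(fit_gls(d)), "GEE")
})

test_that("GLS recovers generator parameters with calibrated model SEs", {
  params <- reference_alternative(n_per_arm = 200)
  truth <- c(params$mu0, params$mu1 - params$mu0)
  set.seed(909)
  reps <- 200
  ok <- matrix(NA, reps, 4) # one indicator per mean parameter
  for (r in seq_len(reps)) {
    d <- generate_trial(params)
    f <- fit_gls(d)
    ok[r, ] <- abs(f$beta - truth) <= 3 * sqrt(diag(f$cov_model))
  }
  # pooled over parameters: a 3-SE band holds ~99.7% per estimate
  expect_gte(mean(ok), 0.99)
})

test_that("GLS and GEE arm effects converge with sample size", {
  params <- reference_alternative()
  gap <- sapply(c(30L, 400L), function(nh) {
    p <- params; p$n_per_arm <- nh
    d <- generate_trial(p, seed = 1234)
    abs(fit_gls(d)$beta["arm:visit2"] - fit_gee(d)$beta["arm:visit2"])
  })
  expect_lte(gap[2], gap[1] + 1e-8)
  expect_lt(gap[2], 1e-6) # complete data, saturated design: identical limit
})

test_that("MBN Wald tests reject less often than robust tests under the null", {
  params <- reference_null(n_per_arm = 20)
  set.seed(4321)
  reps <- 200
  rej <- matrix(NA, reps, 2)
  for (r in seq_len(reps)) {
    d <- generate_trial(params)
    f <- mbn_correct(fit_gee(d))
    b <- f$beta["arm:visit2"]
    rej[r, 1] <- abs(b) / sqrt(f$cov_robust["arm:visit2", "arm:visit2"]) >
      qnorm(0.975)
    rej[r, 2] <- abs(b) / sqrt(f$cov_mbn["arm:visit2", "arm:visit2"]) >
      qnorm(0.975)
  }
  expect_lte(sum(rej[, 2]), sum(rej[, 1]))
})
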