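test_that("generation is byte-identical for a fixed seed and leaves the RNG alone", {
  params <- reference_alternative(n_per_arm = 20)
  set.seed(999); before <- runif(1)
  set.seed(999)
  d1 <- generate_trial(params, seed = 8)
  after <- runif(1)
  d2 <- generate_trial(params, seed = 8)
  expect_identical(d1, d2)
  expect_identical(before, after) # global RNG stream untouched
})

test_that("switching off failures yields zero failure rate", {
  params <- generator_params(gamma1 = c(-30, 0), gamma2 = c(-30, 0, 0),
                             n_per_arm = 2000L)
  d <- generate_trial(params, seed = 2)
  expect_identical(sum(augbin:::d_matrix(d)), 0L)
})

test_that("final mean at the threshold gives response rate one half", {
  params <- generator_params(mu0 = c(0, 20), mu1 = c(0, 20),
                             gamma1 = c(-30, 0), gamma2 = c(-30, 0, 0),
                             n_per_arm = 5000L)
  d <- generate_trial(params, seed = 4)
  n <- nrow(d)
  expect_lt(abs(mean(d$responder) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("calibration hits the reference targets", {
  params <- reference_alternative()
  expect_equal(marginal_response_probability(params, 1), 0.470,
               tolerance = 1e-6)
  expect_equal(marginal_response_probability(params, 0), 0.336,
               tolerance = 1e-6)
  big <- params; big$n_per_arm <- 100000L
  d <- generate_trial(big, seed = 6)
  expect_lt(abs(mean(d$responder[d$arm == 1]) - 0.470), 0.005)
  expect_lt(abs(mean(d$responder[d$arm == 0]) - 0.336), 0.005)
})

test_that("calibration is a fixed point at the current marginals", {
  base <- generator_params()
  p1 <- marginal_response_probability(base, 1)
  p0 <- marginal_response_probability(base, 0)
  cal <- calibrate_generator(p1, p0, base)
  expect_equal(cal$mu1, base$mu1, tolerance = 1e-6)
  expect_equal(cal$mu0, base$mu0, tolerance = 1e-6)
})

test_that("target one half with failures off puts the mean at the threshold", {
  base <- generator_params(gamma1 = c(-30, 0), gamma2 = c(-30, 0, 0))
  cal <- calibrate_generator(0.5, 0.5, base)
  expect_equal(cal$mu1[2], base$threshold, tolerance = 1e-6)
  expect_equal(cal$mu0[2], base$threshold, tolerance = 1e-6)
})

test_that("unreachable targets raise a calibration error", {
  base <- generator_params(gamma1 = c(qlogis(0.5), 0)) # 50% early failure
  expect_error(calibrate_generator(0.8, 0.3, base), "unreachable")
})

test_that("balanced re-sampling draws the requested arm sizes", {
  src <- make_generated_trial(n_per_arm = 200, seed = 12)
  sub <- resample_subtrial(src, 30, seed = 1)
  expect_equal(nrow(sub), 30L)
  expect_equal(sum(sub$arm == 0), 15L)
  expect_equal(sum(sub$arm == 1), 15L)
  expect_true(all(sub$patient_id %in% src$patient_id))
  expect_error(resample_subtrial(src, 31), "even")
  expect_error(resample_subtrial(src, 600), "too small")

  # full-size draw is a permutation of the source
  full <- resample_subtrial(src, 400, seed = 2)
  expect_setequal(full$patient_id, src$patient_id)

  # disjoint seeds give different subsets
  pairs <- replicate(100, {
    s <- sample.int(1e6, 2)
    a <- resample_subtrial(src, 30, seed = s[1])
    b <- resample_subtrial(src, 30, seed = s[2])
    identical(sort(a$patient_id), sort(b$patient_id))
  })
  expect_lt(mean(pairs), 0.05)
})

test_that("label permutation preserves arms and outcomes", {
  d <- make_generated_trial(n_per_arm = 30, seed = 14)
  p <- permute_labels(d, seed = 5)
  expect_equal(sort(p$arm), sort(d$arm))
  expect_identical(augbin:::y_matrix(p), augbin:::y_matrix(d))
  expect_identical(augbin:::d_matrix(p), augbin:::d_matrix(d))
  expect_identical(p$responder, d$responder)
  expect_identical(permute_labels(d, seed = 5), p)
})

test_that("Monte Carlo standard error matches the closed form", {
  expect_equal(monte_carlo_se(0.05, 5000), sqrt(0.05 * 0.95 / 5000))
  # at 5000 replicates the SE of a 5% proportion prints as 0.3%
  expect_equal(round(100 * monte_carlo_se(0.05, 5000), 1), 0.3)
})

test_that("width-to-sample-size conversion and its domain", {
  expect_equal(ci_width_to_sample_size_reduction(0), 0)
  expect_equal(ci_width_to_sample_size_reduction(0.5), 0.75)
  expect_equal(ci_width_to_sample_size_reduction(0.174), 1 - 0.826^2)
  expect_error(ci_width_to_sample_size_reduction(1), "0, 1")
  expect_error(ci_width_to_sample_size_reduction(-0.1), "0, 1")
})

test_that("separation frequency uses a strict threshold", {
  expect_equal(separation_frequency(c(0.4, 0.6, 1.5, 2.0)), 0.5)
  expect_equal(separation_frequency(rep(0.5, 10)), 0)
  expect_equal(separation_frequency(rep(1.0, 10)), 0) # boundary: strict
  expect_error(separation_frequency(numeric(0)), "empty")
  expect_error(separation_frequency(c(-1, 2)), "non-negative")
})

test_that("a degenerate always-infinite method has zero power, full coverage", {
  degenerate <- function(data, scales, ci_level) {
    out <- lapply(scales, function(sc) {
      structure(list(scale = sc, estimate = 0, se = Inf,
                     ci_lower = -Inf, ci_upper = Inf,
                     p_bar_1 = 0.5, p_bar_0 = 0.5, ci_width = Inf,
                     ci_level = ci_level, boundary_warning = FALSE,
                     method = "degenerate"), class = "effect_estimate")
    })
    names(out) <- scales
    out
  }
  oc <- run_operating_characteristics(
    list(degenerate = degenerate), reference_null(),
    n_grid = 30, n_reps = 100, mode = "type1", scale = "risk_difference",
    seed = 77)
  res <- oc$results$degenerate
  expect_equal(res$rate, 0)
  expect_equal(res$coverage, 1)
  expect_equal(res$separation_freq, 1) # infinite widths exceed 1
})

test_that("permutation replicates center the effect on the null value", {
  oc <- run_operating_characteristics(
    oc_method("binary", adjusted = TRUE), reference_null(),
    n_grid = 60, n_reps = 200, mode = "type1", scale = "risk_difference",
    seed = 303)
  res <- oc$results$binary_adjusted
  # mean estimate within 3 MC SEs of zero
  expect_lt(abs(res$mean_estimate),
            3 * res$sd_estimate / sqrt(res$n_used))
  expect_equal(res$coverage, 1 - res$rate)
  expect_equal(res$mc_se, monte_carlo_se(res$rate, res$n_used))
})

test_that("operating-characteristics runs are reproducible given a seed", {
  m <- oc_method("binary", adjusted = TRUE)
  oc1 <- run_operating_characteristics(m, reference_null(), n_grid = 30,
                                       n_reps = 100, mode = "type1",
                                       seed = 11)
  oc2 <- run_operating_characteristics(m, reference_null(), n_grid = 30,
                                       n_reps = 100, mode = "type1",
                                       seed = 11)
  expect_identical(oc1$results, oc2$results)
})
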