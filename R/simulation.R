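#' @name simulation
#' @title Synthetic trial generation and operating-characteristics engine
#'
#' @description
#' The generator emulates the structure of a rheumatoid-arthritis style
#' composite endpoint: a continuous percent-improvement score observed at
#' an interim and a final visit, drawn from a bivariate normal with
#' arm-dependent means, combined with two absorbing failure indicators
#' (pre-interim failure independent of the score; post-interim failure
#' whose log-odds decline in the interim score). Final-visit means can be
#' calibrated so the implied marginal response probabilities hit stated
#' targets (0.470 treatment vs 0.336 placebo for the reference
#' alternative). Re-sampling and permutation harnesses and the
#' operating-characteristics engine estimate power, type I error,
#' coverage, confidence-interval width and separation frequency over a
#' grid of small sample sizes.
NULL

# Run an expression under a temporary RNG state when a seed is supplied.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic-trial generator parameters
#'
#' Defaults state the reference simulated world: score standard deviation
#' 30 at both visits with correlation 0.6, a 5 percent pre-interim failure
#' rate in both arms, a post-interim failure log-odds declining by 0.02 per
#' unit of interim score, response threshold 20 (a 20 percent-improvement
#' responder definition), and a modest score benefit of treatment at both
#' visits. Use [calibrate_generator()] to pin the marginal response
#' probabilities to targets.
#'
#' @param mu0,mu1 per-visit mean outcome (length `T`) in the control and
#'   treatment arm (score units, percent improvement).
#' @param Sigma `T x T` positive-definite within-patient covariance.
#' @param gamma1 interval-1 failure model coefficients `(intercept, arm)`.
#' @param gamma2 interval-2 failure model coefficients
#'   `(intercept, arm, interim-score slope)`.
#' @param threshold response cut-off on the final-visit outcome.
#' @param n_per_arm patients per arm.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(mu0 = c(10, 12),
                             mu1 = c(16, 20),
                             Sigma = 900 * matrix(c(1, 0.6, 0.6, 1), 2, 2),
                             gamma1 = c(stats::qlogis(0.05), 0),
                             gamma2 = c(-2.75, 0, -0.02),
                             threshold = 20,
                             n_per_arm = 40L) {
  Sigma <- as.matrix(Sigma)
  nT <- length(mu0)
  stopifnot(length(mu1) == nT, nrow(Sigma) == nT, ncol(Sigma) == nT,
            length(gamma1) == 2L, length(gamma2) == 3L)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite", call. = FALSE)
  structure(list(mu0 = mu0, mu1 = mu1, Sigma = Sigma,
                 gamma1 = gamma1, gamma2 = gamma2,
                 threshold = threshold, n_per_arm = as.integer(n_per_arm)),
            class = "generator_params")
}

#' Marginal response probability implied by generator parameters
#'
#' Closed-form (quadrature) evaluation of
#' `(1 - pi_D1) E[(1 - pi_D2(y1)) 1{y2 >= c}]` for one arm — the quantity
#' the calibration root-finds on and the oracle for empirical response
#' rates of generated trials.
#'
#' @param params a `generator_params`.
#' @param arm 0 or 1.
#' @param nodes Gauss-Hermite nodes used for the interim-score integral.
#' @return probability in (0, 1).
#' @export
marginal_response_probability <- function(params, arm, nodes = 80L) {
  mu <- if (arm == 1) params$mu1 else params$mu0
  S <- params$Sigma
  s1 <- sqrt(S[1, 1]); s2 <- sqrt(S[2, 2])
  rho <- S[1, 2] / (s1 * s2)
  s_cond <- s2 * sqrt(max(1 - rho^2, 1e-12))
  gh <- gauss_hermite(nodes)
  y1 <- mu[1] + sqrt(2) * s1 * gh$nodes
  w <- gh$weights / sqrt(pi)
  mu_cond <- mu[2] + rho * (s2 / s1) * (y1 - mu[1])
  p_nofail1 <- 1 - plogis(params$gamma1[1] + params$gamma1[2] * arm)
  integ <- (1 - plogis(params$gamma2[1] + params$gamma2[2] * arm +
                         params$gamma2[3] * y1)) *
    stats::pnorm((mu_cond - params$threshold) / s_cond)
  p_nofail1 * sum(w * integ)
}

#' Generate a synthetic composite-endpoint trial
#'
#' Draws `(y1, y2)` bivariate normal per patient from the arm means and
#' covariance, interval-1 failure `D1 ~ Bernoulli(expit(g01 + g11 z))`,
#' interval-2 failure (absorbing) `D2 | D1 = 0 ~
#' Bernoulli(expit(g02 + g12 z + g22 y1))`, and derives responder flags.
#' Byte-identical output for a fixed seed.
#'
#' @param params a `generator_params`.
#' @param seed optional integer seed; when supplied the global RNG state is
#'   left untouched.
#' @return A `trial_dataset`.
#' @export
generate_trial <- function(params, seed = NULL) {
  with_local_seed(seed, {
    n <- 2L * params$n_per_arm
    arm <- rep(c(0L, 1L), each = params$n_per_arm)
    L <- chol(params$Sigma)
    nT <- length(params$mu0)
    Z <- matrix(stats::rnorm(n * nT), n, nT)
    Y <- Z %*% L
    mu_mat <- rbind(matrix(params$mu0, params$n_per_arm, nT, byrow = TRUE),
                    matrix(params$mu1, params$n_per_arm, nT, byrow = TRUE))
    Y <- Y + mu_mat
    d1 <- stats::rbinom(n, 1L, plogis(params$gamma1[1] +
                                        params$gamma1[2] * arm))
    p2 <- plogis(params$gamma2[1] + params$gamma2[2] * arm +
                   params$gamma2[3] * Y[, 1])
    d2 <- ifelse(d1 == 1L, 1L, stats::rbinom(n, 1L, p2))
    baseline <- stats::rnorm(n, 50, 10)
    trial_dataset(
      patient_id = sprintf("P%04d", seq_len(n)),
      arm = arm, baseline = baseline,
      y = Y, d = cbind(d1, d2),
      threshold = params$threshold
    )
  })
}

#' Calibrate generator means to target response probabilities
#'
#' Adjusts each arm's final-visit mean by root-finding on the closed-form
#' marginal response probability until the implied marginals equal the
#' targets to 1e-6. All other parameters are left untouched.
#'
#' @param target_p1,target_p0 target response probabilities (treatment,
#'   control), each in (0, 1).
#' @param base a `generator_params` to start from.
#' @return A calibrated `generator_params`.
#' @export
calibrate_generator <- function(target_p1, target_p0,
                                base = generator_params()) {
  stopifnot(target_p1 > 0, target_p1 < 1, target_p0 > 0, target_p0 < 1)
  solve_arm <- function(arm, target) {
    f <- function(delta) {
      p <- base
      if (arm == 1) p$mu1[2] <- p$mu1[2] + delta
      else p$mu0[2] <- p$mu0[2] + delta
      marginal_response_probability(p, arm) - target
    }
    lim <- 20 * sqrt(base$Sigma[2, 2])
    if (f(-lim) > 0 || f(lim) < 0) {
      stop("target response probability unreachable given the failure rates",
           call. = FALSE)
    }
    stats::uniroot(f, c(-lim, lim), tol = 1e-10)$root
  }
  out <- base
  out$mu1[2] <- out$mu1[2] + solve_arm(1, target_p1)
  out$mu0[2] <- out$mu0[2] + solve_arm(0, target_p0)
  out
}

#' Reference generators for the evaluation
#'
#' `reference_alternative()` is the default world calibrated to marginal
#' response probabilities 0.470 (treatment) and 0.336 (control);
#' `reference_null()` makes the arms identically distributed and calibrates
#' both to 0.336.
#'
#' @param n_per_arm patients per arm.
#' @return A calibrated `generator_params`.
#' @export
reference_alternative <- function(n_per_arm = 40L) {
  base <- generator_params(n_per_arm = n_per_arm)
  calibrate_generator(0.470, 0.336, base)
}

#' @rdname reference_alternative
#' @export
reference_null <- function(n_per_arm = 40L) {
  base <- generator_params(n_per_arm = n_per_arm)
  base$mu1 <- base$mu0
  base$gamma1[2] <- 0
  base$gamma2[2] <- 0
  calibrate_generator(0.336, 0.336, base)
}

#' Draw a balanced sub-trial without replacement
#'
#' Samples `n_total / 2` patients from each arm of a source trial, the
#' re-sampling scheme used to probe small-sample behaviour under a
#' realistic data structure.
#'
#' @param source a `trial_dataset`.
#' @param n_total even total sub-sample size.
#' @param seed optional integer seed.
#' @return A `trial_dataset` with `n_total` patients.
#' @export
resample_subtrial <- function(source, n_total, seed = NULL) {
  if (n_total %% 2L != 0L) stop("n_total must be even", call. = FALSE)
  half <- n_total %/% 2L
  i0 <- which(source$arm == 0)
  i1 <- which(source$arm == 1)
  if (length(i0) < half || length(i1) < half) {
    stop(sprintf("source arms too small for %d per arm", half),
         call. = FALSE)
  }
  with_local_seed(seed, {
    idx <- c(sample(i0, half), sample(i1, half))
    subset_trial(source, idx)
  })
}

# Row subset preserving class and attributes.
subset_trial <- function(data, idx) {
  nT <- n_visits(data)
  trial_dataset(
    patient_id = data$patient_id[idx],
    arm = data$arm[idx],
    baseline = data$baseline[idx],
    y = y_matrix(data)[idx, , drop = FALSE],
    d = d_matrix(data)[idx, , drop = FALSE],
    threshold = response_threshold(data)
  )
}

#' Permute treatment labels
#'
#' Randomly permutes the arm labels across patients, leaving every outcome
#' untouched; arm sizes are preserved. Used to build the empirical null.
#'
#' @param data a `trial_dataset`.
#' @param seed optional integer seed.
#' @return A `trial_dataset`.
#' @export
permute_labels <- function(data, seed = NULL) {
  with_local_seed(seed, {
    trial_dataset(
      patient_id = data$patient_id,
      arm = sample(data$arm),
      baseline = data$baseline,
      y = y_matrix(data),
      d = d_matrix(data),
      threshold = response_threshold(data)
    )
  })
}

#' Monte Carlo standard error of an estimated proportion
#'
#' @param p the proportion.
#' @param n_reps number of simulation replicates.
#' @return `sqrt(p (1 - p) / n_reps)`.
#' @export
monte_carlo_se <- function(p, n_reps) sqrt(p * (1 - p) / n_reps)

#' Convert a confidence-interval width reduction to a sample-size reduction
#'
#' Under the large-sample scaling `width ~ 1/sqrt(n)`, achieving the same
#' width at a fraction `1 - w` of the original width requires a fraction
#' `(1 - w)^2` of the original sample size, i.e. a reduction of
#' `1 - (1 - w)^2`.
#'
#' @param width_reduction fractional width reduction in `[0, 1)`.
#' @return fractional reduction in required sample size.
#' @export
ci_width_to_sample_size_reduction <- function(width_reduction) {
  if (any(width_reduction < 0 | width_reduction >= 1)) {
    stop("width_reduction must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - width_reduction)^2
}

#' Proportion of confidence intervals wider than a threshold
#'
#' Probability-scale intervals wider than 1 are uninformative (the risk
#' difference lives in `[-1, 1]`) and diagnose perfect separation /
#' variance blow-up in the component fits.
#'
#' @param ci_widths numeric vector of non-negative widths.
#' @param threshold width cut-off (default 1); the comparison is strict.
#' @return proportion of widths strictly greater than `threshold`.
#' @export
separation_frequency <- function(ci_widths, threshold = 1) {
  if (length(ci_widths) == 0L) {
    stop("separation frequency undefined for an empty width list",
         call. = FALSE)
  }
  if (any(ci_widths < 0)) stop("widths must be non-negative", call. = FALSE)
  mean(ci_widths > threshold)
}

#' Describe an analysis method for the operating-characteristics engine
#'
#' @param method `"augbin"` or `"binary"`.
#' @param continuous_fitter `"GLS"` or `"GEE"` (augbin only).
#' @param adjusted logical; `TRUE` applies the small-sample corrections
#'   (Firth penalty; MBN for GEE), `FALSE` the unadjusted fits.
#' @param label display label; autogenerated when `NULL`.
#' @return A list of class `oc_method`.
#' @export
oc_method <- function(method = c("augbin", "binary"),
                      continuous_fitter = c("GLS", "GEE"),
                      adjusted = TRUE, label = NULL) {
  method <- match.arg(method)
  continuous_fitter <- match.arg(continuous_fitter)
  if (is.null(label)) {
    label <- if (method == "binary") {
      sprintf("binary_%s", if (adjusted) "adjusted" else "unadjusted")
    } else {
      sprintf("augbin_%s_%s", tolower(continuous_fitter),
              if (adjusted) "adjusted" else "unadjusted")
    }
  }
  structure(list(method = method, continuous_fitter = continuous_fitter,
                 adjusted = isTRUE(adjusted), label = label),
            class = "oc_method")
}

# Fit one method on one replicate and return effects on the analysis scale
# plus the risk-difference scale (for separation diagnostics). `m` may be a
# user function(data, scale, ci_level) returning a named list of
# effect_estimate objects covering both scales.
run_method_once <- function(m, data, scale, ci_level, quadrature_nodes) {
  scales <- unique(c(scale, "risk_difference"))
  if (is.function(m)) return(m(data, scales, ci_level))
  cfg <- analysis_config(threshold = response_threshold(data),
                         continuous_fitter = m$continuous_fitter,
                         firth = m$adjusted, mbn = m$adjusted,
                         ci_level = ci_level,
                         quadrature_nodes = quadrature_nodes)
  if (m$method == "binary") {
    fit <- fit_standard_binary(data, cfg)
    eff <- estimate_effect_binary(fit, data, scale = scales,
                                  ci_level = ci_level)
  } else {
    fit <- fit_augmented_binary(data, cfg)
    eff <- estimate_effect(fit, data, scale = scales, ci_level = ci_level)
  }
  if (length(scales) == 1L) eff <- stats::setNames(list(eff), scales)
  eff
}

#' Estimate operating characteristics over a sample-size grid
#'
#' For each total sample size `n`, draws `n_reps` replicate trials (from a
#' generator, or balanced sub-samples of a source trial), permutes the
#' treatment labels when `mode = "type1"`, applies every method to the same
#' replicate, and summarizes: rejection rate (the proportion of
#' `100(1 - alpha)`% confidence intervals strictly excluding the null value
#' 0), coverage (its complement under the permutation null), mean and
#' median interval width on the analysis scale, and the separation
#' frequency (proportion of risk-difference intervals wider than 1).
#' Replicates where a method's fit fails are excluded from that method's
#' proportions and counted.
#'
#' @param methods a list of [oc_method()] descriptions (or a single one).
#' @param source a `generator_params` (replicates are generated with
#'   `n/2` per arm) or a `trial_dataset` (replicates are re-sampled).
#' @param n_grid vector of even total sample sizes.
#' @param n_reps replicates per sample size (>= 100).
#' @param alpha nominal test level; intervals are at level `1 - alpha`.
#' @param mode `"power"` (alternative as given) or `"type1"` (labels
#'   permuted to break the treatment-outcome association).
#' @param scale analysis scale for estimates and widths.
#' @param seed optional integer seed for the whole run.
#' @param quadrature_nodes Gauss-Hermite nodes for augbin predictions.
#' @return An object of class `oc_result`: per-method data frames with one
#'   row per `n` (`rate`, `coverage`, `mean_estimate`, `sd_estimate`,
#'   `mean_ci_width`, `median_ci_width`, `separation_freq`, `n_used`,
#'   `n_failed`, `mc_se`), plus run metadata.
#' @export
run_operating_characteristics <- function(methods, source,
                                          n_grid = seq(30L, 80L, by = 10L),
                                          n_reps = 1000L, alpha = 0.05,
                                          mode = c("power", "type1"),
                                          scale = "log_odds", seed = NULL,
                                          quadrature_nodes = 40L) {
  mode <- match.arg(mode)
  scale <- match.arg(scale, names(scale_funs))
  if (inherits(methods, "oc_method") || is.function(methods)) {
    methods <- list(methods)
  }
  if (n_reps < 100L) stop("n_reps must be at least 100", call. = FALSE)
  if (any(n_grid %% 2L != 0L)) stop("sample sizes must be even", call. = FALSE)
  labels <- vapply(seq_along(methods), function(i) {
    m <- methods[[i]]
    if (is.function(m)) {
      nm <- names(methods)[i]
      if (!is.null(nm) && nzchar(nm)) nm else sprintf("custom_%d", i)
    } else {
      m$label
    }
  }, "")
  if (anyDuplicated(labels)) stop("method labels must be unique", call. = FALSE)
  ci_level <- 1 - alpha
  from_generator <- inherits(source, "generator_params")
  if (!from_generator && !inherits(source, "trial_dataset")) {
    stop("source must be generator_params or a trial_dataset", call. = FALSE)
  }

  with_local_seed(seed, {
    per_method <- lapply(labels, function(l) vector("list", length(n_grid)))
    names(per_method) <- labels
    for (gi in seq_along(n_grid)) {
      n <- n_grid[gi]
      rec <- lapply(labels, function(l) {
        list(reject = rep(NA, n_reps), width = rep(NA_real_, n_reps),
             rd_width = rep(NA_real_, n_reps),
             estimate = rep(NA_real_, n_reps), failed = 0L)
      })
      names(rec) <- labels
      for (r in seq_len(n_reps)) {
        dat <- if (from_generator) {
          p <- source; p$n_per_arm <- n %/% 2L
          generate_trial(p)
        } else {
          resample_subtrial(source, n)
        }
        if (mode == "type1") dat <- permute_labels(dat)
        for (mi in seq_along(methods)) {
          m <- methods[[mi]]
          eff <- tryCatch(
            run_method_once(m, dat, scale, ci_level, quadrature_nodes),
            error = function(e) NULL
          )
          l <- labels[mi]
          if (is.null(eff)) {
            rec[[l]]$failed <- rec[[l]]$failed + 1L
            next
          }
          e <- eff[[scale]]
          rec[[l]]$reject[r] <- e$ci_lower > 0 || e$ci_upper < 0
          rec[[l]]$estimate[r] <- e$estimate
          rec[[l]]$width[r] <- e$ci_width
          rec[[l]]$rd_width[r] <- eff[["risk_difference"]]$ci_width
        }
      }
      for (l in labels) {
        x <- rec[[l]]
        ok <- !is.na(x$reject)
        x$reject <- x$reject[ok]; x$estimate <- x$estimate[ok]
        x$width <- x$width[ok]; x$rd_width <- x$rd_width[ok]
        used <- length(x$reject)
        rate <- if (used) mean(x$reject) else NA_real_
        per_method[[l]][[gi]] <- data.frame(
          n = n,
          rate = rate,
          coverage = if (mode == "type1") 1 - rate else NA_real_,
          mean_estimate = if (used) mean(x$estimate) else NA_real_,
          sd_estimate = if (used > 1) stats::sd(x$estimate) else NA_real_,
          mean_ci_width = if (used) mean(x$width) else NA_real_,
          median_ci_width = if (used) stats::median(x$width) else NA_real_,
          separation_freq = if (used) separation_frequency(x$rd_width)
                            else NA_real_,
          n_used = used,
          n_failed = x$failed,
          mc_se = if (used) monte_carlo_se(rate, used) else NA_real_
        )
      }
    }
    results <- lapply(per_method, function(lst) do.call(rbind, lst))
    structure(list(
      mode = mode, scale = scale, alpha = alpha, n_grid = n_grid,
      n_reps = n_reps, seed = seed, methods = labels, results = results
    ), class = "oc_result")
  })
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("<oc_result> mode=%s, scale=%s, alpha=%g, reps=%d\n",
              x$mode, x$scale, x$alpha, x$n_reps))
  for (l in x$methods) {
    cat(sprintf("-- %s\n", l))
    print(x$results[[l]], row.names = FALSE, digits = 4)
  }
  invisible(x)
}
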