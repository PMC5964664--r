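#' @name augbin_core
#' @title The augmented binary estimator
#'
#' @description
#' The composite responder endpoint declares a patient a responder when the
#' final-visit continuous outcome `y_2` reaches the cut-off `c` AND no
#' failure (rescue medication, restricted treatment, withdrawal) occurred.
#' Rather than analysing the dichotomised indicator, the augmented binary
#' method models the components directly and factorizes their joint
#' distribution at two visits as
#' \deqn{f(y_1, y_2 | z)\; \Pr(D_1 = 0 | z)\; \Pr(D_2 = 0 | z, y_1),}
#' with `(y_1, y_2)` bivariate normal with arm-dependent means, `D_1` the
#' pre-interim failure indicator (independent of the score) and `D_2` the
#' post-interim failure indicator conditioned on the interim score. The
#' response probability for a patient under assignment `z` is then
#' \deqn{\tilde p(z) = \Pr(D_1=0|z) \int (1-\pi_{D_2}(z, y_1))
#'   \Phi\!\left(\frac{\mu_{2|1}(y_1) - c}{\sigma_{2|1}}\right)
#'   \phi(y_1)\, dy_1,}
#' evaluated by Gauss-Hermite quadrature. Arm-average probabilities
#' standardize over every randomized patient under both assignments, and
#' treatment effects with delta-method confidence intervals are reported on
#' the log-odds, risk-difference and log-risk-ratio scales.
NULL

PROB_CLIP <- 1e-10

# Gauss-Hermite nodes and weights (physicists' convention,
# integral of exp(-x^2) f(x)) via the Golub-Welsch eigen decomposition.
gauss_hermite <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1L, ord])^2)
}

#' Fit the augmented binary model
#'
#' Fits the continuous component by GLS or GEE (with optional MBN
#' correction) and the two failure models by logistic regression (Firth
#' penalized when `config$firth`): interval 1 on intercept + arm, interval 2
#' on intercept + arm + interim outcome, restricted to patients still at
#' risk (no interval-1 failure) with an observed interim outcome.
#'
#' The assembled parameter vector `theta` concatenates the continuous mean
#' coefficients and both failure-model coefficient vectors; its covariance
#' is block-diagonal (MBN-corrected sandwich for GEE when requested,
#' information-based for GLS, penalized-information for the logistic
#' blocks).
#'
#' @param data a `trial_dataset` with two visits.
#' @param config an [analysis_config()].
#' @return An object of class `augbin_fit`.
#' @export
fit_augmented_binary <- function(data, config = analysis_config()) {
  check_two_arms(data, min_per_arm = 2L)
  if (n_visits(data) != 2L) {
    stop("the augmented binary estimator is implemented for T = 2 visits (interim, final)",
         call. = FALSE)
  }
  penalty <- if (config$firth) "firth" else "none"
  cont <- withCallingHandlers(
    if (config$continuous_fitter == "GLS") {
      fit_gls(data, baseline_adjust = config$baseline_adjust)
    } else {
      fit <- fit_gee(data, baseline_adjust = config$baseline_adjust)
      if (config$mbn) mbn_correct(fit) else fit
    },
    error = function(e) stop(sprintf("continuous component: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  Y <- y_matrix(data)
  D <- d_matrix(data)
  X1 <- cbind(`(Intercept)` = 1, arm = data$arm)
  fail1 <- tryCatch(
    fit_logistic(X1, D[, 1L], penalty = penalty),
    error = function(e) stop(sprintf("interval-1 failure model: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  at_risk <- D[, 1L] == 0 & !is.na(Y[, 1L])
  X2 <- cbind(`(Intercept)` = 1, arm = data$arm[at_risk],
              y1 = Y[at_risk, 1L])
  fail2 <- tryCatch(
    fit_logistic(X2, D[at_risk, 2L], penalty = penalty),
    error = function(e) stop(sprintf("interval-2 failure model: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  cov_cont <- if (cont$fitter == "GEE") {
    if (!is.null(cont$cov_mbn)) cont$cov_mbn else cont$cov_robust
  } else {
    cont$cov_model
  }
  theta <- c(cont$beta, fail1$beta, fail2$beta)
  q <- length(theta)
  pc <- cont$p
  cov_theta <- matrix(0, q, q)
  cov_theta[seq_len(pc), seq_len(pc)] <- cov_cont
  cov_theta[pc + 1:2, pc + 1:2] <- fail1$cov
  cov_theta[pc + 2 + 1:3, pc + 2 + 1:3] <- fail2$cov
  idx <- list(cont = seq_len(pc), fail1 = pc + 1:2, fail2 = pc + 2 + 1:3)
  gh <- gauss_hermite(config$quadrature_nodes)
  structure(list(
    cont = cont, fail_models = list(fail1, fail2),
    theta = theta, cov_theta = cov_theta, idx = idx,
    Sigma = cont$Sigma,
    threshold = response_threshold(data),
    baseline_adjust = config$baseline_adjust,
    quadrature_nodes = config$quadrature_nodes,
    gh = gh,
    config = config,
    separation_detected = fail1$separation_detected ||
      fail2$separation_detected,
    n_at_risk_interval2 = sum(at_risk)
  ), class = "augbin_fit")
}

#' @export
print.augbin_fit <- function(x, ...) {
  cat(sprintf("<augbin_fit> continuous: %s%s; failure models: %s penalty; threshold %g\n",
              x$cont$fitter,
              if (!is.null(x$cont$cov_mbn)) " + MBN" else "",
              x$fail_models[[1L]]$penalty, x$threshold))
  if (x$separation_detected) cat("  note: separation detected in a failure model\n")
  cat("  theta:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Predicted response probability under an assigned arm
#'
#' Computes the model-implied probability that a patient would be a
#' responder under assignment `arm`, integrating the fitted bivariate
#' normal over the response region with Gauss-Hermite quadrature and
#' weighting by the probability of avoiding both failure intervals. The
#' result is clipped to `[1e-10, 1 - 1e-10]`.
#'
#' @param fit an `augbin_fit`.
#' @param arm 0 or 1, the assignment to predict under.
#' @param baseline baseline score(s); used only when the fit adjusts for
#'   baseline. May be a vector (one probability per value).
#' @param theta optional parameter vector overriding `fit$theta` (used
#'   internally by the delta method).
#' @return numeric vector of probabilities.
#' @export
predict_response_probability <- function(fit, arm, baseline = NULL,
                                         theta = NULL) {
  stopifnot(inherits(fit, "augbin_fit"), arm %in% c(0, 1))
  if (is.null(theta)) theta <- fit$theta
  bcont <- theta[fit$idx$cont]
  g1 <- theta[fit$idx$fail1]
  g2 <- theta[fit$idx$fail2]
  S <- fit$Sigma
  s1 <- sqrt(S[1, 1]); s2 <- sqrt(S[2, 2])
  rho <- S[1, 2] / (s1 * s2)
  if (fit$baseline_adjust) {
    if (is.null(baseline)) stop("fit adjusts for baseline; supply baseline",
                                call. = FALSE)
    bl <- as.numeric(baseline)
  } else {
    bl <- 0
  }
  mu1 <- bcont[1] + arm * bcont[3] +
    if (fit$baseline_adjust) bl * bcont[5] else 0
  mu2 <- bcont[2] + arm * bcont[4] +
    if (fit$baseline_adjust) bl * bcont[5] else 0
  p_nofail1 <- 1 - plogis(g1[1] + g1[2] * arm)
  s_cond <- s2 * sqrt(max(1 - rho^2, 1e-12))
  nodes <- fit$gh$nodes
  w <- fit$gh$weights / sqrt(pi)
  # one probability per baseline value; vectorized over quadrature nodes
  out <- vapply(seq_along(mu1), function(i) {
    y1 <- mu1[i] + sqrt(2) * s1 * nodes
    mu_cond <- mu2[i] + rho * (s2 / s1) * (y1 - mu1[i])
    integrand <- (1 - plogis(g2[1] + g2[2] * arm + g2[3] * y1)) *
      stats::pnorm((mu_cond - fit$threshold) / s_cond)
    p_nofail1 * sum(w * integrand)
  }, 0)
  pmin(pmax(out, PROB_CLIP), 1 - PROB_CLIP)
}

# Arm-average response probabilities standardized over all patients:
# every randomized patient contributes a prediction under both assignments.
augbin_pbar <- function(fit, data, theta = NULL) {
  bl <- if (fit$baseline_adjust) data$baseline else NULL
  p1 <- predict_response_probability(fit, 1, baseline = bl, theta = theta)
  p0 <- predict_response_probability(fit, 0, baseline = bl, theta = theta)
  c(p1 = mean(p1), p0 = mean(p0))
}

# ---- shared delta-method machinery -----------------------------------------

scale_funs <- list(
  log_odds = list(
    g = function(p1, p0) stats::qlogis(p1) - stats::qlogis(p0),
    dg = function(p1, p0) c(1 / (p1 * (1 - p1)), -1 / (p0 * (1 - p0)))
  ),
  risk_difference = list(
    g = function(p1, p0) p1 - p0,
    dg = function(p1, p0) c(1, -1)
  ),
  log_risk_ratio = list(
    g = function(p1, p0) log(p1) - log(p0),
    dg = function(p1, p0) c(1 / p1, -1 / p0)
  )
)

# Delta-method effects for one or more scales from an arm-probability
# functional pbar_fun(theta) -> c(p1, p0). The (2 x q) Jacobian is computed
# once by central differences and reused across scales.
delta_effects <- function(pbar_fun, theta, cov_theta, scales, ci_level,
                          method) {
  q <- length(theta)
  pb <- unname(pbar_fun(theta))
  J <- matrix(0, 2L, q)
  for (j in seq_len(q)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (pbar_fun(up) - pbar_fun(dn)) / (2 * h)
  }
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  boundary <- any(pb <= 2 * PROB_CLIP | pb >= 1 - 2 * PROB_CLIP)
  out <- lapply(scales, function(sc) {
    f <- scale_funs[[sc]]
    est <- f$g(pb[1], pb[2])
    grad <- drop(f$dg(pb[1], pb[2]) %*% J)
    se <- sqrt(max(0, drop(grad %*% cov_theta %*% grad)))
    structure(list(
      scale = sc, estimate = est, se = se,
      ci_lower = est - zq * se, ci_upper = est + zq * se,
      p_bar_1 = unname(pb[1]), p_bar_0 = unname(pb[2]),
      ci_width = 2 * zq * se, ci_level = ci_level,
      boundary_warning = boundary, method = method
    ), class = "effect_estimate")
  })
  names(out) <- scales
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s (%s)\n", x$scale, x$method))
  cat(sprintf("  estimate %.4f (SE %.4f), %g%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, 100 * x$ci_level, x$ci_lower, x$ci_upper))
  cat(sprintf("  arm-average response probabilities: treated %.4f, control %.4f\n",
              x$p_bar_1, x$p_bar_0))
  if (x$boundary_warning) {
    cat("  warning: an arm-average probability sits at the clipping boundary\n")
  }
  invisible(x)
}

#' Treatment effect with delta-method confidence interval (augmented binary)
#'
#' Averages the per-patient predicted response probabilities under both
#' assignments (standardization over all randomized patients), transforms
#' the pair to the requested scale, and propagates the block-diagonal
#' parameter covariance through a numerically differentiated gradient.
#'
#' @param fit an `augbin_fit`.
#' @param data the `trial_dataset` whose patients define the
#'   standardization population (normally the data the model was fitted to).
#' @param scale `"log_odds"`, `"risk_difference"` or `"log_risk_ratio"`;
#'   may be a vector, in which case a named list is returned.
#' @param ci_level confidence level.
#' @return An `effect_estimate` (or named list of them).
#' @export
estimate_effect <- function(fit, data, scale = "log_odds", ci_level = 0.95) {
  stopifnot(inherits(fit, "augbin_fit"))
  scale <- match.arg(scale, names(scale_funs), several.ok = TRUE)
  res <- delta_effects(function(th) augbin_pbar(fit, data, th),
                       fit$theta, fit$cov_theta, scale, ci_level,
                       method = "augmented_binary")
  if (length(scale) == 1L) res[[1L]] else res
}
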