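# Independent oracles used across the suite. These deliberately take a
# different computational route than the package internals they check.

# Log-likelihood of a logistic model, optionally with the Jeffreys penalty.
oracle_logistic_loglik <- function(beta, X, y, penalized = TRUE) {
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  if (penalized) {
    w <- plogis(eta) * (1 - plogis(eta))
    ll <- ll + 0.5 * determinant(crossprod(X, X * w))$modulus[1]
  }
  ll
}

# Brute-force maximizer of the (penalized) logistic likelihood:
# Nelder-Mead from several starts, refined by BFGS on the negative
# objective. No IRLS, no modified score.
oracle_firth_mle <- function(X, y, penalized = TRUE) {
  obj <- function(b) -oracle_logistic_loglik(b, X, y, penalized)
  p <- ncol(X)
  best <- NULL
  for (start in list(rep(0, p), rep(0.5, p), rep(-0.5, p))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}

# Second, independently coded evaluation of the MBN-corrected covariance.
oracle_mbn <- function(sandwich, naive, K, p, n_obs) {
  total <- sum(n_obs)
  kappa <- (total - 1) / (total - p) * K / (K - 1)
  delta_K <- min(0.5, p / (K - p))
  xi_hat <- max(1, sum(diag(solve(naive) %*% sandwich)) / p)
  kappa * sandwich + delta_K * xi_hat * naive
}

# Observed-data normal log-likelihood for the longitudinal model, used to
# check the EM-based GLS fit by direct numerical maximization.
oracle_gls_loglik <- function(par, Y, arm, nT) {
  beta <- par[1:(2 * nT)]
  L <- matrix(0, nT, nT)
  L[lower.tri(L, diag = TRUE)] <- par[-(1:(2 * nT))]
  diag(L) <- exp(diag(L))
  Sigma <- L %*% t(L)
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    X <- matrix(0, nT, 2 * nT)
    X[cbind(1:nT, 1:nT)] <- 1
    X[cbind(1:nT, nT + 1:nT)] <- arm[i]
    mu <- drop(X %*% beta)[o]
    S <- Sigma[o, o, drop = FALSE]
    r <- Y[i, o] - mu
    ll <- ll - 0.5 * (length(o) * log(2 * pi) +
                        determinant(S)$modulus[1] +
                        drop(r %*% solve(S, r)))
  }
  ll
}

oracle_gls_fit <- function(Y, arm, nT) {
  m0 <- colMeans(Y, na.rm = TRUE)
  start <- c(m0, rep(0, nT), rep(log(stats::sd(Y, na.rm = TRUE)), nT),
             rep(0, nT * (nT - 1) / 2))
  # parameter order for the chol factor: lower triangle column-major
  start <- c(m0, rep(0, nT),
             local({
               L <- diag(log(apply(Y, 2, stats::sd, na.rm = TRUE)), nT)
               L[lower.tri(L, diag = TRUE)]
             }))
  o <- stats::optim(start, function(p) -oracle_gls_loglik(p, Y, arm, nT),
                    method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, function(p) -oracle_gls_loglik(p, Y, arm, nT),
                    method = "BFGS", control = list(maxit = 2000))
  list(beta = o$par[1:(2 * nT)], value = -o$value)
}

# Factorized closed form for the predicted response probability when the
# interval-2 failure model does not depend on the interim score.
oracle_closed_form_prob <- function(g1, g2, mu2, s2, c, arm) {
  (1 - plogis(g1[1] + g1[2] * arm)) *
    (1 - plogis(g2[1] + g2[2] * arm)) *
    stats::pnorm((mu2 - c) / s2)
}

# Small deterministic trial fixture: 2 visits, threshold 20.
make_toy_trial <- function(threshold = 20) {
  trial_dataset(
    patient_id = paste0("P", 1:4),
    arm = c(0, 0, 1, 1),
    baseline = c(50, 55, 48, 52),
    y = matrix(c(5, 8, 12, 10, 25, 10, 30, NA), 4, 2),
    d = matrix(c(0, 0, 0, 0, 0, 0, 0, 1), 4, 2),
    threshold = threshold
  )
}

# A generated trial of moderate size for fitter tests.
make_generated_trial <- function(n_per_arm = 40L, seed = 101L,
                                 alternative = TRUE) {
  params <- if (alternative) reference_alternative(n_per_arm) else
    reference_null(n_per_arm)
  generate_trial(params, seed = seed)
}
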