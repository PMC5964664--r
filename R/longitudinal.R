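#' @name longitudinal
#' @title Repeated-measures fitters for the continuous component
#'
#' @description
#' The continuous component of the composite endpoint (percent improvement
#' at each scheduled visit) is fitted with a saturated time-by-treatment
#' mean model: one intercept per visit, one arm effect per visit, and
#' optionally a common baseline slope. Two fitters are provided:
#'
#' * `fit_gls()` — maximum likelihood under multivariate normality with an
#'   unstructured within-patient covariance, using every patient with at
#'   least one observed visit (missing-at-random assumption);
#' * `fit_gee()` — generalized estimating equations with identity link, a
#'   working correlation, the model-based ("naive") covariance and the
#'   cluster-robust sandwich covariance.
#'
#' `mbn_correct()` applies the Morel-Bokossa-Neerchal small-sample
#' inflation to the sandwich covariance of a GEE fit.
NULL

# Design matrix for one patient: visit intercepts, visit-specific arm
# effects, optional shared baseline slope. Rows = visits.
cont_design <- function(arm, baseline, nT, baseline_adjust) {
  p <- 2L * nT + as.integer(baseline_adjust)
  X <- matrix(0, nT, p)
  X[cbind(seq_len(nT), seq_len(nT))] <- 1
  X[cbind(seq_len(nT), nT + seq_len(nT))] <- arm
  if (baseline_adjust) X[, p] <- baseline
  X
}

cont_param_names <- function(nT, baseline_adjust) {
  nm <- c(paste0("visit", seq_len(nT)), paste0("arm:visit", seq_len(nT)))
  if (baseline_adjust) nm <- c(nm, "baseline")
  nm
}

new_longitudinal_fit <- function(beta, Sigma, cov_model, cov_robust, cov_mbn,
                                 fitter, n_clusters, n_obs, baseline_adjust,
                                 nT, converged, n_iter, extra = list()) {
  structure(c(list(
    beta = beta, Sigma = Sigma, cov_model = cov_model,
    cov_robust = cov_robust, cov_mbn = cov_mbn, fitter = fitter,
    n_clusters = n_clusters, p = length(beta), n_obs = n_obs,
    baseline_adjust = baseline_adjust, n_visits = nT,
    converged = converged, n_iter = n_iter
  ), extra), class = "longitudinal_fit")
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat(sprintf("<longitudinal_fit> %s, %d clusters, %d visits, converged=%s\n",
              x$fitter, x$n_clusters, x$n_visits, x$converged))
  se <- sqrt(diag(if (!is.null(x$cov_mbn)) x$cov_mbn
                  else if (!is.null(x$cov_robust)) x$cov_robust
                  else x$cov_model))
  print(data.frame(estimate = x$beta, se = se))
  invisible(x)
}

#' Fit the continuous component by generalized least squares (normal ML)
#'
#' Maximum-likelihood estimation of the saturated visit/arm mean model with
#' an unstructured T x T covariance, using all patients with at least one
#' observed continuous outcome. Missing visits are handled by an EM update
#' of the covariance (conditional expectations of the unobserved residual
#' products), which yields the exact observed-data ML solution.
#'
#' @param data a `trial_dataset`.
#' @param baseline_adjust include a common baseline slope in the mean model.
#' @param max_iter,tol EM iteration controls.
#' @return A `longitudinal_fit` with `cov_model` from the GLS information
#'   matrix (`cov_robust`/`cov_mbn` are `NULL` for GLS).
#' @export
fit_gls <- function(data, baseline_adjust = FALSE, max_iter = 200L,
                    tol = 1e-8) {
  check_two_arms(data, min_per_arm = 2L)
  nT <- n_visits(data)
  Y <- y_matrix(data)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  arm <- data$arm[keep]
  bl <- data$baseline[keep]
  K <- nrow(Y)
  for (a in 0:1) {
    if (sum(arm == a) < 2L) {
      stop("need >= 2 patients per arm with observed continuous outcomes",
           call. = FALSE)
    }
  }
  p <- 2L * nT + as.integer(baseline_adjust)
  n_obs <- rowSums(!is.na(Y))
  if (sum(n_obs) < p) stop("fewer observations than mean parameters",
                           call. = FALSE)

  complete <- !anyNA(Y)
  Xlist <- lapply(seq_len(K), function(i) {
    cont_design(arm[i], bl[i], nT, baseline_adjust)
  })

  if (complete && !baseline_adjust) {
    # Saturated means with complete data: ML beta = visitwise arm means,
    # ML Sigma = mean residual outer product. No iteration needed.
    m0 <- colMeans(Y[arm == 0, , drop = FALSE])
    m1 <- colMeans(Y[arm == 1, , drop = FALSE])
    beta <- c(m0, m1 - m0)
    fitted <- ifelse(matrix(arm, K, nT) == 1,
                     matrix(m1, K, nT, byrow = TRUE),
                     matrix(m0, K, nT, byrow = TRUE))
    res <- Y - fitted
    Sigma <- crossprod(res) / K
    Sinv <- solve(Sigma)
    A <- matrix(0, p, p)
    X0 <- cont_design(0, 0, nT, FALSE)
    X1 <- cont_design(1, 0, nT, FALSE)
    A <- sum(arm == 0) * crossprod(X0, Sinv %*% X0) +
      sum(arm == 1) * crossprod(X1, Sinv %*% X1)
    cov_model <- solve(A)
    names(beta) <- cont_param_names(nT, FALSE)
    dimnames(cov_model) <- list(names(beta), names(beta))
    return(new_longitudinal_fit(beta, Sigma, cov_model, NULL, NULL, "GLS",
                                K, n_obs, FALSE, nT, TRUE, 1L))
  }

  obs_list <- lapply(seq_len(K), function(i) which(!is.na(Y[i, ])))
  # initial values: visitwise OLS means, diagonal covariance
  beta <- numeric(p)
  for (t in seq_len(nT)) {
    ok <- !is.na(Y[, t])
    if (baseline_adjust) {
      cf <- stats::coef(stats::lm(Y[ok, t] ~ arm[ok] + bl[ok]))
      beta[t] <- cf[1]; beta[nT + t] <- cf[2]
      beta[p] <- beta[p] + cf[3] / nT
    } else {
      beta[t] <- mean(Y[ok & arm == 0, t])
      beta[nT + t] <- mean(Y[ok & arm == 1, t]) - beta[t]
    }
  }
  v <- vapply(seq_len(nT), function(t) stats::var(Y[, t], na.rm = TRUE), 0)
  Sigma <- diag(pmax(v, 1e-8), nT)

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # GLS step for beta given Sigma
    A <- matrix(0, p, p)
    b <- numeric(p)
    Sinv_cache <- list()
    for (i in seq_len(K)) {
      o <- obs_list[[i]]
      key <- paste(o, collapse = ",")
      if (is.null(Sinv_cache[[key]])) {
        Sinv_cache[[key]] <- solve(Sigma[o, o, drop = FALSE])
      }
      Si <- Sinv_cache[[key]]
      Xi <- Xlist[[i]][o, , drop = FALSE]
      XtS <- crossprod(Xi, Si)
      A <- A + XtS %*% Xi
      b <- b + XtS %*% Y[i, o]
    }
    beta_new <- drop(solve(A, b))
    # EM step for Sigma: E[r r' | observed part]
    S_acc <- matrix(0, nT, nT)
    for (i in seq_len(K)) {
      o <- obs_list[[i]]
      m <- setdiff(seq_len(nT), o)
      r <- numeric(nT)
      r[o] <- Y[i, o] - drop(Xlist[[i]][o, , drop = FALSE] %*% beta_new)
      E <- tcrossprod(r)
      if (length(m)) {
        Si <- Sinv_cache[[paste(o, collapse = ",")]]
        B <- Sigma[m, o, drop = FALSE] %*% Si
        r[m] <- drop(B %*% r[o])
        E <- tcrossprod(r)
        C <- Sigma[m, m, drop = FALSE] -
          B %*% Sigma[o, m, drop = FALSE]
        E[m, m] <- E[m, m] + C
      }
      S_acc <- S_acc + E
    }
    Sigma_new <- S_acc / K
    if (min(eigen(Sigma_new, symmetric = TRUE, only.values = TRUE)$values) <=
        1e-10) {
      stop("within-patient covariance iterate is not positive definite",
           call. = FALSE)
    }
    delta <- max(max(abs(beta_new - beta)), max(abs(Sigma_new - Sigma)))
    beta <- beta_new
    Sigma <- Sigma_new
    if (delta < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # information-based covariance of beta at the ML solution
  A <- matrix(0, p, p)
  for (i in seq_len(K)) {
    o <- obs_list[[i]]
    Si <- solve(Sigma[o, o, drop = FALSE])
    Xi <- Xlist[[i]][o, , drop = FALSE]
    A <- A + crossprod(Xi, Si %*% Xi)
  }
  cov_model <- solve(A)
  names(beta) <- cont_param_names(nT, baseline_adjust)
  dimnames(cov_model) <- list(names(beta), names(beta))
  new_longitudinal_fit(beta, Sigma, cov_model, NULL, NULL, "GLS", K, n_obs,
                       baseline_adjust, nT, converged, iter)
}

#' Fit the continuous component by GEE (identity link)
#'
#' Gaussian-type GEE with identity link and a working correlation; missing
#' visits are dropped patientwise (visitwise deletion). Returns the
#' model-based covariance (`cov_model`) and the cluster-robust sandwich
#' (`cov_robust`). Apply [mbn_correct()] afterwards for the small-sample
#' corrected covariance.
#'
#' @inheritParams fit_gls
#' @param working_corr `"exchangeable"` (default), `"independence"` or
#'   `"unstructured"`.
#' @param max_iter,tol iteration controls on the coefficient update.
#' @return A `longitudinal_fit` with `cov_model` and `cov_robust` set.
#' @export
fit_gee <- function(data, working_corr = c("exchangeable", "independence",
                                           "unstructured"),
                    baseline_adjust = FALSE, max_iter = 50L, tol = 1e-8) {
  working_corr <- match.arg(working_corr)
  check_two_arms(data, min_per_arm = 2L)
  nT <- n_visits(data)
  Y <- y_matrix(data)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  arm <- data$arm[keep]
  bl <- data$baseline[keep]
  K <- nrow(Y)
  for (a in 0:1) {
    if (sum(arm == a) < 2L) {
      stop("sandwich covariance requires >= 2 clusters per arm", call. = FALSE)
    }
  }
  p <- 2L * nT + as.integer(baseline_adjust)
  n_obs <- rowSums(!is.na(Y))
  obs_list <- lapply(seq_len(K), function(i) which(!is.na(Y[i, ])))
  Xlist <- lapply(seq_len(K), function(i) {
    cont_design(arm[i], bl[i], nT, baseline_adjust)
  })

  R_full <- function(alpha) {
    if (working_corr == "independence") return(diag(nT))
    if (working_corr == "exchangeable") {
      R <- matrix(alpha, nT, nT); diag(R) <- 1; return(R)
    }
    alpha # unstructured: alpha is already the T x T correlation matrix
  }

  beta <- numeric(p)
  alpha <- if (working_corr == "unstructured") diag(nT) else 0
  phi <- 1
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    R <- R_full(alpha)
    A <- matrix(0, p, p)
    b <- numeric(p)
    Rinv_cache <- list()
    for (i in seq_len(K)) {
      o <- obs_list[[i]]
      key <- paste(o, collapse = ",")
      if (is.null(Rinv_cache[[key]])) {
        Rinv_cache[[key]] <- solve(R[o, o, drop = FALSE])
      }
      Xi <- Xlist[[i]][o, , drop = FALSE]
      XtR <- crossprod(Xi, Rinv_cache[[key]])
      A <- A + XtR %*% Xi
      b <- b + XtR %*% Y[i, o]
    }
    beta_new <- drop(solve(A, b))
    # moment updates of dispersion and working correlation
    res <- lapply(seq_len(K), function(i) {
      o <- obs_list[[i]]
      Y[i, o] - drop(Xlist[[i]][o, , drop = FALSE] %*% beta_new)
    })
    phi <- sum(vapply(res, function(r) sum(r^2), 0)) / (sum(n_obs) - p)
    if (working_corr == "exchangeable") {
      num <- 0; den <- 0
      for (i in seq_len(K)) {
        r <- res[[i]] / sqrt(phi)
        ni <- length(r)
        if (ni > 1) {
          num <- num + (sum(r)^2 - sum(r^2)) / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      alpha <- if (den > p) num / (den - p) else num / den
      alpha <- max(min(alpha, 0.99), -0.99 / (nT - 1))
    } else if (working_corr == "unstructured") {
      S <- matrix(0, nT, nT); cnt <- matrix(0, nT, nT)
      for (i in seq_len(K)) {
        o <- obs_list[[i]]
        r <- res[[i]] / sqrt(phi)
        S[o, o] <- S[o, o] + tcrossprod(r)
        cnt[o, o] <- cnt[o, o] + 1
      }
      alpha <- S / pmax(cnt - p / K, 1)
      dg <- sqrt(diag(alpha))
      alpha <- alpha / outer(dg, dg)
      diag(alpha) <- 1
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop(sprintf("GEE did not converge in %d iterations (last max coefficient change %.3g)",
                 max_iter, delta), call. = FALSE)
  }
  R <- R_full(alpha)
  Bread <- matrix(0, p, p)
  Meat <- matrix(0, p, p)
  for (i in seq_len(K)) {
    o <- obs_list[[i]]
    Vinv <- solve(phi * R[o, o, drop = FALSE])
    Xi <- Xlist[[i]][o, , drop = FALSE]
    XtV <- crossprod(Xi, Vinv)
    Bread <- Bread + XtV %*% Xi
    ri <- Y[i, o] - drop(Xi %*% beta)
    u <- XtV %*% ri
    Meat <- Meat + tcrossprod(u)
  }
  cov_model <- solve(Bread)
  cov_robust <- cov_model %*% Meat %*% cov_model
  cov_robust <- (cov_robust + t(cov_robust)) / 2
  names(beta) <- cont_param_names(nT, baseline_adjust)
  dimnames(cov_model) <- dimnames(cov_robust) <-
    list(names(beta), names(beta))
  new_longitudinal_fit(beta, phi * R, cov_model, cov_robust, NULL, "GEE", K,
                       n_obs, baseline_adjust, nT, converged, iter,
                       extra = list(working_corr = working_corr,
                                    phi = phi, alpha = alpha))
}

#' Morel-Bokossa-Neerchal small-sample covariance correction
#'
#' The robust sandwich covariance of a GEE fit is biased downwards when the
#' number of clusters `K` is small, inflating type I error. The MBN
#' correction replaces it by
#' \deqn{f A + \delta \xi B,}
#' where `A` is the sandwich, `B` the model-based covariance,
#' `f = ((sum n_i - 1)/(sum n_i - p)) * (K/(K - 1))`,
#' `delta = min(0.5, p/(K - p))` and
#' `xi = max(1, trace(B^{-1} A)/p)`. The multiplicative factor `f >= 1` and
#' the additive positive semi-definite term guarantee elementwise diagonal
#' inflation; the correction vanishes as `K` grows.
#'
#' @param fit a `longitudinal_fit` produced by [fit_gee()].
#' @return The fit with `cov_mbn` filled in; all other fields unchanged.
#' @references Morel, J.G., Bokossa, M.C., Neerchal, N.K. (2003) Small
#'   sample correction for the variance of GEE estimators. Biometrical
#'   Journal 45, 395-409.
#' @export
mbn_correct <- function(fit) {
  if (!inherits(fit, "longitudinal_fit") || fit$fitter != "GEE" ||
      is.null(fit$cov_robust)) {
    stop("mbn_correct() requires a GEE fit with a sandwich covariance",
         call. = FALSE)
  }
  K <- fit$n_clusters
  p <- fit$p
  if (K <= p) stop("MBN correction undefined for K <= p clusters",
                   call. = FALSE)
  N <- sum(fit$n_obs)
  A <- fit$cov_robust
  B <- fit$cov_model
  f <- ((N - 1) / (N - p)) * (K / (K - 1))
  delta <- min(0.5, p / (K - p))
  xi <- max(1, sum(diag(solve(B, A))) / p)
  fit$cov_mbn <- f * A + delta * xi * B
  fit
}
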