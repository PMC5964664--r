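#' Construct a composite-endpoint trial dataset
#'
#' Bundles patient-level data for a randomized two-arm trial with a composite
#' responder endpoint: a continuous outcome (percent improvement from
#' baseline) observed at `T` scheduled visits, and `T` absorbing binary
#' failure indicators (rescue medication, protocol-restricted treatment or
#' withdrawal during interval `t`). The derived responder flag is 1 only for
#' patients whose final-visit outcome is observed and at least `threshold`,
#' and who never failed.
#'
#' @param patient_id vector of unique patient identifiers.
#' @param arm integer vector in \{0, 1\}; 0 = control, 1 = treatment.
#' @param baseline numeric vector of baseline scores (score units).
#' @param y numeric matrix, one row per patient, one column per visit;
#'   `NA` marks a missed visit.
#' @param d binary matrix of failure indicators, same shape as `y`; must be
#'   non-decreasing within each row (failure is an absorbing state).
#' @param threshold response cut-off applied to the final-visit outcome
#'   (e.g. 20 for a 20 percent-improvement responder definition).
#'
#' @return An object of class `trial_dataset`: a data frame with columns
#'   `patient_id`, `arm`, `baseline`, `y_1..y_T`, `d_1..d_T`, `responder`,
#'   and attributes `n_visits` and `threshold`.
#' @seealso [read_trial_csv()], [derive_responder()]
#' @export
trial_dataset <- function(patient_id, arm, baseline, y, d, threshold) {
  y <- as.matrix(y)
  d <- as.matrix(d)
  n <- length(patient_id)
  if (length(arm) != n || length(baseline) != n ||
      nrow(y) != n || nrow(d) != n) {
    stop("patient_id, arm, baseline, y and d must describe the same patients",
         call. = FALSE)
  }
  if (ncol(y) != ncol(d)) {
    stop("y and d must have the same number of visits", call. = FALSE)
  }
  if (anyDuplicated(patient_id)) {
    stop("patient_id values must be unique", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop("threshold must be a single finite number", call. = FALSE)
  }
  if (anyNA(arm) || !all(arm %in% c(0, 1))) {
    bad <- patient_id[which(!(arm %in% c(0, 1)))[1L]]
    stop(sprintf("arm must be 0 or 1 (patient %s)", bad), call. = FALSE)
  }
  if (anyNA(d) || !all(d %in% c(0, 1))) {
    stop("failure indicators d must be 0 or 1 with no missing values",
         call. = FALSE)
  }
  if (ncol(d) > 1L) {
    nonmono <- which(apply(d, 1L, function(r) any(diff(r) < 0)))
    if (length(nonmono)) {
      stop(sprintf("failure indicators must be non-decreasing within patient (patient %s)",
                   patient_id[nonmono[1L]]), call. = FALSE)
    }
  }
  storage.mode(y) <- "double"
  nT <- ncol(y)
  responder <- derive_responder_matrix(y[, nT], d, threshold)
  out <- data.frame(
    patient_id = patient_id,
    arm = as.integer(arm),
    baseline = as.numeric(baseline),
    stringsAsFactors = FALSE
  )
  colnames(y) <- paste0("y_", seq_len(nT))
  colnames(d) <- paste0("d_", seq_len(nT))
  out <- cbind(out, as.data.frame(y), as.data.frame(d))
  out$responder <- responder
  rownames(out) <- NULL
  structure(out,
            n_visits = nT,
            threshold = threshold,
            class = c("trial_dataset", "data.frame"))
}

#' Derive the composite responder flag for one patient
#'
#' A patient is a responder if and only if the final-visit continuous outcome
#' is observed, meets or exceeds the cut-off `c`, and no failure indicator
#' ever fired. A missing final outcome is treated as non-response
#' (non-responder imputation).
#'
#' @param y_final final-visit continuous outcome; may be `NA`.
#' @param d binary vector of failure indicators across intervals.
#' @param c response cut-off.
#' @return 1L or 0L.
#' @export
derive_responder <- function(y_final, d, c) {
  stopifnot(length(y_final) == 1L)
  if (anyNA(d) || !all(d %in% c(0, 1))) {
    stop("d must be binary with no missing values", call. = FALSE)
  }
  as.integer(!is.na(y_final) && y_final >= c && all(d == 0))
}

# Vectorized responder derivation over a d-matrix (patients x intervals).
derive_responder_matrix <- function(y_final, d, c) {
  failed <- rowSums(d) > 0
  as.integer(!is.na(y_final) & y_final >= c & !failed)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d patients (%d control / %d treatment), %d visits, threshold %g\n",
              nrow(x), sum(x$arm == 0), sum(x$arm == 1),
              n_visits(x), response_threshold(x)))
  cat(sprintf("  responders: %d (%.1f%%)\n", sum(x$responder),
              100 * mean(x$responder)))
  invisible(x)
}

#' Number of scheduled visits in a trial dataset
#' @param data a `trial_dataset`.
#' @return integer.
#' @export
n_visits <- function(data) attr(data, "n_visits")

#' Response threshold of a trial dataset
#' @param data a `trial_dataset`.
#' @return numeric cut-off on the final-visit outcome.
#' @export
response_threshold <- function(data) attr(data, "threshold")

# Matrix views used by the fitters.
y_matrix <- function(data) {
  as.matrix(data[, paste0("y_", seq_len(n_visits(data))), drop = FALSE])
}
d_matrix <- function(data) {
  as.matrix(data[, paste0("d_", seq_len(n_visits(data))), drop = FALSE])
}

# Both arms must be represented before any between-arm analysis.
check_two_arms <- function(data, min_per_arm = 1L) {
  n0 <- sum(data$arm == 0)
  n1 <- sum(data$arm == 1)
  if (n0 < min_per_arm || n1 < min_per_arm) {
    stop(sprintf("analysis requires at least %d patient(s) per arm (control %d, treatment %d)",
                 min_per_arm, n0, n1), call. = FALSE)
  }
  invisible(TRUE)
}

#' Analysis configuration
#'
#' Collects the knobs shared by the standard binary and augmented binary
#' analyses. Defaults follow the recommended small-sample configuration:
#' Firth-penalized logistic components, GLS for the continuous component,
#' 95 percent confidence level.
#'
#' @param threshold response cut-off on the final-visit outcome (20, 50 and
#'   70 are conventional percent-improvement levels; any real is accepted).
#' @param scale effect scale: `"log_odds"`, `"risk_difference"` or
#'   `"log_risk_ratio"`.
#' @param continuous_fitter `"GLS"` (normal maximum likelihood) or `"GEE"`.
#' @param firth logical; apply Firth's penalized likelihood to logistic
#'   components.
#' @param mbn logical; apply the Morel-Bokossa-Neerchal covariance
#'   correction (GEE only).
#' @param ci_level confidence level in (0, 1).
#' @param quadrature_nodes Gauss-Hermite nodes per dimension used for
#'   response-probability prediction; at least 8.
#' @param baseline_adjust logical; include the baseline score in the mean
#'   and responder models.
#' @param seed optional integer seed recorded with the configuration.
#' @return A validated list of class `augbin_config`.
#' @export
analysis_config <- function(threshold = 20,
                            scale = c("log_odds", "risk_difference", "log_risk_ratio"),
                            continuous_fitter = c("GLS", "GEE"),
                            firth = TRUE,
                            mbn = TRUE,
                            ci_level = 0.95,
                            quadrature_nodes = 40L,
                            baseline_adjust = FALSE,
                            seed = NULL) {
  scale <- match.arg(scale)
  continuous_fitter <- match.arg(continuous_fitter)
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  }
  quadrature_nodes <- as.integer(quadrature_nodes)
  if (is.na(quadrature_nodes) || quadrature_nodes < 8L) {
    stop("quadrature_nodes must be an integer >= 8", call. = FALSE)
  }
  structure(list(
    threshold = threshold,
    scale = scale,
    continuous_fitter = continuous_fitter,
    firth = isTRUE(firth),
    mbn = isTRUE(mbn),
    ci_level = ci_level,
    quadrature_nodes = quadrature_nodes,
    baseline_adjust = isTRUE(baseline_adjust),
    seed = seed
  ), class = "augbin_config")
}

#' Read an analysis configuration from YAML
#'
#' The file holds scalar fields mirroring [analysis_config()]; unknown keys
#' are rejected so that typos fail loudly.
#'
#' @param path path to a YAML file.
#' @return An `augbin_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    stop(sprintf("unknown configuration field(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  do.call(analysis_config, raw)
}

#' Read patient-level trial data from CSV
#'
#' Expects a header row with columns `patient_id`, `arm`, `baseline`,
#' `y_1..y_T` and `d_1..d_T` (comma-separated; an empty cell is a missing
#' value). Responder flags are derived, not read. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @param threshold response cut-off; alternatively pass `config`.
#' @param config optional `augbin_config` supplying the threshold.
#' @return A `trial_dataset`.
#' @export
read_trial_csv <- function(path, threshold = NULL, config = NULL) {
  if (is.null(threshold)) {
    if (is.null(config)) stop("supply threshold or config", call. = FALSE)
    threshold <- config$threshold
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "baseline")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("CSV is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ycols <- grep("^y_[0-9]+$", names(df), value = TRUE)
  dcols <- grep("^d_[0-9]+$", names(df), value = TRUE)
  if (!length(ycols) || !length(dcols)) {
    stop("CSV must contain y_1..y_T and d_1..d_T columns", call. = FALSE)
  }
  nT <- length(ycols)
  if (length(dcols) != nT ||
      !setequal(ycols, paste0("y_", seq_len(nT))) ||
      !setequal(dcols, paste0("d_", seq_len(nT)))) {
    stop("y_* and d_* columns must be numbered 1..T with matching T",
         call. = FALSE)
  }
  trial_dataset(
    patient_id = df$patient_id,
    arm = df$arm,
    baseline = df$baseline,
    y = as.matrix(df[, paste0("y_", seq_len(nT))]),
    d = as.matrix(df[, paste0("d_", seq_len(nT))]),
    threshold = threshold
  )
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]: writes `patient_id`, `arm`, `baseline`,
#' `y_*` and `d_*` (the derived `responder` column is not written; it is
#' reconstructed on read).
#'
#' @param data a `trial_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  nT <- n_visits(data)
  cols <- c("patient_id", "arm", "baseline",
            paste0("y_", seq_len(nT)), paste0("d_", seq_len(nT)))
  utils::write.csv(as.data.frame(data)[, cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
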