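#' @name reporting
#' @title Structured reports: fit summaries, OC comparisons, JSON round trips
NULL

REPORT_SCHEMA_VERSION <- "1.0"

#' Pairwise operating-characteristics comparison
#'
#' Compares the mean confidence-interval widths of two methods over a
#' common sample-size grid: the per-`n` width reduction of method B over
#' method A is `1 - width_B / width_A`; the grid-average reduction is
#' converted to an implied reduction in required sample size by
#' [ci_width_to_sample_size_reduction()] (width scaling as `1/sqrt(n)`).
#' The sample-size fields are always a deterministic function of the width
#' fields — the report carries no independent numbers.
#'
#' @param oc_a,oc_b `oc_result` objects sharing grid, mode and scale.
#' @param method_a,method_b labels of the methods to compare; default to
#'   the first method of each result.
#' @return A list of class `comparison_report`.
#' @export
build_comparison <- function(oc_a, oc_b,
                             method_a = oc_a$methods[1L],
                             method_b = oc_b$methods[1L]) {
  stopifnot(inherits(oc_a, "oc_result"), inherits(oc_b, "oc_result"))
  if (!identical(oc_a$n_grid, oc_b$n_grid)) {
    stop("operating-characteristics grids do not match", call. = FALSE)
  }
  if (!identical(oc_a$mode, oc_b$mode) ||
      !identical(oc_a$scale, oc_b$scale)) {
    stop("mode and scale must match between the two results", call. = FALSE)
  }
  ra <- oc_a$results[[method_a]]
  rb <- oc_b$results[[method_b]]
  if (is.null(ra) || is.null(rb)) stop("unknown method label", call. = FALSE)
  width_reduction <- 1 - rb$mean_ci_width / ra$mean_ci_width
  avg <- mean(width_reduction)
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    method_a = method_a, method_b = method_b,
    mode = oc_a$mode, scale = oc_a$scale,
    n_grid = oc_a$n_grid,
    mean_width_a = ra$mean_ci_width,
    mean_width_b = rb$mean_ci_width,
    width_reduction = width_reduction,
    sample_size_reduction = ci_width_to_sample_size_reduction(
      pmax(width_reduction, 0)),
    avg_width_reduction = avg,
    avg_sample_size_reduction = ci_width_to_sample_size_reduction(max(avg, 0)),
    metadata = list(n_reps = oc_a$n_reps, seed_a = oc_a$seed,
                    seed_b = oc_b$seed, alpha = oc_a$alpha)
  ), class = "comparison_report")
}

#' Render a comparison report as an aligned text table
#'
#' Percentages are shown to one decimal place. The table is a pure
#' rendering of the JSON content.
#'
#' @param report a `comparison_report`.
#' @return character vector of lines, invisibly printed by `cat`.
#' @export
format_comparison <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  hdr <- sprintf("Comparison: %s vs %s (%s scale, %s mode)",
                 report$method_a, report$method_b, report$scale, report$mode)
  tab <- sprintf("%4d %12.4f %12.4f %18.1f %24.1f",
                 report$n_grid, report$mean_width_a, report$mean_width_b,
                 100 * report$width_reduction,
                 100 * report$sample_size_reduction)
  c(hdr,
    sprintf("%4s %12s %12s %18s %24s", "n", "width A", "width B",
            "width red. (%)", "sample-size red. (%)"),
    tab,
    sprintf("Average reduction in C.I. width: %.1f%%",
            100 * report$avg_width_reduction),
    sprintf("Implied reduction in required sample size: %.1f%%",
            100 * report$avg_sample_size_reduction))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

#' Write / read a comparison report as JSON
#'
#' The JSON round trip is lossless for every numeric field.
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @return `path` (writer) or the reconstructed `comparison_report`
#'   (reader).
#' @export
write_comparison_json <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_comparison_json
#' @export
read_comparison_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$n_grid <- as.integer(raw$n_grid)
  structure(raw, class = "comparison_report")
}

#' Serialize an operating-characteristics result to JSON
#'
#' @param oc an `oc_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oc_json <- function(oc, path) {
  stopifnot(inherits(oc, "oc_result"))
  jsonlite::write_json(unclass(oc), path, auto_unbox = TRUE, digits = I(17),
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' Serialize a fitted effect estimate to a JSON report
#'
#' Machine-readable single-analysis report: estimate, SE, CI bounds, scale,
#' arm-average probabilities and component diagnostics.
#'
#' @param effect an `effect_estimate` or named list of them.
#' @param fit the fitted model object (`augbin_fit` or
#'   `standard_binary_fit`) for diagnostics; optional.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effect_json <- function(effect, path, fit = NULL) {
  if (inherits(effect, "effect_estimate")) effect <- list(effect)
  payload <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    estimates = lapply(effect, unclass)
  )
  if (!is.null(fit)) {
    payload$diagnostics <- if (inherits(fit, "augbin_fit")) {
      list(
        continuous_fitter = fit$cont$fitter,
        mbn_applied = !is.null(fit$cont$cov_mbn),
        firth = fit$fail_models[[1L]]$penalty == "firth",
        separation_detected = fit$separation_detected,
        converged = fit$cont$converged &&
          all(vapply(fit$fail_models, `[[`, TRUE, "converged")),
        n_at_risk_interval2 = fit$n_at_risk_interval2
      )
    } else {
      list(
        firth = fit$penalty == "firth",
        separation_detected = fit$separation_detected,
        converged = fit$converged
      )
    }
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}
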