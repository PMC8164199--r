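#' Signed error ratio of an estimated vs. observed activity
#'
#' The signed max/min ratio used as the per-compound "error" of a
#' pharmacophore model: `+estimated/active` when the model over- (or
#' exactly) estimates, `-(active/estimated)` when it underestimates. The
#' magnitude is always >= 1; a perfect fit gives +1.
#'
#' @param estimated predicted activity, > 0; vectorized.
#' @param active observed activity, > 0; vectorized.
#' @return signed ratio(s) with `|value| >= 1`.
#' @export
#' @examples
#' error_ratio(0.72, 0.79) # -1.097...
error_ratio <- function(estimated, active) {
  if (!is.numeric(estimated) || !is.numeric(active) ||
    any(!is.finite(estimated)) || any(!is.finite(active)) ||
    any(estimated <= 0) || any(active <= 0)) {
    abort("`estimated` and `active` must be positive finite numbers",
      class = c("greytox_error_domain", "greytox_error")
    )
  }
  ifelse(estimated >= active, estimated / active, -(active / estimated))
}

#' Threshold set for pharmacophore-model validation
#'
#' @param configuration_max maximum acceptable configuration cost
#'   (non-strict; a significant hypothesis should not exceed 17).
#' @param correlation_min minimum correlation coefficient (strict >).
#' @param error_max bound on the per-compound `|error|` ratio (strict <).
#' @return a named list of thresholds.
#' @export
model_thresholds <- function(configuration_max = 17,
                             correlation_min = 0.7,
                             error_max = 2) {
  list(
    configuration_max = configuration_max,
    correlation_min = correlation_min,
    error_max = error_max
  )
}

#' Validate externally supplied pharmacophore-model statistics
#'
#' Checks a hypothesis summary against the standard acceptance thresholds:
#' configuration cost <= 17, correlation > 0.7, and every compound's
#' signed error ratio (recomputed from its estimated/active pair with
#' [error_ratio()]) strictly below 2 in magnitude. The total-vs-fixed cost
#' gap is reported but never thresholded (no published cutoff exists; a
#' smaller gap indicates a more reliable hypothesis).
#'
#' @param stats a named list or one-row data frame with fields `total_cost`,
#'   `fixed_cost`, `rms`, `correlation`, `configuration`.
#' @param rows a data frame of per-compound fits with columns `compound`,
#'   `estimated`, `active` (both positive).
#' @param thresholds a [model_thresholds()] list.
#' @return a `model_verdict` list: `checks` (one-row tibble of flags, the
#'   cost gap, and overall `pass`) and `compounds` (per-compound errors with
#'   an `error_ok` flag).
#' @export
#' @examples
#' stats <- list(
#'   total_cost = 51.610, fixed_cost = 33.636, rms = 0.055,
#'   correlation = 0.85, configuration = 16.834
#' )
#' rows <- data.frame(compound = "X", estimated = 0.72, active = 0.79)
#' validate_model(stats, rows)$checks$pass
validate_model <- function(stats, rows, thresholds = model_thresholds()) {
  s <- as_record(stats, c("total_cost", "fixed_cost", "rms", "correlation", "configuration"),
    what = "model stats"
  )
  if (s$rms < 0) abort_schema("`rms` must be >= 0")
  if (abs(s$correlation) > 1) abort_schema("`correlation` must lie in [-1, 1]")
  if (s$configuration < 0) abort_schema("`configuration` must be >= 0")
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    abort_schema("`rows` must be a non-empty data frame")
  }
  missing <- setdiff(c("compound", "estimated", "active"), names(rows))
  if (length(missing)) {
    abort_schema(paste0("`rows` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  compounds <- dplyr::mutate(as_tibble(rows),
    error = error_ratio(.data$estimated, .data$active),
    error_ok = abs(.data$error) < thresholds$error_max
  )
  checks <- tibble(
    configuration_ok = s$configuration <= thresholds$configuration_max,
    correlation_ok = s$correlation > thresholds$correlation_min,
    errors_ok = all(compounds$error_ok),
    cost_gap = s$total_cost - s$fixed_cost
  )
  checks$pass <- checks$configuration_ok && checks$correlation_ok && checks$errors_ok
  structure(list(checks = checks, compounds = compounds, thresholds = thresholds),
    class = "model_verdict"
  )
}

#' @export
print.model_verdict <- function(x, ...) {
  cat("<pharmacophore model verdict> pass =", x$checks$pass, "\n")
  print(x$checks, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_verdict <- function(x, ...) x$compounds

#' @exportS3Method generics::glance
glance.model_verdict <- function(x, ...) x$checks
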