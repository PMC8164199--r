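#' Grey relational analysis configuration
#'
#' Settings for scoring a toxicity panel against the acute-toxicity
#' classification boundary. The reference sequence is the constant series at
#' `reference` (1.0 mg/L, the EC50/LC50 acute classification standard); each
#' receptor's toxicity column is one comparison sequence.
#'
#' @param reference reference concentration in mg/L, > 0. Default 1.0.
#' @param rho resolution coefficient in (0, 1) damping the maximum-difference
#'   term of the grey coefficient. Default 0.5, the conventional value.
#' @param normalization `"per_sequence"` (default) takes the min/max of the
#'   absolute differences within each comparison sequence (receptor column);
#'   `"global"` takes them over the whole difference matrix. The two agree
#'   only when every column shares its extremes; `per_sequence` is the
#'   convention that reproduces the worked reference tables bundled with the
#'   package, `global` is the textbook double-extremum form.
#' @param weights optional non-negative receptor weights summing to 1, in
#'   panel column order; default equal weights (the plain horizontal mean).
#' @return a `gra_config` list.
#' @export
gra_config <- function(reference = 1.0,
                       rho = 0.5,
                       normalization = c("per_sequence", "global"),
                       weights = NULL) {
  if (!is.numeric(reference) || length(reference) != 1 || !is.finite(reference) || reference <= 0) {
    abort_config("`reference` must be a single positive number (mg/L)")
  }
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0 || rho >= 1) {
    abort_config("`rho` must lie strictly inside (0, 1)")
  }
  normalization <- match.arg(normalization)
  if (!is.null(weights)) {
    if (any(!is.finite(weights)) || any(weights < 0)) {
      abort_config("`weights` must be non-negative and finite")
    }
    if (abs(sum(weights) - 1) > 1e-9) {
      abort_config("`weights` must sum to 1")
    }
  }
  structure(
    list(
      reference = reference, rho = rho,
      normalization = normalization, weights = weights
    ),
    class = "gra_config"
  )
}

resolve_weights <- function(config, n) {
  w <- config$weights
  if (is.null(w)) {
    return(rep(1 / n, n))
  }
  if (length(w) != n) {
    abort_config(paste0("`weights` has length ", length(w), " but the panel has ", n, " receptors"))
  }
  w
}

#' Absolute differences from the reference sequence
#'
#' For every compound k and receptor i, computes
#' \eqn{\Delta_i(k) = |x_0 - x_i(k)|} where \eqn{x_0} is the constant
#' reference concentration, together with the per-column and global extremes
#' that feed the grey coefficient.
#'
#' @param panel a `tox_panel`.
#' @param config a [gra_config()].
#' @return a `gra_differences` tibble (compound column plus one difference
#'   column per receptor) with attributes `column_min`, `column_max`,
#'   `global_min`, `global_max`, and `reference`.
#' @export
gra_differences <- function(panel, config = gra_config()) {
  assert_panel(panel)
  ids <- receptor_ids(panel)
  out <- dplyr::mutate(as_tibble(panel)[c("compound", ids)], dplyr::across(
    dplyr::all_of(ids), ~ abs(config$reference - .x)
  ))
  m <- as.matrix(out[ids])
  structure(out,
    column_min = apply(m, 2, min),
    column_max = apply(m, 2, max),
    global_min = min(m),
    global_max = max(m),
    reference = config$reference,
    receptors = receptors(panel),
    class = c("gra_differences", class(tibble()))
  )
}

#' Grey interconnect coefficients
#'
#' Applies the grey coefficient formula
#' \deqn{\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
#'                      {\Delta_i(k) + \rho\,\Delta_{\max}}}
#' to a difference matrix. Under `per_sequence` normalization
#' \eqn{\Delta_{\min}, \Delta_{\max}} are each comparison sequence's own
#' extremes over compounds; under `global` they are the extremes over the
#' entire matrix. Every coefficient lies in (0, 1] and equals 1 exactly when
#' its difference attains the governing minimum.
#'
#' @param diffs a `gra_differences` object.
#' @param config a [gra_config()].
#' @return a `gra_coefficients` tibble with the `config` attached.
#' @export
gra_coefficients <- function(diffs, config = gra_config()) {
  ids <- setdiff(names(diffs), "compound")
  m <- as.matrix(diffs[ids])
  if (attr(diffs, "global_max") == 0) {
    abort(
      "degenerate panel: every comparison value equals the reference, the grey coefficient is undefined",
      class = c("greytox_error_degenerate", "greytox_error")
    )
  }
  if (config$normalization == "per_sequence") {
    lo <- attr(diffs, "column_min")
    hi <- attr(diffs, "column_max")
  } else {
    lo <- rep(attr(diffs, "global_min"), length(ids))
    hi <- rep(attr(diffs, "global_max"), length(ids))
  }
  xi <- sweep(
    sweep(m, 2, config$rho * hi, "+"), 2, lo + config$rho * hi,
    FUN = function(den, num) num / den
  )
  out <- dplyr::bind_cols(diffs["compound"], as_tibble(xi))
  structure(out,
    config = config,
    receptors = attr(diffs, "receptors"),
    class = c("gra_coefficients", class(tibble()))
  )
}

#' Grey interconnect degrees
#'
#' The horizontal weighted mean of each compound's grey coefficients: the
#' compound's comprehensive characterization value of its multireceptor
#' toxicity. With equal weights this is the plain arithmetic mean over the
#' n comparison sequences. Higher degree = toxicity profile closer to the
#' 1.0 mg/L classification boundary = lower comprehensive toxicity.
#'
#' @param coeffs a `gra_coefficients` object.
#' @param config a [gra_config()]; its `weights` must match the receptor
#'   count.
#' @return a `gra_degrees` tibble with columns `compound` and `degree`, and
#'   attribute `n` (number of sequences averaged).
#' @export
gra_degrees <- function(coeffs, config = gra_config()) {
  ids <- setdiff(names(coeffs), "compound")
  w <- resolve_weights(config, length(ids))
  m <- as.matrix(coeffs[ids])
  out <- tibble(compound = coeffs$compound, degree = as.numeric(m %*% w))
  structure(out,
    n = length(ids), weights = w,
    class = c("gra_degrees", class(tibble()))
  )
}

#' Run the full grey relational characterization
#'
#' Deterministic composition of [gra_differences()], [gra_coefficients()]
#' and [gra_degrees()]: from a compound-by-receptor acute-toxicity panel to
#' one comprehensive multireceptor-toxicity characterization value per
#' compound.
#'
#' @param panel a `tox_panel` (values in mg/L, all > 0).
#' @param config a [gra_config()].
#' @return a `gra_result` list with elements `differences`, `coefficients`,
#'   `degrees`, and `config`.
#' @export
#' @examples
#' panel <- read_tox_panel(greytox_example("pae_acute_toxicity.csv"))
#' res <- run_gra(panel)
#' res$degrees
run_gra <- function(panel, config = gra_config()) {
  diffs <- gra_differences(panel, config)
  coeffs <- gra_coefficients(diffs, config)
  degrees <- gra_degrees(coeffs, config)
  structure(
    list(
      differences = diffs, coefficients = coeffs,
      degrees = degrees, config = config
    ),
    class = "gra_result"
  )
}

#' @export
print.gra_result <- function(x, ...) {
  cat(
    "<grey relational characterization>\n",
    "  ", nrow(x$degrees), " compounds, ", attr(x$degrees, "n"), " receptors; ",
    "reference ", x$config$reference, " mg/L, rho ", x$config$rho,
    ", ", x$config$normalization, " extremes\n",
    sep = ""
  )
  print(x$degrees, ...)
  invisible(x)
}

#' @describeIn run_gra long tibble of coefficients joined with degrees.
#' @param x a `gra_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.gra_result <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(x$coefficients), -"compound",
    names_to = "receptor", values_to = "coefficient"
  )
  dplyr::left_join(long, as_tibble(x$degrees), by = "compound")
}

#' @describeIn run_gra one-row summary (sizes, settings, degree range).
#' @exportS3Method generics::glance
glance.gra_result <- function(x, ...) {
  tibble(
    n_compounds = nrow(x$degrees),
    n_receptors = attr(x$degrees, "n"),
    reference = x$config$reference,
    rho = x$config$rho,
    normalization = x$config$normalization,
    min_degree = min(x$degrees$degree),
    max_degree = max(x$degrees$degree)
  )
}

#' @describeIn run_gra bar chart of grey interconnect degrees by compound.
#' @param object a `gra_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.gra_result <- function(object, ...) {
  d <- dplyr::arrange(as_tibble(object$degrees), .data$degree)
  d$compound <- factor(d$compound, levels = d$compound)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$compound)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "grey interconnect degree (1 = at the 1.0 mg/L boundary)",
      y = NULL,
      title = "Comprehensive multireceptor toxicity characterization"
    ) +
    ggplot2::theme_minimal()
}

#' Write grey relational results as CSV files
#'
#' Writes `differences.csv` (6-decimal display, with Min/Max rows appended),
#' `coefficients.csv` and `degrees.csv` (4-decimal display) into a
#' directory, mirroring the layout of the worked reference tables.
#'
#' @param result a `gra_result`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the paths written.
#' @export
write_gra <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- setdiff(names(result$differences), "compound")
  fmt <- function(df, digits) {
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    dplyr::mutate(as_tibble(df), dplyr::across(
      dplyr::all_of(num), ~ sprintf(paste0("%.", digits, "f"), round_half_up(.x, digits))
    ))
  }
  diffs <- as_tibble(result$differences)
  extremes <- dplyr::bind_rows(
    tibble(compound = "Min(i)(k)", !!!as.list(attr(result$differences, "column_min"))),
    tibble(compound = "Max(i)(k)", !!!as.list(attr(result$differences, "column_max")))
  )
  paths <- c(
    differences = file.path(dir, "differences.csv"),
    coefficients = file.path(dir, "coefficients.csv"),
    degrees = file.path(dir, "degrees.csv")
  )
  readr::write_csv(fmt(dplyr::bind_rows(diffs, extremes), 6), paths["differences"])
  readr::write_csv(fmt(result$coefficients, 4), paths["coefficients"])
  readr::write_csv(fmt(result$degrees, 4), paths["degrees"])
  invisible(paths)
}
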