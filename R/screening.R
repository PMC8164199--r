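#' Percent change rate
#'
#' The universal comparison statistic of the derivative screens:
#' \eqn{(new - old)/old \times 100}, sign preserved. Values are returned at
#' full precision; use [round_half_up()] for the 2-decimal display
#' convention of the reports.
#'
#' @param old baseline value(s); must be nonzero.
#' @param new new value(s).
#' @return percent change, vectorized over inputs.
#' @export
#' @examples
#' change_rate(0.7171, 0.8214) # +14.54...%
change_rate <- function(old, new) {
  if (!is.numeric(old) || !is.numeric(new)) {
    abort_schema("`old` and `new` must be numeric")
  }
  if (any(!is.finite(old)) || any(!is.finite(new))) {
    abort_schema("`old` and `new` must be finite")
  }
  if (any(old == 0)) {
    abort("change rate is undefined for old = 0",
      class = c("greytox_error_undefined_rate", "greytox_error")
    )
  }
  (new - old) / old * 100
}

#' Screen derivatives for increased comprehensive characterization
#'
#' Stage-1 derivative screen: a derivative passes when its estimated
#' comprehensive characterization value exceeds the parent's by strictly
#' more than `threshold` percent (a higher characterization value means a
#' toxicity profile closer to the 1.0 mg/L boundary, i.e. lower
#' comprehensive toxicity).
#'
#' @param records a data frame with columns `parent_id`, `derivative_id`,
#'   `estimated_parent`, `estimated_derivative` (and optionally
#'   `substituent`).
#' @param threshold pass threshold in percent; strict inequality. Default 10.
#' @return a `screen_report` tibble preserving input order, with columns
#'   `rate` (percent, full precision) and `passed`; the threshold is stored
#'   in the `screen_threshold` attribute.
#' @export
#' @examples
#' recs <- readr::read_csv(greytox_example("pae_mte_activity.csv"),
#'   show_col_types = FALSE
#' )
#' sum(screen_activity_increase(recs)$passed)
screen_activity_increase <- function(records, threshold = 10) {
  need <- c("parent_id", "derivative_id", "estimated_parent", "estimated_derivative")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort_schema(paste0("records are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0) abort_schema("`records` must be non-empty")
  out <- dplyr::mutate(as_tibble(records),
    rate = change_rate(.data$estimated_parent, .data$estimated_derivative),
    passed = .data$rate > threshold
  )
  structure(out,
    screen_threshold = threshold,
    class = c("screen_report", class(tibble()))
  )
}

#' Screen derivatives for toxicity reduction on every receptor
#'
#' Stage-2 derivative screen, run on negative-log toxicity values
#' (pEC50/pLC50): for each derivative, the percent change of each
#' receptor's p-value relative to its parent is computed, and the
#' derivative is flagged `all_reduced` when every receptor's rate is
#' strictly negative (p-value decreased = concentration increased = less
#' toxic). A proportionality diagnostic (max/min absolute rate) quantifies
#' how close the multireceptor decline is to 1:1:1:1.
#'
#' @param parents a `p_tox_panel` (or same-shaped tibble) holding the parent
#'   compounds' negative-log values.
#' @param derivatives same shape for the derivatives, plus a `parent` column
#'   naming each derivative's parent compound.
#' @param prop_tolerance proportionality flag threshold on the max/min
#'   absolute-rate ratio; see [proportionality()]. Default 2.5.
#' @return an `mr_screen` list with `rates` (long tibble: derivative,
#'   parent, receptor, parent_value, derivative_value, rate) and `summary`
#'   (one row per derivative: `all_reduced`, `prop_ratio`,
#'   `prop_applicable`, `prop_ok`).
#' @export
screen_multireceptor_reduction <- function(parents, derivatives,
                                           prop_tolerance = 2.5) {
  if (nrow(derivatives) == 0) {
    return(structure(
      list(
        rates = tibble(
          derivative = character(), parent = character(), receptor = character(),
          parent_value = numeric(), derivative_value = numeric(), rate = numeric()
        ),
        summary = tibble(
          derivative = character(), parent = character(), all_reduced = logical(),
          prop_ratio = numeric(), prop_applicable = logical(), prop_ok = logical()
        )
      ),
      class = "mr_screen"
    ))
  }
  if (!"parent" %in% names(derivatives)) {
    abort_schema("`derivatives` needs a `parent` column naming each parent compound")
  }
  rec_p <- receptor_ids(parents)
  rec_d <- receptor_ids(derivatives)
  if (!setequal(rec_p, rec_d)) {
    abort_schema(paste0(
      "parent and derivative panels must share the same receptor set; differ on: ",
      paste(union(setdiff(rec_p, rec_d), setdiff(rec_d, rec_p)), collapse = ", ")
    ))
  }
  unknown <- setdiff(derivatives$parent, parents$compound)
  if (length(unknown)) {
    abort_schema(paste0("parent compound(s) not in parent panel: ", paste(unknown, collapse = ", ")))
  }
  long_p <- tidyr::pivot_longer(as_tibble(parents)[c("compound", rec_p)],
    -"compound",
    names_to = "receptor", values_to = "parent_value"
  )
  rates <- as_tibble(derivatives)[c("compound", "parent", rec_p)] |>
    tidyr::pivot_longer(-c("compound", "parent"),
      names_to = "receptor", values_to = "derivative_value"
    ) |>
    dplyr::left_join(long_p, by = c(parent = "compound", "receptor")) |>
    dplyr::mutate(rate = change_rate(.data$parent_value, .data$derivative_value)) |>
    dplyr::rename(derivative = "compound") |>
    dplyr::select("derivative", "parent", "receptor", "parent_value", "derivative_value", "rate")
  summary <- rates |>
    dplyr::group_by(.data$derivative, .data$parent) |>
    dplyr::summarise(
      all_reduced = all(.data$rate < 0),
      prop = list(proportionality(.data$rate, tolerance = prop_tolerance)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("prop") |>
    dplyr::rename(
      prop_ratio = "ratio", prop_applicable = "applicable",
      prop_ok = "within_tolerance"
    )
  # keep the derivatives' input order
  summary <- summary[match(
    intersect(derivatives$compound, summary$derivative), summary$derivative
  ), ]
  structure(list(rates = rates, summary = summary), class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(
    "<multireceptor reduction screen> ", nrow(x$summary), " derivatives, ",
    sum(x$summary$all_reduced), " with all receptors reduced\n",
    sep = ""
  )
  print(x$summary, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_screen <- function(x, ...) x$rates

#' @exportS3Method generics::glance
glance.mr_screen <- function(x, ...) {
  tibble(
    n_derivatives = nrow(x$summary),
    n_all_reduced = sum(x$summary$all_reduced),
    n_proportional = sum(x$summary$prop_ok %in% TRUE)
  )
}

#' Proportionality of per-receptor change rates
#'
#' Quantifies how close a derivative's multireceptor decline is to 1:1:1:1
#' as the ratio of the largest to the smallest absolute per-receptor rate.
#' The flag is advisory: the ratio is always reported alongside it. Not
#' applicable (ratio `NA`) when rates mix signs or any rate is zero.
#'
#' @param rates numeric vector of per-receptor percent changes.
#' @param tolerance flag threshold on the ratio (>= 1). Default 2.5, chosen
#'   so declines the field would call near-proportional (ratio about 2.35
#'   for the least uniform bundled example) are flagged.
#' @return a list with `ratio`, `applicable`, and `within_tolerance`.
#' @export
#' @examples
#' proportionality(c(-3.75, -8.80, -5.57, -7.31))
proportionality <- function(rates, tolerance = 2.5) {
  if (!is.numeric(rates) || length(rates) == 0 || any(!is.finite(rates))) {
    abort_schema("`rates` must be a non-empty finite numeric vector")
  }
  if (any(rates == 0) || length(unique(sign(rates))) > 1) {
    return(list(ratio = NA_real_, applicable = FALSE, within_tolerance = NA))
  }
  ratio <- max(abs(rates)) / min(abs(rates))
  list(ratio = ratio, applicable = TRUE, within_tolerance = ratio <= tolerance)
}
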