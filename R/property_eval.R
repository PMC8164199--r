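#' Reaction energy barrier
#'
#' \eqn{\Delta E = E_{TS} - \sum E_{reactant}}: transition-state energy
#' minus the summed reactant energies of the primary metabolic (ester to
#' monoester) step. Units are the caller's; no conversion is performed.
#'
#' @param e_ts transition-state energy.
#' @param e_reactants numeric vector of reactant energies (same units).
#' @return the barrier, same units as the inputs.
#' @export
#' @examples
#' reaction_barrier(-500.0, -500.15)
reaction_barrier <- function(e_ts, e_reactants) {
  if (!is.numeric(e_ts) || length(e_ts) != 1 || !is.finite(e_ts)) {
    abort_schema("`e_ts` must be a single finite number")
  }
  if (!is.numeric(e_reactants) || length(e_reactants) == 0 || any(!is.finite(e_reactants))) {
    abort_schema("`e_reactants` must be a non-empty finite numeric vector")
  }
  e_ts - sum(e_reactants)
}

#' Functional-property verdict for a derivative
#'
#' Compares quantum-chemical summaries of a derivative against its parent:
#' * stability: total-energy change rate <= 0 passes outright; a positive
#'   rate passes only while strictly below `energy_increase_limit` percent;
#' * insulation: the HOMO-LUMO energy-gap change rate is reported but never
#'   thresholded (informational);
#' * existence: the derivative's lowest vibrational frequency must be > 0
#'   (a real minimum, so the structure can exist stably).
#'
#' All rates use [change_rate()]; note that for (negative) total energies
#' the sign of the rate follows that arithmetic, not the direction of the
#' energy itself.
#'
#' @param parent,derivative named lists or one-row data frames with fields
#'   `total_energy` (a.u.), `energy_gap` (eV), `frequency` (cm-1).
#' @param energy_increase_limit percent limit on a positive total-energy
#'   change rate. Default 5.
#' @return a one-row tibble with the three change rates and flags
#'   `stability`, `existence`, and `pass` (their conjunction).
#' @export
evaluate_functional <- function(parent, derivative, energy_increase_limit = 5) {
  fields <- c("total_energy", "energy_gap", "frequency")
  p <- as_record(parent, fields, "parent")
  d <- as_record(derivative, fields, "derivative")
  energy_rate <- change_rate(p$total_energy, d$total_energy)
  gap_rate <- change_rate(p$energy_gap, d$energy_gap)
  freq_rate <- change_rate(p$frequency, d$frequency)
  stability <- energy_rate <= 0 || energy_rate < energy_increase_limit
  existence <- d$frequency > 0
  tibble(
    total_energy_rate = energy_rate,
    energy_gap_rate = gap_rate,
    frequency_rate = freq_rate,
    frequency = d$frequency,
    stability = stability,
    existence = existence,
    pass = stability && existence
  )
}

#' POPs-property verdict for a derivative
#'
#' Screens the classical persistent-organic-pollutant descriptors:
#' bioaccumulation (log Kow), long-range transport (log Koa) and
#' persistence (half-life in air). Change rates for the two log-scale
#' partition coefficients are percent changes of the logarithms themselves
#' -- unconventional, but the convention of the reference reports this
#' package reproduces; the returned `note` records it. The persistence
#' flag is `derivative half-life > threshold` (default two days).
#'
#' @param parent,derivative named lists or one-row data frames with fields
#'   `log_koa`, `log_kow`, `half_life` (hours).
#' @param air_half_life_threshold persistence cutoff in hours. Default 48.
#' @return a one-row tibble with the three change rates, the derivative
#'   half-life, the `persistent` flag, and a `note`.
#' @export
evaluate_pops <- function(parent, derivative, air_half_life_threshold = 48) {
  fields <- c("log_koa", "log_kow", "half_life")
  p <- as_record(parent, fields, "parent")
  d <- as_record(derivative, fields, "derivative")
  if (p$half_life <= 0 || d$half_life <= 0) {
    abort_schema("half-lives must be positive")
  }
  tibble(
    log_koa_rate = change_rate(p$log_koa, d$log_koa),
    log_kow_rate = change_rate(p$log_kow, d$log_kow),
    half_life_rate = change_rate(p$half_life, d$half_life),
    half_life = d$half_life,
    persistent = d$half_life > air_half_life_threshold,
    note = "log Kow/log Koa rates are percent changes of log-scale quantities"
  )
}

#' Docking-score change report
#'
#' Per-protein percent changes of docking scores between a parent and a
#' derivative. Lower score = weaker binding = lower predicted toxicity to
#' the receptor organism the protein represents, so `all_weaker` is TRUE
#' when every protein's rate is strictly negative.
#'
#' @param parent,derivative named numeric vectors (protein id -> score) or
#'   data frames with columns `protein` and `score`; non-negative scores.
#' @return a `docking_change` tibble (protein, parent_score,
#'   derivative_score, rate) with logical attribute `all_weaker`.
#' @export
docking_change <- function(parent, derivative) {
  to_scores <- function(x, what) {
    if (is.data.frame(x)) {
      if (!all(c("protein", "score") %in% names(x))) {
        abort_schema(paste0(what, " needs columns `protein` and `score`"))
      }
      x <- setNames(x$score, x$protein)
    }
    if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
      abort_schema(paste0(what, " must be a named numeric vector or protein/score data frame"))
    }
    if (any(!is.finite(x)) || any(x < 0)) {
      abort_schema(paste0(what, " scores must be finite and non-negative"))
    }
    x
  }
  p <- to_scores(parent, "parent")
  d <- to_scores(derivative, "derivative")
  if (!setequal(names(p), names(d))) {
    abort_schema(paste0(
      "parent and derivative protein sets differ: ",
      paste(union(setdiff(names(p), names(d)), setdiff(names(d), names(p))), collapse = ", ")
    ))
  }
  d <- d[names(p)]
  out <- tibble(
    protein = names(p),
    parent_score = unname(p),
    derivative_score = unname(d),
    rate = change_rate(unname(p), unname(d))
  )
  structure(out,
    all_weaker = all(out$rate < 0),
    class = c("docking_change", class(tibble()))
  )
}

#' @export
print.docking_change <- function(x, ...) {
  cat("<docking score changes> all_weaker =", attr(x, "all_weaker"), "\n")
  print(as_tibble(x), ...)
  invisible(x)
}
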