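#' Configuration for the synthetic panel generator
#'
#' The generator emulates the numeric regime of multireceptor acute-toxicity
#' panels of strongly toxic compounds: concentrations spanning roughly five
#' orders of magnitude below the 1.0 mg/L classification boundary, with
#' correlated receptor sensitivities (a fixed log10 offset per receptor) and
#' log-normal cell noise. The default offsets reproduce the sensitivity
#' ordering of the bundled phthalate panel (mysid most sensitive, daphnid
#' and fish least), so synthetic panels stress the same per-column-extreme
#' structure that distinguishes the two grey-coefficient normalizations.
#'
#' @param n_compounds number of compounds (>= 1). Default 14.
#' @param receptor_offsets named vector of per-receptor log10 offsets.
#'   Default `c(green_algae = 0, daphnid = 0.8, mysid = -0.6, fish = 0.78)`.
#' @param potency_range log10 mg/L interval the base potencies are drawn
#'   uniformly from; upper bound must stay below log10 of `reference`.
#'   Default `c(-5, -0.2)`.
#' @param noise_sd standard deviation of per-cell log10 noise, >= 0.
#'   Default 0.15.
#' @param seed integer seed; every draw is reproducible from it.
#' @param derivative_effects log10 shifts applied by
#'   [generate_derivatives()]; positive = less toxic. Default
#'   `c(0.5, 1, 2)`.
#' @param reference classification boundary in mg/L. Default 1.0.
#' @param clip clip generated values strictly below `reference`? Default
#'   TRUE; turn off only for robustness testing.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_compounds = 14,
                       receptor_offsets = c(
                         green_algae = 0, daphnid = 0.8,
                         mysid = -0.6, fish = 0.78
                       ),
                       potency_range = c(-5, -0.2),
                       noise_sd = 0.15,
                       seed = 1L,
                       derivative_effects = c(0.5, 1, 2),
                       reference = 1.0,
                       clip = TRUE) {
  if (!is.numeric(n_compounds) || n_compounds < 1) {
    abort_config("`n_compounds` must be >= 1")
  }
  if (is.null(names(receptor_offsets)) || any(!nzchar(names(receptor_offsets)))) {
    abort_config("`receptor_offsets` must be a named vector (one offset per receptor)")
  }
  if (length(potency_range) != 2 || diff(potency_range) < 0) {
    abort_config("`potency_range` must be an increasing log10 interval")
  }
  if (potency_range[2] >= log10(reference)) {
    abort_config("`potency_range` upper bound must lie below log10(reference)")
  }
  if (noise_sd < 0) abort_config("`noise_sd` must be >= 0")
  structure(
    list(
      n_compounds = as.integer(n_compounds),
      receptor_offsets = receptor_offsets,
      potency_range = potency_range,
      noise_sd = noise_sd,
      seed = as.integer(seed),
      derivative_effects = derivative_effects,
      reference = reference,
      clip = clip
    ),
    class = "sim_config"
  )
}

clip_below <- function(values, config) {
  if (!config$clip) {
    return(values)
  }
  pmin(values, config$reference * (1 - 1e-9))
}

#' Generate a synthetic toxicity panel
#'
#' Each cell is \eqn{10^{p_k + s_i + \epsilon}} with compound potency
#' \eqn{p_k} uniform on `potency_range`, receptor offset \eqn{s_i}, and
#' normal log10 noise, clipped just below the reference boundary. The same
#' seed yields a bit-identical panel.
#'
#' @param config a [sim_config()].
#' @return a `tox_panel`.
#' @export
#' @examples
#' generate_panel(sim_config(n_compounds = 5, seed = 42))
generate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  n <- config$n_compounds
  offsets <- config$receptor_offsets
  p <- runif(n, config$potency_range[1], config$potency_range[2])
  eps <- matrix(rnorm(n * length(offsets), 0, config$noise_sd), nrow = n)
  logc <- outer(p, offsets, "+") + eps
  values <- clip_below(10^logc, config)
  data <- dplyr::bind_cols(
    tibble(compound = sprintf("C%02d", seq_len(n))),
    as_tibble(values)
  )
  tox_panel(data)
}

#' Generate derivative panels by shifting a parent panel
#'
#' Each derivative effect is a uniform log10 shift applied to every cell of
#' the parent panel (positive shift = higher concentration = less toxic),
#' clipped below the reference boundary. Optional per-receptor jitter
#' breaks exact proportionality.
#'
#' @param panel the parent `tox_panel`.
#' @param config a [sim_config()]; `derivative_effects` supplies the shifts
#'   and `seed` drives the jitter draw.
#' @param jitter_sd per-receptor log10 jitter around each shift. Default 0.
#' @return a `derivative_panels` tibble: columns `compound` (derivative
#'   id), `parent`, `shift`, then one column per receptor (mg/L).
#' @export
generate_derivatives <- function(panel, config = sim_config(), jitter_sd = 0) {
  assert_panel(panel)
  ids <- receptor_ids(panel)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed + 1L)
  out <- purrr::map_dfr(seq_along(config$derivative_effects), function(j) {
    shift <- config$derivative_effects[j]
    jit <- rnorm(length(ids), 0, jitter_sd)
    values <- sweep(panel_matrix(panel), 2, shift + jit, function(v, s) v * 10^s)
    values <- clip_below(values, config)
    dplyr::bind_cols(
      tibble(
        compound = paste0(panel$compound, "_d", j),
        parent = panel$compound,
        shift = shift
      ),
      as_tibble(values)
    )
  })
  structure(out, class = c("derivative_panels", class(tibble())))
}

#' Generate parent/derivative property-record pairs and barrier cases
#'
#' Produces paired records with controlled change rates so the verdict
#' logic of the property evaluators is exercised on both sides of every
#' decision boundary: total-energy changes straddling the +5 percent limit,
#' frequencies of both signs, half-lives straddling the 48 h persistence
#' cutoff, and transition-state/reactant energy sets with known barriers.
#'
#' @param config a [sim_config()]; `seed` drives the base-value draws.
#' @return a list with tibbles `functional` (parent/derivative quantum
#'   records plus the requested `energy_rate`), `pops` (POPs records plus
#'   requested half-lives) and `barriers` (`e_ts`, `e_reactants` list
#'   column, and the known `barrier`).
#' @export
generate_property_records <- function(config = sim_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed + 2L)
  energy_rates <- c(-6, -1, 4.99, 5.01, 8)
  freqs <- c(15, 8, 22, -1, 30)
  base_energy <- -runif(length(energy_rates), 900, 1400)
  base_gap <- runif(length(energy_rates), 4.5, 6)
  functional <- tibble(
    pair = paste0("F", seq_along(energy_rates)),
    parent_total_energy = base_energy,
    parent_energy_gap = base_gap,
    parent_frequency = runif(length(energy_rates), 5, 20),
    energy_rate = energy_rates,
    derivative_total_energy = base_energy * (1 + energy_rates / 100),
    derivative_energy_gap = base_gap * (1 + rnorm(length(energy_rates), 0, 0.02)),
    derivative_frequency = freqs
  )
  half_lives <- c(14.2, 47, 48, 49, 200)
  pops <- tibble(
    pair = paste0("P", seq_along(half_lives)),
    parent_log_koa = runif(length(half_lives), 10, 14),
    parent_log_kow = runif(length(half_lives), 6, 10),
    parent_half_life = runif(length(half_lives), 8, 15),
    derivative_log_koa = runif(length(half_lives), 9, 13),
    derivative_log_kow = runif(length(half_lives), 5, 9),
    derivative_half_life = half_lives
  )
  barrier <- c(50, 5, 0.3, 0)
  reactants <- purrr::map(barrier, ~ -sort(runif(2, 100, 700)))
  barriers <- tibble(
    case = paste0("B", seq_along(barrier)),
    e_reactants = reactants,
    e_ts = purrr::map_dbl(reactants, sum) + barrier,
    barrier = barrier
  )
  list(functional = functional, pops = pops, barriers = barriers)
}
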