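#' @keywords internal
run_manifest <- function(config, inputs, outputs) {
  digest <- function(paths) {
    tibble(
      path = unname(paths),
      md5 = unname(tools::md5sum(unname(paths)))
    )
  }
  list(
    tool = "greytox",
    version = as.character(utils::packageVersion("greytox")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = digest(inputs),
    outputs = digest(outputs)
  )
}

write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the grey relational stage on a panel file
#'
#' Reads a toxicity panel CSV, runs [run_gra()], and writes
#' `differences.csv`, `coefficients.csv`, `degrees.csv` and a
#' `manifest.json` (config snapshot, input/output MD5 digests) into
#' `out_dir`. Inputs are never mutated; no partial outputs are left behind
#' on a validation failure because validation precedes any write.
#'
#' @param panel_path input panel CSV.
#' @param out_dir output directory (created if needed).
#' @param config a [gra_config()].
#' @param schema optional YAML panel schema path (see [read_tox_panel()]).
#' @return the manifest, invisibly.
#' @export
cmd_gra <- function(panel_path, out_dir, config = gra_config(), schema = NULL) {
  panel <- read_tox_panel(panel_path, schema = schema)
  result <- run_gra(panel, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_gra(result, out_dir)
  manifest <- run_manifest(
    config = config[c("reference", "rho", "normalization", "weights")],
    inputs = c(panel_path, schema),
    outputs = paths
  )
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' Run the two-stage derivative screen on table files
#'
#' Stage 1 ([screen_activity_increase()]) reads a derivative-activity table
#' (`parent_id`, `derivative_id`, `estimated_parent`,
#' `estimated_derivative`); stage 2 ([screen_multireceptor_reduction()])
#' reads a pEC50/pLC50 table whose parent rows have an empty/NA `parent`
#' column and whose derivative rows name their parent. Stage 2 is
#' restricted to the derivatives that passed stage 1 and appear in the
#' p-value table. Writes `stage1.csv`, `stage2_rates.csv`,
#' `stage2_summary.csv` and a manifest.
#'
#' @param activity_path derivative-activity CSV (stage 1).
#' @param ptox_path negative-log toxicity CSV (stage 2); optional.
#' @param out_dir output directory.
#' @param threshold stage-1 percent threshold (strict >). Default 10.
#' @param prop_tolerance proportionality flag threshold. Default 2.5.
#' @return the manifest, invisibly, with a `summary` element
#'   (`n_stage1`, `n_stage2`).
#' @export
cmd_screen <- function(activity_path, ptox_path = NULL, out_dir,
                       threshold = 10, prop_tolerance = 2.5) {
  if (!file.exists(activity_path)) abort_schema(paste0("file not found: ", activity_path))
  records <- readr::read_csv(activity_path, show_col_types = FALSE, progress = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- c(stage1 = file.path(out_dir, "stage1.csv"))
  if (nrow(records)) {
    stage1 <- screen_activity_increase(records, threshold = threshold)
    n_stage1 <- sum(stage1$passed)
  } else {
    stage1 <- tibble()
    n_stage1 <- 0L
  }
  readr::write_csv(as_tibble(stage1), outputs["stage1"])
  n_stage2 <- NA_integer_
  if (!is.null(ptox_path)) {
    if (!file.exists(ptox_path)) abort_schema(paste0("file not found: ", ptox_path))
    ptox <- readr::read_csv(ptox_path,
      show_col_types = FALSE, progress = FALSE,
      na = c("", "NA")
    )
    keep <- setdiff(names(ptox), grep("^reported_", names(ptox), value = TRUE))
    ptox <- ptox[keep]
    parents <- dplyr::filter(ptox, is.na(.data$parent))
    derivs <- dplyr::filter(ptox, !is.na(.data$parent))
    if (nrow(stage1)) {
      derivs <- dplyr::semi_join(
        derivs, dplyr::filter(stage1, .data$passed),
        by = c(compound = "derivative_id")
      )
    }
    screen <- screen_multireceptor_reduction(parents, derivs,
      prop_tolerance = prop_tolerance
    )
    n_stage2 <- sum(screen$summary$all_reduced)
    outputs <- c(outputs,
      stage2_rates = file.path(out_dir, "stage2_rates.csv"),
      stage2_summary = file.path(out_dir, "stage2_summary.csv")
    )
    readr::write_csv(screen$rates, outputs["stage2_rates"])
    readr::write_csv(screen$summary, outputs["stage2_summary"])
  }
  manifest <- run_manifest(
    config = list(threshold = threshold, prop_tolerance = prop_tolerance),
    inputs = c(activity_path, ptox_path),
    outputs = outputs
  )
  manifest$summary <- list(n_stage1 = n_stage1, n_stage2 = n_stage2)
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' Generate a synthetic dataset directory
#'
#' Writes a generated parent panel (`panel.csv`), its derivative panels
#' (`derivatives.csv`), the corresponding negative-log table in the layout
#' [cmd_screen()] consumes (`ptox.csv`), and a manifest recording the seed.
#' Running twice with the same config yields identical CSVs.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
cmd_simulate <- function(config = sim_config(), out_dir) {
  panel <- generate_panel(config)
  derivs <- generate_derivatives(panel, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- c(
    panel = file.path(out_dir, "panel.csv"),
    derivatives = file.path(out_dir, "derivatives.csv"),
    ptox = file.path(out_dir, "ptox.csv")
  )
  readr::write_csv(as_tibble(panel), outputs["panel"])
  readr::write_csv(as_tibble(derivs), outputs["derivatives"])
  p_parent <- dplyr::mutate(as_tibble(neg_log10(panel)), parent = NA_character_, .after = "compound")
  p_deriv <- dplyr::mutate(
    as_tibble(derivs),
    dplyr::across(dplyr::all_of(receptor_ids(panel)), ~ -log10(.x))
  )
  p_deriv$shift <- NULL
  readr::write_csv(dplyr::bind_rows(p_parent, p_deriv), outputs["ptox"])
  manifest <- run_manifest(
    config = unclass(config),
    inputs = character(),
    outputs = outputs
  )
  write_manifest(manifest, out_dir)
  invisible(manifest)
}
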