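#' Round half away from zero
#'
#' Display rounding used throughout reports: exact halves round away from
#' zero (so 14.545 -> 14.55, -7.305 -> -7.31), matching the convention of
#' the screening tables this package reproduces. The scaled value is
#' pre-rounded at 6 decimals so that quotients such as 0.82/0.80 = 1.025,
#' which binary floating point stores just below the half, still round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(1.025, -7.305), 2)
round_half_up <- function(x, digits = 0) {
  scaled <- round(abs(x) * 10^digits, 6)
  sign(x) * floor(scaled + 0.5) / 10^digits
}

#' Path to a bundled example data file
#'
#' The package ships a set of plain-CSV example tables: an ECOSAR-predicted
#' acute-toxicity panel of 14 phthalate esters against four aquatic receptors
#' (`pae_acute_toxicity.csv` with schema `pae_panel_schema.yml`), derivative
#' activity estimates (`pae_mte_activity.csv`), per-receptor pEC50/pLC50
#' predictions for derivatives (`pae_derivative_ptox.csv`,
#' `pae_single_receptor_ptox.csv`), quantum and POPs property summaries,
#' docking scores, metabolite toxicities, reaction energy barriers, and
#' pharmacophore-model statistics.
#'
#' @param file file name; with no argument, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
#' @examples
#' greytox_example()
#' greytox_example("pae_acute_toxicity.csv")
greytox_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "greytox")))
  }
  path <- system.file("extdata", file, package = "greytox")
  if (!nzchar(path)) {
    abort(paste0("no example file '", file, "'"), class = "greytox_error_schema")
  }
  path
}

abort_schema <- function(msg) abort(msg, class = c("greytox_error_schema", "greytox_error"))
abort_validation <- function(msg) abort(msg, class = c("greytox_error_validation", "greytox_error"))
abort_config <- function(msg) abort(msg, class = c("greytox_error_config", "greytox_error"))

# one-row record helper: accepts a named list or a 1-row data frame and
# checks the named fields exist and are finite
as_record <- function(x, fields, what = "record") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort_schema(paste0(what, " must have exactly one row"))
    x <- as.list(x)
  }
  if (!is.list(x)) abort_schema(paste0(what, " must be a named list or one-row data frame"))
  missing <- setdiff(fields, names(x))
  if (length(missing)) {
    abort_schema(paste0(what, " is missing field(s): ", paste(missing, collapse = ", ")))
  }
  for (f in fields) {
    if (!is.numeric(x[[f]]) || !is.finite(x[[f]])) {
      abort_schema(paste0(what, " field '", f, "' must be a finite number"))
    }
  }
  x
}
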