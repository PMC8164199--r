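#' Construct a compound-by-receptor toxicity panel
#'
#' A toxicity panel holds one positive acute-toxicity concentration
#' (EC50/LC50, mg/L) per compound and receptor. It is stored as a tibble
#' whose first column, `compound`, carries unique compound identifiers and
#' whose remaining columns are one numeric column per receptor. Receptor
#' metadata (display name, toxicity endpoint such as `"96-EC50"`, units)
#' travels with the panel as the `"receptors"` attribute.
#'
#' @param data a data frame with a `compound` column (or a first column that
#'   will be treated as compound identifiers) and one numeric column per
#'   receptor, values in mg/L.
#' @param receptors optional receptor metadata: a data frame with columns
#'   `id` (matching the value columns), `name`, and `endpoint`. Defaults to
#'   ids as names and endpoint `"EC50/LC50"`.
#' @return a `tox_panel` tibble.
#' @export
#' @examples
#' tox_panel(data.frame(compound = c("A", "B"), fish = c(0.01, 0.5)))
tox_panel <- function(data, receptors = NULL) {
  if (!is.data.frame(data) || ncol(data) < 2 || nrow(data) < 1) {
    abort_schema("a panel needs at least one compound row and one receptor column")
  }
  data <- as_tibble(data)
  if (!"compound" %in% names(data)) names(data)[1] <- "compound"
  data <- dplyr::relocate(data, "compound")
  data$compound <- as.character(data$compound)
  receptors <- receptor_meta(setdiff(names(data), "compound"), receptors)
  out <- new_panel(data, receptors, "tox_panel")
  assert_panel(out)
  out
}

receptor_meta <- function(ids, receptors = NULL) {
  if (is.null(receptors)) {
    receptors <- tibble(id = ids, name = ids, endpoint = "EC50/LC50")
  }
  receptors <- as_tibble(receptors)
  if (!all(c("id", "endpoint") %in% names(receptors))) {
    abort_schema("receptor metadata needs 'id' and 'endpoint' columns")
  }
  if (!"name" %in% names(receptors)) receptors$name <- receptors$id
  if (!setequal(receptors$id, ids)) {
    abort_schema(paste0(
      "receptor metadata ids do not match panel columns: ",
      paste(setdiff(ids, receptors$id), collapse = ", ")
    ))
  }
  if (any(!nzchar(receptors$endpoint)) || anyNA(receptors$endpoint)) {
    abort_schema("receptor endpoints must be non-empty")
  }
  receptors$units <- "mg/L"
  receptors[match(ids, receptors$id), c("id", "name", "endpoint", "units")]
}

new_panel <- function(data, receptors, class) {
  structure(data,
    receptors = receptors,
    class = c(class, class(tibble()))
  )
}

#' Receptor metadata of a panel
#' @param panel a `tox_panel` or `p_tox_panel`.
#' @return a tibble with columns `id`, `name`, `endpoint`, `units`.
#' @export
receptors <- function(panel) attr(panel, "receptors")

#' Receptor (value) column ids of a panel
#' @inheritParams receptors
#' @return character vector of receptor column names.
#' @export
receptor_ids <- function(panel) setdiff(names(panel), c("compound", "parent"))

# panel values as a compounds x receptors matrix
panel_matrix <- function(panel) {
  ids <- receptor_ids(panel)
  m <- as.matrix(panel[ids])
  rownames(m) <- panel$compound
  m
}

#' Validate a toxicity panel
#'
#' Checks the panel invariants -- unique compound ids, no missing cells, all
#' concentrations strictly positive -- and returns structured findings
#' rather than raising, so a whole file can be audited in one pass.
#'
#' @param panel a `tox_panel` (or any data frame of the same shape).
#' @return a tibble of findings with columns `compound`, `receptor`, `rule`,
#'   `message`; zero rows when every invariant holds.
#' @export
#' @examples
#' validate_tox_panel(tox_panel(data.frame(compound = "A", fish = 0.2)))
validate_tox_panel <- function(panel) {
  findings <- tibble(
    compound = character(), receptor = character(),
    rule = character(), message = character()
  )
  add <- function(compound, receptor, rule, message) {
    dplyr::bind_rows(findings, tibble(
      compound = compound, receptor = receptor, rule = rule, message = message
    ))
  }
  dup <- unique(panel$compound[duplicated(panel$compound)])
  for (id in dup) {
    findings <- add(id, NA_character_, "unique_compound", "compound id is duplicated")
  }
  for (rec in receptor_ids(panel)) {
    col <- panel[[rec]]
    if (!is.numeric(col)) {
      findings <- add(NA_character_, rec, "numeric", "column is not numeric")
      next
    }
    bad <- which(!is.finite(col) | col <= 0)
    for (i in bad) {
      findings <- add(
        panel$compound[i], rec, "positive",
        paste0("value ", col[i], " is not a positive finite concentration")
      )
    }
  }
  findings
}

assert_panel <- function(panel) {
  findings <- validate_tox_panel(panel)
  if (nrow(findings)) {
    first <- findings[1, ]
    abort_validation(paste0(
      "invalid panel (", nrow(findings), " finding(s)); first: [",
      first$rule, "] compound ", first$compound, ", receptor ",
      first$receptor, ": ", first$message
    ))
  }
  invisible(panel)
}

#' Read a toxicity panel from CSV
#'
#' Expects a header row, a compound-identifier column and one numeric column
#' per receptor (RFC 4180, UTF-8, `.` decimal separator). Endpoint labels
#' are supplied through a YAML schema file, not inferred from headers.
#'
#' @param path CSV file path.
#' @param schema optional path to a YAML schema with keys `compound_column`
#'   and `receptors` (list of `id`/`name`/`endpoint`); receptors listed in
#'   the schema must exist in the file.
#' @return a `tox_panel`, preserving the row order of the file.
#' @export
read_tox_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) abort_schema(paste0("file not found: ", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_schema(paste0("cannot parse '", path, "': ", conditionMessage(e)))
  )
  if (nrow(data) == 0 || ncol(data) < 2) {
    abort_schema(paste0("'", path, "' has no panel data (need a compound column and >= 1 receptor column)"))
  }
  receptors <- NULL
  if (!is.null(schema)) {
    cfg <- yaml::read_yaml(schema)
    cc <- cfg$compound_column %||% "compound"
    if (!cc %in% names(data)) abort_schema(paste0("missing column '", cc, "' declared by schema"))
    names(data)[names(data) == cc] <- "compound"
    receptors <- dplyr::bind_rows(lapply(cfg$receptors, as_tibble))
    missing <- setdiff(receptors$id, names(data))
    if (length(missing)) {
      abort_schema(paste0("missing column(s) declared by schema: ", paste(missing, collapse = ", ")))
    }
    data <- data[c("compound", receptors$id)]
  }
  tox_panel(data, receptors)
}

#' Write a panel to CSV
#'
#' @param panel a `tox_panel` or `p_tox_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tox_panel <- function(panel, path) {
  readr::write_csv(as_tibble(panel), path)
  invisible(path)
}

#' Negative log10 transform of a toxicity panel
#'
#' Converts concentrations (mg/L) to pEC50/pLC50 values,
#' \eqn{p = -\log_{10}(c)}; higher means more toxic. The transform is the
#' common scale on which derivative toxicity-reduction screens operate.
#'
#' @param panel a `tox_panel` with strictly positive values.
#' @return a `p_tox_panel` of the same shape.
#' @export
#' @examples
#' neg_log10(tox_panel(data.frame(compound = "A", fish = 0.01)))
neg_log10 <- function(panel) {
  assert_panel(panel)
  out <- dplyr::mutate(as_tibble(panel), dplyr::across(
    dplyr::all_of(receptor_ids(panel)), ~ -log10(.x)
  ))
  new_panel(out, receptors(panel), "p_tox_panel")
}

#' @export
print.tox_panel <- function(x, ...) {
  cat("<toxicity panel> ", nrow(x), " compounds x ", length(receptor_ids(x)),
    " receptors (mg/L)\n",
    sep = ""
  )
  print(as_tibble(x), ...)
  invisible(x)
}

#' @export
print.p_tox_panel <- function(x, ...) {
  cat("<pEC50/pLC50 panel> ", nrow(x), " compounds x ",
    length(receptor_ids(x)), " receptors (-log10 mg/L)\n",
    sep = ""
  )
  print(as_tibble(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tox_panel <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -dplyr::any_of(c("compound", "parent")),
    names_to = "receptor", values_to = "value"
  )
}

#' @exportS3Method generics::tidy
tidy.p_tox_panel <- tidy.tox_panel

`%||%` <- function(a, b) if (is.null(a)) b else a
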