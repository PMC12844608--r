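#' Plot-level trial records
#'
#' A plot record is one field observation from a replacement-series trial:
#' a (site, season, block, treatment, component) cell carrying a dry-matter
#' yield and, optionally, nitrogen measurements. The three treatments are the
#' two pure stands (`PURE_IR`, `PURE_C`) and the mixture (`MIX`); in the
#' mixture the two components are sampled separately, so `MIX` rows appear
#' once per component.
#'
#' Columns of a `plot_records` tibble:
#' \describe{
#'   \item{site_id, season_id, block_id}{trial structure identifiers (character).}
#'   \item{treatment}{one of `"PURE_IR"`, `"PURE_C"`, `"MIX"`.}
#'   \item{component}{`"IR"` (the grass) or `"C"` (the clover component).}
#'   \item{dmy}{dry-matter yield, t/ha.}
#'   \item{n_conc}{nitrogen concentration in the dry matter, g/kg (optional).}
#'   \item{n_uptake}{nitrogen uptake, kg/ha (optional; equals `dmy * n_conc`
#'     when both are present, units t/ha x g/kg = kg/ha).}
#'   \item{sown_proportion}{sown fraction of the component, in \[0, 1\].}
#'   \item{sowing_date, harvest_date}{ISO-8601 dates; harvest must fall
#'     strictly after sowing.}
#' }
#'
#' @name plot_records
NULL

.required_cols <- c(
  "site_id", "season_id", "block_id", "treatment", "component",
  "dmy", "sown_proportion", "sowing_date", "harvest_date"
)
.optional_cols <- c("n_conc", "n_uptake")
.treatments <- c("PURE_IR", "PURE_C", "MIX")
.components <- c("IR", "C")

#' Read plot-level records from a delimited text file
#'
#' Reads a CSV (or TSV) of plot records, optionally remapping arbitrary file
#' headers onto the schema via a column map, and validates every row. Rows
#' violating an invariant are dropped with a row-indexed diagnostic; the
#' rejects are attached to the result (see [rejected_records()]).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @param col_map Optional named character vector mapping schema names to the
#'   file's header names, e.g. `c(dmy = "yield_t_ha")`, or the path to a
#'   YAML/JSON file holding such a map. Unmapped schema names are looked up
#'   under their own name.
#' @return A `plot_records` tibble of the validated rows, with the rejected
#'   rows (and reasons) in the `"rejects"` attribute.
#' @seealso [validate_plot_records()], [write_plot_records()]
#' @export
read_plot_records <- function(path, delim = ",", col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "intercrop_schema_error")
  }
  col_map <- read_col_map(col_map)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           show_col_types = FALSE, progress = FALSE)
  schema_names <- c(.required_cols, .optional_cols)
  have <- character(0)
  for (nm in schema_names) {
    src <- if (!is.null(col_map) && nm %in% names(col_map)) col_map[[nm]] else nm
    if (src %in% names(raw)) {
      names(raw)[names(raw) == src] <- nm
      have <- c(have, nm)
    }
  }
  missing <- setdiff(.required_cols, have)
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "intercrop_schema_error")
  }
  df <- raw[, intersect(schema_names, names(raw))]
  for (nm in c("dmy", "sown_proportion", "n_conc", "n_uptake")) {
    if (nm %in% names(df)) {
      vals <- df[[nm]]
      num <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & vals != "" & is.na(num))
      if (length(bad) > 0) {
        abort(paste0("non-numeric ", nm, " in row(s): ", paste(bad, collapse = ", ")),
              class = "intercrop_parse_error")
      }
      df[[nm]] <- num
    }
  }
  for (nm in c("sowing_date", "harvest_date")) {
    parsed <- as.Date(df[[nm]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df[[nm]]))
    if (length(bad) > 0) {
      abort(paste0("unparseable ISO-8601 date in ", nm, ", row(s): ",
                   paste(bad, collapse = ", ")), class = "intercrop_parse_error")
    }
    df[[nm]] <- parsed
  }
  validate_plot_records(as_tibble(df))
}

read_col_map <- function(col_map) {
  if (is.null(col_map) || is.character(col_map) && !is.null(names(col_map))) {
    return(col_map)
  }
  if (is.character(col_map) && length(col_map) == 1L && file.exists(col_map)) {
    txt <- readLines(col_map, warn = FALSE)
    parsed <- if (grepl("\\.json$", col_map)) {
      jsonlite::fromJSON(paste(txt, collapse = "\n"))
    } else {
      yaml::yaml.load(paste(txt, collapse = "\n"))
    }
    return(unlist(parsed))
  }
  if (is.list(col_map)) return(unlist(col_map))
  abort("col_map must be a named character vector, list, or a YAML/JSON file path",
        class = "intercrop_schema_error")
}

#' Validate plot records row by row
#'
#' Checks every row against the schema invariants: non-negative yield, a
#' legal treatment/component combination, sown proportion in \[0, 1\],
#' harvest strictly after sowing, and — when both nitrogen fields are
#' present — consistency `n_uptake = dmy * n_conc` to relative tolerance
#' `1e-6`. Invalid rows are removed and reported.
#'
#' @param df A data frame with the `plot_records` columns.
#' @param rel_tol Relative tolerance for the nitrogen consistency check.
#' @return A validated `plot_records` tibble; rejected rows, with their
#'   original row index and reason, sit in the `"rejects"` attribute.
#' @export
validate_plot_records <- function(df, rel_tol = 1e-6) {
  df <- as_tibble(df)
  n <- nrow(df)
  reasons <- rep(NA_character_, n)
  note <- function(idx, why) {
    idx <- idx[is.na(reasons[idx])]
    reasons[idx] <<- why
  }
  note(which(is.na(df$dmy)), "missing dmy")
  note(which(df$dmy < 0), "negative dmy")
  combo_ok <- (df$treatment == "PURE_IR" & df$component == "IR") |
    (df$treatment == "PURE_C" & df$component == "C") |
    (df$treatment == "MIX" & df$component %in% .components)
  note(which(!df$treatment %in% .treatments), "unknown treatment")
  note(which(!combo_ok), "treatment/component mismatch")
  note(which(is.na(df$sown_proportion) | df$sown_proportion < 0 | df$sown_proportion > 1),
       "sown_proportion outside [0, 1]")
  note(which(!(df$harvest_date > df$sowing_date)), "harvest_date not after sowing_date")
  if (all(c("n_conc", "n_uptake") %in% names(df))) {
    both <- !is.na(df$n_conc) & !is.na(df$n_uptake)
    expected <- df$dmy * df$n_conc
    inconsistent <- both & abs(df$n_uptake - expected) >
      rel_tol * pmax(abs(expected), .Machine$double.xmin)
    note(which(inconsistent), "n_uptake inconsistent with dmy * n_conc")
  }
  bad <- which(!is.na(reasons))
  rejects <- tibble(row = bad, reason = reasons[bad])
  if (length(bad) > 0) {
    warn(paste0(length(bad), " record(s) rejected: ",
                paste0("row ", rejects$row, " (", rejects$reason, ")", collapse = "; ")),
         class = "intercrop_validation_warning")
    df <- df[-bad, , drop = FALSE]
  }
  structure(df, rejects = rejects, class = c("plot_records", class(df)))
}

#' Rejected rows of a validated record set
#'
#' @param records A `plot_records` tibble from [read_plot_records()] or
#'   [validate_plot_records()].
#' @return A tibble with columns `row` (original row index) and `reason`.
#' @export
rejected_records <- function(records) {
  attr(records, "rejects") %||% tibble(row = integer(0), reason = character(0))
}

#' Write plot records to a delimited text file
#'
#' Inverse of [read_plot_records()]: dates are written ISO-8601 so that a
#' write/read round trip is the identity on all fields.
#'
#' @param records A `plot_records` tibble.
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_plot_records <- function(records, path, delim = ",") {
  readr::write_delim(as_tibble(records), path, delim = delim)
  invisible(path)
}
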