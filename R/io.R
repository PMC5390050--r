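# CSV schemas for every table the pipeline reads or writes.
# Dialect is fixed: comma-separated, header row, UTF-8, "." decimal mark.
table_schemas <- function() {
  list(
    calibration = list(
      required = c("analyte", "level_ug_per_ml", "response", "day", "lab",
                   "replicate"),
      numeric = c("level_ug_per_ml", "response")
    ),
    peaks = list(
      required = c("sample_id", "analyte", "response", "mass_mg", "volume_ml",
                   "dilution"),
      numeric = c("response", "mass_mg", "volume_ml", "dilution")
    ),
    spiking = list(
      required = c("analyte", "replicate", "value", "added_mg_per_g"),
      numeric = c("value", "added_mg_per_g")
    ),
    stability = list(
      required = c("analyte", "timepoint_h", "value"),
      numeric = c("timepoint_h", "value")
    ),
    interlab = list(
      required = c("lab", "material", "analyte", "day", "replicate", "value"),
      numeric = "value"
    )
  )
}

#' Read and validate a pipeline CSV
#'
#' Reads one of the pipeline's CSV dialects (comma-separated, header row,
#' UTF-8, `"."` decimal mark) and validates it against the named schema:
#' required columns must be present, numeric columns must parse as numbers,
#' and analyte ids must belong to the canonical roster. Row-level problems
#' are collected and reported together with their line numbers. Values
#' written with a European decimal comma are rejected explicitly with a
#' remediation hint.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"calibration"`, `"peaks"`, `"spiking"`,
#'   `"stability"`, `"interlab"`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema = names(table_schemas())) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  spec <- table_schemas()[[schema]]

  data <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  check_columns(data, spec$required, sprintf("%s table '%s'", schema, path))

  problems <- character(0)
  for (col in spec$numeric) {
    raw <- data[[col]]
    comma <- grepl("^-?[0-9]+,[0-9]+$", raw)
    if (any(comma)) {
      abort(sprintf(
        paste0("column `%s` of %s uses a decimal comma (e.g. \"%s\" on data ",
               "row %d); rewrite the file with \".\" as the decimal mark."),
        col, path, raw[which(comma)[1]], which(comma)[1]))
    }
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "column `%s`: non-numeric value(s) on data row(s) %s",
        col, paste(head(bad, 5), collapse = ", ")))
    }
    data[[col]] <- parsed
  }
  if ("analyte" %in% names(data)) {
    known <- c(analyte_roster(), "monomers")
    bad <- which(!data$analyte %in% known)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "column `analyte`: unknown analyte id(s) %s on data row(s) %s",
        paste(unique(data$analyte[bad]), collapse = ", "),
        paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    abort(paste(c(sprintf("validation of %s failed:", path),
                  paste0("  - ", problems)), collapse = "\n"))
  }
  data
}

#' Write a pipeline CSV
#'
#' Writes a table in the pipeline's CSV dialect (see [read_table()]).
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
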