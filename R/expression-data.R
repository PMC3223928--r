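#' Validate a long-format expression table
#'
#' The package's universal data currency is a plain long tibble of
#' efficiency-corrected relative expression values with one row per measured
#' cell: columns `treatment`, `replicate`, `gene` and `value` (linear scale,
#' strictly positive). Missing cells may either be absent rows or rows with
#' `NA` in `value`; both are treated identically. Replicate labels are nested
#' within treatments: replicate "r1" of treatment A and replicate "r1" of
#' treatment B are different biological samples.
#'
#' @param data A data frame with columns `treatment`, `replicate`, `gene`,
#'   `value`.
#' @return The validated data as a tibble with character label columns and a
#'   double `value` column.
#' @examples
#' ng_data(data.frame(
#'   treatment = "ctrl", replicate = c("r1", "r2"),
#'   gene = "actb", value = c(1.02, 0.97)
#' ))
#' @export
ng_data <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data.frame of (treatment, replicate, gene, value).")
  }
  needed <- c("treatment", "replicate", "gene", "value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`data` is missing required column(s): ",
      paste0("`", missing_cols, "`", collapse = ", "), "."
    ))
  }
  out <- as_tibble(data)[needed]
  out$treatment <- as.character(out$treatment)
  out$replicate <- as.character(out$replicate)
  out$gene <- as.character(out$gene)
  if (!is.numeric(out$value)) {
    abort("`value` must be numeric (linear-scale relative expression).")
  }
  out$value <- as.double(out$value)

  bad <- which(!is.na(out$value) & out$value <= 0)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      paste0(
        "Expression values must be strictly positive (log transform must be ",
        "defined); found %g for treatment '%s', replicate '%s', gene '%s' ",
        "(%d offending row%s)."
      ),
      out$value[i], out$treatment[i], out$replicate[i], out$gene[i],
      length(bad), if (length(bad) == 1) "" else "s"
    ))
  }

  key <- paste(out$treatment, out$replicate, out$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
    abort(sprintf(
      "Duplicate (treatment, replicate, gene) triple: ('%s', '%s', '%s').",
      parts[1], parts[2], parts[3]
    ))
  }
  out
}

#' Convert between long and wide expression layouts
#'
#' The wide convenience layout has one row per gene, a `gene` column, and one
#' column per sample named `<treatment>:<replicate>`. Conversion is lossless;
#' `NA` cells mark missing measurements.
#'
#' @param data A long expression table (see [ng_data()]) or a wide data frame.
#' @return A tibble in the other layout.
#' @export
expression_to_wide <- function(data) {
  data <- ng_data(data)
  data$sample <- paste(data$treatment, data$replicate, sep = ":")
  tidyr::pivot_wider(
    data[c("gene", "sample", "value")],
    names_from = "sample", values_from = "value"
  )
}

#' @rdname expression_to_wide
#' @export
expression_to_long <- function(data) {
  data <- as_tibble(data)
  if (!"gene" %in% names(data)) {
    abort("Wide expression tables must have a `gene` column.")
  }
  sample_cols <- setdiff(names(data), "gene")
  if (!all(grepl(":", sample_cols, fixed = TRUE))) {
    abort("Wide sample columns must be named `<treatment>:<replicate>`.")
  }
  long <- tidyr::pivot_longer(
    data,
    cols = dplyr::all_of(sample_cols),
    names_to = c("treatment", "replicate"), names_sep = ":",
    values_to = "value"
  )
  ng_data(long[c("treatment", "replicate", "gene", "value")])
}

#' Read and write expression CSV files
#'
#' The canonical on-disk format is a long CSV with header
#' `treatment,replicate,gene,value`; empty cells or the literal `NA` mark
#' missing values, the decimal separator is always a dot, and lines starting
#' with `#` are ignored (run metadata is written there). A wide dialect (one
#' row per gene, `<treatment>:<replicate>` columns) is accepted and produced
#' for convenience.
#'
#' @param path Path of the CSV file.
#' @param dialect `"long"` (canonical) or `"wide"`.
#' @return `read_expression_csv()` returns a validated long tibble;
#'   `write_expression_csv()` returns `path` invisibly.
#' @export
read_expression_csv <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Input file does not exist: '%s'.", path))
  }
  raw <- readr::read_csv(
    path,
    comment = "#", na = c("", "NA"), show_col_types = FALSE,
    locale = readr::locale(decimal_mark = ".")
  )
  if (dialect == "long") {
    ng_data(raw)
  } else {
    expression_to_long(raw)
  }
}

#' @rdname read_expression_csv
#' @param data Expression table to write (long layout expected).
#' @param header Optional character vector written as leading `# ` comment
#'   lines (configuration, seed) so that outputs are self-describing.
#' @export
write_expression_csv <- function(data, path,
                                 dialect = c("long", "wide"), header = NULL) {
  dialect <- match.arg(dialect)
  data <- ng_data(data)
  out <- if (dialect == "wide") expression_to_wide(data) else data
  write_csv_with_header(out, path, header)
}

# Plain-text CSV writer that can prepend `# ` comment metadata lines.
write_csv_with_header <- function(df, path, header = NULL) {
  body <- readr::format_csv(df, na = "NA")
  lines <- c(
    if (!is.null(header)) paste0("# ", header),
    sub("\n$", "", body)
  )
  writeLines(lines, path)
  invisible(path)
}
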