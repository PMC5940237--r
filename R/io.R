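#' Read a feature table from tab-separated text
#'
#' Parses the plain-text table dialect used throughout the package: one
#' header row of identifiers, one identifier column, numeric body, optional
#' leading `#` comment lines. The canonical internal orientation is features
#' as rows and samples as columns; tables stored the other way round are
#' transposed on read. A column literally named `taxonomy` (any case) is
#' ignored by the numeric parser.
#'
#' @param path Path to a TSV file.
#' @param orientation `"features_as_rows"` (default) or `"samples_as_rows"`.
#' @return A [feature_table()]. The state is `"counts"` if every entry is an
#'   integer, otherwise `"unknown"`: a non-integer body is *not* assumed to
#'   be relative abundance — set the state explicitly once you know the
#'   scale (e.g. via [to_relative_abundance()] or [feature_table()]).
#' @export
read_feature_table <- function(path,
                               orientation = c("features_as_rows",
                                               "samples_as_rows")) {
  orientation <- match.arg(orientation)
  assert_that(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) >= 2, "table must have a header and at least one row: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol_expected <- length(header)
  col_ids <- header[-1]
  keep <- tolower(col_ids) != "taxonomy"
  dup <- unique(col_ids[keep][duplicated(col_ids[keep])])
  assert_that(length(dup) == 0, "duplicated column identifiers: ", oxford(dup))
  body <- cells[-1]
  row_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = sum(keep))
  for (i in seq_along(body)) {
    row <- body[[i]]
    assert_that(length(row) == ncol_expected,
                sprintf("ragged row %d ('%s'): expected %d fields, found %d",
                        i, row[1], ncol_expected, length(row)))
    row_ids[i] <- row[1]
    num <- suppressWarnings(as.numeric(row[-1][keep]))
    if (anyNA(num)) {
      j <- which(is.na(num))[1]
      stop_percnorm(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                            row[1], col_ids[keep][j], row[-1][keep][j]))
    }
    values[i, ] <- num
  }
  dup <- unique(row_ids[duplicated(row_ids)])
  assert_that(length(dup) == 0, "duplicated row identifiers: ", oxford(dup))
  dimnames(values) <- list(row_ids, col_ids[keep])
  if (orientation == "samples_as_rows") values <- t(values)
  state <- if (all(values >= 0) && all(values == round(values))) "counts" else "unknown"
  feature_table(values, state = state)
}

#' Write a feature table as tab-separated text
#'
#' Writes the table in the canonical features-as-rows orientation with full
#' repeatable precision (15 significant digits), so a write/read round trip
#' reproduces the values exactly. Any header comment lines attached to the
#' table (e.g. the normalization provenance recorded by
#' [percentile_normalize()]) are emitted first, prefixed with `#`.
#'
#' @param x A [feature_table()].
#' @param path Output file path.
#' @param id_column Name of the identifier column in the header (default
#'   `"feature_id"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  validate_feature_table(x)
  v <- ft_values(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in attr(x, "header_comments")) writeLines(paste0("# ", h), con)
  writeLines(paste(c(id_column, colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1, function(row)
    paste(formatC(row, digits = 15, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a TSV with columns `sample_id`, `study_id`, `group`, the per-sample
#' design used for percentile normalization and batch correction. `group`
#' values must be exactly `"case"` or `"control"`.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `sample_id`, `study_id`, `group`.
#' @export
read_sample_metadata <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE)
  need <- c("sample_id", "study_id", "group")
  missing <- setdiff(need, names(md))
  assert_that(length(missing) == 0,
              "metadata is missing columns: ", oxford(missing))
  md <- md[, need]
  check_sample_info(md, md$sample_id)
}

#' @rdname read_sample_metadata
#' @param metadata Data frame as returned by [read_sample_metadata()].
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata[, c("sample_id", "study_id", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample ID list
#'
#' One sample identifier per line, the format used for the case/control ID
#' lists given to the command-line `percentile-normalize` tool. Blank lines
#' and `#` comments are ignored.
#'
#' @param path Path to a text file.
#' @return Character vector of IDs.
#' @export
read_id_list <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0, "duplicated ids in ", path, ": ", oxford(dup))
  ids
}
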