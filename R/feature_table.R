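#' Feature abundance tables
#'
#' A `feature_table` is the package's basic container: a numeric matrix of
#' microbial feature abundances (OTUs or genera as rows, samples as columns)
#' together with a `state` flag recording the scale the values live on:
#'
#' * `"counts"` — non-negative integers (read counts).
#' * `"relative"` — relative-abundance scale. Columns sum to one immediately
#'   after [to_relative_abundance()]; operations such as [back_transform()]
#'   and the lognormal simulator also return values on this scale without
#'   re-closing columns to one, so unit sums are checked only by
#'   [validate_feature_table()] with `strict = TRUE`.
#' * `"log"` — natural-log transformed relative abundances.
#' * `"percentile"` — values in \[0, 100\] produced by
#'   [percentile_normalize()].
#' * `"unknown"` — scale not yet established (e.g. freshly parsed text).
#'
#' Feature and sample identifiers are opaque, case-sensitive strings and
#' must be unique. An optional `sample_info` data frame (columns
#' `sample_id`, `study_id`, `group`) travels with the table and is used by
#' percentile tables to carry study/group provenance through pooling.
#'
#' @param values Numeric matrix, features as rows, samples as columns. Must
#'   have unique, non-empty row and column names.
#' @param state Character scalar, one of `"counts"`, `"relative"`, `"log"`,
#'   `"percentile"`, `"unknown"`.
#' @param sample_info Optional data frame with columns `sample_id`,
#'   `study_id`, `group`, one row per sample (matched to columns by
#'   `sample_id`).
#' @return An object of class `feature_table`.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 0, 4), nrow = 3,
#'             dimnames = list(paste0("otu", 1:3), c("s1", "s2")))
#' ft <- feature_table(m, state = "counts")
#' to_relative_abundance(ft)
#' @export
feature_table <- function(values, state = "unknown", sample_info = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must have feature (row) and sample (column) names")
  structure(values,
            state = match.arg(state, ft_states()),
            sample_info = check_sample_info(sample_info, colnames(values)),
            class = "feature_table") |>
    validate_feature_table()
}

ft_states <- function() c("unknown", "counts", "relative", "log", "percentile")

check_sample_info <- function(sample_info, sample_ids) {
  if (is.null(sample_info)) return(NULL)
  assert_that(is.data.frame(sample_info) &&
                all(c("sample_id", "study_id", "group") %in% names(sample_info)),
              "sample_info must be a data frame with columns sample_id, study_id, group")
  assert_that(!anyDuplicated(sample_info$sample_id),
              "sample_info has duplicated sample ids")
  missing <- setdiff(sample_ids, sample_info$sample_id)
  assert_that(length(missing) == 0,
              "sample_info is missing samples: ", oxford(missing))
  bad <- setdiff(unique(sample_info$group), c("case", "control"))
  assert_that(length(bad) == 0,
              "sample_info group values must be 'case' or 'control', found: ",
              oxford(bad))
  out <- sample_info[match(sample_ids, sample_info$sample_id),
                     c("sample_id", "study_id", "group"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a feature table
#'
#' Checks the structural invariants of a [feature_table()]: unique
#' identifiers, finite values (`NA` is permitted only in pooled percentile
#' tables, where it marks a feature unobserved in a study), non-negativity
#' for count/relative/percentile states and the \[0, 100\] range for
#' percentiles. With `strict = TRUE`, additionally requires unit column sums
#' (within 1e-9) for `state = "relative"` and integer values for
#' `state = "counts"`.
#'
#' @param x A `feature_table`.
#' @param strict Logical; also check scale-closure invariants (see above).
#' @return `x`, invisibly usable in a pipe (returned unchanged).
#' @export
validate_feature_table <- function(x, strict = FALSE) {
  assert_that(inherits(x, "feature_table"), "not a feature_table")
  state <- ft_state(x)
  dup_f <- unique(rownames(x)[duplicated(rownames(x))])
  assert_that(length(dup_f) == 0, "duplicated feature ids: ", oxford(dup_f))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  assert_that(length(dup_s) == 0, "duplicated sample ids: ", oxford(dup_s))
  v <- unclass(x)
  attributes(v) <- list(dim = dim(x))
  assert_that(!any(is.infinite(v)), "values must be finite")
  if (anyNA(v)) {
    assert_that(state == "percentile",
                "NA values are only allowed in pooled percentile tables")
  }
  if (state %in% c("counts", "relative", "percentile")) {
    assert_that(all(v >= 0, na.rm = TRUE),
                "negative values are not allowed when state is ", state)
  }
  if (state == "percentile") {
    assert_that(all(v <= 100, na.rm = TRUE), "percentile values must be <= 100")
  }
  if (strict && state == "relative") {
    cs <- colSums(v)
    bad <- colnames(x)[abs(cs - 1) > 1e-9]
    assert_that(length(bad) == 0,
                "columns do not sum to 1: ", oxford(bad))
  }
  if (strict && state == "counts") {
    assert_that(all(v == round(v)), "counts must be integers")
  }
  x
}

#' @rdname feature_table
#' @param x Object to test or query.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

#' @rdname feature_table
#' @export
ft_state <- function(x) attr(x, "state")

#' @rdname feature_table
#' @export
sample_info <- function(x) attr(x, "sample_info")

set_state <- function(x, state) {
  attr(x, "state") <- match.arg(state, ft_states())
  x
}

ft_values <- function(x) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(v), dimnames = dimnames(x))
  v
}

#' @export
as.matrix.feature_table <- function(x, ...) ft_values(x)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples [state: %s]\n",
              nrow(x), ncol(x), ft_state(x)))
  si <- sample_info(x)
  if (!is.null(si)) {
    tab <- table(si$study_id, si$group)
    cat("samples per study/group:\n")
    print(tab)
  }
  n <- min(nrow(x), 5L)
  m <- min(ncol(x), 5L)
  print(ft_values(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x))
  if (missing(j)) j <- seq_len(ncol(x))
  v <- ft_values(x)[i, j, drop = FALSE]
  si <- sample_info(x)
  if (!is.null(si)) si <- si[match(colnames(v), si$sample_id), , drop = FALSE]
  structure(v, state = ft_state(x), sample_info = si, class = "feature_table")
}

#' Convert counts to relative abundance
#'
#' Divides each sample (column) by its total, the standard total-sum scaling
#' used before genus collapsing and percentile normalization. Zero entries
#' stay zero; the operation is idempotent on columns already summing to one.
#'
#' @param x A `feature_table` with state `"counts"`, `"relative"` or
#'   `"unknown"`.
#' @return A `feature_table` with state `"relative"`; every column sums to 1.
#' @export
to_relative_abundance <- function(x) {
  validate_feature_table(x)
  assert_that(ft_state(x) %in% c("counts", "relative", "unknown"),
              "cannot convert a table with state ", ft_state(x),
              " to relative abundance")
  v <- ft_values(x)
  assert_that(all(v >= 0), "negative values are not allowed")
  totals <- colSums(v)
  bad <- colnames(v)[totals <= 0]
  assert_that(length(bad) == 0,
              "samples with zero total abundance: ", oxford(bad))
  out <- sweep(v, 2, totals, "/")
  structure(out, state = "relative", sample_info = sample_info(x),
            class = "feature_table")
}

#' Collapse features to genus level
#'
#' Sums all rows that share a genus-level annotation, mirroring the usual
#' practice of summarizing OTU tables at genus rank before cross-study
#' comparison. Features lacking a genus are grouped under their most
#' resolved available rank, labelled `"<rank>:<name>"`, so unannotated OTUs
#' are never silently merged into a named genus; features with no annotation
#' at any rank collapse under `"unclassified"`. Column sums are preserved
#' exactly.
#'
#' @param x A `feature_table`.
#' @param taxonomy Data frame with a `feature_id` column plus lineage rank
#'   columns (any of `kingdom`, `phylum`, `class`, `order`, `family`,
#'   `genus`, in that hierarchical order); `NA` or `""` marks a missing
#'   rank. Every feature of `x` must be present.
#' @return A `feature_table` with one row per distinct collapse label, in
#'   order of first appearance.
#' @export
collapse_to_genus <- function(x, taxonomy) {
  validate_feature_table(x)
  assert_that(is.data.frame(taxonomy) && "feature_id" %in% names(taxonomy),
              "taxonomy must be a data frame with a feature_id column")
  missing <- setdiff(rownames(x), taxonomy$feature_id)
  assert_that(length(missing) == 0,
              "features missing from taxonomy: ", oxford(missing))
  ranks <- intersect(c("kingdom", "phylum", "class", "order", "family", "genus"),
                     names(taxonomy))
  assert_that(length(ranks) > 0, "taxonomy has no recognized rank columns")
  tax <- taxonomy[match(rownames(x), taxonomy$feature_id), , drop = FALSE]
  labels <- vapply(seq_len(nrow(tax)), function(i) {
    lineage <- as.character(unlist(tax[i, ranks]))
    present <- !is.na(lineage) & nzchar(lineage)
    if (!any(present)) return("unclassified")
    deepest <- max(which(present))
    if (ranks[deepest] == "genus") lineage[deepest]
    else paste0(ranks[deepest], ":", lineage[deepest])
  }, character(1))
  v <- rowsum(ft_values(x), group = labels, reorder = FALSE)
  structure(v, state = ft_state(x), sample_info = sample_info(x),
            class = "feature_table")
}

#' Split a feature table by study and group
#'
#' Partitions the samples of a table by study and case/control status. The
#' partition is exact: every sample lands in exactly one sub-table and the
#' column order within sub-tables follows the input order.
#'
#' @param x A `feature_table`.
#' @param metadata Data frame with columns `sample_id`, `study_id`, `group`
#'   (`"case"` or `"control"`) covering every sample of `x`.
#' @return Named list (one element per study) of lists with elements
#'   `control` and `case`, each a `feature_table` (possibly with zero
#'   columns).
#' @export
split_by_design <- function(x, metadata) {
  validate_feature_table(x)
  metadata <- check_sample_info(metadata, colnames(x))
  studies <- unique(metadata$study_id)
  out <- lapply(studies, function(s) {
    ids <- metadata$sample_id[metadata$study_id == s]
    grp <- metadata$group[metadata$study_id == s]
    list(control = x[, colnames(x) %in% ids[grp == "control"]],
         case = x[, colnames(x) %in% ids[grp == "case"]])
  })
  names(out) <- studies
  out
}
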