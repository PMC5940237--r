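#' Replace zeros with tiny uniform pseudo relative abundances
#'
#' Microbiome tables are zero-inflated, and ranking many tied zeros piles
#' ranks up at the bottom of each feature's distribution. Before percentile
#' conversion, every zero entry is therefore replaced by an independent draw
#' from Uniform(0, `upper_bound`] — by default (0, 1e-9], smaller than any
#' true nonzero relative abundance in a realistic dataset — which breaks the
#' ties without disturbing the ranks of observed values. Because of this
#' random draw, downstream p-values can shift slightly between runs with
#' different seeds, so the seed should be recorded alongside any result.
#'
#' @param x A `feature_table` with state `"relative"`.
#' @param upper_bound Upper bound of the uniform replacement draw, in
#'   relative-abundance units (default `1e-9`). Must be positive and should
#'   be below the smallest true nonzero abundance in the data.
#' @param seed Integer seed for the replacement draws, or `NULL` to draw
#'   from the current RNG stream. Identical seeds give identical output.
#' @return A `feature_table` with the same state and no zero entries.
#' @export
replace_zeros <- function(x, upper_bound = 1e-9, seed = NULL) {
  validate_feature_table(x)
  assert_that(ft_state(x) == "relative",
              "replace_zeros expects a relative-abundance table, got state ",
              ft_state(x))
  assert_that(is.numeric(upper_bound) && length(upper_bound) == 1 &&
                upper_bound > 0, "upper_bound must be a positive number")
  v <- ft_values(x)
  assert_that(all(v >= 0), "negative values are not allowed")
  zero <- which(v == 0)
  if (length(zero)) {
    # (1 - runif()) lies in (0, 1], so draws are strictly positive
    v[zero] <- with_seed_or_stream(seed,
                                   (1 - stats::runif(length(zero))) * upper_bound)
  }
  structure(v, state = ft_state(x), sample_info = sample_info(x),
            class = "feature_table")
}

# counts of reference values strictly below / weakly below each score,
# computed by sorted search; exact under ties
percentile_counts <- function(scores, reference) {
  n <- length(reference)
  sr <- sort(reference)
  weak <- findInterval(scores, sr)              # #{ref <= score}
  strict <- n - findInterval(-scores, sort(-reference))  # n - #{ref >= score}
  list(strict = strict, weak = weak, n = n)
}

#' Percentile of a score within a reference distribution
#'
#' The mean-of-strict-and-weak convention: the percentile of `score` within
#' `reference` is
#' \deqn{100 \cdot \frac{\#\{r < s\} + \#\{r \le s\}}{2n},}
#' the average of the strict and weak empirical ranks. Under this
#' convention, `n` distinct reference values map onto the uniform grid
#' \eqn{100(k - 0.5)/n}, `k = 1..n`, when scored against themselves.
#'
#' @param reference Non-empty numeric vector of reference values.
#' @param score Numeric vector of scores to convert.
#' @return Numeric vector of percentiles in \[0, 100\], one per score.
#' @examples
#' percentile_of_score(1:5, 3)        # 50
#' percentile_of_score(c(1, 2, 2, 3), 2)  # 50
#' @export
percentile_of_score <- function(reference, score) {
  assert_that(is.numeric(reference) && length(reference) > 0 &&
                !anyNA(reference), "reference must be non-empty and free of NA")
  assert_that(is.numeric(score) && !anyNA(score), "score must be numeric without NA")
  pc <- percentile_counts(score, reference)
  100 * (pc$strict + pc$weak) / (2 * pc$n)
}

#' Percentile-normalize one study against its own controls
#'
#' The core batch-correction step. Within a study, for every feature the
#' control values are converted to percentiles of themselves (which puts
#' the controls on a uniform grid between 0 and 100) and the case values to
#' percentiles of the same control distribution. Study-specific batch
#' effects are present in cases and controls alike, so expressing cases
#' relative to the within-study controls cancels them without any
#' parametric model; normalized studies live on a common percentile axis
#' and can be pooled with [pool_studies()]. Zeros are first replaced via
#' [replace_zeros()].
#'
#' @param x A `feature_table` with state `"relative"` containing at least
#'   the listed samples.
#' @param control_ids Non-empty character vector of control sample IDs.
#' @param case_ids Character vector of case sample IDs (may be empty, e.g.
#'   when self-normalizing a control-only pool).
#' @param study_id Study label carried into the output's provenance.
#' @param upper_bound,seed Passed to [replace_zeros()].
#' @return A `feature_table` with state `"percentile"`, columns ordered
#'   `c(control_ids, case_ids)`, and a `sample_info` attribute recording
#'   study and group per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 40, 5, 35), nrow = 1,
#'             dimnames = list("otu1", paste0("s", 1:6)))
#' ft <- feature_table(m, state = "relative")
#' percentile_normalize(ft, control_ids = paste0("s", 1:4),
#'                      case_ids = c("s5", "s6"), seed = 1)
#' @export
percentile_normalize <- function(x, control_ids, case_ids = character(),
                                 study_id = "study", upper_bound = 1e-9,
                                 seed = NULL) {
  validate_feature_table(x)
  assert_that(length(control_ids) > 0, "control_ids must be non-empty")
  ids <- c(control_ids, case_ids)
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0, "sample ids listed twice: ", oxford(dup))
  unknown <- setdiff(ids, colnames(x))
  assert_that(length(unknown) == 0,
              "sample ids not in the table: ", oxford(unknown))
  sub <- replace_zeros(x[, ids], upper_bound = upper_bound, seed = seed)
  v <- ft_values(sub)
  ctrl <- seq_along(control_ids)
  out <- matrix(NA_real_, nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
  for (g in seq_len(nrow(v))) {
    out[g, ] <- percentile_of_score(v[g, ctrl], v[g, ])
  }
  info <- data.frame(sample_id = ids, study_id = study_id,
                     group = rep(c("control", "case"),
                                 c(length(control_ids), length(case_ids))),
                     stringsAsFactors = FALSE)
  res <- structure(out, state = "percentile", sample_info = info,
                   class = "feature_table")
  attr(res, "header_comments") <- c(
    sprintf("percentile-normalized: study=%s", study_id),
    sprintf("zero replacement: upper_bound=%g seed=%s", upper_bound,
            if (is.null(seed)) "ambient" else as.character(seed)),
    sprintf("controls: n=%d; cases: n=%d", length(control_ids),
            length(case_ids)))
  validate_feature_table(res)
}

#' Pool percentile-normalized studies
#'
#' Concatenates normalized studies column-wise over the union of their
#' features, putting all studies on the shared percentile axis so that a
#' single pooled test can be run per feature. A feature absent from a study
#' is marked `NA` for that study's samples and excluded pairwise from
#' downstream rank tests (a feature never observed in a study carries no
#' rank information there); set `absent = "zero"` to instead treat absence
#' as zero abundance (percentile 0).
#'
#' @param tables List of two or more percentile tables from
#'   [percentile_normalize()], each carrying study/group provenance.
#' @param absent `"exclude"` (default) or `"zero"`; how to fill features a
#'   study never observed.
#' @return A pooled `feature_table` with state `"percentile"` and combined
#'   `sample_info`; its sample count is the sum of the inputs'.
#' @export
pool_studies <- function(tables, absent = c("exclude", "zero")) {
  absent <- match.arg(absent)
  assert_that(is.list(tables) && length(tables) >= 2,
              "pooling requires at least two normalized studies")
  for (t in tables) {
    assert_that(is_feature_table(t) && ft_state(t) == "percentile",
                "all inputs must be percentile tables")
    assert_that(!is.null(sample_info(t)),
                "all inputs must carry sample_info provenance")
  }
  all_samples <- unlist(lapply(tables, colnames))
  dup <- unique(all_samples[duplicated(all_samples)])
  assert_that(length(dup) == 0,
              "duplicate sample ids across studies: ", oxford(dup))
  features <- unique(unlist(lapply(tables, rownames)))
  fill <- if (absent == "exclude") NA_real_ else 0
  out <- matrix(fill, nrow = length(features), ncol = length(all_samples),
                dimnames = list(features, all_samples))
  for (t in tables) out[rownames(t), colnames(t)] <- ft_values(t)
  info <- do.call(rbind, lapply(tables, sample_info))
  rownames(info) <- NULL
  res <- structure(out, state = "percentile", sample_info = info,
                   class = "feature_table")
  validate_feature_table(res)
}
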