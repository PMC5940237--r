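#' Occurrence-based abundance filter
#'
#' Keeps a feature if it occurs (value > 0) in at least a given fraction of
#' group-A samples *or* at least that fraction of group-B samples — by
#' default one third of controls or one third of cases — reducing the
#' multiple-testing burden before differential testing. The filter must be
#' evaluated on pre-replacement abundances ("occurred" means truly nonzero),
#' so apply it before [replace_zeros()] or any correction that removes
#' zeros.
#'
#' @param x A `feature_table` on a non-log scale (counts or relative).
#' @param group_a_ids,group_b_ids Non-empty character vectors of sample IDs
#'   for the two groups.
#' @param fraction Required occurrence fraction (default `1/3`).
#' @return Character vector of retained feature IDs, in table order.
#' @export
abundance_filter <- function(x, group_a_ids, group_b_ids, fraction = 1 / 3) {
  validate_feature_table(x)
  assert_that(ft_state(x) != "log",
              "the occurrence filter must be run on pre-log abundances")
  assert_that(length(group_a_ids) > 0 && length(group_b_ids) > 0,
              "both groups must be non-empty")
  unknown <- setdiff(c(group_a_ids, group_b_ids), colnames(x))
  assert_that(length(unknown) == 0,
              "sample ids not in the table: ", oxford(unknown))
  v <- ft_values(x)
  frac_a <- rowSums(v[, group_a_ids, drop = FALSE] > 0) / length(group_a_ids)
  frac_b <- rowSums(v[, group_b_ids, drop = FALSE] > 0) / length(group_b_ids)
  tol <- 1e-12
  rownames(x)[frac_a + tol >= fraction | frac_b + tol >= fraction]
}

#' Wilcoxon rank-sum test, normal approximation
#'
#' Two-sided rank-sum test using midranks and the plain normal
#' approximation
#' \deqn{z = \frac{R_x - n_x (N + 1)/2}{\sqrt{n_x n_y (N + 1)/12}},}
#' with *no* tie correction and *no* continuity correction. This is the
#' convention of the widely used `scipy.stats.ranksums` routine, kept here
#' so results are directly comparable with analyses built on it; with the
#' zero-replacement step upstream, ties are essentially absent anyway. A
#' positive `z` means `x` tends to rank higher than `y`.
#'
#' @param x,y Non-empty numeric vectors (NAs dropped).
#' @return Named numeric vector with elements `z` and `p` (two-sided).
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))  # z = -1.964, p = 0.0495
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  assert_that(length(x) >= 1 && length(y) >= 1,
              "both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  z <- (R1 - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# vectorized rank-sum across the rows of a matrix; NA entries (features
# absent from a study after pooling) are dropped pairwise per feature
ranksum_rows <- function(v, case_idx, control_idx) {
  stats_one <- function(row) {
    wilcoxon_ranksum(row[case_idx], row[control_idx])
  }
  res <- t(apply(v, 1, stats_one))
  if (nrow(v) == 1) res <- matrix(res, nrow = 1)
  data.frame(feature_id = rownames(v), z = res[, 1], p = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Feature-wise rank-sum tests on a table
#'
#' Runs [wilcoxon_ranksum()] (cases vs controls) for every feature of a
#' table and applies Benjamini-Hochberg FDR adjustment across features.
#' `NA` entries — features marked absent for a study by [pool_studies()] —
#' are excluded pairwise.
#'
#' @param x A `feature_table`.
#' @param case_ids,control_ids Sample IDs of the two groups.
#' @return Data frame with columns `feature_id`, `n_case`, `n_control`,
#'   `z`, `p`, `q` and `direction` (`"case_enriched"`, `"control_enriched"`
#'   or `"tied"` from the sign of `z`).
#' @export
test_features <- function(x, case_ids, control_ids) {
  validate_feature_table(x)
  unknown <- setdiff(c(case_ids, control_ids), colnames(x))
  assert_that(length(unknown) == 0,
              "sample ids not in the table: ", oxford(unknown))
  v <- ft_values(x)
  res <- ranksum_rows(v, match(case_ids, colnames(v)),
                      match(control_ids, colnames(v)))
  res$n_case <- rowSums(!is.na(v[, case_ids, drop = FALSE]))
  res$n_control <- rowSums(!is.na(v[, control_ids, drop = FALSE]))
  res$q <- bh_fdr(res$p)
  res$direction <- ifelse(res$z > 0, "case_enriched",
                          ifelse(res$z < 0, "control_enriched", "tied"))
  res[, c("feature_id", "n_case", "n_control", "z", "p", "q", "direction")]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' capped at 1 and returned in input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, `q >= p` elementwise.
#' @export
bh_fdr <- function(pvalues) {
  assert_that(is.numeric(pvalues) && !anyNA(pvalues) &&
                all(pvalues > 0 & pvalues <= 1),
              "p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's method for combining p-values
#'
#' Combines k independent p-values via \eqn{X^2 = -2 \sum \ln p_i}, referred
#' to a chi-square distribution with 2k degrees of freedom.
#'
#' @param pvalues Numeric vector of p-values in (0, 1]; exact zeros are an
#'   error (floor them first).
#' @return Combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.01748
#' @export
fisher_combine <- function(pvalues) {
  assert_that(is.numeric(pvalues) && length(pvalues) >= 1 && !anyNA(pvalues),
              "pvalues must be a non-empty numeric vector")
  assert_that(all(pvalues > 0 & pvalues <= 1),
              "p-values must lie in (0, 1]; floor exact zeros before combining")
  x2 <- -2 * sum(log(pvalues))
  stats::pchisq(x2, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Stouffer's weighted z method for combining p-values
#'
#' Converts each p-value to a normal quantile \eqn{z_i = \Phi^{-1}(1 -
#' p_i)}, forms \eqn{Z = \sum w_i z_i / \sqrt{\sum w_i^2}} and returns
#' \eqn{1 - \Phi(Z)}. In per-study meta-analysis the conventional weight is
#' \eqn{w_i = \sqrt{n_{case,i} + n_{control,i}}}, supplied by the caller.
#'
#' @param pvalues Numeric vector of p-values strictly inside (0, 1); 0 and
#'   1 give unbounded quantiles and are an error.
#' @param weights Positive weights, same length as `pvalues` (default:
#'   equal).
#' @return Combined p-value.
#' @examples
#' stouffer_combine(c(0.05, 0.05))  # ~0.0100
#' @export
stouffer_combine <- function(pvalues, weights = rep(1, length(pvalues))) {
  assert_that(is.numeric(pvalues) && length(pvalues) >= 1 && !anyNA(pvalues),
              "pvalues must be a non-empty numeric vector")
  assert_that(all(pvalues > 0 & pvalues < 1),
              "p-values must lie strictly inside (0, 1); clamp 0/1 before combining")
  assert_that(length(weights) == length(pvalues) && all(weights > 0),
              "weights must be positive and match pvalues in length")
  z <- stats::qnorm(1 - pvalues)
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  stats::pnorm(Z, lower.tail = FALSE)
}

#' Screen features with opposing directions across studies
#'
#' Before Fisher/Stouffer combination, features that respond significantly
#' in *opposite* directions in different studies are excluded: a feature
#' enriched in cases in one study and in controls in another is not a
#' consistent association, and two-sided combination would happily merge
#' the two conflicting signals. Under the default rule a feature is
#' excluded iff at least two studies show within-study `q <= threshold`
#' with opposite direction signs; `rule = "p"` uses raw p-values instead,
#' and `rule = "any"` excludes on any sign conflict regardless of
#' significance.
#'
#' @param per_study Data frame of within-study results with columns
#'   `feature_id`, `study_id`, `z`, `p`, `q` (as from [test_features()],
#'   one block per study); at most one row per feature and study.
#' @param rule `"q"` (default), `"p"` or `"any"`.
#' @param threshold Significance threshold for rules `"q"`/`"p"` (default
#'   0.05).
#' @return Character vector of excluded feature IDs.
#' @export
opposing_direction_screen <- function(per_study, rule = c("q", "p", "any"),
                                      threshold = 0.05) {
  rule <- match.arg(rule)
  need <- c("feature_id", "study_id", "z", "p", "q")
  assert_that(is.data.frame(per_study) && all(need %in% names(per_study)),
              "per_study must have columns ", paste(need, collapse = ", "))
  assert_that(!anyDuplicated(per_study[, c("feature_id", "study_id")]),
              "at most one result per feature and study")
  sig <- switch(rule,
                q = per_study$q <= threshold,
                p = per_study$p <= threshold,
                any = rep(TRUE, nrow(per_study)))
  hits <- per_study[sig & per_study$z != 0, , drop = FALSE]
  if (nrow(hits) == 0) return(character(0))
  excluded <- tapply(sign(hits$z), hits$feature_id,
                     function(s) any(s > 0) && any(s < 0))
  names(excluded)[which(excluded)]
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities
#' \eqn{d(u, v) = \sum_g |u_g - v_g| / \sum_g (u_g + v_g)} between samples,
#' computed on relative abundances (delegates to [vegan::vegdist()]).
#'
#' @param x A `feature_table` with non-negative values on a non-log scale;
#'   all-zero samples are an error.
#' @return A `stats::dist` object over the samples, values in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  validate_feature_table(x)
  assert_that(ft_state(x) != "log",
              "Bray-Curtis requires non-negative abundances, not log values")
  v <- ft_values(x)
  assert_that(!anyNA(v), "Bray-Curtis does not accept NA values")
  bad <- colnames(v)[colSums(v) <= 0]
  assert_that(length(bad) == 0, "all-zero samples: ", oxford(bad))
  vegan::vegdist(t(v), method = "bray")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared distances into among- and within-group components,
#' \deqn{F = \frac{SS_{among}/(a - 1)}{SS_{within}/(N - a)},}
#' and assesses it by permuting group labels, so
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}. The fraction of total
#' variance explained by the grouping is \eqn{R^2 = SS_{among}/SS_{total}}.
#' Delegates to [vegan::adonis2()] with a mandatory seed.
#'
#' @param d A `dist` object (e.g. from [bray_curtis()]).
#' @param labels Group label per sample, aligned with (or named by) the
#'   labels of `d`; at least two groups of at least two samples each.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List of class `"permanova_result"` with elements `pseudo_F`,
#'   `p`, `r2`, `n_permutations` and `seed`.
#' @export
permanova <- function(d, labels, n_permutations = 999L, seed = 1L) {
  assert_that(inherits(d, "dist"), "d must be a dist object")
  if (!is.null(names(labels)) && !is.null(attr(d, "Labels"))) {
    missing <- setdiff(attr(d, "Labels"), names(labels))
    assert_that(length(missing) == 0,
                "samples without a group label: ", oxford(missing))
    labels <- labels[attr(d, "Labels")]
  }
  labels <- factor(as.character(labels))
  assert_that(length(labels) == attr(d, "Size"),
              "labels must have one entry per sample in d")
  sizes <- table(labels)
  assert_that(nlevels(labels) >= 2, "at least two groups are required")
  small <- names(sizes)[sizes < 2]
  assert_that(length(small) == 0,
              "groups with fewer than 2 samples: ", oxford(small))
  df <- data.frame(group = labels)
  fit <- withr::with_seed(as.integer(seed),
                          vegan::adonis2(d ~ group, data = df,
                                         permutations = n_permutations))
  structure(list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1], r2 = fit$R2[1],
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f (%.3f%% of variance), p = %.4g [%d permutations, seed %d]\n",
              x$pseudo_F, x$r2, 100 * x$r2, x$p, x$n_permutations, x$seed))
  invisible(x)
}
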