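#' Configuration for the in-silico experiments
#'
#' Shared settings of the control-titration and null false-positive
#' experiments: the mixing-fraction grid, the per-group subsample size, the
#' number of iterations, the significance threshold and the seed. The
#' defaults (40 samples per group, 20 iterations, threshold 0.05) are the
#' study conditions of the validation experiments.
#'
#' @param fractions Ascending grid of mixing fractions in \[0, 1\]
#'   including the endpoints (titration only).
#' @param group_size Samples per group after subsampling (default 40).
#' @param iterations Number of random subsampling iterations (default 20).
#' @param threshold Significance threshold on q (titration) or p (null
#'   experiment); default 0.05.
#' @param filter_fraction Occurrence fraction of [abundance_filter()].
#' @param upper_bound Zero-replacement upper bound for the percentile
#'   treatment.
#' @param seed Integer seed driving every random step of the experiment.
#' @return List of class `"titration_config"`.
#' @export
titration_config <- function(fractions = c(0, 0.25, 0.5, 0.75, 1),
                             group_size = 40L, iterations = 20L,
                             threshold = 0.05, filter_fraction = 1 / 3,
                             upper_bound = 1e-9, seed = 1L) {
  assert_that(all(fractions >= 0 & fractions <= 1),
              "fractions must lie in [0, 1]")
  assert_that(!is.unsorted(fractions) && 0 %in% fractions && 1 %in% fractions,
              "fractions must be sorted ascending and include 0 and 1")
  assert_that(group_size >= 1 && iterations >= 1,
              "group_size and iterations must be positive")
  structure(list(fractions = fractions, group_size = as.integer(group_size),
                 iterations = as.integer(iterations), threshold = threshold,
                 filter_fraction = filter_fraction,
                 upper_bound = upper_bound, seed = as.integer(seed)),
            class = "titration_config")
}

experiment_methods <- function() c("raw", "percentile", "eb_adjust",
                                   "linear_remove")

# Apply one data treatment to the three sample pools. For "percentile",
# each constituent study is normalized against its own control pool BEFORE
# any mixing (the method's intended use: cases and controls_a form study A,
# controls_b self-normalizes as study B). For "eb_adjust"/"linear_remove",
# the combined pools are log-transformed, corrected once with batch =
# source study, and back-transformed; iteration subsets are then drawn from
# the corrected values. "raw" leaves the data untouched.
treat_pools <- function(cases, controls_a, controls_b, method, upper_bound) {
  combined <- cbind_tables(list(cases, controls_a, controls_b))
  if (method == "raw") return(combined)
  if (method == "percentile") {
    study_a <- percentile_normalize(combined,
                                    control_ids = colnames(controls_a),
                                    case_ids = colnames(cases),
                                    study_id = "A",
                                    upper_bound = upper_bound)
    study_b <- percentile_normalize(combined,
                                    control_ids = colnames(controls_b),
                                    study_id = "B",
                                    upper_bound = upper_bound)
    return(cbind_tables(list(study_a, study_b)))
  }
  batch <- rep(c("A", "B"), c(ncol(cases) + ncol(controls_a),
                              ncol(controls_b)))
  logged <- log_transform(set_state(combined, "relative"))
  corrected <- switch(method,
                      eb_adjust = eb_batch_adjust(logged, batch),
                      linear_remove = linear_batch_remove(logged, batch))
  back_transform(corrected)
}

cbind_tables <- function(tables) {
  feats <- rownames(tables[[1]])
  for (t in tables) {
    assert_that(identical(rownames(t), feats),
                "tables must share an identical feature set")
  }
  v <- do.call(cbind, lapply(tables, ft_values))
  infos <- lapply(tables, sample_info)
  info <- if (all(!vapply(infos, is.null, logical(1))))
    do.call(rbind, infos) else NULL
  if (!is.null(info)) rownames(info) <- NULL
  structure(v, state = ft_state(tables[[1]]), sample_info = info,
            class = "feature_table")
}

check_pools <- function(cases, controls_a, controls_b, config) {
  for (t in list(cases, controls_a, controls_b)) {
    if (!is.null(t)) validate_feature_table(t)
  }
  gs <- config$group_size
  assert_that(ncol(controls_a) >= gs && ncol(controls_b) >= gs,
              "each control pool must hold at least group_size samples")
  if (!is.null(cases)) {
    assert_that(ncol(cases) >= gs,
                "the case pool must hold at least group_size samples")
  }
}

#' Control-titration experiment
#'
#' Emulates the danger of pooling control samples across batches: case and
#' control groups are subsampled to `group_size` each, and the control
#' group is gradually substituted with randomly chosen controls from a
#' *different* study along the fraction grid (at fraction `f`,
#' `round(f * group_size)` controls come from `controls_b` and the rest
#' from `controls_a`). For each iteration and fraction the data treatment
#' is applied, features are occurrence-filtered on the pre-treatment
#' abundances of the selected samples, rank-sum tests with BH adjustment
#' are run, and the number of features with `q <= threshold` is recorded.
#' With batch-shifted control pools, raw pooling shows a steep rise of
#' spurious associations with `f`, while percentile normalization stays
#' flat.
#'
#' @param cases,controls_a Case and control pools of the recipient study
#'   (shared feature set).
#' @param controls_b Control pool of the donor study.
#' @param config A [titration_config()].
#' @param method One of `"raw"`, `"percentile"`, `"eb_adjust"`,
#'   `"linear_remove"`.
#' @param normalize_after_mixing Misuse mode for `"percentile"`: normalize
#'   each iteration's cases against the already-mixed control group instead
#'   of per-study controls. Exists to demonstrate why mixing before
#'   normalizing defeats the method; default `FALSE`.
#' @return List of class `"experiment_result"` with `per_iteration` (tidy
#'   data frame: `method`, `fraction`, `iteration`, `n_significant`),
#'   `summary` (mean per fraction) and `config`.
#' @export
titration_experiment <- function(cases, controls_a, controls_b,
                                 config = titration_config(),
                                 method = experiment_methods(),
                                 normalize_after_mixing = FALSE) {
  method <- match.arg(method)
  check_pools(cases, controls_a, controls_b, config)
  raw <- cbind_tables(list(cases, controls_a, controls_b))
  gs <- config$group_size
  rows <- list()
  with_seed_or_stream(config$seed, {
    treated <- if (method == "percentile" && normalize_after_mixing) NULL
               else treat_pools(cases, controls_a, controls_b, method,
                                config$upper_bound)
    for (iter in seq_len(config$iterations)) {
      case_ids <- sample(colnames(cases), gs)
      ctrl_a_perm <- sample(colnames(controls_a), gs)
      ctrl_b_perm <- sample(colnames(controls_b), gs)
      for (f in config$fractions) {
        n_b <- round(f * gs)
        ctrl_ids <- c(ctrl_a_perm[seq_len(gs - n_b)],
                      ctrl_b_perm[seq_len(n_b)])
        keep <- abundance_filter(raw, ctrl_ids, case_ids,
                                 fraction = config$filter_fraction)
        n_sig <- 0L
        if (length(keep)) {
          tab <- if (is.null(treated)) {
            percentile_normalize(raw, control_ids = ctrl_ids,
                                 case_ids = case_ids,
                                 upper_bound = config$upper_bound)
          } else treated
          res <- test_features(tab[keep, c(case_ids, ctrl_ids)],
                               case_ids, ctrl_ids)
          n_sig <- sum(res$q <= config$threshold)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(method = method, fraction = f, iteration = iter,
                     n_significant = n_sig, stringsAsFactors = FALSE)
      }
    }
  })
  per_iteration <- do.call(rbind, rows)
  summary <- stats::aggregate(n_significant ~ method + fraction,
                              data = per_iteration, FUN = mean)
  names(summary)[names(summary) == "n_significant"] <- "mean_significant"
  structure(list(per_iteration = per_iteration, summary = summary,
                 config = config),
            class = "experiment_result")
}

#' Null false-positive experiment
#'
#' Compares two *control* pools from different batches as if one were a
#' case group: per iteration, `group_size` artificial controls are drawn
#' from pool A and `group_size` artificial cases from pool B, the data
#' treatment is applied, features are occurrence-filtered, and the fraction
#' of rank-sum `p <= threshold` among tested features is recorded. Since no
#' biological difference exists, a calibrated analysis should sit near the
#' threshold; raw pooling across batches inflates the fraction drastically.
#'
#' @param controls_a,controls_b Control pools of the two studies (shared
#'   feature set).
#' @inheritParams titration_experiment
#' @return List of class `"experiment_result"` with `per_iteration`
#'   (`method`, `iteration`, `fraction_significant`), `summary` (the mean
#'   fraction) and `config`.
#' @export
null_fp_experiment <- function(controls_a, controls_b,
                               config = titration_config(),
                               method = experiment_methods()) {
  method <- match.arg(method)
  check_pools(NULL, controls_a, controls_b, config)
  raw <- cbind_tables(list(controls_a, controls_b))
  gs <- config$group_size
  rows <- list()
  with_seed_or_stream(config$seed, {
    treated <- treat_null_pools(controls_a, controls_b, method,
                                config$upper_bound)
    for (iter in seq_len(config$iterations)) {
      ctrl_ids <- sample(colnames(controls_a), gs)
      case_ids <- sample(colnames(controls_b), gs)
      keep <- abundance_filter(raw, ctrl_ids, case_ids,
                               fraction = config$filter_fraction)
      frac <- NA_real_
      if (length(keep)) {
        res <- test_features(treated[keep, c(case_ids, ctrl_ids)],
                             case_ids, ctrl_ids)
        frac <- mean(res$p <= config$threshold)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, iteration = iter,
                   fraction_significant = frac, stringsAsFactors = FALSE)
    }
  })
  per_iteration <- do.call(rbind, rows)
  summary <- data.frame(method = method,
                        mean_fraction = mean(per_iteration$fraction_significant))
  structure(list(per_iteration = per_iteration, summary = summary,
                 config = config),
            class = "experiment_result")
}

treat_null_pools <- function(controls_a, controls_b, method, upper_bound) {
  combined <- cbind_tables(list(controls_a, controls_b))
  if (method == "raw") return(combined)
  if (method == "percentile") {
    a <- percentile_normalize(combined, control_ids = colnames(controls_a),
                              study_id = "A", upper_bound = upper_bound)
    b <- percentile_normalize(combined, control_ids = colnames(controls_b),
                              study_id = "B", upper_bound = upper_bound)
    return(cbind_tables(list(a, b)))
  }
  batch <- rep(c("A", "B"), c(ncol(controls_a), ncol(controls_b)))
  logged <- log_transform(set_state(combined, "relative"))
  corrected <- switch(method,
                      eb_adjust = eb_batch_adjust(logged, batch),
                      linear_remove = linear_batch_remove(logged, batch))
  back_transform(corrected)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("in-silico experiment result\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cross-study meta-analysis workflow
#'
#' Runs the full case-control meta-analysis for one analysis method and
#' summarizes it the way cross-study comparisons are usually tabulated:
#' the number of features significant (`q <= threshold`) in the pooled
#' (or combined) analysis, alongside the union (`U`), intersection (`I`)
#' and significant-in-at-least-two-studies (`2N`) counts of the
#' within-study results.
#'
#' Within-study tests are always computed on the raw relative abundances
#' (occurrence-filtered per study). The pooled analysis depends on
#' `method`: `"percentile"` normalizes each study against its own controls,
#' pools with [pool_studies()] and tests pooled cases vs pooled controls
#' (the self-normalized control percentiles serve as the pooled control
#' sample); `"eb_adjust"`/`"linear_remove"` correct the combined
#' log-transformed table with batch = study and test the back-transformed
#' values; `"fisher"`/`"stouffer"` combine the within-study p-values (after
#' [opposing_direction_screen()]), with Stouffer weights
#' `sqrt(n_case + n_control)` per study, and apply BH across features.
#'
#' @param tables Named list (study ID -> `feature_table`, state
#'   `"relative"`) of two or more studies.
#' @param metadata Data frame (`sample_id`, `study_id`, `group`) covering
#'   every sample; every study must contain both groups.
#' @param method One of `"percentile"`, `"fisher"`, `"stouffer"`,
#'   `"eb_adjust"`, `"linear_remove"`.
#' @param filter_fraction Occurrence filter fraction (default 1/3), applied
#'   within each study for within-study tests and on the pooled groups for
#'   pooled tests.
#' @param threshold Significance threshold on q (default 0.05).
#' @param upper_bound,seed Zero-replacement policy for the percentile
#'   method.
#' @param direction_rule Rule of [opposing_direction_screen()] for the
#'   combination methods.
#' @param absent How [pool_studies()] fills features unobserved in a study.
#' @param p_floor Clamp applied to within-study p-values before
#'   Fisher/Stouffer combination, which cannot accept 0 or 1 (default
#'   `1e-15`).
#' @return List of class `"meta_analysis_result"`: `summary` (one-row data
#'   frame with `method`, `pooled_significant`, `union`, `intersection`,
#'   `two_plus`), `pooled` (per-feature pooled/combined results),
#'   `within_study` (stacked per-study results) and `excluded` (features
#'   removed by the direction screen; combination methods only).
#' @export
meta_analysis_pipeline <- function(tables, metadata,
                                   method = c("percentile", "fisher",
                                              "stouffer", "eb_adjust",
                                              "linear_remove"),
                                   filter_fraction = 1 / 3, threshold = 0.05,
                                   upper_bound = 1e-9, seed = NULL,
                                   direction_rule = "q",
                                   absent = "exclude", p_floor = 1e-15) {
  method <- match.arg(method)
  assert_that(is.list(tables) && length(tables) >= 2,
              "meta-analysis requires at least two studies")
  assert_that(!is.null(names(tables)) && all(nzchar(names(tables))),
              "tables must be named by study id")
  studies <- names(tables)
  md_by_study <- lapply(studies, function(s) {
    md <- metadata[metadata$study_id == s, , drop = FALSE]
    missing <- setdiff(colnames(tables[[s]]), md$sample_id)
    assert_that(length(missing) == 0,
                "study ", s, " has samples without metadata: ",
                oxford(missing))
    for (grp in c("case", "control")) {
      assert_that(any(md$group == grp),
                  "study ", s, " has no ", grp, " samples; case and control",
                  " groups must be consistently defined across studies")
    }
    md
  })
  names(md_by_study) <- studies

  with_seed_or_stream(seed, {
    within <- lapply(studies, function(s) {
      md <- md_by_study[[s]]
      tab <- tables[[s]]
      case_ids <- intersect(colnames(tab), md$sample_id[md$group == "case"])
      ctrl_ids <- intersect(colnames(tab), md$sample_id[md$group == "control"])
      keep <- abundance_filter(tab, ctrl_ids, case_ids,
                               fraction = filter_fraction)
      res <- test_features(tab[keep, ], case_ids, ctrl_ids)
      res$study_id <- s
      res
    })
    names(within) <- studies
    within_all <- do.call(rbind, within)
    sig_sets <- lapply(within, function(r) r$feature_id[r$q <= threshold])
    sig_counts <- table(unlist(sig_sets))
    summary_within <- list(
      union = length(unique(unlist(sig_sets))),
      intersection = sum(sig_counts == length(studies)),
      two_plus = sum(sig_counts >= 2))

    excluded <- character(0)
    if (method %in% c("fisher", "stouffer")) {
      excluded <- opposing_direction_screen(within_all,
                                            rule = direction_rule,
                                            threshold = threshold)
      pooled <- combine_study_pvalues(within, method, excluded, p_floor)
    } else if (method == "percentile") {
      normalized <- lapply(studies, function(s) {
        md <- md_by_study[[s]]
        tab <- tables[[s]]
        percentile_normalize(
          tab,
          control_ids = intersect(colnames(tab),
                                  md$sample_id[md$group == "control"]),
          case_ids = intersect(colnames(tab),
                               md$sample_id[md$group == "case"]),
          study_id = s, upper_bound = upper_bound)
      })
      pooled_tab <- pool_studies(normalized, absent = absent)
      pooled <- pooled_group_test(pooled_tab, tables, md_by_study,
                                  filter_fraction)
    } else {
      pooled_tab <- corrected_pooled_table(tables, md_by_study, method)
      pooled <- pooled_group_test(pooled_tab, tables, md_by_study,
                                  filter_fraction)
    }
  })
  pooled_sig <- sum(pooled$q <= threshold, na.rm = TRUE)
  summary <- data.frame(method = method, pooled_significant = pooled_sig,
                        union = summary_within$union,
                        intersection = summary_within$intersection,
                        two_plus = summary_within$two_plus,
                        stringsAsFactors = FALSE)
  structure(list(summary = summary, pooled = pooled,
                 within_study = within_all, excluded = excluded),
            class = "meta_analysis_result")
}

# pooled rank-sum test of all case vs all control columns; the occurrence
# filter is evaluated on the pooled pre-treatment abundances
pooled_group_test <- function(pooled_tab, tables, md_by_study,
                              filter_fraction) {
  si <- sample_info(pooled_tab)
  case_ids <- si$sample_id[si$group == "case"]
  ctrl_ids <- si$sample_id[si$group == "control"]
  raw_union <- union_raw_table(tables)
  keep <- abundance_filter(raw_union, intersect(ctrl_ids, colnames(raw_union)),
                           intersect(case_ids, colnames(raw_union)),
                           fraction = filter_fraction)
  keep <- intersect(rownames(pooled_tab), keep)
  res <- test_features(pooled_tab[keep, ], case_ids, ctrl_ids)
  res$method <- "pooled"
  res
}

# union-of-features raw table across studies (absent features as zero, i.e.
# never observed), used only for occurrence filtering of pooled tests
union_raw_table <- function(tables) {
  features <- unique(unlist(lapply(tables, rownames)))
  samples <- unlist(lapply(tables, colnames))
  v <- matrix(0, nrow = length(features), ncol = length(samples),
              dimnames = list(features, samples))
  for (t in tables) v[rownames(t), colnames(t)] <- ft_values(t)
  structure(v, state = "relative", sample_info = NULL,
            class = "feature_table")
}

corrected_pooled_table <- function(tables, md_by_study, method) {
  raw_union <- union_raw_table(tables)
  batch <- unlist(lapply(names(tables), function(s)
    rep(s, ncol(tables[[s]]))))
  logged <- log_transform(raw_union)
  corrected <- switch(method,
                      eb_adjust = eb_batch_adjust(logged, batch),
                      linear_remove = linear_batch_remove(logged, batch))
  out <- back_transform(corrected)
  info <- do.call(rbind, md_by_study)
  rownames(info) <- NULL
  attr(out, "sample_info") <- check_sample_info(info, colnames(out))
  out
}

combine_study_pvalues <- function(within, method, excluded, p_floor) {
  all_feat <- unique(unlist(lapply(within, function(r) r$feature_id)))
  rows <- lapply(all_feat, function(f) {
    recs <- do.call(rbind, lapply(within, function(r)
      r[r$feature_id == f, , drop = FALSE]))
    if (f %in% excluded) {
      return(data.frame(feature_id = f, n_studies = nrow(recs),
                        statistic = NA_real_, p = NA_real_,
                        excluded = TRUE,
                        reason = "significant responses in opposing directions",
                        stringsAsFactors = FALSE))
    }
    p <- pmin(pmax(recs$p, p_floor), 1 - p_floor)
    comb <- if (method == "fisher") {
      fisher_combine(p)
    } else {
      stouffer_combine(p, weights = sqrt(recs$n_case + recs$n_control))
    }
    stat <- if (method == "fisher") -2 * sum(log(p))
            else stats::qnorm(1 - comb)
    data.frame(feature_id = f, n_studies = nrow(recs), statistic = stat,
               p = comb, excluded = FALSE, reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !out$excluded
  out$q[tested] <- bh_fdr(pmin(pmax(out$p[tested], p_floor), 1))
  out$method <- method
  out
}

#' @export
print.meta_analysis_result <- function(x, ...) {
  cat("cross-study meta-analysis\n")
  print(x$summary, row.names = FALSE)
  if (length(x$excluded)) {
    cat("excluded by direction screen: ", oxford(x$excluded), "\n")
  }
  invisible(x)
}
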