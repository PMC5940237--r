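#' Lognormal group specification
#'
#' Describes one group (cases or controls of one feature in one study) as
#' draws `exp(Normal(mu, sigma))`; `sigma = 0` gives the constant
#' `exp(mu)`.
#'
#' @param mu Log-scale location.
#' @param sigma Log-scale standard deviation, `>= 0`.
#' @param n_samples Number of samples, `> 0`.
#' @return A list of class `"lognormal_group_spec"`.
#' @export
lognormal_group_spec <- function(mu, sigma, n_samples) {
  assert_that(is.numeric(sigma) && sigma >= 0, "sigma must be >= 0")
  assert_that(is.numeric(n_samples) && n_samples >= 1,
              "n_samples must be a positive integer")
  structure(list(mu = mu, sigma = sigma, n_samples = as.integer(n_samples)),
            class = "lognormal_group_spec")
}

#' Synthetic study specification
#'
#' One study's generative model: a list of features, each with a control
#' and a case [lognormal_group_spec()], plus a zero-inflation probability
#' applied after the lognormal draw (a value is set to exact zero with this
#' probability, emulating under-sampled sparse taxa).
#'
#' @param study_id Study label.
#' @param features Named list; each element is `list(control = <spec>,
#'   case = <spec>)`. All features of a study must agree on group sample
#'   sizes.
#' @param zero_inflation Probability in \[0, 1\] of zeroing a value.
#' @return A list of class `"synthetic_study_spec"`.
#' @export
synthetic_study_spec <- function(study_id, features, zero_inflation = 0) {
  assert_that(is.list(features) && length(features) >= 1,
              "at least one feature is required")
  assert_that(zero_inflation >= 0 && zero_inflation <= 1,
              "zero_inflation must lie in [0, 1]")
  n_ctrl <- unique(vapply(features, function(f) f$control$n_samples, 1L))
  n_case <- unique(vapply(features, function(f) f$case$n_samples, 1L))
  assert_that(length(n_ctrl) == 1 && length(n_case) == 1,
              "all features must share the study's group sample sizes")
  if (is.null(names(features)))
    names(features) <- paste0("feature_", seq_along(features))
  structure(list(study_id = study_id, features = features,
                 zero_inflation = zero_inflation,
                 n_control = n_ctrl, n_case = n_case),
            class = "synthetic_study_spec")
}

#' Two-study lognormal parameters of the conceptual demonstration
#'
#' The single-feature, two-study configuration used to illustrate
#' percentile normalization: 100 control and 100 case samples per study,
#' with study 1 controls ~ lognormal(mu = 0.1, sigma = 0.7) and cases ~
#' lognormal(0.8, 0.5), and study 2 controls ~ lognormal(1.5, 0.2) and
#' cases ~ lognormal(1.75, 0.13) — two studies whose raw distributions are
#' on visibly different scales but whose case/control contrast points the
#' same way.
#'
#' @param n_samples Samples per group (default 100).
#' @return List of two [synthetic_study_spec()] objects.
#' @export
demo_two_study_specs <- function(n_samples = 100L) {
  list(
    synthetic_study_spec("study1", list(
      otu1 = list(control = lognormal_group_spec(0.1, 0.7, n_samples),
                  case = lognormal_group_spec(0.8, 0.5, n_samples)))),
    synthetic_study_spec("study2", list(
      otu1 = list(control = lognormal_group_spec(1.5, 0.2, n_samples),
                  case = lognormal_group_spec(1.75, 0.13, n_samples)))))
}

#' Simulate feature tables from study specifications
#'
#' Draws per-study case/control matrices of lognormal values (with optional
#' zero inflation) according to a list of [synthetic_study_spec()]s. Values
#' are interpreted on the relative-abundance scale; they are not closed to
#' unit column sums, which keeps the specified per-study location/scale
#' (batch) structure intact. Deterministic under `seed`.
#'
#' @param specs List of [synthetic_study_spec()] objects with distinct
#'   study IDs.
#' @param seed Integer seed, or `NULL` to draw from the ambient stream.
#' @return List with elements `tables` (named list of `feature_table`s with
#'   state `"relative"`, one per study, controls first) and `metadata` (one
#'   data frame of `sample_id`, `study_id`, `group` covering all studies).
#' @export
simulate_two_study_dataset <- function(specs, seed = NULL) {
  assert_that(is.list(specs) && length(specs) >= 1,
              "at least one study spec is required")
  ids <- vapply(specs, function(s) s$study_id, character(1))
  assert_that(!anyDuplicated(ids), "study ids must be distinct")
  with_seed_or_stream(seed, {
    tables <- lapply(specs, simulate_one_study)
  })
  names(tables) <- ids
  metadata <- do.call(rbind, lapply(tables, sample_info))
  rownames(metadata) <- NULL
  list(tables = tables, metadata = metadata)
}

simulate_one_study <- function(spec) {
  n_ctrl <- spec$n_control
  n_case <- spec$n_case
  G <- length(spec$features)
  v <- matrix(NA_real_, nrow = G, ncol = n_ctrl + n_case,
              dimnames = list(names(spec$features),
                              c(sprintf("%s_ctrl_%03d", spec$study_id,
                                        seq_len(n_ctrl)),
                                sprintf("%s_case_%03d", spec$study_id,
                                        seq_len(n_case)))))
  for (g in seq_len(G)) {
    f <- spec$features[[g]]
    v[g, ] <- exp(stats::rnorm(n_ctrl + n_case,
                               mean = c(rep(f$control$mu, n_ctrl),
                                        rep(f$case$mu, n_case)),
                               sd = c(rep(f$control$sigma, n_ctrl),
                                      rep(f$case$sigma, n_case))))
  }
  if (spec$zero_inflation > 0) {
    drop <- stats::runif(length(v)) < spec$zero_inflation
    v[drop] <- 0
  }
  info <- data.frame(sample_id = colnames(v), study_id = spec$study_id,
                     group = rep(c("control", "case"), c(n_ctrl, n_case)),
                     stringsAsFactors = FALSE)
  feature_table(v, state = "relative", sample_info = info)
}

#' Simulate multi-feature case-control studies with batch structure
#'
#' Builds a realistic multi-study benchmark: each feature `g` has a
#' baseline log abundance `mu_g ~ Normal(0, feature_mu_sd)` and log-scale
#' spread `base_sigma`, shared across studies. Study `s` applies a batch
#' effect shared across features — a location shift `batch_mu_shift[s]`
#' and a scale factor `batch_sigma_scale[s]` — and a fraction
#' `effect_fraction` of features carries a consistent disease signal: case
#' samples of affected features are shifted by `effect_size` on the log
#' scale in every study. Zero inflation is applied after the draw. Sample
#' sizes may differ per study (recycled if scalar).
#'
#' @param n_features Number of features.
#' @param n_control,n_case Per-study group sizes (vectors of length
#'   `n_studies`, or scalars).
#' @param batch_mu_shift,batch_sigma_scale Per-study batch location shift
#'   and scale factor (length `n_studies`).
#' @param feature_mu_sd SD of the per-feature baseline log abundance.
#' @param base_sigma Baseline log-scale SD of every feature.
#' @param effect_fraction Fraction of features carrying the disease signal.
#' @param effect_size Log-scale case shift of affected features.
#' @param zero_inflation Probability of zeroing any value after the draw.
#' @param seed Integer seed, or `NULL`.
#' @return As [simulate_two_study_dataset()], plus an `effect_features`
#'   character vector naming the planted features.
#' @export
simulate_case_control_studies <- function(n_features = 2000L,
                                          n_control = 50L, n_case = 50L,
                                          batch_mu_shift = c(0, 1.5),
                                          batch_sigma_scale = c(1, 2),
                                          feature_mu_sd = 1,
                                          base_sigma = 0.7,
                                          effect_fraction = 0,
                                          effect_size = 1,
                                          zero_inflation = 0.25,
                                          seed = NULL) {
  n_studies <- length(batch_mu_shift)
  assert_that(length(batch_sigma_scale) == n_studies,
              "batch_mu_shift and batch_sigma_scale must have equal length")
  n_control <- rep_len(n_control, n_studies)
  n_case <- rep_len(n_case, n_studies)
  with_seed_or_stream(seed, {
    mu_g <- stats::rnorm(n_features, 0, feature_mu_sd)
    n_effect <- round(effect_fraction * n_features)
    effect_idx <- if (n_effect > 0) sample.int(n_features, n_effect)
                  else integer(0)
    feature_ids <- sprintf("feature_%04d", seq_len(n_features))
    specs <- lapply(seq_len(n_studies), function(s) {
      features <- lapply(seq_len(n_features), function(g) {
        shift <- if (g %in% effect_idx) effect_size else 0
        mu <- mu_g[g] + batch_mu_shift[s]
        sigma <- base_sigma * batch_sigma_scale[s]
        list(control = lognormal_group_spec(mu, sigma, n_control[s]),
             case = lognormal_group_spec(mu + shift, sigma, n_case[s]))
      })
      names(features) <- feature_ids
      synthetic_study_spec(paste0("study", s), features,
                           zero_inflation = zero_inflation)
    })
    out <- simulate_two_study_dataset(specs, seed = NULL)
  })
  out$effect_features <- feature_ids[sort(effect_idx)]
  out
}
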