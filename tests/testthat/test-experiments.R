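# shared pools: study A is an internal null (cases drawn from the control
# distribution), study B contributes batch-shifted controls
make_pools <- function(n_features = 80, seed = 61) {
  sim <- simulate_case_control_studies(
    n_features = n_features, n_control = c(30, 30), n_case = c(30, 2),
    batch_mu_shift = c(0, 1.5), batch_sigma_scale = c(1, 2),
    effect_fraction = 0, zero_inflation = 0.25, seed = seed)
  list(cases = sim$tables$study1[, ids_of(sim$metadata, "study1", "case")],
       controls_a = sim$tables$study1[, ids_of(sim$metadata, "study1",
                                               "control")],
       controls_b = sim$tables$study2[, ids_of(sim$metadata, "study2",
                                               "control")])
}

test_that("experiment configs validate the fraction grid", {
  expect_error(titration_config(fractions = c(0, 0.5)), "include 0 and 1")
  expect_error(titration_config(fractions = c(0, 1.2)), "\\[0, 1\\]")
  expect_error(titration_config(group_size = 0), "positive")
})

test_that("titration at f = 0 reduces to a within-study subsampled analysis", {
  pools <- make_pools()
  cfg <- titration_config(fractions = c(0, 1), group_size = 10,
                          iterations = 4, seed = 3)
  res <- titration_experiment(pools$cases, pools$controls_a,
                              pools$controls_b, config = cfg, method = "raw")
  at0 <- res$per_iteration[res$per_iteration$fraction == 0, ]
  # study A is a null study: subsampled within-study tests find ~nothing
  expect_lte(mean(at0$n_significant), 1)
  expect_equal(nrow(res$per_iteration), 8)
  expect_equal(nrow(res$summary), 2)
})

test_that("experiments are deterministic under their seed", {
  pools <- make_pools(n_features = 40)
  cfg <- titration_config(fractions = c(0, 1), group_size = 10,
                          iterations = 2, seed = 9)
  for (m in c("raw", "percentile")) {
    a <- titration_experiment(pools$cases, pools$controls_a,
                              pools$controls_b, config = cfg, method = m)
    b <- titration_experiment(pools$cases, pools$controls_a,
                              pools$controls_b, config = cfg, method = m)
    expect_identical(a$per_iteration, b$per_iteration)
  }
  a <- null_fp_experiment(pools$controls_a, pools$controls_b,
                          config = cfg, method = "percentile")
  b <- null_fp_experiment(pools$controls_a, pools$controls_b,
                          config = cfg, method = "percentile")
  expect_identical(a$per_iteration, b$per_iteration)
})

test_that("pool sizes are checked against the group size", {
  pools <- make_pools(n_features = 20)
  cfg <- titration_config(group_size = 200, iterations = 1, seed = 1)
  expect_error(titration_experiment(pools$cases, pools$controls_a,
                                    pools$controls_b, config = cfg,
                                    method = "raw"), "group_size")
  expect_error(null_fp_experiment(pools$controls_a, pools$controls_b,
                                  config = cfg, method = "raw"),
               "group_size")
})

test_that("null comparison of exchangeable pools rejects at about the level", {
  # both pools drawn from one study's control distribution: exchangeable null
  sim <- simulate_case_control_studies(
    n_features = 400, n_control = c(60, 60), n_case = c(2, 2),
    batch_mu_shift = c(0, 0), batch_sigma_scale = c(1, 1),
    effect_fraction = 0, zero_inflation = 0.25, seed = 71)
  cfg <- titration_config(group_size = 20, iterations = 5, seed = 8)
  for (m in c("raw", "percentile")) {
    res <- null_fp_experiment(sim$tables$study1[, ids_of(sim$metadata,
                                                         "study1", "control")],
                              sim$tables$study2[, ids_of(sim$metadata,
                                                         "study2", "control")],
                              config = cfg, method = m)
    # binomial-scale tolerance around 0.05 over ~400 x 5 feature tests
    expect_lt(res$summary$mean_fraction, 0.09)
  }
})

test_that("batch-shifted pools inflate raw comparisons but not percentile", {
  pools <- make_pools(n_features = 150, seed = 62)
  cfg <- titration_config(group_size = 25, iterations = 5, seed = 12)
  raw <- null_fp_experiment(pools$controls_a, pools$controls_b,
                            config = cfg, method = "raw")
  perc <- null_fp_experiment(pools$controls_a, pools$controls_b,
                             config = cfg, method = "percentile")
  expect_gt(raw$summary$mean_fraction, 0.3)
  expect_lt(perc$summary$mean_fraction, raw$summary$mean_fraction)
  expect_lt(perc$summary$mean_fraction, 0.1)
})

test_that("the meta-analysis pipeline recovers a planted effect", {
  sim <- simulate_case_control_studies(
    n_features = 60, n_control = c(40, 40), n_case = c(40, 40),
    batch_mu_shift = c(0, 1.5), batch_sigma_scale = c(1, 1.5),
    effect_fraction = 0.1, effect_size = 2, zero_inflation = 0.2, seed = 81)
  res <- meta_analysis_pipeline(sim$tables, sim$metadata,
                                method = "percentile", seed = 5)
  sig <- res$pooled$feature_id[res$pooled$q <= 0.05]
  expect_gte(length(intersect(sig, sim$effect_features)), 5)
  # pooled detections should not be dominated by null features
  expect_lt(length(setdiff(sig, sim$effect_features)), 6)
  expect_named(res$summary, c("method", "pooled_significant", "union",
                              "intersection", "two_plus"))
  expect_gte(res$summary$union, res$summary$two_plus)
  expect_gte(res$summary$two_plus, res$summary$intersection)
})

test_that("combination methods run the direction screen before combining", {
  sim <- simulate_case_control_studies(
    n_features = 60, n_control = c(40, 40), n_case = c(40, 40),
    batch_mu_shift = c(0, 1.5), batch_sigma_scale = c(1, 1.5),
    effect_fraction = 0.1, effect_size = 2, zero_inflation = 0.2, seed = 81)
  for (m in c("fisher", "stouffer")) {
    res <- meta_analysis_pipeline(sim$tables, sim$metadata, method = m,
                                  seed = 5)
    sig <- res$pooled$feature_id[!is.na(res$pooled$q) & res$pooled$q <= 0.05]
    expect_gte(length(intersect(sig, sim$effect_features)), 3)
    expect_true(all(is.na(res$pooled$p[res$pooled$excluded])))
  }
})

test_that("model-based corrections also surface the pooled signal", {
  sim <- simulate_case_control_studies(
    n_features = 60, n_control = c(40, 40), n_case = c(40, 40),
    batch_mu_shift = c(0, 1.5), batch_sigma_scale = c(1, 1.5),
    effect_fraction = 0.1, effect_size = 2, zero_inflation = 0.2, seed = 81)
  for (m in c("eb_adjust", "linear_remove")) {
    res <- meta_analysis_pipeline(sim$tables, sim$metadata, method = m,
                                  seed = 5)
    sig <- res$pooled$feature_id[res$pooled$q <= 0.05]
    expect_gte(length(intersect(sig, sim$effect_features)), 3)
  }
})

test_that("the pipeline rejects degenerate designs", {
  sim <- small_null_pair(n_features = 20, seed = 82)
  expect_error(meta_analysis_pipeline(sim$tables[1], sim$metadata,
                                      method = "percentile"),
               "at least two studies")
  md <- sim$metadata
  md$group[md$study_id == "study2"] <- "control"
  expect_error(meta_analysis_pipeline(sim$tables, md, method = "percentile"),
               "consistently defined")
})

test_that("pooled percentile analysis under a pure null stays calibrated", {
  sim <- small_null_pair(n_features = 200, seed = 83)
  res <- meta_analysis_pipeline(sim$tables, sim$metadata,
                                method = "percentile", seed = 2)
  expect_lte(sum(res$pooled$q <= 0.05), 2)
})
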