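# shared fixture builders; everything is generated in code at test time

toy_table <- function(values, state = "relative",
                      features = paste0("otu", seq_len(nrow(values))),
                      samples = paste0("s", seq_len(ncol(values))),
                      sample_info = NULL) {
  dimnames(values) <- list(features, samples)
  feature_table(values, state = state, sample_info = sample_info)
}

random_relative_table <- function(n_features = 8, n_samples = 6, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(rexp(n_features * n_samples), n_features, n_samples)
    v <- sweep(v, 2, colSums(v), "/")
  })
  toy_table(v, state = "relative")
}

# one balanced two-study null pair with strong batch structure, small sizes
small_null_pair <- function(n_features = 60, seed = 1) {
  simulate_case_control_studies(
    n_features = n_features, n_control = 20, n_case = 20,
    batch_mu_shift = c(0, 1.5), batch_sigma_scale = c(1, 2),
    effect_fraction = 0, zero_inflation = 0.25, seed = seed)
}

ids_of <- function(metadata, study, group) {
  metadata$sample_id[metadata$study_id == study & metadata$group == group]
}

normalize_studies <- function(sim, seed = 1) {
  lapply(names(sim$tables), function(s) {
    percentile_normalize(sim$tables[[s]],
                         control_ids = ids_of(sim$metadata, s, "control"),
                         case_ids = ids_of(sim$metadata, s, "case"),
                         study_id = s, seed = seed)
  })
}

# column-bind the two study tables of a simulated pair (shared feature set)
cbind_raw_pair <- function(sim) {
  v <- do.call(cbind, lapply(sim$tables, as.matrix))
  feature_table(v, state = "relative", sample_info = sim$metadata)
}

# brute-force oracle for the mean-of-strict-and-weak percentile
percentile_oracle <- function(reference, score) {
  100 * (sum(reference < score) + sum(reference <= score)) /
    (2 * length(reference))
}
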