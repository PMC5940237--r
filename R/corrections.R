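#' Log-transform with a half-minimum pseudo abundance
#'
#' The model-based batch corrections operate in log space. Zeros are first
#' replaced by half the smallest positive value of the whole matrix (a
#' single global pseudo relative abundance), then the natural logarithm is
#' applied elementwise. For a zero-free table, [back_transform()] inverts
#' this exactly.
#'
#' @param x A `feature_table` with state `"relative"` (or `"unknown"`),
#'   non-negative with at least one positive entry.
#' @return A `feature_table` with state `"log"`.
#' @export
log_transform <- function(x) {
  validate_feature_table(x)
  assert_that(ft_state(x) %in% c("relative", "unknown"),
              "log_transform expects a relative-abundance table, got state ",
              ft_state(x))
  v <- ft_values(x)
  assert_that(all(v >= 0), "negative values are not allowed")
  pos <- v[v > 0]
  assert_that(length(pos) > 0, "cannot log-transform an all-zero matrix")
  v[v == 0] <- min(pos) / 2
  structure(log(v), state = "log", sample_info = sample_info(x),
            class = "feature_table")
}

#' Exponential back-transform from log space
#'
#' Inverts [log_transform()] elementwise. Columns are *not* re-normalized
#' to unit sums: downstream rank-based tests are scale-free, so the
#' corrected values are used on the relative-abundance scale as they come.
#'
#' @param x A `feature_table` with state `"log"`.
#' @return A `feature_table` with state `"relative"` and strictly positive
#'   entries.
#' @export
back_transform <- function(x) {
  validate_feature_table(x)
  assert_that(ft_state(x) == "log",
              "back_transform expects state 'log', got ", ft_state(x))
  structure(exp(ft_values(x)), state = "relative",
            sample_info = sample_info(x), class = "feature_table")
}

resolve_batch <- function(x, batch) {
  if (!is.null(names(batch))) {
    missing <- setdiff(colnames(x), names(batch))
    assert_that(length(missing) == 0,
                "samples without a batch label: ", oxford(missing))
    batch <- batch[colnames(x)]
  }
  assert_that(length(batch) == ncol(x),
              "batch must have one label per sample")
  factor(as.character(batch))
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric empirical-Bayes adjustment of additive (location) and
#' multiplicative (scale) batch effects in log-transformed data, the
#' approach popularized for microarray batch correction. Per feature, the
#' grand mean and batch means are fit by least squares and residuals are
#' standardized by the pooled variance; per batch, feature-wise additive
#' and multiplicative effects are estimated and shrunk toward a normal
#' (location) and inverse-gamma (scale) prior with method-of-moments
#' hyperparameters, iterating the standard fixed point to convergence; the
#' shrunken effects are then removed and the grand mean and scale restored.
#' Only the batch variable is modelled — no biological covariates — which
#' matches default whole-dataset usage.
#'
#' Features with zero pooled variance cannot be standardized and are passed
#' through unadjusted with a warning. With a single feature the prior
#' collapses onto that feature's own estimates, so no shrinkage occurs.
#'
#' @param x A `feature_table` with state `"log"`.
#' @param batch Batch label per sample: a character/factor vector either
#'   named by sample ID or aligned with the columns of `x`. At least two
#'   batches, each with at least two samples.
#' @param tol Relative-change convergence tolerance of the fixed-point
#'   iteration (default `1e-6`).
#' @param max_iter Iteration cap (default 500).
#' @return A `feature_table` with state `"log"`, adjusted in place.
#' @seealso [linear_batch_remove()] for the non-shrunken linear analogue.
#' @export
eb_batch_adjust <- function(x, batch, tol = 1e-6, max_iter = 500L) {
  validate_feature_table(x)
  assert_that(ft_state(x) == "log",
              "eb_batch_adjust expects state 'log', got ", ft_state(x))
  batch <- resolve_batch(x, batch)
  nb <- table(batch)
  assert_that(nlevels(batch) >= 2, "at least two batches are required")
  small <- names(nb)[nb < 2]
  assert_that(length(small) == 0,
              "batches with fewer than 2 samples: ", oxford(small))
  v <- ft_values(x)
  G <- nrow(v); N <- ncol(v)
  lev <- levels(batch)
  batch_means <- vapply(lev, function(b)
    rowMeans(v[, batch == b, drop = FALSE]), numeric(G))
  if (G == 1) batch_means <- matrix(batch_means, nrow = 1,
                                    dimnames = list(rownames(v), lev))
  w <- as.numeric(nb[lev]) / N
  grand <- as.numeric(batch_means %*% w)
  resid <- v - batch_means[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums(resid^2) / N
  flat <- var_pooled <= 0
  if (any(flat)) {
    warning(sum(flat), " feature(s) with zero pooled variance passed through",
            " unadjusted: ", oxford(rownames(v)[flat]))
  }
  use <- which(!flat)
  out <- v
  if (length(use)) {
    z <- sweep(sweep(v[use, , drop = FALSE], 1, grand[use], "-"),
               1, sqrt(var_pooled[use]), "/")
    for (b in lev) {
      zb <- z[, batch == b, drop = FALSE]
      n <- ncol(zb)
      g_hat <- rowMeans(zb)
      d_hat <- apply(zb, 1, stats::var)
      est <- eb_shrink(zb, g_hat, d_hat, n, tol, max_iter)
      z[, batch == b] <- (zb - est$gamma) / sqrt(est$delta)
    }
    out[use, ] <- sweep(sweep(z, 1, sqrt(var_pooled[use]), "*"),
                        1, grand[use], "+")
  }
  structure(out, state = "log", sample_info = sample_info(x),
            class = "feature_table")
}

# fixed-point shrinkage of per-batch additive (gamma) and multiplicative
# (delta) effects toward normal / inverse-gamma priors with
# method-of-moments hyperparameters
eb_shrink <- function(zb, g_hat, d_hat, n, tol, max_iter) {
  G <- length(g_hat)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  m <- mean(d_hat)
  s2 <- stats::var(d_hat)
  if (G < 2 || !is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) {
    # degenerate prior: shrinkage target is the feature's own estimate
    return(list(gamma = g_hat, delta = pmax(d_hat, .Machine$double.eps)))
  }
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_old <- g_hat
  d_old <- d_hat
  for (i in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((zb - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), tol),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < tol) break
  }
  list(gamma = g_old, delta = d_old)
}

#' Linear-model batch subtraction
#'
#' Per feature, fits ordinary least squares of the log abundance on batch
#' indicators (sum-to-zero contrasts plus an intercept) and subtracts the
#' fitted batch component, retaining the intercept. For a one-way batch
#' design this equalizes each feature's batch means exactly (to the
#' unweighted mean of the batch means); it is the non-shrunken linear
#' analogue of [eb_batch_adjust()] and is idempotent.
#'
#' @inheritParams eb_batch_adjust
#' @return A `feature_table` with state `"log"`, batch means equalized per
#'   feature.
#' @export
linear_batch_remove <- function(x, batch) {
  validate_feature_table(x)
  assert_that(ft_state(x) == "log",
              "linear_batch_remove expects state 'log', got ", ft_state(x))
  batch <- resolve_batch(x, batch)
  nb <- table(batch)
  assert_that(nlevels(batch) >= 2, "at least two batches are required")
  small <- names(nb)[nb < 2]
  assert_that(length(small) == 0,
              "batches with fewer than 2 samples: ", oxford(small))
  v <- ft_values(x)
  lev <- levels(batch)
  batch_means <- vapply(lev, function(b)
    rowMeans(v[, batch == b, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1) batch_means <- matrix(batch_means, nrow = 1)
  intercept <- rowMeans(batch_means)
  out <- v - batch_means[, as.integer(batch), drop = FALSE] + intercept
  structure(out, state = "log", sample_info = sample_info(x),
            class = "feature_table")
}
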