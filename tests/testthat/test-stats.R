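test_that("abundance filter implements the one-third occurrence rule", {
  # 18 samples: 6 cases, 12 controls
  v <- matrix(0, 2, 18, dimnames = list(c("kept", "dropped"),
                                        paste0("s", 1:18)))
  cases <- paste0("s", 1:6)
  controls <- paste0("s", 7:18)
  v["kept", 1:2] <- 1          # 2/6 cases -> at the boundary, kept
  v["dropped", c(1, 7:9)] <- 1 # 1/6 cases and 3/12 controls -> dropped
  ft <- toy_table(v, state = "relative", features = rownames(v),
                  samples = colnames(v))
  expect_equal(abundance_filter(ft, cases, controls), "kept")
  expect_error(abundance_filter(ft, character(0), controls), "non-empty")
})

test_that("abundance filter matches a brute-force evaluation of the rule", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      v <- matrix(rbinom(20 * 12, 1, 0.3) * runif(240), 20, 12)
      a <- sample(12, 5)
    })
    b <- setdiff(1:12, a)
    ft <- toy_table(v, state = "relative")
    expected <- rownames(ft)[vapply(seq_len(20), function(g) {
      sum(v[g, a] > 0) / length(a) >= 1 / 3 ||
        sum(v[g, b] > 0) / length(b) >= 1 / 3
    }, logical(1))]
    expect_identical(abundance_filter(ft, colnames(ft)[a], colnames(ft)[b]),
                     expected)
  }
})

test_that("rank-sum z and p match the hand-computed example", {
  res <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res["z"]), -4.5 / sqrt(5.25), tolerance = 1e-12)
  expect_equal(unname(res["p"]), 0.04953461, tolerance = 1e-6)
  res <- wilcoxon_ranksum(c(1, 4), c(2, 3))
  expect_equal(unname(res["z"]), 0)
  expect_equal(unname(res["p"]), 1)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "non-empty")
})

test_that("rank-sum p agrees with an exact permutation-moment oracle", {
  # oracle: enumerate all case/control assignments of the midranks, take the
  # exact permutation mean and variance of the rank sum, then the normal tail
  oracle <- function(x, y) {
    r <- rank(c(x, y))
    n1 <- length(x)
    sums <- apply(utils::combn(length(r), n1), 2, function(i) sum(r[i]))
    z <- (sum(r[seq_len(n1)]) - mean(sums)) /
      sqrt(mean(sums^2) - mean(sums)^2)
    2 * pnorm(-abs(z))
  }
  withr::with_seed(21, {
    for (i in 1:20) {
      x <- rnorm(sample(2:8, 1))
      y <- rnorm(sample(2:8, 1))
      expect_equal(unname(wilcoxon_ranksum(x, y)["p"]), oracle(x, y),
                   tolerance = 1e-10)
    }
  })
})

test_that("rank-sum agrees with wilcox.test's normal approximation (no ties)", {
  withr::with_seed(22, {
    x <- rnorm(15)
    y <- rnorm(12)
  })
  mine <- wilcoxon_ranksum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-12)
})

test_that("test_features is rank-invariant and flags directions", {
  sim <- small_null_pair(n_features = 30, seed = 31)
  tab <- replace_zeros(sim$tables[[1]], seed = 1)
  cases <- ids_of(sim$metadata, "study1", "case")
  controls <- ids_of(sim$metadata, "study1", "control")
  base <- test_features(tab, cases, controls)
  logged <- toy_table(log(as.matrix(tab)), state = "unknown",
                      features = rownames(tab), samples = colnames(tab))
  trans <- test_features(logged, cases, controls)
  expect_equal(trans$z, base$z)
  expect_equal(trans$p, base$p)
  expect_equal(trans$q, base$q)
  expect_true(all(base$direction[base$z > 0] == "case_enriched"))
  expect_true(all(base$direction[base$z < 0] == "control_enriched"))
})

test_that("BH adjustment matches the step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  # property vs a brute-force step-up oracle
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) q[o[i]] <- min(1, min(m * p[o[i:m]] / (i:m)))
    q
  }
  withr::with_seed(33, {
    for (i in 1:10) {
      p <- runif(sample(3:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, step_up(p), tolerance = 1e-12)
      expect_true(all(q >= p))
    }
  })
})

test_that("Fisher and Stouffer match their closed forms", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747866, tolerance = 1e-6)
  expect_equal(fisher_combine(0.3), 0.3, tolerance = 1e-12)
  expect_equal(stouffer_combine(c(0.5, 0.5)), 0.5)
  expect_equal(stouffer_combine(c(0.05, 0.05)), 0.01000463, tolerance = 1e-6)
  expect_equal(stouffer_combine(0.2, weights = 7), 0.2, tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(stouffer_combine(c(0.5, 1)), "strictly inside")
})

test_that("combination methods agree with integration oracles on a grid", {
  grid <- expand.grid(p1 = c(0.001, 0.01, 0.05, 0.2, 0.5, 0.9),
                      p2 = c(0.001, 0.01, 0.05, 0.2, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    p <- c(grid$p1[i], grid$p2[i])
    # P(P1 * P2 <= c) = c(1 - ln c) for independent uniforms
    cc <- prod(p)
    expect_equal(fisher_combine(p), cc * (1 - log(cc)), tolerance = 1e-8)
    # P(Z1 + Z2 >= s) by numerical integration over the first quantile
    s <- sum(qnorm(1 - p))
    oracle <- integrate(function(t) dnorm(t) * pnorm(s - t, lower.tail = FALSE),
                        -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(stouffer_combine(p), oracle, tolerance = 1e-8)
  }
})

test_that("the direction screen excludes significant sign conflicts", {
  res <- data.frame(
    feature_id = c("f1", "f1", "f2", "f3", "f3"),
    study_id = c("A", "B", "A", "A", "B"),
    z = c(2.5, -2.4, 3.0, 2.0, -1.9),
    p = c(0.005, 0.01, 0.001, 0.04, 0.06),
    q = c(0.01, 0.02, 0.005, 0.2, 0.3))
  # f1: significant in both, opposite signs -> excluded
  # f2: significant in one study only -> retained
  # f3: opposite signs but q > 0.05 -> retained under the default rule
  expect_identical(opposing_direction_screen(res), "f1")
  # raw-p rule: f3 still retained (p = 0.06 in study B)
  expect_identical(opposing_direction_screen(res, rule = "p"), "f1")
  # any-conflict rule also catches f3
  expect_setequal(opposing_direction_screen(res, rule = "any"),
                  c("f1", "f3"))
  expect_identical(opposing_direction_screen(res[res$q > 0.5, ]),
                   character(0))
})

test_that("Bray-Curtis matches its definition", {
  ft <- toy_table(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2), state = "relative")
  expect_equal(as.vector(bray_curtis(ft)), 0)
  ft <- toy_table(matrix(c(1, 0, 0, 1), 2, 2), state = "relative")
  expect_equal(as.vector(bray_curtis(ft)), 1)
  ft <- toy_table(matrix(c(0.5, 0.5, 1, 0), 2, 2), state = "relative")
  expect_equal(as.vector(bray_curtis(ft)), 0.5)
  # oracle on random tables: sum|u-v| / sum(u+v)
  ft <- random_relative_table(6, 5, seed = 41)
  d <- as.matrix(bray_curtis(ft))
  v <- as.matrix(ft)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], sum(abs(v[, i] - v[, j])) / sum(v[, i] + v[, j]),
                 tolerance = 1e-12)
  }
  expect_error(bray_curtis(toy_table(cbind(c(1, 1), c(0, 0)),
                                     state = "relative")), "all-zero")
})

test_that("PERMANOVA pseudo-F matches the sums-of-squares formula", {
  ft <- random_relative_table(5, 10, seed = 42)
  labels <- rep(c("a", "b"), each = 5)
  d <- bray_curtis(ft)
  res <- permanova(d, labels, n_permutations = 199, seed = 1)
  # independent oracle from squared distances
  dm <- as.matrix(d)^2
  N <- 10
  ss_total <- sum(dm[upper.tri(dm)]) / N
  ss_within <- sum(dm[1:5, 1:5][upper.tri(dm[1:5, 1:5])]) / 5 +
    sum(dm[6:10, 6:10][upper.tri(dm[6:10, 6:10])]) / 5
  ss_among <- ss_total - ss_within
  f_oracle <- (ss_among / 1) / (ss_within / (N - 2))
  expect_equal(res$pseudo_F, f_oracle, tolerance = 1e-10)
  expect_equal(res$r2, ss_among / ss_total, tolerance = 1e-10)
  # determinism under the seed
  res2 <- permanova(d, labels, n_permutations = 199, seed = 1)
  expect_identical(res$p, res2$p)
})

test_that("PERMANOVA separates well-separated clouds at the minimal p", {
  withr::with_seed(43, {
    v <- cbind(matrix(runif(40, 0, 0.1), 4, 10),
               matrix(runif(40, 10, 10.1), 4, 10))
  })
  ft <- toy_table(v, state = "relative")
  res <- permanova(bray_curtis(ft), rep(c("a", "b"), each = 10),
                   n_permutations = 99, seed = 2)
  expect_equal(res$p, 1 / 100)
  expect_error(permanova(bray_curtis(ft), rep("a", 20)), "two groups")
  expect_error(permanova(bray_curtis(ft), c(rep("a", 19), "b")),
               "fewer than 2")
})
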