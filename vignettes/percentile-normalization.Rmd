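---
title: "Percentile normalization for batch effects in case-control microbiome studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile normalization for batch effects in case-control microbiome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percnorm)
```

## The problem

Microbiome case-control studies carried out by different groups — or even by
the same group in different sequencing runs — differ systematically in ways
that have nothing to do with disease: reagent lots, extraction kits,
primers, personnel. These *batch effects* are often as large as, or larger
than, the biological contrast of interest, so directly pooling raw feature
tables (OTU or genus abundances) across studies produces large numbers of
spurious "disease-associated" taxa. Parametric corrections developed for
microarray data exist, but microbiome abundance distributions are
zero-inflated and poorly described by the Gaussian location/scale models
those corrections assume, and in practice batches are frequently confounded
with biology (e.g. control cohorts defined differently across studies).

`percnorm` implements a model-free alternative that exploits the structure
of case-control designs: every study carries its own internal control
population, and whatever batch effect distorts the cases of a study
distorts its controls equally.

## The method

For each study and each feature \(g\), let \(c_1, \dots, c_n\) be the
control values (relative abundances) and \(x\) a sample value. The
percentile of \(x\) within the control distribution, using the
mean-of-strict-and-weak convention, is

\[
\mathrm{perc}(x) \;=\; 100 \cdot
\frac{\#\{c_i < x\} + \#\{c_i \le x\}}{2n}.
\]

Control values are converted to percentiles of themselves — \(n\) distinct
controls land exactly on the uniform grid \(\{100(k - 0.5)/n\}\),
\(k = 1..n\) — and case values to percentiles of the same control
distribution. Because the transform is computed within a study, any
study-specific monotone distortion cancels: the output is invariant under
strictly increasing transforms applied jointly to a feature's case and
control values (a property the test suite checks directly). Normalized
studies live on a shared 0–100 axis and can be pooled for a single
non-parametric test per feature; we use the Wilcoxon rank-sum statistic
with midranks and the plain normal approximation (no tie or continuity
correction), followed by Benjamini–Hochberg FDR control.

**Zero replacement.** Abundance tables are full of zeros, and ranking many
tied zeros piles mass at the bottom of the control grid. Before percentile
conversion every zero is replaced by an independent draw from
Uniform(0, `upper_bound`] with `upper_bound = 1e-9` — smaller than any
true nonzero relative abundance at realistic sequencing depths — which
breaks ties without disturbing the ranks of observed values. The draw is
random, so borderline p-values can shift slightly between seeds; every
stochastic entry point therefore takes an explicit seed, the CLI requires
one, and percentile tables record seed and bound in their header. Inside
the experiment drivers the seed argument defaults to `NULL`, meaning "draw
from the ambient stream", so that a single experiment-level seed governs
the whole run reproducibly.

## Comparator corrections

Two corrections commonly benchmarked against percentile normalization are
provided on the same `feature_table` surface:

* `eb_batch_adjust()` — parametric empirical-Bayes location/scale
  adjustment in log space: per feature, batch means are fit by least
  squares and residuals standardized by the pooled (maximum-likelihood)
  variance; per batch, feature-wise additive and multiplicative effects
  are shrunk toward a normal and an inverse-gamma prior with
  method-of-moments hyperparameters, iterating the standard fixed point to
  a relative tolerance of 1e-6 (capped at 500 iterations); shrunken
  effects are removed and the grand mean and scale restored. Only batch is
  modelled, matching default whole-dataset usage. The test suite
  cross-checks the output against an independent reference implementation
  (`sva::ComBat`) to ~1e-4.
* `linear_batch_remove()` — per feature, OLS on batch indicators with
  sum-to-zero contrasts and an intercept; the fitted batch component is
  subtracted, which equalizes per-feature batch means exactly (checked to
  1e-10, and against `limma::removeBatchEffect` to 1e-12). It is
  idempotent.

Both operate after `log_transform()`, which replaces zeros with half the
smallest positive value of the whole matrix and takes natural logs. The
log base is a convention (the back-transform is the matching exponential,
and downstream rank tests are base-invariant), and columns are *not*
re-normalized to unit sums after `back_transform()` — rank-based tests are
scale-free, so re-closing the composition would change nothing while
hiding the correction's actual output. For the same reason the
`"relative"` state of a `feature_table` denotes a scale, not a guarantee
of unit column sums: exact closure holds right after
`to_relative_abundance()` (and is checkable with
`validate_feature_table(strict = TRUE)`), while corrected or simulated
tables on the relative scale generally do not close to one.

## Combining p-values instead of pooling

The classic alternative to pooling runs the test within each study and
combines p-values: Fisher's \(-2\sum\ln p_i \sim \chi^2_{2k}\) or
Stouffer's weighted \(Z = \sum w_i z_i / \sqrt{\sum w_i^2}\) with
\(w_i = \sqrt{n_{case,i} + n_{control,i}}\). Both are computed from
two-sided p-values without sign restoration, so a feature that points in
*opposite* directions in different studies could be combined into a
spurious "significant" result; `opposing_direction_screen()` therefore
excludes, before combination, features significantly associated in
opposite directions in at least two studies. "Significant" is not
operationally pinned down by common usage, so the rule is configurable:
the default requires within-study \(q \le 0.05\) on both sides; `rule =
"p"` uses raw p-values; `rule = "any"` excludes every sign conflict.
Extreme within-study p-values are clamped to \([10^{-15}, 1 - 10^{-15}]\)
before combination because the normal quantile is unbounded at 0 and 1.

## The synthetic-data generator

`simulate_case_control_studies()` emulates the features of real
case-control collections that matter for batch correction:

* per-feature baseline log abundance \(\mu_g \sim N(0, 1)\) with log-scale
  spread \(\sigma = 0.7\) (the same order as the published two-study
  demonstration parameters, available verbatim via
  `demo_two_study_specs()`: study 1 controls \(\mu = 0.1, \sigma = 0.7\),
  cases \(\mu = 0.8, \sigma = 0.5\); study 2 controls
  \(\mu = 1.5, \sigma = 0.2\), cases \(\mu = 1.75, \sigma = 0.13\);
  100 samples per group);
* a study-wide batch effect shared across features — a location shift and
  a scale factor on the log scale. The default "strong" setting
  (\(\Delta\mu = 1.5\), \(\sigma \times 2\)) makes most features differ
  detectably between control cohorts of different studies, comparable to
  the published observation that two thirds of abundance-filtered OTUs
  differed between two real control populations;
* a consistent disease signal on a configurable fraction of features
  (case log abundances shifted by `effect_size` in every study);
* zero inflation at rate 0.25 applied after the lognormal draw.

What it does **not** emulate: compositional closure (values are kept on an
open relative scale so that the injected location/scale batch structure is
exactly known rather than partially cancelled by re-normalization),
feature-feature correlation, overdispersed sequencing-depth noise, and
feature-specific batch responses. Passing tests on these conditions
therefore demonstrate the rank-based machinery and the batch-cancellation
logic, not robustness to every property of real amplicon data.

## The in-silico experiments

`titration_experiment()` subsamples case and control groups to 40 samples
each (20 iterations) and substitutes `round(f * 40)` controls (round half
to even, endpoints exact) with controls from a second study along
\(f \in \{0, 0.25, 0.5, 0.75, 1\}\). Subsampling is without replacement
within an iteration; the fraction grid and counts are configurable. For
the percentile treatment each constituent study is normalized against its
own control pool *before* mixing (the method's intended use; a
`normalize_after_mixing` mode exists to demonstrate the misuse). For the
model-based treatments the combined pools are corrected **once** with
batch = source study and iteration subsets are drawn from the corrected
values; correcting each 80-sample subset separately would make batch
perfectly confounded with the case/control label at \(f = 1\) (and
undefined at \(f = 0\), where only one batch is present), which is not how
whole-dataset corrections are used. A consequence worth knowing: at
\(f = 0\) every method reduces to a within-study subsampled analysis.

`null_fp_experiment()` draws 40 artificial "controls" from one study's
control pool and 40 artificial "cases" from another's (20 iterations) and
records the fraction of features with rank-sum \(p \le 0.05\). Features
are occurrence-filtered — kept if nonzero in at least one third of either
group, evaluated on pre-replacement abundances of the selected samples —
before testing, in both experiments.

## Calibration: what is exactly 0.05 and what is not

Three distinct null constructions appear in the tests, and they behave
differently for a reason:

1. *Within-study case-control null.* Percentile conversion preserves all
   within-study ranks, so the downstream rank-sum test is exactly the
   ordinary rank-sum test: calibrated.
2. *Pooled case-control null with balanced groups.* Two studies whose
   cases and controls share a distribution within each study, 50/50 per
   study, strong batch shifts: the pooled rank-sum on percentile
   normalized data rejects at ≈ 0.05 (checked against binomial 99% bounds
   over 2000 features), while the cross-batch comparison that naive raw
   pooling implies (study-1 controls vs study-2 controls) rejects for
   ~90% of features. Note that pooling *raw* case vs control groups under
   this balanced design is also calibrated — both groups are identical
   mixtures — which is exactly why balanced nulls cannot expose batch
   effects and why the cross-batch contrast is the informative raw arm.
   Group-size confounding changes the picture: with strongly unbalanced
   designs (e.g. 80/20 vs 20/80) the pooled percentile test loses
   calibration too, because the pooled control sample is a deterministic
   percentile grid while the case sample is not; balance restores the
   symmetry. Sizeable, similarly sized control cohorts are a stated
   applicability condition of the method.
3. *Subsampled artificial case-control comparisons* (the null
   false-positive experiment) on percentile-normalized data are mildly
   **conservative** (observed fractions 0.01–0.04): both artificial groups
   are drawn without replacement from near-uniform finite percentile
   grids, which carries less rank variance than i.i.d. sampling. This
   matches the published qualitative finding that percentile normalization
   yields the *fewest* false positives among the treatments, and it is a
   property of the construction, not a defect to be corrected.

## Numerical choices and degenerate inputs

* Percentiles are real numbers in \([0, 100]\), never rounded; write/read
  round trips use 15 significant digits.
* Pooling over the union of feature sets marks features unobserved in a
  study `NA` and drops them pairwise in tests (a feature never observed in
  a study carries no rank information there); `absent = "zero"` treats
  absence as zero abundance instead, for users who prefer the
  zero-imputation reading.
* The occurrence filter compares `count/n ≥ fraction` with a 1e-12
  tolerance so that exact boundary cases (2 of 6 at fraction 1/3) are
  kept.
* `eb_batch_adjust()` passes zero-pooled-variance features through
  unadjusted with a warning; with a single feature the prior collapses to
  that feature's own estimates (no shrinkage). Shrinkage pulls batch
  effects toward the per-batch prior mean, so pooled per-feature means are
  preserved only approximately (drift well below the noise scale on
  balanced designs), not exactly.
* PERMANOVA (via `vegan::adonis2`) uses 999 permutations by default and a
  mandatory seed; \(p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})\).
* Fisher/Stouffer reject p-values of exactly 0 (Fisher) or 0/1 (Stouffer);
  the pipeline clamps before combining, as noted above.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on synthetic
data at sizes chosen to make the Monte-Carlo assertions sharp while
keeping a full run in the tens of seconds: 2000 features for the pooled
calibration check (binomial 99% bounds), 400 features for the titration
and null false-positive experiments at the canonical 40 + 40 / 20
iterations, 200 features × 2 × 50 samples for the batch-correction
recovery simulation, and 500 simulated communities (16 samples, 199
permutations) for the PERMANOVA calibration check.

## Limitations

* The method requires a sizeable control cohort per study — the control
  grid resolution limits the percentile resolution of the cases — and
  consistently defined case/control groups across studies; it corrects
  batch effects only insofar as they act equally on a study's cases and
  controls.
* Pooled percentile values are comparable across studies only in rank
  terms; they are not abundance estimates, and community-level analyses
  (Bray-Curtis, PERMANOVA) are run on relative abundances, not
  percentiles.
* The rank-sum implementation deliberately omits tie and continuity
  corrections to match the convention of the reference analyses; with the
  zero-replacement step ties are essentially absent, but running it on
  heavily tied data without replacement would be anti-conservative.
* Raw 16S read processing (quality filtering, OTU picking, taxonomy
  assignment) is out of scope; the package starts from feature tables.

## A worked example

```{r example, eval = FALSE}
library(percnorm)

# two synthetic studies with a strong batch shift and a planted signal
sim <- simulate_case_control_studies(
  n_features = 200, n_control = c(40, 40), n_case = c(40, 40),
  batch_mu_shift = c(0, 1.5), batch_sigma_scale = c(1, 1.5),
  effect_fraction = 0.1, effect_size = 2, zero_inflation = 0.2, seed = 1)

res <- meta_analysis_pipeline(sim$tables, sim$metadata,
                              method = "percentile", seed = 2)
res$summary
head(res$pooled)

# how badly would naive pooling have misled us?
null_fp <- null_fp_experiment(
  split_by_design(sim$tables$study1, sim$metadata)$study1$control,
  split_by_design(sim$tables$study2, sim$metadata)$study2$control,
  config = titration_config(group_size = 20, iterations = 10, seed = 3),
  method = "raw")
null_fp$summary
```
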