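---
title: "Univariate and multivariate biomarker selection for EV multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Univariate and multivariate biomarker selection for EV multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesicomics)
```

## The analysis problem

Mesenchymal stromal cells (MSCs) become strongly immunosuppressive after
priming with inflammatory cytokines (IFN-γ + TNF-α), and much of that
activity travels in the extracellular vesicles (EVs) they release. A
typical study design profiles a small donor-paired cohort — each of ~7
donors contributes both a control and a primed sample, measured in
technical replicates — with label-free shotgun proteomics, and a subset
of donors additionally with small-RNA sequencing of the miRNA content.
The statistical task is to nominate which proteins and miRNAs the
priming modulates, to demonstrate that the selected panels carry the
priming information (classification), and to connect the two molecular
layers through miRNA–target–pathway relations.

`vesicomics` implements that full analysis chain as reusable, tested R
functions, together with synthetic-data generators that reproduce the
statistical structure such a cohort is assumed to have (planted ground
truth included), so every stage can be validated end to end without
access to raw instrument data.

## Univariate protein selection

A protein is called modulated when three criteria hold jointly:

1. **Welch test, BH-adjusted.** Two-sided unequal-variance t-test on
   log2 intensities, primed vs control, across all observations;
   Benjamini–Hochberg adjustment; adjusted p < 0.05.
2. **Fold-change window.** Group fold change FC = mean(primed) /
   mean(control) on the linear intensity scale outside
   (1/1.5, 1.5). The lower bound is the symmetric reciprocal of the
   upper one; 0.5 is available via `univariate_config(fc_low = 0.5)`
   for users who prefer the wider window.
3. **Presence rule.** Per donor *i*, the paired fold change
   FC_i = mean over replicates(primed) / mean over replicates(control)
   must cross the same window in at least `k_min = 4` of
   `n_total = 7` donors. A donor with an entirely missing side
   contributes 0 while the denominator stays fixed, which makes the
   rule conservative under missingness.

Two statistical properties of this design are worth stating explicitly.
First, the Welch stage treats observations as independent; in a
donor-paired design the shared donor effects cancel from the group-mean
difference but still inflate the within-group variance estimate, so the
unpaired test is *conservative* when between-donor variability is
present. We therefore calibrate its type-I error on a null with the
donor variance set to zero (independent observations), which is the
regime the statistic is actually specified for. Second, missing values
are excluded pairwise and a feature needs at least two observations per
group to receive a p-value at all.

The ΔΔCt helper (`ddct_relative_expression()`) implements the standard
relative qPCR quantification RQ = 2^−ΔΔCt against a reference RNA
(U6 in the EV setting) and a calibrator sample, for validating selected
miRNAs.

## Ranking-PCA and PLS-DA

The multivariate machinery asks a different question: which *panel* of
variables, taken together, separates primed from control observations?

**Ranking-PCA** is a greedy forward selection in PCA score space. All
features are autoscaled (centered, unit variance — the chemometrics
convention; centering-only is available). Starting from the empty set,
every unranked feature is tentatively added, PCA is run on the
autoscaled candidate set, and a discrimination score is computed from
the first `n_pc` score vectors (1 by default, appropriate for the
degrees of freedom of a 7-donor cohort); the feature maximizing the
score is permanently added and the process repeats to a feature budget.
Ties break by ascending feature identifier, making the ranking fully
deterministic.

Two scores are implemented, selectable via `criterion`:

- `"separation"` (default): the absolute difference of the class means
  of the PC scores. Because autoscaling bounds each feature's
  contribution, the greedy keeps accumulating genuinely class-separated
  variables; in simulations with planted effects this variant recovers
  essentially all planted features within a 2 × n_planted budget.
- `"standardized"`: the separation divided by the pooled within-class
  standard deviation of the scores. This sharpens the earliest picks,
  but once the classes are fully separated it rewards
  variance-cancelling "suppressor" variables, so deep ranks admit
  features with no class effect of their own. It is the right choice
  when the goal is the smallest panel that classifies, not an
  exhaustive biomarker list. A pooled sd of exactly zero with unequal
  means yields an infinite sentinel that outranks every finite score.

**PLS-DA** then classifies on the ranked panel. The class response is
coded −1 (control) / +1 (primed) and regressed on the autoscaled
feature block by NIPALS partial least squares with `n_lv = 1` latent
variable (again matching the small-cohort degrees of freedom). With one
latent variable the weight vector has the closed form w ∝ Xᵀy, which
the test suite uses as an independent oracle. The decision threshold
sits at ŷ = 0; an exact tie is assigned to the control class with a
warning. Positive regression coefficients correspond to proteins
up-regulated in primed samples, and ordering by decreasing
|coefficient| orders the panel by discrimination ability.

**Validation** uses leave-one-individual-out cross-validation: one fold
per donor, with *all* of that donor's observations (both conditions,
every replicate) held out together. Feature ranking, preprocessing and
the PLS-DA fit are recomputed inside each fold on training data only —
selection inside the fold is the only reading that avoids selection
leakage, and it is what `loo_cv_by_individual()` does. Held-out
predictions pool into a single confusion matrix, from which we report
accuracy (percent correctly assigned) and the non-error rate NER%
(unweighted mean of the per-class accuracies, robust to class
imbalance). Missing intensities are imputed at the training-fold
feature mean (equivalently zero after centering), never with held-out
information.

The final "modulated" panel is the intersection of the univariate
selection with the top-ranked multivariate features
(`intersect_selections()`), with directions taken from the univariate
fold changes.

## miRNA differential expression

Counts are normalized with median-of-ratios size factors (median across
all-nonzero features of the count over the feature's geometric mean;
the median is taken on the log-ratio scale, matching the reference
implementations; a positive-count pseudo-reference is available for
sparse matrices). The two-group test is a deliberately simple negative
binomial Wald test: a method-of-moments dispersion pooled within groups
and floored at the Poisson limit, a delta-method standard error for the
difference of log group means under var = μ + αμ², and reference to a
t distribution with n₁ + n₂ − 2 degrees of freedom rather than a
normal, which absorbs the noise of moment-based dispersion estimation
at the 4–5 samples per group typical of these designs (empirically this
keeps the null rejection rate at the nominal 5%). P-values are
BH-adjusted and miRNAs flagged at 5% FDR. The log2 fold change uses a
0.5 pseudo-count only when a group mean is exactly zero, so noise-free
inputs recover planted effects exactly. No dispersion shrinkage,
outlier filtering or independent filtering is attempted — this stage is
a self-contained stand-in for the shrinkage-based DE packages, not a
reimplementation of them.

## Cross-omics integration

`merge_blocks()` follows the retention rules appropriate for a
donor-matched merge of two characterizations with unequal coverage:
replicates are collapsed to one profile per (donor, condition); only
donors present in both blocks are retained; proteins quantified in
fewer than `min_presence = 2` retained donors are dropped (miRNAs are
kept when nonzero in at least one sample). Counts are made commensurate
with intensities by log2(normalized count + 1), and each block is
autoscaled independently before stacking — otherwise the block with the
larger variance scale dominates every subsequent rotation. The merged
matrix then goes through the same Ranking-PCA (budget 200 by default)
and a PCA on the selected subset; PC1 is oriented toward the primed
class mean so that positive loadings consistently mark primed-up
variables, and a block-composition report records how many top-ranked
variables are miRNAs vs proteins.

## Pathway coverage and over-representation

For a list of differentially expressed miRNAs, a user-supplied
miRNA→gene target map and GMT gene sets, `pathway_target_coverage()`
reports per pathway the percentage of member genes targeted by at least
one DE miRNA. A multiply-targeted gene counts once for coverage but
contributes to every targeting miRNA's chord-diagram edge weight
(`chord_edges()`), matching chord-plot semantics. The companion
`hypergeometric_ora()` is a generic over-representation stage (upper
tail of the hypergeometric, BH across pathways, enriched at adjusted
p < 0.05) whose universe defaults to the union of pathway genes and can
be overridden with a whole-proteome background. Database content is
never bundled: coverage percentages are inherently version-dependent on
the target and pathway resources supplied.

## The synthetic cohort

`sim_design()` encodes the reference study conditions: 7 donors × 2
conditions × 3 technical replicates; 500 proteins of which 50 carry a
planted |log2 fold change| of 3 (half up, half down, exercising both
coefficient signs); donor effects N(0, 0.5²) on the log2 scale shared
between a donor's control and primed observations (the paired
structure); replicate noise N(0, 0.3²); 5% missing values. Three
replicates reflect typical DIA acquisition practice; the 0.5 donor sd
is a realistic between-donor spread for log2 label-free intensities.
Missingness is MCAR by default with an optional left-censored mode
(`missing_mode = "censored"`), because label-free MS missingness is in
reality abundance-biased; the selection rules themselves make no
missingness-mechanism assumption. miRNA counts are negative binomial
with multiplicative library-size factors (variance μ + αμ², dispersion
0.05, base mean 500, 5 samples per group), and pathway resources plant
an exact per-pathway coverage fraction by construction.

What passing tests on these cohorts shows — and what it does not: the
pipeline provably recovers planted effects of the simulated magnitude
and classifies separable cohorts perfectly, with calibrated null
behaviour. Real MS data add features the generator does not emulate
(correlated features, heavy-tailed noise, abundance-dependent CVs,
batch structure), so performance numbers on synthetic cohorts are
statements about the machinery, not about any particular biological
dataset.

## Numerical choices and degenerate inputs

- PCA is computed by SVD of the preprocessed matrix; zero-variance
  features are dropped (with a warning) under autoscaling, and kept as
  exact-zero columns inside the ranking kernel so every feature retains
  its identifier slot.
- Ranking-PCA ties break by ascending feature identifier; constant
  features score 0 and therefore sort purely by identifier.
- PLS-DA errors on a constant class vector and on `n_lv` exceeding the
  rank of the preprocessed matrix; the NIPALS residual is checked at
  every component.
- A fold change with a zero control mean or an all-missing group is
  flagged and can never be selected; a Welch test with both group
  variances zero and equal means returns p = 1 by convention.
- All-zero count features are excluded from testing and reported with
  `NA` statistics.
- Problem sizes throughout the test suite (500–1000 features, 42
  observations, 20 label permutations) were chosen so the full
  validation runs on a laptop-class single core in about a minute while
  keeping Monte-Carlo bands (3 binomial SEs) tight enough to detect
  real miscalibration.

## Command-line use

The R functions are the primary interface. For pipeline reproduction a
thin wrapper script is installed under `exec/`: `vesicomics simulate`
writes a complete synthetic input set, and `vesicomics run --config
cfg.yaml` executes the full chain (`run_pipeline()`), writing each
stage's table as TSV plus a JSON summary and a log; reruns with the
same configuration and seed are byte-identical. Individual stages are
deliberately not duplicated as subcommands — in R they are one function
call each.

## Known limitations

- The NB stage's moment dispersion is noisy below ~4 samples per group;
  the t reference compensates on average but individual dispersion
  estimates remain crude compared to shrinkage estimators.
- Greedy forward selection is myopic: with the `"standardized"`
  criterion it will happily rank suppressor variables once separation
  saturates (see above), and with either criterion it does not attempt
  to de-correlate the panel.
- `loo_cv_by_individual()` requires at least 3 donors and warns (but
  proceeds) when a donor lacks one condition; with very unbalanced
  folds NER% is the metric to trust, not accuracy.
- The coverage statistic treats the target map as ground truth;
  coverage percentages move with the map and pathway versions supplied.
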