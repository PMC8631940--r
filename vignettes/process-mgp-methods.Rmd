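---
title: "Process-centered multivariate genotype-phenotype mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-centered multivariate genotype-phenotype mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Morphological traits such as craniofacial shape are extraordinarily
polygenic, and single-marker association scans recover only a sliver of
their heritable variation. `mgpmap` takes the complementary,
process-centered route: instead of testing markers one at a time
against univariate summaries, it asks how much of a *multivariate*
shape space covaries with allelic variation at *all* markers tagging a
biologically coherent gene set — say, every gene annotated to
"chondrocyte differentiation" — and in which direction of shape space
that joint effect points.

The intended data are multiparental populations such as the Diversity
Outbred (DO) mouse, where each genome is a mosaic of eight founder
haplotypes and each marker carries an 8-vector of estimated founder
diplotype contributions rather than a biallelic dosage.

## The model

### From gene sets to a genotype block

A text query against a gene-ontology snapshot selects annotation terms;
the union of their genes (direct annotations only, no GO-graph closure)
is intersected with a gene catalog holding one interval per symbol (the
longest transcript; ties broken by smallest start). For each gene the
markers closest upstream and downstream of the gene's midpoint
(`floor((start + end)/2)`, in base-pair coordinates, strand ignored)
are located, and their founder-probability 8-vectors averaged. A gene
whose midpoint falls exactly on a marker, or outside the chromosome's
marker span, uses that single marker. The per-gene 8-column blocks are
concatenated: `m` genes give an `n x 8m` genotype block whose per-gene
rows sum to one.

### Shape preprocessing

Landmark configurations (`K` landmarks in 3D; 54 is the reference
case) are superimposed by Generalized Procrustes Analysis: centering,
scaling to unit centroid size, and iterative proper rotation to the
evolving mean until the mean moves less than `1e-10` (at most 200
iterations). The converged solution is rotated into the principal axes
of the mean shape with fixed sign conventions, so the output is
invariant to specimen order and to arbitrary rigid transformations of
the input. No tangent-space projection is applied; analyses operate on
the aligned coordinates.

For structures with object symmetry, each configuration is paired with
its reflected-and-relabeled copy, GPA is run over the doubled sample,
and the frame is rotated so the symmetry plane is exactly `x = 0`
(without this step the symmetric component is not mirror-invariant and
re-symmetrizing would not be idempotent). The symmetric component is
the average of the aligned original and reflected copies, the
asymmetric component the remainder, so `symmetric + asymmetric =
aligned` holds exactly as stored. Directional asymmetry is tested by
Procrustes ANOVA: `F = (SS_DA/df1) / (SS_FA/df2)` with `df1` the
empirical rank of the centered asymmetric matrix and
`df2 = (n - 1) df1`. The rank-based degrees of freedom are a declared
convention — reported df values for this test vary across software and
are rarely reconstructible from stated quantities — and the empirical
rank is what makes the null distribution F-distributed when the
asymmetric subspace is smaller than `3K` (the calibration test in the
suite checks exactly this). Finally, shape is residualized on
dummy-coded covariates (breeding generation and sex), with the grand
mean added back, so downstream fits see within-generation,
sex-adjusted variation.

### The regularized PLS engine

Both blocks are column-standardized (zero-variance columns become zero
vectors) and the cross-correlation matrix `C = X'Y/(n-1)` is formed.
A lasso soft-threshold `sign(c) max(|c| - lambda, 0)` is applied
entrywise, and the first singular triple `(u, d, v)` of the thresholded
matrix gives the genetic loadings `u` (one per gene-founder column) and
phenotypic loadings `v` (one per shape coordinate). Only the first
paired axes are computed; multi-component deflation is deliberately out
of scope. The sign of `v` is fixed (largest-magnitude entry positive)
so loadings are reproducible. Genotype scores are `t = X_std u`; the
shape regression `b = Y_c' t / t't` maps scores back onto the original
shape scale, and variance explained is the trace ratio
`R^2 = trace(cov(t b')) / trace(cov(Y))`.

Standardizing both blocks is a deliberate choice: it puts `lambda` on
the correlation scale, where values in the 0.04–0.1 range are
meaningful regardless of landmark units. Its one consequence worth
knowing: `v` carries the *correlation* profile of an effect, so for a
noiseless rank-1 architecture `v` retains only the sign pattern of the
true direction while the regression vector `b` recovers it exactly; in
the realistic regime where per-coordinate noise dominates any single
effect, `v` and `b` agree closely (the test suite asserts both
behaviors).

Lambda can be fixed (0.06 by default, within the range used in
practice) or chosen by 10-fold cross-validation over a 0.01–0.20 grid:
folds are a seeded specimen-level shuffle, standardization is
re-estimated per training fold, held-out error is the mean squared
prediction error on the original shape scale, and ties go to the
sparser model. Cross-validated lambda minimizes *prediction* error,
which favors heavier shrinkage than direction recovery would; this is
the familiar error-versus-interpretability tradeoff of sparse PLS, and
the grid's minimum (typically 0.04–0.08 on the synthetic data) is
exposed rather than hidden.

### Inference

- **Permutation null for R²**: the observed gene set's R² is compared
  with fits of randomly drawn same-size gene sets from the catalog at
  identical lambda. Draws are matched on mean within-set linkage
  disequilibrium within a tolerance (default 0.05); after 50 rejections
  the closest candidate is accepted. Resampling whole *genes* (not raw
  markers) automatically reproduces the two-flanking-marker averaging
  and most of the LD structure of real sets. The LD summary between two
  founder-probability blocks is the maximum over founders of the
  squared correlation of matching probability tracks — a declared
  substitute, since no canonical LD definition exists for 8-state
  founder probabilities. The p-value uses the add-one estimator
  `(1 + #(null >= observed)) / (1 + n_perm)`, which is unbiased under
  exchangeability and cannot return zero.
- **Vector correlations** between effect directions use the Pearson
  correlation over the `3K` coordinates with `df = 3K - 2` (162
  coordinates give df 160), a two-sided t test, and an optional
  coordinate subset (e.g. palate-only landmarks).
- **Gene drops** rank genes by the Euclidean norm of their eight
  founder loadings in the full fit, then cumulatively remove the
  heaviest genes, refitting at the same lambda and recording R² and the
  absolute correlation with the full-model direction. Architectures
  driven by one dominant gene collapse after the first removal; diffuse
  architectures barely move.
- **Process clustering**: pairwise `|r|` matrices are clustered on
  `1 - |r|` (complete linkage by default; single/average available)
  and clustering stability is the correlation between cophenetic and
  original distances over the `m(m-1)/2` pairs (`df = pairs - 2`; 15
  processes give df 103).
- **Mutant contrasts**: reference and mutant samples are jointly
  registered (size removed, symmetrized when a pairing is given) and
  the effect direction is the mutant-minus-reference mean difference
  per coordinate — exactly the group-coded multivariate linear-model
  coefficient, used as a direction, never as a test statistic. For
  display, effects are projected onto the first two PCs of the pooled
  sample, magnified 4x by convention, with a normal-theory 95% data
  ellipse (chi-square quantile, 2 df) around the reference scores.

## The synthetic-data generator

Real DO data are large and access-controlled, so the package ships a
generator that emulates the statistical structure the method assumes;
it is first-class, tested code, and the whole test suite runs on it.

- **Genotypes**: per specimen and chromosome, two independent founder
  Markov chains over an evenly spaced marker grid (uniform start; per
  interval, switch to a uniformly chosen other founder with probability
  `switch_prob`). The diplotype probability is the average of the two
  haplotype indicators — giving the {0, 0.5, 1} structure of real
  reconstructions — optionally softened toward the uniform simplex to
  mimic reconstruction uncertainty.
- **Genome defaults**: 20 chromosomes x 50 markers at 1 Mb spacing
  with `switch_prob = 0.15`. These were chosen so that LD decays over
  a few megabases and is negligible across chromosomes, the regime
  that makes random-gene permutation draws a meaningful null; with few
  chromosomes or rare switching, every gene tags every other and the
  null collapses onto the observed statistic.
- **Annotations**: 200 genes placed at non-overlapping random
  intervals (some with a second, shorter transcript so the
  longest-transcript rule is exercised), one causal-process term of 20
  genes containing the 2 causal genes plus decoys, and several decoy
  terms.
- **Shapes**: a deterministic bilaterally symmetric template (unit
  centroid size) plus, per causal gene, `(P_g c_g) w`: the gene's
  averaged founder probabilities contracted with a zero-sum founder
  coefficient vector (effects are contrasts among founders, matching
  zero-centered allele-effect displays), times a shared unit direction
  `w` that respects the symmetry pairing and is orthogonal to the
  template's similarity transforms (so GPA cannot absorb it). Isotropic
  Gaussian noise (`sd` 0.005) and a small symmetric sex dimorphism
  complete the model. The effect scale is calibrated so the genetic
  share of total raw-coordinate variance equals `effect_size` exactly
  (5% by default, the small-effect regime for which DO studies
  recommend samples of 800+); with zero noise the scale is arbitrary
  and the share is 1.
- **What it does not emulate**: pedigree structure across generations
  (specimens are exchangeable, so kinship is a pure screen), linkage
  between causal and annotated-but-noncausal processes, measurement
  error correlated across landmarks, and real cranial geometry. Tests
  passing on this generator show the estimator and its inference are
  correct under the model's assumptions — not that any particular
  biological claim holds in real data.

## Problem sizes and numerical choices

The test suite and acceptance script use the generator's default study
conditions: n = 800 specimens, 1000 markers, a 20-gene process with 2
causal genes at a 5% variance share for recovery and power runs;
n = 300 with 199 permutations x 200 datasets for null calibration;
n = 20 with 500 replicates for asymmetry-test calibration. The
permutation engine precomputes per-gene standardized blocks, the
gene-level LD matrix, and the standardized shape block once per
dataset, so a single refit is one cross-product and one singular
triple.

Other numerical conventions: GPA convergence `1e-10` with 200
iteration cap; singular triples via dense LAPACK SVD up to
`p + q = 2000` columns and a deterministic power iteration (tolerance
`1e-10`, started from the largest-norm column) beyond; rank decisions
at relative singular-value tolerance `1e-8`; degenerate inputs
(zero-variance vectors, saturated fits, zero fluctuating asymmetry)
are signaled explicitly rather than returning NaN.

## Known limitations

- Only the first PLS axis pair is estimated; processes whose secondary
  axes carry distinct biology are summarized by their dominant axis
  only.
- The method is additive in founder probabilities; epistatic structure
  enters only through the covariances it induces.
- Individual marker effects have no parametric test by design;
  inference is permutation-based at the process level.
- The LD-matching rule and the founder-track LD summary are declared
  conventions, not estimates of any population-genetic quantity.
- Gene identity is keyed on symbols; a symbol on two chromosomes is
  rejected rather than disambiguated.
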