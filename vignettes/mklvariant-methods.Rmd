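---
title: "Multiple kernel learning for variant pathogenicity: model and methods"
author: "mklvariant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple kernel learning for variant pathogenicity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mklvariant)
```

## The problem

Deciding whether a single-nucleotide variant (SNV) is pathogenic or
neutral draws on heterogeneous annotation sources: evolutionary
conservation scores, transcription-factor binding evidence, chromatin
state, genome segmentation, and more. These sources differ in scale,
dimensionality and coverage, and no single one suffices — conservation
is strong but silent in poorly aligned regions, functional-genomics
tracks are informative but sparse. `mklvariant` integrates such
*feature groups* at the level of similarity rather than raw features,
using multiple kernel learning (MKL) with a support vector machine
(SVM), and augments the classifier with calibrated posteriors, a
reject option (cautious classification), and a principled treatment of
variants missing whole annotation groups.

## The model

Each feature group $\ell = 1,\dots,p$ yields a base kernel $K_\ell$, a
variant-by-variant similarity matrix. The classifier operates on the
composite kernel

$$K \;=\; \sum_{\ell=1}^{p} \lambda_\ell K_\ell, \qquad
  \sum_\ell \lambda_\ell = 1,\;\; \lambda_\ell \ge 0,$$

where the kernel weights $\lambda_\ell$ are *learned* jointly with a
soft-margin SVM, so that they express the relative informativeness of
the annotation sources. The decision function is
$\mathrm{sign}(\phi)$ with
$\phi(x) = \sum_i \alpha_i y_i K(x, x_i) + b$; ties at $\phi = 0$
are resolved to the positive (pathogenic) class, consistent with the
at-or-above convention used everywhere scores are thresholded in this
package.

### Base kernels

`compute_base_kernels()` standardizes every feature column to zero
mean and unit variance on the training rows (constant columns map to
zero), imputes value-missing cells at the feature mean (zero after
standardization), and builds either a linear kernel (inner products;
the default) or an RBF kernel with a median-heuristic bandwidth. Every
kernel is then unit-diagonal normalized,
$K(i,j) \leftarrow K(i,j)/\sqrt{K(i,i)K(j,j)}$ with $0/0 \mapsto 0$.
Normalization matters because feature groups can range from a handful
to hundreds of features: without it, high-dimensional groups dominate
the composite kernel purely through scale. The linear default keeps
small training problems well conditioned and the learned weights
interpretable; RBF is available where nonlinear structure within a
group is expected. For a one-dimensional group, standardization plus
unit-diagonal normalization collapses the linear kernel to a sign
kernel — a degenerate but well-defined case the tests exercise.

### Learning the weights

`train_mkl()` minimizes the MKL objective by alternating optimization:

1. at fixed $\lambda$, solve the soft-margin SVM dual exactly on
   $K(\lambda)$ (a box-constrained quadratic program with one equality
   constraint, solved by an interior-point method with a
   retry-at-lower-precision/ridge ladder for degenerate kernels);
2. update $\lambda$ by a reduced-gradient step over the probability
   simplex, with Armijo backtracking in which every trial point
   re-solves the SVM.

The dual-optimal objective $J(\lambda)$ is convex in $\lambda$ (a
pointwise maximum of linear functions) and, by Danskin's theorem, its
gradient at the dual optimum $\alpha^\*$ is
$\partial J/\partial\lambda_\ell = -\tfrac12 (\alpha^\*\!\circ y)^\top
K_\ell (\alpha^\*\!\circ y)$, so accepted steps strictly decrease $J$
and the per-iteration objective trace is monotone non-increasing — a
property the test suite asserts directly. Starting point is the
uniform simplex $\lambda_\ell = 1/p$; iteration stops when the
relative objective change falls below `tol` (default $10^{-5}$), the
weight vector moves less than $10^{-4}$ in max-norm, or the reduced
gradient vanishes (KKT). With a single kernel the simplex is a point
and the procedure reduces exactly to a standard SVM, which is how the
implementation is validated against an independent solver (libsvm).

### Choosing C

The SVM constant $C$ governs how much the classifier may bend to fit
individual training examples. This matters doubly under MKL: at large
$C$, uninformative ("noise") kernels can earn weight by helping the
SVM memorize training labels, diluting the weight on genuinely
informative groups. `tune_C()` therefore selects $C$ by an inner
stratified 3-fold cross-validation over the grid
$\{0.01, 0.1, 1, 10, 100\}$, scored by AUC of the held-out decision
values (ties resolved toward the smaller, more regularized value). On
the reference synthetic conditions this selection lands at the
regularized end and the learned weight concentrates almost entirely on
the informative group; at a fixed $C = 1$ the same data yield a
noticeably more diluted weight vector. Training-time functions take a
fixed `C` (default 1) so that oracle comparisons are like-for-like;
study-level workflows (`cmd_train(C = "auto")`, the benchmarks) use
the tuned value.

### Posteriors and cautious classification

`fit_platt()` maps decision values to posterior probabilities
$P(y{=}1 \mid \phi) = 1/(1 + e^{a\phi + b})$ by minimizing the
cross-entropy against Platt's smoothed targets
$t_+ = (N_+{+}1)/(N_+{+}2)$, $t_- = 1/(N_-{+}2)$ with a damped Newton
iteration (deterministic; convergence declared at gradient max-norm
$10^{-6}$ or a line search stalled at machine precision). The sigmoid
is always fitted on *out-of-fold* decision values (`mkl_cv()`): a
sigmoid fitted on the same examples the SVM trained on is
overconfident, because training decision values cluster beyond the
margin.

A prediction's confidence is $\max(P, 1-P) \in [0.5, 1]$.
`cautious_subset()` keeps records with confidence at or above a
cutoff; raising the cutoff trades coverage (kept fraction) for
accuracy of the kept subset. Cutoffs apply to confidence, not raw
posterior, so confident *negative* predictions are retained
symmetrically. Reporting tiers in `cmd_rank()` default to
$\{0.26, 0.90, 0.95\}$; the sub-0.5 value is an operating point on the
posterior itself (a positive-call threshold), not a confidence.

### Missing feature groups

Real annotation is incomplete: a variant may lack an entire feature
group. At prediction time, `rescale_weights()` sets the missing
groups' weights to zero and renormalizes the remainder,
$\lambda'_\ell = \lambda_\ell / \sum_{\ell \in \text{avail}}
\lambda_\ell$, and `decision_function()` applies this row by row. A
variant with no available group yields an explicit no-prediction
marker (`NA`, written as `.` in output tables), never a number.
Published weight vectors are printed rounded, so the rescaling entry
point tolerates a simplex defect up to 0.05 before renormalizing.

## Dataset assembly

The assembly operations encode common benchmark-construction rules:

- `filter_controls_by_maf()` keeps controls with minor allele
  frequency at or above 1% (inclusive); common variants are unlikely
  to be strongly deleterious. Controls lacking MAF are dropped with a
  count (or rejected, configurable).
- `remove_pathogenic_overlap()` removes controls whose
  `(chrom, pos, ref, alt)` key also appears among the pathogenic
  variants.
- `select_negatives_within_window()` retains negatives within 1000 nt
  of some positive on the same chromosome. The geometry is symmetric
  and inclusive ($|\Delta\mathrm{pos}| \le w$): the most permissive
  reading of "within a window of some positive", chosen over a fixed
  genome tiling because it is translation invariant and
  parameter-free. Sentinels: $w = \infty$ keeps all negatives sharing
  a chromosome with a positive; $w = 0$ keeps exact-coordinate
  matches only.
- `split_by_coding()` partitions on the input coding flag (does the
  variant introduce an amino-acid substitution); consequence calling
  itself is upstream of this package.
- `assemble_training_set()` requires at least one observed value in
  every selected feature group and optionally draws a class-balanced
  subsample, uniformly without replacement under an explicit seed.

Coordinates are 1-based and fully closed (VCF convention); only
biallelic SNVs are modeled. Multi-allelic sites and indels are out of
scope — rows violating `ref != alt` or single-nucleotide alleles are
rejected at construction.

## The synthetic study

`synthetic_config()` / `generate_synthetic()` define the conditions
under which every end-to-end claim in this package is tested, so their
defaults are fixed and documented rather than tuned per test:

- **Classes and features.** 200 variants per class; four feature
  groups of 10 features; class-conditional multivariate normals with
  identity covariance. One informative group separates the latent
  classes by `effect_size = 2`, defined as the Euclidean norm of the
  between-class mean difference in units of the per-feature standard
  deviation (the shift is spread evenly over the group's features).
  This makes the single-group Bayes AUC
  $\Phi(2/\sqrt{2}) \approx 0.92$: discriminative, but genuinely
  overlapping, so calibration and cautious classification have
  something to do. The remaining three groups are pure noise.
- **Contamination.** 5% of the negatives are *contaminants*: latent
  positives carrying the control label. Control sets drawn from
  population polymorphism inevitably contain such mislabeled true
  positives; this is what the MAF-shift diagnostic detects.
- **Allele frequencies.** Clean controls draw MAF from
  $0.5 \cdot \mathrm{Beta}(2, 5)$ (mean 0.14, comfortably above the
  1% filter); pathogenic variants and contaminants draw from
  $0.5 \cdot \mathrm{Beta}(1, 9)$ (mean 0.05). Deleterious variants
  are held at low frequency by selection, and the contaminant model
  makes the diagnostic's expected direction (confident false
  positives shifted toward rare alleles) a property of the generative
  process rather than of a particular seed.
- **Positions.** Positives scatter uniformly over two 1-Mb
  chromosomes; 90% of negatives are placed within 1000 nt of a random
  positive, exercising the window-selection rule.
- **Missingness.** Group- and value-level missingness rates default
  to zero and are switched on per experiment; the generator
  guarantees the container invariant (group-missing implies all cells
  missing, and never silently the converse).

What the generator does *not* emulate: correlated features within a
group, heavy-tailed or discrete annotation values, linkage structure
between nearby variants, and class imbalance at genome scale. Passing
tests on this generator demonstrate the correctness and qualitative
behavior of the machinery — weight concentration, calibration,
coverage/accuracy trade-offs, the MAF shift — not performance on real
annotation data.

## Benchmarks and problem sizes

The packaged self-benchmarks re-run the full procedure at sizes chosen
to keep each one in the minutes range on a single core while leaving
no doubt about the qualitative outcome:

- `benchmark_weight_recovery()`: 20 independent train/test study
  pairs (200/class each); per study, `tune_C()` then `train_mkl()`,
  with single-kernel baselines at the same $C$. Median informative
  weight and the MKL-vs-best-single AUC gap are the headline outputs.
- `benchmark_cautious()`: one 5-fold cross-validated study without
  contamination, swept at confidence cutoffs
  $\{0.5, 0.7, 0.9, 0.95\}$.
- `benchmark_maf_shift()`: 20 replicates of train / calibrate /
  evaluate on three independent studies, with the diagnostic applied
  at the 0.90 posterior tier.

`scripts/acceptance.R` runs exactly these benchmarks plus the
solver-against-oracle and counting-against-enumeration checks, and
writes every quantity as JSON.

## Numerical choices

- SVM dual: interior-point QP at 8 significant figures; on failure
  (rank-deficient kernels, extreme $C$) retried at lower precision
  and then with ridge jitter up to $10^{-6}$, which perturbs the
  objective by a bounded, documented amount. The iterate is then
  refined to a machine-precision KKT point by exact active-set
  polishing: solve the free-set stationarity system (SVD
  pseudo-inverse, since with a rank-deficient kernel every
  least-squares solution yields identical decision values) and move
  single worst violators between the bound and free sets; the
  refinement is adopted only when it reaches a near-exact KKT point.
- Bias: mean over free support vectors; when none are free, the
  midpoint of the interval bracketed by the bound KKT conditions
  (the libsvm convention, so decision values remain comparable across
  implementations even when the bias is not unique).
- PSD: base kernels are PSD by construction; validation uses a
  relative eigenvalue tolerance of $10^{-8}$.
- Tie-breaks: thresholded scores at the threshold predict positive;
  $\phi = 0$ predicts positive; threshold sweeps resolve balanced
  accuracy ties to the smallest threshold; `tune_C` resolves AUC ties
  to the smallest (most regularized) $C$.
- Reproducibility: every stochastic step (generation, fold shuffles,
  balanced sampling, grid-search splits) takes an explicit seed, and
  seeded code restores the caller's RNG state.

## Known limitations

- The MKL objective is convex in $\lambda$ only at the dual optimum
  path; the alternating scheme is guaranteed monotone, not
  certificate-optimal. In practice the reduced-gradient loop
  terminates at a KKT point in well under the 100-iteration cap.
- The interior-point dual solve is $O(n^3)$; training is comfortable
  to a few thousand variants but is not a genome-scale trainer.
  (Scoring new variants is linear in the number of training points
  and poses no such limit.)
- Weight rescaling treats missing groups as missing at random; when a
  group is informative *and* systematically missing for a class,
  rescaled predictions can be biased — combination-specific weight
  sets would be the remedy and are not implemented.
- Platt calibration assumes the out-of-fold decision values are
  exchangeable with deployment-time ones; distribution shift between
  training and scoring data invalidates the posterior scale, though
  ranking is unaffected.
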