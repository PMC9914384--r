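---
title: "Entropy-controlled marine predators feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-controlled marine predators feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmpa)
```

## The problem

Deep convolutional backbones used as feature extractors emit wide activation
vectors — here the 1024-unit DarkNet53 and 1920-unit DenseNet201
global-average-pool layers, serially fused into D = 2944 features per image.
In blood-cell (leukocyte) classification and similar biomedical settings,
many of these columns are redundant or near-zero, and classifiers built on
the full fused vector pay a large computational and memory cost for no gain
in accuracy. `ecmpa` implements a wrapper feature selector that searches for
a small, discriminative column subset, together with the surrounding
pipeline stages: image contrast enhancement, feature fusion, a genetic
algorithm (GA) convergence baseline, classifier evaluation, and one-way
ANOVA reporting.

## The two-stage selector

**Stage 1 — entropy filter (unsupervised).** Each feature column is binned
into `entropy_bins` equal-width bins over its own range and scored by its
Shannon entropy in bits. Columns are sorted in descending entropy and the
top `ec` percent are retained, with a floor of one column
(`max(1, ceiling(ec/100 * D))`), ties broken toward the lower column index.
The rationale: a near-constant or low-variability activation cannot
discriminate classes, and the class structure of an informative column (a
mixture of per-class components) spreads its histogram, raising its binned
entropy. The estimator is deliberately simple and deterministic: equal-width
histograms over the per-column min–max with 256 bins by default (the 8-bit
convention), entropy of a constant column defined as 0. Because the binning
is affine-invariant per column, the filter ranks columns by distributional
*shape*, not scale.

**Stage 2 — marine predators search (wrapper).** The marine predators
algorithm (MPA) is run over the continuous box $[lb, ub]^{d_2}$, where
$d_2$ is the number of retained columns. A position $x$ is mapped to a
feature subset by strict thresholding, $m_j = \mathbf{1}[x_j > t]$, and its
cost is the holdout misclassification error of a k-nearest-neighbour
classifier trained on the masked columns. The empty subset is assigned cost
1.0 (the worst value) without fitting, keeping the objective total. The
best agent at the end of the run, binarized and mapped back through the
retained-column indices, is the selection.

### MPA movement rules

With population $N$, iterations $I_{max}$, and the adaptive scale
$CF = (1 - I/I_{max})^{2I/I_{max}}$ (1 at the start, 0 at the end):

* Iterations in the first third (exploration): Brownian steps
  $s = R_B \otimes (E - R_B \otimes x)$, $x \leftarrow x + P\,R \otimes s$
  with $R_B \sim N(0,1)$, $R \sim U(0,1)$, $P = 0.5$.
* Middle third: the first half of the agents take Lévy steps of the same
  prey-centred form; the second half take elite-centred Brownian steps
  $x \leftarrow E + P\,CF\, R_B \otimes (E - R_B \otimes x)$.
* Final third (exploitation): all agents take elite-centred Lévy steps
  $x \leftarrow E + P\,CF\, R_L \otimes (E - x)$.

Phase boundaries are at `floor(IMax/3)` and `floor(2*IMax/3)`. After every
movement a FADs (fish aggregating devices) perturbation is applied per
agent: with probability `FADs = 0.2` a long jump
$CF\,[lb + R\otimes(ub-lb)]\otimes U$ with a random binary mask $U$;
otherwise a scaled difference of two random agents. Positions are clamped
to the box after every update — clamping (rather than reflection or
rescaling) keeps the geometric meaning of the binarization threshold
intact. Agent-wise memory saving keeps the better of each agent's previous
and current position (ties keep the previous), which together with the
elite update makes the best-cost trace non-increasing by construction.

Lévy steps are drawn with Mantegna's algorithm
($u/|v|^{1/\beta}$, $u \sim N(0, \sigma_u^2)$, $v \sim N(0,1)$, default
$\beta = 1.5$) and scaled by 0.05 inside the movement rules, following the
reference implementation of the optimizer; `sample_levy()` itself exposes
the unscaled sampler. At $\beta = 2$ Mantegna's $\sigma_u$ collapses to
essentially zero; the sampler remains well defined.

### The fitness partition

The cost function conceptually re-partitions the data at every evaluation.
We instead draw one stratified train/test split per run (test fraction
`ho`) and reuse it for all evaluations: with a resampled split, the
memory-saving comparison between an agent's previous and current cost is
dominated by partition noise, and the monotone trace loses meaning. The
`resample_split = TRUE` option restores per-evaluation resampling for users
who prefer the unbiased-but-noisy variant. The k-NN inside the fitness is
an exact Euclidean majority-vote classifier with deterministic tie rules
(equal distances resolved by training row order; tied votes go to the first
factor level), implemented in-package so that runs are bit-reproducible and
the GA baseline can share the identical code path.

### Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| `ec` | 5 (%) | retains ~148 of 2944 fused columns; on the synthetic benchmark the entropy gap comfortably covers the planted signal |
| `t` | 0.5 | midpoint of the unit box: expected initial subset size $d_2/2$ |
| `lb`, `ub` | 0, 1 | symmetric unit box around the threshold |
| `ho` | 0.2 | 80/20 fitness holdout |
| `k` | 5 | conventional k-NN neighbourhood |
| `N`, `IMax` | 20, 30 | 620 fitness evaluations per run; converges on the benchmark while keeping a full 10-seed study in minutes on one CPU |
| `P`, `FADs`, `beta` | 0.5, 0.2, 1.5 | reference MPA constants |

All indices in the package (APIs, reports, index files) are 1-based, the R
convention; the CLI help says so explicitly.

## GA baseline and convergence comparison

The baseline is a textbook generational GA over binary chromosomes of
length $d_2$: tournament selection of size 2, uniform crossover
(`pc = 0.8`), per-bit mutation (`pm = 1/d_2`), elitism 1, and the same
fitness function and partition as ECMPA. Comparisons are aligned by
cumulative fitness evaluations, not iterations, so equal budgets mean equal
work; `compare_convergence()` refuses traces with different budgets. With
matched `N` and `IMax` both optimizers spend $N(I_{max}+1)$ evaluations.

## Preprocessing: HSI histogram equalization

Colour contrast enhancement equalizes intensity while fixing chromaticity:
convert RGB to hue–saturation–intensity with the standard geometric
formulas ($I = (R+G+B)/3$, $S = 1 - \min(R,G,B)/I$, hue from the acos
form), equalize the intensity plane, and convert back. HSI (not HSV) is
used throughout. Numerical conventions: gray pixels take $H = 0$, $S = 0$;
the acos argument is clamped to $[-1, 1]$; out-of-gamut values on the
inverse conversion are clipped to $[0, 1]$.

The equalizer is the classical CDF mapping on `levels` (default 256)
uniformly quantized bins: each value maps to the empirical CDF at its bin,
a monotone mapping that preserves pixel rank order. A constant channel is
the degenerate single-bin case and is returned unchanged. The mapping is
idempotent up to quantization: re-equalizing changes pixels by at most a
few quantization steps (the package tests assert 0.02), with the residual
coming from gamut clipping of the brightest pixels. Hue and saturation are
exactly preserved wherever no clipping occurs; clipping can only affect
pixels driven to the gamut boundary, which in cell-like images are the
bright, nearly achromatic background pixels.

## The synthetic data generator

`gen_feature_dataset()` emulates fused post-ReLU deep features:
half-normal (absolute-Gaussian) activations, a `sparsity` fraction (default
0.5, after the observation that many deep features are redundant or contain
zeros) of the noise columns shrunk to near-zero scale 0.01, and a small
planted set of informative columns whose class means are spaced `effect`
noise-SDs apart. The default benchmark (n = 500, D = 2944, 40 informative,
5 balanced classes named after the five leukocyte subtypes, effect 3)
mirrors the scale of a fused 2944-feature table over a 5-class design.

What the generator does *not* emulate: correlations between activations of
the same backbone, heavy-tailed activation magnitudes, within-class image
structure, or label noise. Passing tests on this generator therefore show
that the selector recovers a planted low-dimensional signal embedded in
sparse half-normal noise — not that it reproduces any particular accuracy
on real stained-smear images.

A consequence of planting *redundant* informative columns (each one
separates the classes on its own) is that the wrapper cost saturates at
zero error for many different subsets; the optimizer then has no gradient
toward including *all* planted columns, and the selected set is a
sufficient rather than complete subset of the signal. Selection quality is
therefore judged by the holdout accuracy of the selected subset and by
exhaustive-search equivalence at small $d_2$, not by planted-index recall.

`gen_cell_images()` produces light-background images with a darker,
purple-hued elliptical nucleus. Pixel noise is a shared luminance jitter
(multiplying all three channels), the natural sensor-noise model that
leaves chromaticity piecewise-constant, so the hue/saturation-preservation
property of the enhancement stage can be asserted exactly.

## Statistical reporting

`anova_one_way()` delegates the decomposition to `stats::aov()` and
reports the SS/df/MS/F/p table; the all-constant 0/0 case is reported as
F = 0, p = 1 by convention so the routine is total. `f_pvalue()` is the
upper tail of the F distribution; for $d_1 = 2$ it equals
$(1 + F d_1/d_2)^{-d_2/2}$, a useful cross-check. Bartlett's test and the
Shapiro–Wilk test are delegated to the standard `stats` routines;
Bartlett's statistic is undefined for a zero-variance group and is raised
as an error.

The evaluation classifiers are the in-package k-NN and the e1071 SVMs
with kernels named `linear`, `quadratic` (polynomial degree 2, `coef0 = 1`),
`cubic` (degree 3, `coef0 = 1`) and `rbf`, regularization constant 1,
one-vs-one multiclass, no scaling (activations are already commensurate).
No hyperparameter search is performed.

## Problem sizes used by the test suite

The package's own studies run at: the full benchmark scale
(n = 500, D = 2944) for the selection, reduction and GA-comparison studies,
10 seeds each; d₂ = 8 with exhaustive enumeration of all 255 subsets for
oracle equivalence, 10 seeds; and n ≤ 500, D ≤ 200 for the remaining
property tests. A full 10-seed benchmark study completes in a few minutes
on a single CPU.

## Known limitations

* The entropy filter is unsupervised; a label-aware first stage (mutual
  information) is out of scope by design.
* The wrapper cost contains no subset-size penalty, so among zero-error
  subsets the selector has no preference for smaller ones.
* Box constraints only; no general constraint handling in the optimizer.
* The SVM kernels expose no hyperparameter search; they are evaluation
  baselines, not tuned classifiers.
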