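---
title: "Cross-platform normalization with NDEG references: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform normalization with NDEG references: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnorm)
```

## The problem

Microarrays and RNA-seq measure the same transcriptome on incompatible
scales: probe intensities and (for RSEM-style quantification) estimated
counts differ in dynamic range, skew, and in a roughly monotone
platform-specific distortion. A classifier trained on one platform therefore
transfers poorly to the other unless both matrices are first mapped onto a
common scale. `crossnorm` implements a protocol built around an idea
borrowed from experimental biology's housekeeping genes: use
**non-differentially expressed genes (NDEGs)** — genes whose expression does
not vary across the class labels — as the reference set that anchors the
normalization, and **differentially expressed genes (DEGs)** as the
classifier features.

## Gene selection by one-way ANOVA

For each gene, samples are grouped by class label and the classic variance
ratio is computed:

$$F = \frac{\mathrm{MSB}}{\mathrm{MSW}}
    = \frac{\sum_i n_i(\bar Y_i - \bar Y)^2 / (k-1)}
           {\sum_i \sum_j (Y_{ij} - \bar Y_i)^2 / (N-k)},$$

with the p-value taken from the upper tail of the $F(k-1,\,N-k)$
distribution. Genes with $p < \tau_{\mathrm{DEG}}$ (default 0.05, strict
inequality) become features; genes with $p > \tau_{\mathrm{NDEG}}$ (default
0.95, strict) become normalization references. Constant genes are assigned
$(F=0,\,p=1)$ rather than dropped, so they remain NDEG candidates; a gene
with zero within-group variance but non-zero between-group variance gets
$(F=\infty,\,p=0)$. Optional multiple-testing correction uses
Benjamini–Hochberg step-up (`stats::p.adjust`), thresholding q-values
instead of p-values.

Selection runs on the **training platform's full labelled sample set**, once
per direction, before partitioning — mirroring the protocol's stage order —
and the training-derived DEG/NDEG lists are used for both platforms. The
alternative (per-platform gene sets) would make the feature space depend on
the test platform's labels, which the harness forbids.

## The nine normalization schemes

Five schemes need no reference genes:

* **LOG** — $x \mapsto \log_2(x + c)$, pseudo-count $c = 1$ by default.
  Negative input is rejected as a sign the data are already logged.
* **Z** — per-gene standardization with the population SD (ddof 0);
  constant rows map to zero.
* **NST** — per-gene rank $\to$ percentile $\mathrm{rank}/(n+1)$ $\to$
  standard-normal quantile (rank-based inverse normal transformation).
* **NPN** — the same rank machinery with a selectable target; the normal
  target reproduces NST exactly, the uniform target returns percentiles.
* **QN** — classic quantile normalization: the target at each rank position
  is the cross-sample mean of position-sorted values.

Four reference-based composites use the NDEG list:

* **LOG_RQN** — log2, then reference-based quantile normalization: the
  sorted NDEG values of each sample are averaged position-wise into a
  target vector of length $m$, and *all* genes are percentile-mapped onto
  it.
* **LOG_RQN_Z** — LOG_RQN followed by a per-gene z-score.
* **LOG_NPN_Z** — the same percentile mapping onto the NDEG reference
  distribution, followed by a z-score (kept as a named variant because the
  protocol composes it separately).
* **LOG_NICG_Z** — log2, subtract each sample's mean over the NDEG
  (internal control) rows — division by the geometric-mean control signal on
  the linear scale — then z-score.

### Numerical conventions

Ties receive average ranks everywhere; tied QN values receive the mean of
their tied target positions. Quantile-function interpolation places the
value of rank $r$ among $G$ at $u = (r - 0.5)/G$ and target position $j$ of
$m$ at $(j-0.5)/m$, with linear interpolation in between
(`stats::approx`) and clamping beyond the end positions; this convention
avoids $\pm\infty$ at the extremes, and makes RQN with reference = all
genes coincide exactly with QN when $G = m$. Inverse-normal scores use
$\mathrm{rank}/(n+1)$ for the same reason. A reference target of length 1
cannot be interpolated and is rejected.

### Who fits on whose samples

Per-gene transforms (Z, NST, NPN) and plain QN are inherently per-dataset:
each matrix is transformed with its own samples. For the quantile-mapping
composites the package fits the reference target **once on the training
samples and shares it with the test platform**. This is deliberate: if each
platform fit its own target, a monotone platform distortion would survive
intact in each platform's own units (a power distortion scales the NDEG
quantiles along with everything else), and the two normalized matrices
would remain offset. Mapping both platforms onto the single
training-derived target is what actually places them on a common scale —
the frozen-reference idiom — and uses no test-platform statistics at
training time. The module surface still allows per-matrix fitting
(`normalize_expression()` refits on its input when no pre-fitted target is
supplied); the harness always shares the training target.

## Partitioning and the cross-platform protocol

Training samples are drawn per class as $\lfloor 0.75\,n_c \rfloor$ without
replacement — the only rounding convention that reproduces training sizes
of 390 (from per-class counts 98/58/231/127/8) and 389 (96/58/231/127/8).
The test set is the *other* platform's sample list minus the training IDs,
so samples measured on both platforms never appear on both sides. A class
too small to contribute ($\lfloor 0.75 n_c\rfloor = 0$) produces a warning,
not an error. Tuning uses stratified 10-fold cross-validation: within each
class the training IDs are shuffled and dealt round-robin, so per-class
fold sizes differ by at most one. The whole split-tune-test cycle repeats
(default five times) with per-repeat seeds `base_seed + r - 1`.

## Classifiers and tuning

Five families sit behind one fit/predict-proba contract: linear/RBF SVM
(e1071), ridge multinomial logistic regression (glmnet), random forest
(ranger), gradient-boosted trees (xgboost) and a single-hidden-layer
perceptron (nnet). Grid search scores each configuration by the mean
weighted F1 across folds; ties go to the first configuration in enumeration
order, and the winner is refit on all training samples. Two mappings
deserve a note:

* **LR**: the C grid ($10^{-2}\ldots10$, 5 log-spaced points) maps to
  glmnet ridge penalties $\lambda = 1/(Cn)$; glmnet is fit down a short
  descending $\lambda$ path ending at the target (single small $\lambda$
  values do not converge reliably) and predictions are taken at the target.
  The solver axis of the original grids has no glmnet analogue.
* **MLP**: nnet supports one hidden layer, so the multi-layer shapes of the
  original grids become single-layer sizes {30, 50, 100} crossed with decay
  {1e-4, 1e-3}, early stopping replaced by the 500-iteration cap.

A `fast = TRUE` profile shrinks every grid to one point so the full
protocol runs at desk scale; the full grids (e.g. 729 XGB points) are the
defaults of `classifier_grid()`.

## Evaluation

Test-set predictions feed a fixed-class-order confusion matrix, from which
the package computes Cohen's kappa $(P_o-P_e)/(1-P_e)$, balanced accuracy
(mean per-class recall; absent classes contribute recall 0 with a warning),
macro specificity, support-weighted F1 and support-weighted one-vs-rest
AUC (Mann–Whitney formulation, tie-corrected). Repeats are summarized by
the composite

$$\mathrm{Evalue} = -100\,\bar\kappa\,\overline{BA}\,
  \ln\!\bigl(\max(\sigma_\kappa \sigma_{BA},\,\varepsilon)\bigr),$$

with sample SDs over repeats and $\varepsilon = 10^{-12}$ clamping
zero-spread runs to a finite value. The $\sigma$ terms are read as standard
deviations and the logarithm as natural: only that reading produces values
of the order of hundreds at realistic spreads ($\sigma \approx 0.01$–$0.05$);
variances or base-10 logs would require implausibly tiny spreads. The
statistic is monotone decreasing in $\sigma_\kappa\sigma_{BA}$ at fixed
positive means, so it prefers high-mean, low-spread configurations.

## The synthetic generator

`synthetic_design()` / `generate_cross_platform()` emulate the study
conditions so every stage is testable without external data: a latent
log2-scale expression matrix (gene baselines $\sim N(8, 2^2)$), planted
DEGs adding a $\pm\,\text{effect\_size}\times\text{noise\_sd}$ shift
(default 2 SD) to one randomly chosen class, independent per-platform
measurement noise ($\sigma = 1$ by default), platform A exponentiated
directly and platform B passed through a monotone distortion first (default:
log-scale scaling by $\gamma = 1.3$). The default class sizes
96/58/231/127/8 reproduce a 29:1 largest:smallest imbalance, and two extra
Basal samples exist on platform B only, exercising the variable-test-size
path. Defaults of 2000 genes with 200 planted DEGs keep a full
repeated-evaluation run in tens of seconds while leaving selection
well-powered.

Three generator choices are worth making explicit:

* Shifts are planted only in classes with at least 20 samples
  (`min_shift_class_size`), encoding the study condition that the planted
  signal is carried by classes large enough to detect it; an 8-sample class
  cannot reliably carry a 2-SD shift through a skew-misspecified
  linear-scale F-test.
* Each platform draws its own measurement noise around the shared latent
  signal, as two assays of the same sample would; with zero noise and no
  distortion the platforms are bitwise identical.
* `dropout_rate` defaults to 0: since cleaning drops any gene with a single
  missing value, per-entry dropout at realistic sample counts would remove
  nearly every gene; non-zero rates are intended for small matrices that
  exercise the cleaning rules.

What the generator does **not** emulate: count-based (negative binomial)
RNA-seq noise, probe-level microarray artifacts, correlated gene modules,
or batch structure within a platform. Passing tests on this generator show
the machinery is correct under a monotone distortion with independent
lognormal noise — not that the method wins on any particular real dataset.
One consequence of the lognormal tails is visible in the test suite: null
F-test p-values are exactly uniform only on the log scale, where the
generator's noise is normal, so the calibration check runs there, while the
pipeline itself — following the protocol's stage order — selects genes on
the raw training matrix.

## Problem sizes used in tests

The packaged tests run the full protocol on generated data at desk scale:
selection calibration on 5000 null genes, recovery and the cross-platform
benefit on the default 2000-gene design with the full 522-sample imbalanced
cohort, three repeats, the one-point fast grids, and a linear SVM for the
benefit comparison. These sizes are the package's chosen study conditions
for reproducible desk runs; the same functions scale to full grids and five
repeats by flipping `fast = FALSE` and `n_repeats = 5`.

## Known limitations

* The NDEG anchor assumes some genes are truly class-stable on both
  platforms; if the reference set is contaminated by class signal, the
  shared target reintroduces it into both matrices.
* RQN interpolation is piecewise linear between reference quantiles; with
  very small NDEG sets the target is coarse (and a singleton reference is
  rejected).
* Probability outputs of the linear SVM come from libsvm's internal
  cross-validation and are not bit-reproducible across sessions; predicted
  labels, kappa and balanced accuracy are.
* The harness does not correct class imbalance beyond stratification and
  the weighted-F1 tuning criterion, matching the protocol it implements.
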