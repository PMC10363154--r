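---
title: "Detecting differentially active features from density distributions"
author: "kldHaystack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially active features from density distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kldHaystack)
```

# The problem

Single-cell and spatial genomics experiments place samples (cells, spots,
pucks, bulk samples) in some coordinate space — a 1D pseudotime ordering, 2D
or 3D tissue coordinates, or a latent embedding such as principal
components — and measure, for each sample, the activity of thousands of
features: transcripts, proteins, accessible chromatin regions, or gene-set
scores. A basic exploratory question is which features are *differentially
active*: expressed or accessible in a biased subset of the space rather than
uniformly over it. Cluster-based tests answer a narrower question (different
between *these* predefined groups); methods tied to a particular data
distribution (e.g. counts) cannot accept proteins, scores or accessibility.
kldHaystack answers the general question without clustering samples and
without distributional assumptions on the activity values, which only need
to be non-negative and finite.

# The model

## Density on a grid

Let $s_i \in \mathbb{R}^d$ be the coordinates of sample $i = 1 \dots n$ and
$y_{f,i} \ge 0$ the activity of feature $f$ in sample $i$. Each coordinate
dimension is first standardized to mean 0 and standard deviation 1 (sample
sd), so distances are comparable across dimensions of different numeric
range. Zero-variance dimensions are centered and kept as zeros so column
indices remain stable.

The distribution of samples in the space is summarised at $g$ *grid points*
(default $g = 100$). Grid points are the centroids of a k-means clustering
of the coordinates: this spreads them roughly uniformly over the occupied
part of the space while leaving empty regions empty, which classical
space-filling designs do not guarantee in high dimensions. The clusters
themselves are discarded; only the centroids matter. Alternatives are the
k-means++ seeding rule alone (cheaper, no Lloyd iterations) or user-supplied
grid coordinates. In the limit $g = n$, every sample is its own centroid,
which is also what is returned when a user requests more grid points than
there are samples (with a warning).

The Gaussian kernel bandwidth $h$ is the median over samples of the
Euclidean distance to the nearest grid point; normalized distances are
$\mathrm{dist}_{ij} = \lVert s_i - g_j \rVert / h$ and the *density
contribution* of sample $i$ to grid point $j$ is

$$ d_{ij} = \exp\!\left(-\mathrm{dist}_{ij}^2 / 2\right) \in (0, 1]. $$

Because $h$ rescales with the data, $d_{ij}$ is invariant under rigid
rotations and uniform rescalings of the space. If every sample coincides
with a grid point ($h = 0$) the geometry is degenerate and an error asks
the user to reduce $g$.

## Reference and feature distributions, divergence

The reference distribution is the normalized total density,
$Q_j \propto \sum_i d_{ij}$, strictly positive in every bin because the
Gaussian kernel never vanishes. Each feature's activity-weighted analogue
is $P_{f,j} \propto \sum_i d_{ij}\, y_{f,i}$. The test statistic is the
Kullback–Leibler divergence

$$ D_{KL}(f) = \sum_{j=1}^{g} P_{f,j} \log\!\frac{P_{f,j}}{Q_j}, $$

with natural logarithm and $0 \log 0 := 0$. If activity is unrelated to
position, $P_f \approx Q$ and $D_{KL}(f) \approx 0$; localized activity
inflates it. $D_{KL}$ is invariant to positive rescaling of a feature's
activity (normalization absorbs the scale), so counts, CPM or scores give
the same statistic up to their shape. All features are processed in one
sparse-capable matrix product (activity × density) followed by row
normalization; this is numerically identical to the per-feature definition
and is what makes scans over tens of thousands of features cheap. All-zero
features have no defined $P_f$; they are flagged `all_zero` and reported as
NA rather than dropped, so output rows stay aligned with the input.

## Significance: CV-stratified permutation null with spline calibration

Permuting a feature's activity across samples destroys any position link
while preserving its marginal distribution, so permutation $D_{KL}$ values
form the natural null. Permuting every feature is wasteful; instead the
null is *calibrated across features* through the coefficient of variation
$\mathrm{CV} = \mathrm{sd}/\mathrm{mean}$, which determines how dispersed a
feature's mass is and hence how large its null divergences run.

A panel of reference features (default $m = 100$) is chosen spread evenly
over the observed CV range — by default spacing targets on the $\log$ CV
scale, the scale the curves are fitted on (linear spacing is available as a
switch). Each reference feature is permuted (default 100 times,
independently per feature) and its null $\log D_{KL}$ values are summarised
by their mean and standard deviation; $\log D_{KL}$ under the null is
approximately normal. Two spline regressions then model these moments as
functions of $\log \mathrm{CV}$: natural cubic splines with degrees of
freedom selected from 1–10 by tenfold cross-validation (B-splines search
degree 1–5 as well, with df ≥ degree), minimising mean squared prediction
error, independently for the mean and sd curves. Folds come from a seeded
shuffle of the panel. Among candidates whose CV errors tie to within
numerical noise the least flexible wins, so featureless reference
statistics select df = 1 rather than an arbitrary overfit.

For any feature, the fitted curves predict $\hat\mu$ and $\hat\sigma$ of
its null $\log D_{KL}$ from its $\log \mathrm{CV}$, and

$$ z_f = \frac{\log D_{KL}(f) - \hat\mu}{\hat\sigma}, \qquad
   p_f = \Pr(Z > z_f), $$

an upper-tail normal probability: only *excess* divergence is significant,
there is no "significant depletion". The p-value is computed in log space
throughout (`pnorm(..., log.p = TRUE)`), so values such as $10^{-300}$ and
far beyond remain finite and comparable — essential because strong spatial
features in large datasets routinely reach such magnitudes.
Benjamini–Hochberg adjustment is also carried out on the $\log_{10}$ scale
for the same reason; the unadjusted value is the primary output, the
adjusted one is provided as plumbing. Features are ranked by increasing
$\log_{10} p$ (ties broken by input order).

# Numerical and degenerate-input choices

* **Kernel underflow.** Mathematically $d_{ij} > 0$ always, but
  $\exp(-\mathrm{dist}^2/2)$ underflows to exactly 0 in double precision
  beyond normalized distance ≈ 38.6. The kernel is floored at the smallest
  positive normal double, restoring strict positivity of $Q$ so
  $\log Q_j$ is always defined.
* **Predicted sd floor.** $\hat\sigma$ is floored at $10^{-6}$; a zero or
  negative predicted sd (possible for a flexible spline at the edge of the
  span) would make $z$ undefined.
* **Extrapolation.** $\log \mathrm{CV}$ values outside the reference span
  are clamped to the span boundary, with a warning. Splines extrapolate
  poorly; clamping is conservative.
* **Flags.** `all_zero` features get NA p-values and no rank; features with
  zero CV or zero divergence (constants) are flagged `zero_cv` with
  $p = 1$ and ranked after all `ok` features. Ranks over `ok` features are
  always a permutation of $1..n_{ok}$.
* **Reference dropouts.** A reference feature whose permutation replicates
  are (almost) entirely zero carries no information about the null spread
  and is dropped with a warning; if fewer than 12 usable reference features
  remain the fit refuses (tenfold cross-validation needs headroom).
* **Determinism.** One master seed drives grid k-means, fold assignment and
  per-reference-feature permutation streams (derived as seed + feature
  index). Identical inputs and seed give byte-identical result files.

# Downstream summaries

**Gene-set scores.** Sets are read from GMT; sets with fewer than 10
members present (configurable) are excluded with a log message. The score
of a set in a sample is the mean of its members' max-normalized activities,
min-max rescaled to $[0,1]$ per set — directly usable as an activity matrix
for a second scan, which turns the feature-level machinery into a
pathway-level one. This is deliberately *not* a re-implementation of
Seurat's `AddModuleScore` (no expression-bin-matched control subtraction);
it is a simpler documented score capturing average member activity, which
is all the scan requires of it.

**Module clustering.** The $P_f$ profiles of the top-ranked features
(default top 1000) are clustered into modules: k-means with a fixed seed
(the convention for pseudotime trajectories, where $k = 6$ modules is a
common choice for visualization), or hierarchical clustering with
correlation distance ($1 - r$) and average linkage, returning the
dendrogram order plus a $k$-cut labelling (used for grouping high-scoring
gene sets by spatial similarity). Profile-based clustering is used rather
than smoothed raw expression: the profiles are already the
density-normalized objects the test itself ranks on.

# The synthetic-data generator

`makeCoords` and `makeActivity` generate datasets with known ground truth.
Coordinates emulate three archetypes: well-separated Gaussian blobs
(cluster-structured latent spaces; centers drawn with a minimum-separation
rule so the true partition is recoverable), a uniform hypercube, and a
sorted 1D pseudotime in $[0,1]$. Planted features have intensity
$\lambda_i = b + A \exp(-\lVert s_i - c\rVert^2 / 2w^2)$ with the bump
center $c$ drawn from the sample coordinates themselves (so effects are
never planted in empty space), and Poisson (UMI-like, the default) or
log-normal (normalized-expression-like) noise. Null features reuse the same
intensity construction but permute the surface across samples before
drawing noise: their marginal level distribution matches the planted
features exactly, yet activity is exchangeable across samples — the
construction on which the calibration tests rest.

Defaults are baseline $b = 0.5$, amplitude $A = 2$ and width $w = 1$ (in
raw coordinate units): a fivefold peak over baseline about as wide as one
blob, a moderate, realistic effect for count data of this sparsity — strong
effects in the test suite use $A = 4$, the top of the dose ladder
$\{0.5, 1, 2, 4\}$ over which mean divergence rises monotonically. The
generator does **not** emulate dropout beyond Poisson sparsity, batch
effects, doublets, or gene–gene correlation; tests passing on it show the
statistical machinery is correct and calibrated under exchangeability, not
that any particular real tissue behaves this way.

# Problem sizes used by the test and acceptance runs

The package's own checks run at desk scale, chosen to make the statistical
properties measurable with comfortable margins: calibration on 2,000
exchangeable null features over 1,000 samples; planted-feature recovery
with 100 planted among 1,900 null features; permutation agreement against
10,000 direct permutations for five features spanning the CV range;
trajectory recovery with three pseudotime-localized patterns (width 0.07 on
a unit pseudotime, amplitude 4) among 540 nulls. The full-data applications
the method targets (10^5–10^6 samples) differ only in runtime, not in any
algorithmic branch.

# Known limitations

* Two-condition contrasts (e.g. wild-type vs knockout) are out of scope;
  the scan is a one-sample test against the pooled reference density.
* The p-value ranking of *signal-free* features is sampling noise and is
  not reproducible across grid resolutions — only features with genuine
  structure keep their ranks when $g$ changes. Stability claims should be
  read as claims about detected features.
* The CV-calibrated null assumes permutation nulls vary smoothly with CV;
  feature classes with wildly different marginal shapes at the same CV
  (e.g. a mix of binary and continuous features) are better scanned
  separately.
* The gene-set score is a simplified mean-of-members summary, not Seurat's
  control-matched module score.
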