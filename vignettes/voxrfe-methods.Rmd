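---
title: "Methods: spatially constrained SVM-RFE for 3D brain volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially constrained SVM-RFE for 3D brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedure it
implements, the choices that were genuinely open, and what its synthetic
validation does and does not establish.

## The classification problem

Each subject contributes one positive-valued 3D volume (e.g. a regional
cerebral blood flow map from perfusion SPECT) on a common grid, typically
after co-registration and spatial normalization done upstream. With a
brain mask of $N$ voxels and $M$ subjects in two groups, the data are a
subjects $\times$ voxels matrix; every in-mask voxel is one classifier
feature. $M \ll N$ by two to three orders of magnitude, so the whole
design is a fight against that imbalance: aggressive blind screening,
then a spatial-coherence constraint, then margin-based elimination.

Two normalizations are assumed. Rows are divided by their within-mask
mean (`whole_brain_normalize()`), removing global flow/uptake differences
between subjects; this makes effects *relative* (a 15% regional change is
15% whatever the subject's global level). Columns are mapped to
$[-1, 1]$ by min–max scaling fitted on training data only
(`minmax_scale()`); test values may fall outside $[-1, 1]$ and are not
clipped, and constant training columns map to 0.

## Information-gain screening

`information_gain()` discretizes one voxel's values by recursive binary
splitting on the sorted values, accepting a cut only when it passes the
Fayyad–Irani minimum-description-length criterion, and returns
$IG = H(y) - \sum_b \frac{n_b}{N} H(y \mid b)$ in bits. If no cut is ever
accepted the gain is exactly zero. `ig_filter()` keeps the voxels with
strictly positive gain.

The MDL stopping rule is a deliberate design decision. A plain
entropy-based gain over all cut points is positive for almost any
feature, which would screen out nothing; only a sparsity-inducing
acceptance rule produces the observed behaviour of such screens in
practice — a few percent of voxels surviving. Two implementation details
matter for correctness: cuts are admissible only between distinct values
(tied values always share a bin), and all logarithms are base 2 with
$0 \log 0 := 0$. The gain therefore depends only on the ordering of the
values, making it invariant under strictly monotone transforms; the test
suite asserts this, and checks the implementation against an independent
exhaustive-cut-point oracle on small fixtures.

The Lilliefors screen (`normality_screen()`) is descriptive only: it
reports the fraction of voxels whose within-class distributions fail to
reject normality. It motivates using an order-based screen and rank-sum
cluster p-values rather than gating anything.

## Spatial clustering on the voxel lattice

`grid_dbscan()` is a single-pass DBSCAN specialised to integer voxel
coordinates with $\epsilon = \sqrt{2}$ and $MinPts = 2$ (the
neighbourhood count includes the voxel itself). Under these defaults a
voxel is a core point iff it has at least one neighbour at Euclidean
distance $\le \sqrt 2$ — the 18-neighbourhood of faces (distance 1) and
edges (distance $\sqrt 2$), excluding corners (distance $\sqrt 3$) — and
the labeling provably equals connected components of the 18-adjacency
graph. The test suite asserts that equivalence against a brute-force
component oracle on hundreds of random universes. We interpret
$\epsilon = \sqrt 2$ as "distance $\le \sqrt 2$": face-adjacent voxels
necessarily qualify under the stated radius even though prose
descriptions of edge-sharing neighbourhoods sometimes elide them.

Cluster IDs are canonical — decreasing size, ties broken by the smallest
member coordinate in x-fastest scan order — so labelings are bit-stable
under permutation of the input, which keeps traces and reports
diff-able. `size_filter()` drops noise voxels and clusters below
`min_cluster_size` (default 20 voxels).

### Calibrating the cluster-size threshold

`estimate_cluster_threshold()` reproduces the classical Monte-Carlo
cluster-extent logic: simulate white Gaussian noise on the grid, smooth
it to the assumed noise smoothness (FWHM in voxels), variance-normalize
per voxel so the field is exactly unit variance everywhere (this removes
boundary attenuation bias), threshold two-sidedly at the voxel-level
$p$, and record the maximum connected cluster size inside the mask under
the *same* $\le\sqrt2$ adjacency the pipeline uses. The returned $k$ is
the smallest cluster size whose occurrence frequency is at most the
family-wise $\alpha$.

The default retention threshold of 20 voxels is consistent with this
simulation at the package's reference configuration: the standard MNI
field of view at 4 mm acquisition-resolution voxels (a 40×48×35 grid),
noise smoothness 10 mm FWHM (2.5 voxels), two-sided voxel $p = 0.002$,
$\alpha = 0.01$. Users should recalibrate for their own grid: the result
is *extremely* sensitive to the assumed smoothness expressed in voxels.
At this grid, assuming 8 mm instead of 10 mm moves the threshold from the
high twenties to the high teens, and running the same simulation on a
2 mm grid with 10 mm smoothness (5 voxels FWHM) yields thresholds near
two hundred 2 mm voxels. A 20-voxel rule is therefore only meaningful
together with the voxel size and smoothness it was derived under.
One-sided thresholding at the same $p$ gives a single suprathreshold
field of twice the density and raises the threshold; we keep the
two-sided convention because group differences of either sign are of
interest.

## SVM grid search and recursive elimination

The parameter grid (`svm_param_grid()`) spans four kernels (linear,
radial, polynomial, sigmoid) and two formulations (C-SVM, ν-SVM) with
C ∈ {2, 4, 10, 12, 15, 20}, γ ∈ {0.001, …, 0.1}, degree ∈ {3…7},
coef0 ∈ {0.01, …, 20}, ν ∈ {0.2, 0.29, 0.4, 0.5}; only the parameters
relevant to a kernel/formulation pair vary, so the full grid has 2,590
distinct points in a deterministic order. Fits go through the libsvm
binding (`e1071::svm`), with the polynomial kernel
$(\gamma \langle x, x'\rangle + c_0)^d$.

Each iteration of `voxrfe()` scores every grid point by stratified
k-fold cross-validated F-measure on the active voxels (recall breaks
ties, then grid order), ranks voxels by $|w_j|$ from a linear C-SVM fit
on all active voxels (ranking cost defaults to 1 — the evaluation kernel
never influences the ranking), and eliminates the $R = 100$ weakest,
ties broken by ascending column index. Iterations continue until at most
$R$ voxels remain after an evaluation or clustering empties the set, so
the loop always ends within $\lceil n/R \rceil + 1$ iterations with
strictly decreasing voxel counts.

The best iteration maximizes cross-validated F-measure with ties broken
by recall and then by the *earliest* iteration — the largest spatially
supported voxel set among equals. We considered the opposite (parsimony)
rule; preferring the earliest tie is consistent with the
first-encountered convention used for parameter ties and keeps the full
spatial extent of the discriminative regions in the report, which is the
scientific deliverable.

### Selection leakage, and the nested mode

In the default protocol the information-gain screen and the elimination
loop see **all** subjects; cross-validation only scores parameter sets.
This mirrors classical practice when the goal is region discovery, and
it is optimistic: on pure-noise cohorts the selected voxels classify the
very subjects they were selected on far above chance. The package
therefore also provides `nested_cv()`, which re-runs the *entire*
selection inside each outer training fold and predicts the untouched
held-out subjects. The null-calibration test uses the nested mode —
chance-level performance on effect-free cohorts is a property only the
leakage-free protocol can have — and any generalization claim should be
based on it.

## Evaluation conventions

`stratified_folds()` deals each class's shuffled subjects round-robin,
remainders to the currently smallest folds: fold sizes differ by at most
one and per-fold class counts are within one of proportionality (for
93 + 69 subjects and $k = 10$: eight folds of 16 and two of 17).
Confusion metrics are pooled over held-out predictions by default;
per-fold averaging is available but unstable at small fold sizes. The
positive class is the disease class; precision, recall (= sensitivity),
specificity and F default to 0 on zero denominators. Leave-one-out is
the exhaustive $k = N$ case with pooled counts.

## The synthetic cohort generator

`generate_cohort()` builds, per subject,
$\text{baseline} \cdot (1 + s \cdot \text{effect} \cdot \mathbf{1}[\text{cluster}]) + \mathcal N(0, \sigma)$,
then smooths with a normalized separable Gaussian kernel, masks and
flattens. Effects are multiplicative on a positive baseline because
whole-brain normalization preserves relative effects; smoothing is
applied after effect and noise, mimicking acquisition smoothing of real
data; planted clusters are lattice balls (radius ≥ 2 gives ≥ 33 voxels,
comfortably above the 20-voxel retention rule), pairwise non-adjacent so
they remain distinct components.

Defaults describe a perfusion-map study at acquisition resolution:
40×48×35 grid of 4 mm voxels, ellipsoidal brain-scale mask (~30,000
in-mask voxels), baseline 50 (the order of grey-matter rCBF in
ml/100 g/min), raw noise σ = 30 before smoothing — i.e. roughly 8%
between-subject variability per voxel after 10 mm smoothing — effect
size 15%, 20 subjects per group, and a 0.9 positive-sign mix (regional
increases dominating, as is typical for stimulant-dependence cohorts).
The generator is deterministic: the full cohort is a pure function of
its config, including the seed.

What it does *not* emulate: vascular texture, scanner noise spectra,
motion, partial-volume effects, inter-subject anatomical variability, or
registration error. Passing the recovery tests therefore shows the
pipeline recovers compact smooth multiplicative effects under Gaussian
noise — not that it would survive the artefact structure of real SPECT.

### What the validation suite computes

The test suite runs, among unit oracles: (a) a null calibration — twenty
effect-free cohorts (40×48×35, 20 + 20 subjects), each evaluated with
5-fold `nested_cv()`, asserting the mean pooled F-measure is within
three standard errors of the balanced-chance level 0.5; (b) a signal
recovery check — three seeded cohorts with 30% effects in three
radius-4 balls, asserting best-iteration Jaccard overlap with ground
truth above 0.3 and cross-validated F ≥ 0.9. Radius 4 (not the default
3) is used for recovery because ground truth is defined *before*
smoothing: the smoothing halo around a planted ball carries genuine
discriminative signal, and for balls comparable in size to the kernel
the halo alone caps the achievable Jaccard near 0.3 regardless of
selection quality. These runs use the linear C-SVM sub-grid; grid
breadth is a model-selection concern orthogonal to the properties being
asserted, and the reduced grid keeps each pipeline run to seconds.

## Numerical and degenerate-case choices

* Matrix orientation is subjects × voxels (the estimator convention);
  voxel columns enumerate the mask in x-fastest scan order, so column
  indices are reproducible across runs. Coordinates are 0-based lattice
  indices; world coordinates come from the affine only for reporting.
* Non-finite voxel values inside the mask, nonpositive whole-brain
  means, geometry mismatches, duplicate/missing labels, and a training
  fold missing a class are hard errors, never silent repairs.
* A cohort whose screen or clustering leaves no voxels yields a fit
  object with an explicit status flag (`no_voxels_after_ig`,
  `no_clusters`) rather than an error; the CLI turns those into nonzero
  exits.
* All randomness (fold shuffles, cohort simulation, noise fields) is
  derived from explicit integer seeds through a private RNG scope that
  never disturbs the caller's RNG state.
* The cluster-extent simulation refuses `alpha < 1/n_iter` (the tail
  would be unresolvable) and counts isolated suprathreshold voxels as
  extent 1.

## Known limitations

* The default protocol's cross-validated figures are optimistic by
  construction (see the leakage discussion); use `nested_cv()` for
  honest generalization estimates.
* The information-gain screen is univariate; voxels informative only in
  combination are invisible to it.
* The 20-voxel cluster rule is not portable across voxel sizes or
  smoothness levels; recalibrate with `estimate_cluster_threshold()`.
* ν-SVM grid points can be infeasible for strongly imbalanced cohorts
  (libsvm raises an error, which is surfaced with the parameter set
  attached rather than skipped).
* Atlas labeling assigns each cluster by its centroid voxel only.
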