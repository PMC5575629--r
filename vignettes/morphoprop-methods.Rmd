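---
title: "Semi-supervised MRI classification with morphoprop: models and methods"
author: "morphoprop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised MRI classification with morphoprop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early-stage cognitive decline (very mild to mild Alzheimer's disease,
CDR 0.5–1) produces measurable gray-matter (GM) atrophy in structural
MRI long before clinical certainty, but expert diagnostic labels are
expensive: in a realistic screening cohort only a small fraction of
subjects have confirmed diagnoses. morphoprop addresses this with a
*transductive* classifier: given registered GM probability volumes for
all subjects and diagnoses for a labeled subset, it spreads those
labels over a similarity graph connecting every subject, so the
geometry of the *unlabeled* subjects' features participates in their
own classification.

The pipeline has four stages, each exposed as ordinary functions so any
stage can be replaced or inspected:

1. **VBM-style feature extraction** — locate voxels where the two
   diagnostic groups differ and read each subject's GM values there;
2. **PCA compression** with a cumulative-energy rule;
3. **graph construction** — a Gaussian-kernel affinity matrix and its
   column-normalized transition matrix;
4. **clamped label propagation** — iterative or closed form — followed
   by per-row argmax decoding.

## Feature extraction from GM volumes

Input volumes are assumed spatially registered and segmented upstream
(for real data, the standard SPM-style preprocessing); the package
validates shape and voxel-size consistency only.

Each volume is smoothed with an isotropic Gaussian kernel of FWHM 10 mm
(`smoothGaussian`), the conventional choice for GM morphometry; the
per-axis standard deviation in voxels is
$\sigma_{vox} = \mathrm{FWHM} / (2\sqrt{2\ln 2}\,\cdot\, s)$
for voxel size $s$ mm. Smoothing uses separable banded convolution
operators with replicate (nearest-neighbor) boundary padding, so a
constant volume passes through unchanged and mask edges are not
darkened; kernels are truncated at $4\sigma$. An analysis mask keeps
voxels whose cohort-mean GM probability exceeds 0.1 (`makeGMMask`).

Within the mask, `voxelwiseTTest` computes the pooled-variance
two-sample t statistic per voxel (patients first, df $= n_1+n_2-2$).
Pooling matches the general-linear-model form used by the standard
neuroimaging packages; an unequal-variance option was considered and
rejected to stay aligned with that convention. P-values are two-sided
by default; `tail = "less"` gives the one-sided atrophy contrast
(patients below controls) for users who want the directional test.
Suprathreshold voxels ($p < 0.05$, *uncorrected*) are grouped into
connected components (`extractClusters`) under 6-connectivity by
default (18/26 available), and components are kept whenever they
exceed the extent threshold, whose default of zero keeps every
component. The uncorrected threshold is a deliberate simplification:
random-field-theory correction belongs to the upstream SPM machinery
and is out of scope here; consequences are discussed under
*Limitations*.

Feature vectors (`assembleFeatures`) read each subject's **unsmoothed**
segmentation values at every cluster voxel — smoothing informs *where*
to look, not *what* is read — ordered by cluster id and then
lexicographically by voxel coordinate (x, then y, then z; 1-based array
indices, the R convention). A flag-free design choice worth noting:
the t-test groups default to the full cohort's diagnoses, which is
transductively legitimate but lets test labels influence feature
*selection*. `runVolumePipeline(tTestSubjects = ...)` restricts the
contrast to a training subset when that leakage matters.

## PCA with cumulative-energy selection

`fitPCA` centers the feature matrix (optional standardization) and
takes the SVD — numerically preferable to forming the
$m \times m$ covariance when $m \gg n$, as here where $m$ is a voxel
count. All $\min(n-1, m)$ components are kept in the model with
variances on the $1/(n-1)$ convention; signs are fixed by making each
component's largest-magnitude loading positive, so results are
reproducible across eigen-solvers. `selectDimension(model, energy)`
returns the smallest $d$ whose leading components carry strictly more
than the requested fraction of total variance; the pipeline default is
0.99. On real imaging cohorts, where feature correlations are strong,
this rule selects far fewer dimensions than subjects; on synthetic
cohorts whose off-region variance is pure i.i.d. noise the spectrum is
flat and the rule selects close to full rank — both are correct
readings of the spectrum, and the
classifier is insensitive to the difference because the graph uses
distances, which full-rank PCA preserves.

## The affinity graph and transition matrix

Subjects become nodes; edge weights are

$$w_{ij} = \exp\!\left(-\frac{\lVert v_i - v_j\rVert^2}{2\sigma^2}\right)$$

for connected pairs, with $w_{ii} = e^0 = 1$. The default graph is
fully connected; a symmetrized k-nearest-neighbor mode is available
(edge kept iff either endpoint is among the other's $k$ nearest). The
self-loop has a visible consequence: the transition matrix has a
positive diagonal, so propagation is damped — each node always retains
part of its own current label mass.

The transition matrix normalizes **columns**:
$T_{ij} = w_{ij} / \sum_k w_{kj}$. Most label-propagation expositions
row-normalize; both are implemented (`buildTransition(rowNormalize =)`),
with column normalization the default because it is the definition the
propagation equations here are built on. With labeled subjects ordered
first, $T$ partitions into $T_{LL}, T_{LU}, T_{UL}, T_{UU}$ blocks.
`randomWalkMatrix` ($P = D^{-1}A$) is provided for diagnostics; the
solver does not use it.

## Clamped label propagation and its closed form

`initLabelState` builds the $n \times c$ matrix $Y$: labeled rows
one-hot, unlabeled rows uniform $1/c$ (the choice is immaterial — the
fixed point does not depend on it). The iterative solver repeats

1. $Y \leftarrow TY$;
2. normalize each row of $Y$ to sum 1;
3. reset labeled rows to their one-hot state (clamping),

until the largest elementwise change drops below `tol` ($10^{-8}$ by
default, `maxIter` $10^4$; at cohort sizes of order $10^2$ with dense
$T$ each sweep is microseconds, so generous caps cost nothing).

**A subtlety worth documenting.** Because every row of $Y$ sums to 1
entering step 1, row-normalizing $TY$ is algebraically identical to
multiplying by the row-renormalized matrix
$\bar T = T / \mathrm{rowSums}(T)$. The iterative procedure above is
therefore exactly the classical harmonic iteration with $\bar T$, and
its true fixed point is

$$Y_U = (I - \bar T_{UU})^{-1}\, \bar T_{UL}\, Y_L ,$$

whereas the commonly printed closed form uses the un-renormalized $T$:
$Y_U = (I - T_{UU})^{-1} T_{UL} Y_L$. The two coincide when
$T_{UU} = 0$ (after row normalization) and on symmetric
configurations, and differ elsewhere by an amount governed by degree
heterogeneity — small, but occasionally enough to flip the label of a
subject whose top-two class scores are nearly tied.
`propagateClosedForm` therefore exposes both:
`variant = "printed"` (default; the textbook equation) and
`variant = "harmonic"` (the exact fixed point of the iteration, which
matches `propagateIterative` elementwise to solver tolerance). Tests
assert elementwise agreement for the harmonic variant and document the
printed variant's behavior; neither is silently rewritten into the
other. Both solvers require the spectral radius of the unlabeled block
to be below 1 — guaranteed whenever unlabeled subjects retain
connectivity to labeled ones, and checked explicitly with an
actionable error otherwise (a too-small $\sigma$ can underflow the
kernel and disconnect the graph).

Decoding is per-row argmax; exact ties break toward the lowest class
index, deterministically, with a message when the rule fires.

## Experimental protocol

`crossValidateSigma` selects the bandwidth: a pool of 30 subjects is
drawn at random, split into 6 disjoint folds of 5; for each candidate
$\sigma$ each fold is scored by propagating the other 25 subjects'
labels to it, and the best mean fold accuracy wins (ties toward the
smaller $\sigma$). Candidates must lie in the open interval (0, 10);
the default grid is $\{0.05, 0.1, 0.25, 0.5, 1, 2, 5\}$. A candidate
whose kernel underflows scores `NA` and is never selected.
$\sigma$ is selected once and reused across evaluation splits rather
than re-cross-validated per split — cheaper, and the selection pool is
part of the protocol, not of any single split.

`repeatedSplitEvaluation` then draws `nRuns = 40` random training sets
of `trainSize = 25` subjects (stratified half-and-half; the reference
cohort is balanced 49/49), propagates, and averages accuracy,
sensitivity and specificity over runs — reported with standard
deviations, which the averages alone would hide. Per-run seeds derive
from the master seed by run index, so adding runs never reshuffles
earlier ones. `dimensionSweep` repeats the evaluation across PCA
dimensions with identical seeds for a controlled comparison.

## What the synthetic generator does and does not emulate

`generateVolumeCohort` builds a smooth ellipsoidal "brain" (GM
probability 0.8 inside, 0 outside, one light smoothing pass so the 0.1
mask threshold acts on a soft edge), subtracts a fixed effect inside
spherical "atrophy" regions for the patient class, adds i.i.d.
Gaussian voxel noise, and clips to [0, 1]. Defaults mirror the
reference study geometry: 49 subjects per class, 1-mm isotropic
voxels, effect 0.25 with noise SD 0.05 (a strong, cleanly detectable
contrast). A master seed expands to per-subject substreams through a
counter, so enlarging a cohort leaves earlier subjects bit-identical.

What it deliberately does **not** emulate: real cortical anatomy,
registration error, partial-volume effects, spatially *correlated*
noise, scanner artifacts, or subtle/diffuse atrophy. Passing the
end-to-end tests therefore demonstrates that the machinery — masking,
t-maps, clusters, PCA, graph, propagation, protocol — is implemented
correctly and recovers a known signal; it does not predict accuracy on
clinical data, where effect sizes are far smaller and feature noise is
structured. `generateFeatureCloud` (Gaussian blobs at a chosen
separation; standard interleaved two-moons in the first two axes,
remaining axes pure noise, `separation` unused for moons) isolates the
propagation stage from imaging entirely.

## Numerical choices and degenerate inputs

* Smoothing kernels truncate at $4\sigma$ and are renormalized, so
  operator rows sum to 1 exactly (constant-volume invariance is exact;
  volume-wide sums are preserved to well under 1% for interior-scale
  kernels).
* A voxel with zero pooled variance and zero mean difference yields
  $t = 0, p = 1$; zero variance with a nonzero difference (possible
  only in noiseless synthetic data) yields $t = \pm\infty, p = 0$.
  Both are counted and reported. The second rule is what lets a
  noiseless cohort's atrophy region be detected at all.
* Cluster ids are assigned by lexicographic order of each component's
  smallest voxel, making labels independent of voxel visiting order.
* Empty cluster sets (no suprathreshold voxel) warn and propagate an
  empty set; the pipeline stops with an explicit error rather than
  classifying on zero features.
* Duplicate subjects at distance 0 are legal (affinity 1).
* All randomness flows from explicit integer seeds through
  deterministic substream derivation; the entire pipeline is
  bit-reproducible for a fixed master seed.

## Problem sizes used in the test suite

The packaged tests run the full pipeline on a 49+49 cohort of
$32^3$ volumes with one spherical atrophy region (effect 0.25, noise
SD 0.05) — the reference geometry at a field of view just large enough
to hold the template and halo — and assert mean accuracy of at least
95% over 40 random 25-subject training splits, plus recovery of the
true region by the detected clusters. Solver equivalence is checked on
50 random instances with up to 30 nodes and 2–4 classes on both full
and kNN graphs. `scripts/acceptance.R` re-runs the same experiment
from scratch at a caller-chosen seed and writes the headline numbers
as JSON.

## Known limitations

* Default feature selection sees all diagnoses (transductive leakage
  into the t-test); use `tTestSubjects` for a leakage-free protocol.
* Uncorrected $p < 0.05$ voxel thresholds admit false-positive
  clusters; with smoothed noise these are large and numerous enough to
  dilute features in low-signal regimes. Multiple-comparison
  correction is out of scope.
* Dense $n \times n$ matrices throughout: intended for cohorts of
  order $10^2$–$10^3$ subjects, not $10^4+$.
* Binary classification is the tested path; the label machinery
  accepts any number of classes but the metrics module is two-class.
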