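---
title: "Embedded functional connectivity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedded functional connectivity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnembed)
```

## The problem

Resting-state fMRI has no task structure, so functional integration is
assessed through statistical dependencies between signal sources. When the
sources are subject-specific independent components (ICs), each subject is
summarized by an $M \times T$ matrix of component time courses ($M$
components, $T$ time points; here $M$ varies over subjects in 20--40 and
$T = 150$). A functional connectivity network (FCN) puts one node per
component and an edge wherever two components' time courses are strongly
related. `fcnembed` implements a pipeline in which the pairwise
(dis)similarity matrix is optionally passed through a manifold-learning
embedding before the graph is thresholded, on the premise that connectivity
structure may live on a low-dimensional nonlinear manifold that raw
pairwise metrics do not expose.

The pipeline has five stages, each exposed as ordinary functions on
matrices and tibbles:

1. **Reproducibility ranking** of repeated ICA runs (`raicar()` and
   friends), because single ICA realizations are stochastic.
2. **Distances** between component time courses: the lag-maximized
   cross-correlation pseudo-distance and the Euclidean distance.
3. **Embeddings**: classical MDS, ISOMAP, diffusion maps, Gaussian kernel
   PCA, and a distance-only locally linear embedding (LLE); then pairwise
   distances among the embedded coordinates.
4. **Graphs**: proportional thresholding to a binary FCN, largest
   connected component, and three global measures — average path length
   $L$, global clustering coefficient $C_g$, median degree $M_k$.
5. **Classification**: repeated stratified k-fold cross-validation of the
   three graph features with four classifiers, and a full
   method × metric × threshold sweep.

## Distance metrics

For time courses $A_i$, $A_j$ the cross-correlation function at lag $l$ is
estimated by averaging lagged cross-products over the $T-l$ overlapping
samples and normalizing by full-series (population) standard deviations.
The pseudo-distance is

$$d_c(i,j) \;=\; 1 - \max_{l = 0,\dots,3} |CCF(A_i, A_j, l)|,$$

with the maximum taken over both argument orders, equivalently lags
$-3,\dots,3$. Two numerical choices are deliberate:

* **Symmetry.** With only nonnegative lags in one argument order the
  matrix is not symmetric; every downstream stage (thresholding, MDS,
  heat kernels) assumes symmetry, so both orders are scanned.
* **Clamping.** The finite-sample normalization can push $|CCF|$ slightly
  above 1; it is clamped at 1 before the subtraction so $d_c \ge 0$.

The Euclidean metric is the plain $L_2$ distance between rows. $d_c$ is
invariant to per-row affine rescaling; $L_2$ is not — the two metrics
genuinely measure different things, which is why both are swept.

## Embeddings

All five methods consume only a distance matrix, so they compose with
either metric. Eigenvector signs are fixed (largest-magnitude entry
positive) so results are deterministic.

**Classical MDS** double-centers the squared distances,
$B = -\tfrac12 H D^2 H$ with $H = I - \tfrac1M \mathbf{1}\mathbf{1}^T$,
and uses the top-$p$ positive eigenpairs, $y = \sqrt{\lambda_j}\, v_j$.
With a Euclidean input this is exactly PCA. The cross-correlation
pseudo-distance is not Euclidean, so $B$ can have negative eigenvalues;
these are discarded and $p$ counts positive eigenpairs only (standard
classical-MDS practice).

**ISOMAP** builds the union-symmetrized $k$-nearest-neighbor graph,
replaces distances by shortest-path (geodesic) lengths, and applies MDS.
Shortest paths are computed over the edge *lengths* $d_{ij}$; the
reciprocal weights $1/d_{ij}$ sometimes quoted for neighbor graphs are
recorded on the graph but play no role in the geodesics, since the
quantity being minimized is a sum of distances. A disconnected graph is an
error carrying the component sizes — this is why the study grid starts at
$k = 3$; at the cohort level a subject whose graph is disconnected is
excluded (up to a 20% budget) rather than failing the whole configuration.

**Diffusion maps** converts distances to affinities with the heat kernel
$W_{ij} = \exp(-d_{ij}^2/\sigma)$, forms the row-stochastic operator
$P = K^{-1}W$ (with $K = \mathrm{diag}(\text{row sums})$) and its
symmetric conjugate $\bar P = K^{-1/2} W K^{-1/2}$, eigendecomposes
$\bar P$, maps back via $V = K^{-1/2}U$, drops the trivial pair
$(\lambda = 1, \text{constant})$, and uses coordinates
$\lambda_j^t v_j$. The diffusion time defaults to $t = 1$ and is exposed
as a parameter; $t$ only rescales axes by $\lambda_j^t$, a smooth
reweighting that leaves proportionally thresholded graphs largely
unchanged over $t = 0, 1, 2$. The diffusion
distance $\sum_m (P^t_{im} - P^t_{jm})^2$ compares the $t$-step
transition profiles of two nodes (the row-wise form; it is zero for
duplicated points).

The kernel scale $\sigma$ is selected from the data: the total affinity
$S_w(\sigma) = \sum_{ij} W_{ij}$ rises sigmoidally (against
$\log \sigma$) from $M$ to $M^2$; `select_sigma()` takes the median of
$S_w$ across subjects on a grid of 50 log-spaced points spanning
$[0.01, 100] \times \mathrm{median}(D^2)$, locates the maximum
central-difference slope, and reports the contiguous "linear region"
where the slope stays within 5% of that maximum.

**Kernel PCA** uses the Gaussian kernel
$K_{ij} = \exp(-d_{ij}^2 / 2\gamma^2)$, double-centers it
($K' = HKH$), and projects $K'$ onto its top-$p$ eigenvectors. The
per-subject default $\gamma$ is the median over rows of the row's minimum
off-diagonal distance — the typical nearest-neighbor scale. As
$\gamma \to \infty$ the kernel linearizes and the leading coordinates
converge to PCA scores; this limit is one of the package's standing
checks.

**LLE (distance-only variant).** Each point's local Gram matrix is
recovered from pairwise distances alone by centering on the point,
$G_{jl} = \tfrac12 (d_{ij}^2 + d_{il}^2 - d_{jl}^2)$; the reconstruction
weights solve $Gw = \mathbf{1}$, normalized to sum 1; the embedding comes
from the eigenvectors of $W' = (I-W)^T(I-W)$ for the $p$ smallest
*nonzero* eigenvalues (the zero eigenvalue with constant eigenvector is
discarded), scaled by $\sqrt{M}$ for unit covariance.

When points lie exactly on a low-dimensional patch the local Gram is
rank-deficient and needs a ridge. The package adds
$10^{-9}\,\mathrm{tr}(G)/k$ — and only when `qr()` reports rank
deficiency. A much larger ridge (the $10^{-3}$ factor often quoted)
perturbs the reconstruction weights enough that, amplified through the
small eigengap at the bottom of the LLE spectrum, exact-plane recovery
degrades from $\sim 10^{-7}$ to $\sim 10^{-1}$ affine residual; the tiny
ridge preserves exact local reconstructions while still making the solve
well-posed.

A separate caveat: on *irregularly sampled* flat patches the null space
of $W'$ can be larger than the expected $1 + p$ dimensions (constant plus
affine); the extra numerically-null mode mixes freely with the affine
ones and plane recovery then fails for any implementation. The recovery
checks therefore use a jittered grid — the well-sampled case the method's
own assumptions require.

**Embedding dimension.** All methods share the eigengap rule: sort the
usable eigenvalues (descending; ascending for LLE, where small
eigenvalues carry the signal), take consecutive differences, and pick the
position of the largest gap, clamped to $[2, 5]$. The floor of 2 reflects
that one coordinate rarely supports a meaningful graph; the cap of 5
reflects that observed spectra place their gaps within the first five
dimensions. Ties take the smallest dimension.

## Graphs and measures

Proportional thresholding keeps the $\lceil \mathrm{pt} \cdot
M(M-1)/2 \rceil$ smallest-distance pairs, so all subjects' graphs share a
density. The ceiling (rather than floor) guarantees nonempty graphs at
the 20% grid floor even for small $M$; ties at the cut break by a stable
(distance, node-pair) sort for cross-platform determinism. Edge sets are
nested in pt by construction. The default grid is 0.20--0.70 in steps of
0.02 (26 points): below 20% graphs fragment badly; above 70% the added
edges are weak connections.

If thresholding fragments the graph, all three measures are computed on
the largest connected component (ties take the component containing the
lowest node index). $L$ is the mean unweighted hop distance over ordered
pairs; $C_g$ is the transitivity ratio of closed to all triplets; $M_k$
is the median degree. Graph algorithms are delegated to igraph; the test
suite holds them to exact agreement with brute-force oracles
(Floyd–Warshall, $O(M^3)$ triplet enumeration, sorted-degree median).

## Reproducibility ranking of ICA realizations

Given $K$ realizations of an $M$-component decomposition, the
cross-realization correlation matrix (CRCM) holds the absolute spatial
correlations between all $MK$ maps. Alignment is greedy: seed a group
with the global maximum outside the diagonal blocks, extend it in every
other realization with the still-unused component most correlated (mean
of $|r|$) with the two seeds, and repeat $M$ times; ties break on the
lowest (realization, component) index so results are deterministic.

The correlation threshold is read off the histogram of upper-triangle,
off-diagonal-block entries: 50 equal bins on $[0,1]$, a 3-bin moving
average, and the valley between the two highest local maxima — taken as
the middle of the minimum plateau, since well-separated modes leave a run
of empty bins. When no second mode exists the threshold falls back to
0.5. Each aligned group's reproducibility index sums its supra-threshold
pairwise correlations, so it lies in $[0, K(K-1)/2]$ (435 at $K = 30$).
Components are kept when the index reaches half the maximum (217.5), and
a subject with fewer than 20 kept components is flagged for exclusion —
graphs that small fragment under thresholding. Selective averaging
flips members to the seed's sign and averages only members with at least
one supra-threshold correlation in the group; when mixing matrices are
present the same members' sign-aligned time courses are averaged too
(the time-course rule mirrors the map rule, a choice this package makes
explicit).

## The classification harness

Features are the triple $(L, C_g, M_k)$ per subject; the patient-like
group is the positive class. `repeated_kfold_cv()` draws stratified folds
fresh each repeat (class imbalance such as 57/47 makes unstratified folds
noisy), standardizes features by the training fold's own statistics,
tunes hyperparameters by a stratified 75/25 holdout grid search *inside*
the training fold, refits on the whole training fold, and scores the held
out fold. Nothing computed on validation rows ever reaches the model —
the label-permutation null sitting at 50% is the standing leak check.
Classifier internals are delegated behind a fit/predict contract:
linear-kernel and RBF-kernel SVMs (`e1071`), k-nearest neighbors
(`class`), and a single-hidden-layer network (`nnet`). Grids are small,
as fits three features: $C \in \{0.1, 1, 10\}$, RBF width
$\{0.1, 1, 10\}$ times the median heuristic, $k \in \{3,5,7,9\}$, hidden
units $\{3, 5, 8\}$.

`sweep_configurations()` crosses methods (plus the raw-matrix baseline),
metrics, parameter settings, the threshold grid and classifiers,
computing each subject's per-configuration distance matrix once and
reusing it across thresholds. For diffusion maps a single global
$\sigma$ comes from the cohort-level sum-of-weights rule unless
overridden (per-subject overrides are also supported). Failing subjects
are excluded per configuration up to the 20% budget; failing
configurations are recorded, not fatal. The best row per
method × metric is flagged, giving the familiar best-per-method report
layout.

## The synthetic cohort generator

Real IC time courses are not distributionally characterized, so the
generator is a stand-in built to exercise the pipeline's assumptions, not
a claim about fMRI statistics. Each subject draws a component count
uniformly from 20--40 and $T = 150$ time points. Components are grouped
into blocks; each block carries one smooth AR(1) latent signal
($\phi = 0.8$, unit marginal variance), and a member is

$$x = c \cdot \text{latent} + \sqrt{1 - c^2}\, \varepsilon +
\sigma_\text{noise}\, \eta,$$

so within-block correlation is approximately $c^2$ (attenuated by
measurement noise). The two groups differ only in coupling: defaults are
blocks of 5 at $c = 0.8$ (control-like) versus $c = 0.45$ (patient-like,
mimicking dysconnectivity), with $\sigma_\text{noise} = 0.2$. All
randomness flows from one integer seed through per-subject substreams, so
cohorts are bit-identical regardless of how they are consumed.

Realization stacks plant `n_reproducible` base maps into every
realization under a fresh random permutation, sign flip and Gaussian
jitter (mimicking ICA's order/sign indeterminacy and run-to-run noise),
and fill the remaining slots with fresh noise maps. Jitter SD 0.3 puts
pairwise planted correlations near $1/(1+0.3^2) \approx 0.92$.

**What passing tests do and do not show.** The generator produces
block-structured, stationary, Gaussian signals. Real fMRI components are
none of these things exactly (hemodynamic smoothness, artifacts,
nonstationarity), so green tests demonstrate that the pipeline's
machinery is correct and calibrated — not that any particular embedding
will win on real data. Indeed, on these synthetic cohorts the raw
cross-correlation matrix classifies near ceiling and the embeddings add
nothing: the block structure is directly visible in pairwise
correlations, so the real-data finding that diffusion maps outperform
the raw matrix is *not* reproduced here and should not be expected to
be.

## Problem sizes used by the checks

The standing verification suite runs RAICAR recovery on stacks of
$K = 30$, $M = 25$ (20 planted) at 800 voxels; embedding fidelity on
point clouds of 20--50 points; the CV harness on a 104-subject separable
cohort at 10-fold × 10 repeats; and the end-to-end sweep on 40 subjects
over the full 26-point threshold grid with the RBF-SVM. These sizes
exercise every code path at the component counts the pipeline targets
while staying desk-scale; the repeat count (10 rather than 100) only
widens the SD of accuracy estimates, not their means.

## Known limitations

* The $\epsilon$-neighborhood graph rule and Nyström out-of-sample
  extension are not implemented; neighbor graphs are k-NN only.
* The cross-correlation distance is a pseudo-distance (no triangle
  inequality); MDS on it relies on discarding negative eigenvalues.
* LLE on irregularly sampled flat manifolds can have a degenerate bottom
  spectrum (above); embedded coordinates are then not unique.
* Synthetic cohorts cannot arbitrate between embedding methods (above);
  they calibrate the machinery only.
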