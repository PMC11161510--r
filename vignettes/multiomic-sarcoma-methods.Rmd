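---
title: "Methods: radiomic and transcriptomic subtyping of soft-tissue sarcoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic and transcriptomic subtyping of soft-tissue sarcoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and rationale

`sarcomix` implements a complete multi-omic subtyping pipeline for locally
advanced soft-tissue sarcoma: harmonization of conventional MRI, handcrafted
and deep (autoencoder) radiomics, stability-based consensus clustering of
each feature space, survival modeling of the resulting groupings, and
differential expression between combined radiomic–transcriptomic groups.
Patient imaging of this kind is rarely public, so the package treats a
synthetic cohort generator as a first-class module: every statistical claim
the package makes is demonstrated on cohorts whose ground truth is planted
and known.

This vignette records the modeling choices, their assumptions, the defaults
and why they were chosen, what the synthetic data do and do not emulate,
and the numerical conventions in corner cases. It states no empirical
result beyond what the package's tests and acceptance script themselves
compute.

# MRI harmonization

Conventional MR signal intensities have no physical units and vary by
scanner, coil and protocol. The chain applied before any feature
extraction is, in fixed order:

1. **Resampling** to a common voxel size (default 1 × 1 × 4 mm, the usual
   anisotropic clinical resolution) by linear interpolation in physical
   space. Voxel centers are laid on a regular grid from the volume origin,
   preserving the physical extent to within one voxel.
2. **Bias-field correction.** Surface coils modulate intensities by a
   smooth multiplicative field. The estimator fits a polynomial (total
   degree 2 by default — one inflection per axis is enough for coil
   profiles at tumor scale) in the spatial coordinates to the in-mask
   log-intensities and divides it out, preserving the in-mask mean exactly.
   This is a deliberately transparent surrogate with the same contract as
   histogram-sharpening field estimators: it removes planted smooth
   multiplicative fields (the tests require a ≥ 5-fold reduction of the
   in-mask coefficient of variation) without iterative machinery.
   Non-positive inputs are shifted positive before the log and shifted
   back.
3. **Histogram matching** to a reference volume by monotone
   piecewise-linear quantile mapping (64 match points by default; the
   identity up to one quantization step when a volume is matched to
   itself). The reference is configurable; a cohort's first volume per
   channel is the natural choice when nothing else is specified. A
   constant reference yields a constant output at the reference value.
4. **Range rescaling** of [min, max] onto [−10000, 10000]; a constant
   volume maps to the lower bound (documented convention). The chain
   therefore ends exactly on that range for any non-constant input.

For texture analysis, in-mask intensities are **discretized** into 256
gray levels by min–max binning (levels 1..256, so logarithmic terms are
well defined); the binning is invariant to positive affine intensity
transforms, which makes every downstream texture feature invariant too.
The deep branch instead uses the **center slice**: the slice at the floor
of the mean of the first and last mask-bearing indices along the
through-plane axis, with out-of-mask pixels set to zero.

# Handcrafted radiomics

59 texture features per sequence and 4 shape features from the
contrast-enhanced mask, with the counts fixed to 13 (first-order) + 7 × 3
(co-occurrence at neighbor distances 1, 2, 4) + 11 (run length) + 3
(neighborhood gray-level difference) + 11 (zone length):

* Texture matrices aggregate the 13 unique 3-D directions; only voxel
  pairs fully inside the mask contribute; every matrix normalization sums
  to 1. Entropies use base 2.
* Degenerate matrices (a flat region, no valid pairs) return the neutral
  values of a constant image rather than NaN; the flat-region coarseness is
  capped at 10⁶ instead of dividing by zero.
* Zone labeling treats same-level 26-connected voxels as one zone; the
  implementation builds the adjacency graph and takes connected components
  (igraph), and is validated in the tests against an independent
  recursive flood fill, as the run-length and co-occurrence paths are
  validated against exhaustive pair/run enumeration on all 512 two-level
  3 × 3 × 1 images.
* Surface area for the shape features counts exposed voxel faces and
  multiplies by 2/3: axis-aligned face counting overestimates a smooth
  surface by exactly 3/2 in the fine-resolution limit (the integral of
  |n₁|+|n₂|+|n₃| over a sphere), so the corrected estimator makes the
  sphericity of a large digitized ball converge to 1. Compacity is the
  dimensionless V / (√π · A^{3/2}).
* GLCM correlation is reported from the *symmetric* co-occurrence matrix.
  On a discrete linear gradient restricted to its own direction this
  equals the correlation of the symmetrized lag-1 pair set — slightly
  below 1 at small sizes and converging to 1 with gradient length — which
  is what the tests assert via an explicit pair-set oracle.

Reproducibility filtering uses the intraclass correlation for a two-way
absolute-agreement single-measurement design — the strictest of the common
ICC variants, appropriate when the repeat segmentation is a systematic
factor — at the conventional threshold ICC ≥ 0.90 (boundary inclusive).
A zero-variance feature has an undefined ICC and fails the filter.

# Deep radiomics

The convolutional autoencoder operates on the background-zeroed,
[0, 1]-scaled center slice (default input 64 × 64). The encoder stacks
stride-2 convolutions with kernel 4 and padding 1 — this geometry halves
the spatial size exactly, so the transposed-convolution decoder mirrors it
without output padding — followed by a dense latent layer (default 1024
latent features, the deep-radiomics dimensionality). The decoder ends in a
sigmoid. Defaults: 4 blocks of 8/16/32/64 channels, Adam at 10⁻³ (an
optional cosine annealing to a tenth of the initial rate stabilizes final
reconstruction quality), batch size 32.

The loss is the reconstruction mean squared error on the [0, 1] scale,
optionally plus λ times the negative Cox partial log-likelihood (Breslow
ties) of a linear risk head on the latent vector, computed batch-wise.
λ = 0 recovers the plain autoencoder — CAE and HSCAE are literally one
code path — and λ > 0 ("half-supervised") tilts the latent geometry toward
survival-relevant image content. The Cox form was chosen over an
event-by-horizon cross-entropy because it uses the censored times directly
and matches the downstream survival analyses. Training uses repeated
random 90/10 holdouts (the leave-10%-out protocol; repeats configurable,
with 100 mirroring the reference protocol and 1 adequate at desk scale),
records the held-out MSE per repeat — the quality contract is a held-out
MSE below 0.01, i.e. "below 1%" — and optionally refits on all images.
Optional augmentation composes random flips, ±20° rotation, ±10% zoom, a
mild elastic deformation and ±5% intensity jitter; flips are exact index
reversals, and all augmentation is deterministic per seed.

Class-activation maps for the prognostic head weight each last-encoder
activation by the closed-form gradient of the risk output with respect to
it (the dense head makes this exact, no autodiff needed), sum over
channels, rectify, and upsample bilinearly to the input. With that
convention the map value is each location's additive contribution to the
predicted risk.

The whole network is implemented as vectorized base-R matrix operations
(im2col convolutions with cached gather/scatter index tables). This keeps
the package dependency-free on the deep-learning side and fully
reproducible: training is a pure function of (data, config, seed). The
backward pass is validated against finite differences in the development
history and indirectly by the loss-decrease and planted-signal tests.

# Consensus clustering

Each grouping (handcrafted radiomics, CAE and HSCAE latents, expression)
uses the same machinery: features are centered and scaled (population-SD
convention; zero-variance columns dropped with a warning), each of B
resamples retains a random 60% of subjects (i.e. 40% left out; B defaults
to 1000 in the function and 10,000 mirrors the reference protocol), each
subsample is clustered by average-linkage hierarchical clustering under
the Pearson distance (1 − correlation of feature profiles — note this sees
profile *shape*, not mean offsets), and consensus(i, j) is the fraction of
co-sampled resamples in which i and j co-cluster. Final labels cut the
average-linkage tree of 1 − consensus. Pairs never co-sampled (possible
only at very small B) are imputed at 0.5 with a warning.

**Number of clusters.** The classical delta-area criterion on the
consensus-CDF was implemented and evaluated first, but on cleanly planted
data the CDF area keeps growing by a roughly constant relative amount past
the true k (splitting a tight cluster still converts co-clustered mass
into ambiguous mass), so no fixed threshold separates true from overfit k.
Model order is therefore selected by the *proportion of ambiguously
clustered pairs* (PAC: consensus entries strictly inside (0.1, 0.9)): the
largest k with PAC ≤ 0.02 is chosen, else the k minimizing PAC; the CDF
areas remain available in the fitted model for inspection, and `k_fixed`
overrides selection. On planted well-separated blobs PAC is exactly zero
for every k up to the truth and rises sharply beyond it.

Clusters are renamed A, B, C… by decreasing size (ties keep the original
order), matching the convention that cluster A is the most numerous. New
observations are assigned by minimal Pearson distance to the stored
cluster centroids (per-cluster means of scaled features, with the scaler
stored in the model); exact ties go to the lexicographically first label.
Merge ties inside the hierarchical step follow `stats::hclust`'s
deterministic ordering.

# Survival and association statistics

Standard estimators delegate to the survival package: Kaplan–Meier with
Greenwood errors (set to 0 where S(t) = 0), log-rank, Cox partial
likelihood with Efron tie handling and Wald 95% intervals. Multivariable
models are complete-case with the dropped-row count reported. Backward
selection removes, at each step, the covariate whose removal most lowers
the AIC, stopping when no removal lowers it — by construction the final
AIC never exceeds the full model's. (A null covariate survives this
procedure whenever its likelihood-ratio chi-square exceeds 2, i.e. with
probability ≈ 0.157; the tests assert that theoretical rate rather than a
higher one.)

Harrell's concordance is implemented in-package with an explicit pair
convention: a pair is orderable iff the strictly earlier time is an event;
tied risk scores count 1/2; tied times are not orderable. The tests check
exact agreement with a brute-force pair enumeration. Cross-validated
concordance stratifies folds by event status (so no fold is event-free),
fits on the training folds, scores the held-out fold by linear predictor,
and summarizes fold values by mean and percentile interval. The bootstrap
comparison of two models resamples subjects with replacement, recomputes
both cross-validated concordances per replicate (same fold seed for both
models), and reports the doubled smaller tail proportion of the difference
distribution around zero — a two-sided percentile convention; degenerate
replicates are redrawn and counted.

Association tests follow the conventions under which the reference
cross-tabulations reproduce to four decimals: Pearson chi-square without
continuity correction for R × C tables, Yates-corrected for 2 × 2;
group-location tests are rank-based by default (Mann–Whitney with normal
approximation and tie correction for two groups, Kruskal–Wallis beyond),
with no normality gating. The nomogram-probability grouping cuts the
predicted 10-year overall survival at ≤ 0.51 / ≤ 0.66 / above; the
semantic radiophenotype is high-risk iff ≥ 2 of the 3 radiological flags
are present; the combined group crosses a radiomic with a transcriptomic
label and pools everything against the double-A (worst × worst) cell.

# Transcriptomics

Counts are voom-normalized (log₂-CPM with 0.5 offset and precision weights
from the fitted mean–variance trend, via limma under a group-means
design); batch correction is parametric empirical-Bayes location/scale
adjustment (ComBat via sva), the identity for a single batch, and refuses
single-sample batches. Differential expression is a per-gene Welch t-test
on log₂ expression (Welch rather than pooled because batch-corrected
groups need not share variances; a pooled option would be a trivial
extension), with a gene called only if its Benjamini–Hochberg-adjusted p
is below α = 0.05 *and* its absolute fold change reaches 2. Note the gate's
statistical consequence: a gene whose true fold change is exactly at the
gate is called only about half the time, so planted-recovery checks plant
log₂FC = 2 against the FC-2 gate. Degenerate per-gene variances are
floored at 10⁻⁸ and flagged. Enrichment is hypergeometric
over-representation of the called genes within each geneset intersected
with the tested universe, BH-adjusted across sets, with the activation
status reported as the proportion of the set's called genes that are
up-regulated.

The discriminant signature uses nearest shrunken centroids: standardized
class-versus-overall centroid contrasts d_kj = (x̄_kj − x̄_j)/(m_k (s_j + s₀))
with s₀ the median pooled within-class SD, soft-thresholded at Δ;
classification minimizes the standardized squared distance to the shrunken
centroids minus 2·log prior. Δ is chosen by cross-validation with the
one-standard-error rule (the largest Δ within one SE of the minimal CV
error — the sparsest model statistically indistinguishable from the best).
At Δ = 0 the classifier provably reduces to plain diagonal-covariance
nearest-centroid classification, which the tests verify against an
independent oracle. A Δ that empties the signature is flagged and
predictions fall back to the majority prior.

# The synthetic cohort generator

The generator is the package's substitute for patient data and defines the
conditions under which every downstream claim is tested:

* **Images**: ellipsoidal tumors on a 3-channel (T1-like, T2-like,
  CE-like) background, diameter drawn per phenotype, intensities = base
  level × smooth random bias field × (1 + texture-contrast ×
  Gaussian-filtered noise), with phenotype-probability-driven focal
  features — a low-enhancement central core ("necrosis", bright on the
  T2-like channel), an enhancing rim beyond the mask ("peritumoral
  enhancement"), and coarse intra-tumoral heterogeneity patches. Masks are
  non-empty, connected ellipsoids strictly inside the grid.
* **Survival**: exponential event times with rate baseline ×
  exp(log-hazard of the group), independent exponential censoring —
  memoryless by design so closed-form oracles exist (the censoring-free
  event-rate MLE, planted log-hazard recovery by Cox).
* **Expression**: negative-binomial counts with log-normal gene
  abundances, log-normally distributed gene-wise dispersions (median 0.1,
  matching the mean–variance structure voom assumes), uniform library
  sizes, multiplicative per-gene batch effects, and a planted block of
  differential genes (half up, half down) at a configurable log₂ fold
  change between expression groups.
* **Dependence structure**: an explicit mixing matrix maps imaging groups
  to expression-group distributions, so the degree of association between
  the two subtypings is a controllable parameter — identity mixing makes
  them redundant, uniform mixing makes them independent (the structure in
  which combining the two groupings is most informative, and under which
  the package's final acceptance check shows the combined Cox model's
  cross-validated concordance exceeding either grouping alone).

The default three-phenotype table (40% large/necrotic/heterogeneous
high-hazard, 35% intermediate, 25% small/homogeneous low-hazard, with
Pr-OS centers 0.45/0.60/0.75 and log-hazards 1.0/0.4/0) reflects a
plausible high/intermediate/low-risk sarcoma cohort; the values were fixed
once as the package's study conditions.

What the generator does *not* emulate: MR physics (no k-space, no partial
volume, no fat suppression), anatomy beyond a flat background, non-convex
or infiltrative tumor shapes, informative censoring, isoform-level
expression, or library-preparation artifacts beyond a multiplicative batch
effect. Passing tests therefore demonstrate the statistical machinery's
correctness and calibration under the stated generative assumptions — not
clinical performance on real cohorts, whose effect sizes and artifact
structure can differ substantially.

# Reproducibility and problem sizes

Every stochastic function is a pure function of its parameters and a seed
(the global RNG state is saved and restored), and the pipeline derives
per-stage seeds from one master seed. The test suite sizes simulations for
desk-scale runtimes: texture oracles enumerate all 512 two-level
3 × 3 × 1 images; concordance/multiplicity/enrichment oracles use n ≤ 6,
500 short vectors and a 20-gene universe; parameter-recovery checks use
n = 2000 survival records, 20-seed consensus recoveries, 1500-gene
expression matrices; the autoencoder contracts train small networks on
30–200 slices of 32–64 pixels. The acceptance script trains the 64 × 64
autoencoder on 200 synthetic slices with a 90/10 holdout and reports the
held-out reconstruction MSE as a percentage.

# Known limitations

* The bias-field estimator is a low-order polynomial surrogate; fields
  with higher spatial frequency than the chosen order are not removed.
* The autoencoder is single-sequence and 2-D by design (center slice of
  the contrast-enhanced channel); no pre-trained weights are used, so
  latent spaces are cohort-specific.
* PAC-based model-order selection assumes the candidate range contains the
  truth and that clusters are stable under 60% subsampling; very small
  clusters (< ~5 subjects) may not survive resampling.
* The bootstrap concordance comparison is computationally heavy at the
  reference protocol's 1000 replicates; tests use smaller B, and the
  percentile p-value is approximate for small B.
* Welch t-tests on voom-normalized values ignore the voom precision
  weights (a weighted-t variant would use them); this matches the
  exploratory character of the differential-expression stage.
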