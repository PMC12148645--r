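---
title: "Methods: SAF classification and developmental bundle statistics"
author: "SAFTractometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAF classification and developmental bundle statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SAFTractometry)
```

# What the package models

Short association fibers (SAFs, or U-fibers) are streamlines of roughly
5-40 mm that run directly beneath the cortical sheet and connect adjacent
cortical areas. A practical way to organize them is by proximity to the
major long-range (LR) white-matter bundles: every streamline from a
superficial white-matter tractogram that passes through the binary mask of
an LR tract is assigned to that tract's SAF bundle. The package implements
this classification, the extraction of bundle-average microstructural
features, and the statistics used to characterize how those features
develop with age and how tightly an LR bundle's microstructure is coupled
to that of its associated SAF bundle.

Because full-scale imaging data are not needed to validate any of the
computations, the package ships a first-class synthetic-data module:
geometric phantoms with exact ground truth for the classification stages,
and cohort generators with known regression and coupling structure for the
statistical stages.

# The classification computation

`classifySAF()` chains four operations, each exported on its own:

1. **Length filtering** (`filterByLength()`): arc length is the sum of
   consecutive segment norms; the SAF band is the closed interval
   [5, 40] mm. Both bounds are inclusive — the convention for tracking
   length limits, which state bounds without strictness.
2. **Assignment** (`assignStreamlines()`): each streamline is resampled to
   a spacing of half the smallest voxel edge and mapped world-to-voxel
   with the NIfTI affine, points going to the *nearest* voxel (voxel
   centers at integer indices, 0-based). A streamline joins every bundle
   whose mask it touches; no exclusivity is imposed, since masks of
   distinct tracts overlap in real anatomy. The half-edge spacing
   guarantees that a resampled point lands in every voxel whose interior
   the path crosses by more than a corner clip; the test suite verifies
   agreement with an exact segment-voxel ray-marching oracle on random
   phantoms.
3. **Clustering** (`quickBundles()`, `mdfDistance()`): the clustering
   metric is the minimum average direct-flip (MDF) distance on 12-point
   resampled streamlines. Clustering is a deterministic single pass in
   input order: a streamline joins the first cluster (in creation order)
   whose running centroid lies within the threshold, otherwise it founds a
   new cluster; centroids are running means of resampled points, with the
   newcomer flipped first when its flipped orientation is closer. The
   first-fit tie-break pins determinism for testing.
4. **Outlier rejection** (`removeOutliers()`): published pipelines prune
   outliers with a hierarchical QuickBundles procedure controlled by a
   single `alpha` parameter whose internal semantics are not documented in
   the literature that cites it. The package therefore re-specifies the
   rule explicitly: QuickBundles is run at each threshold of a geometric
   ladder (8 levels spanning 2-16 mm, bracketing typical bundle spread
   below and gross deviation above); a streamline scores the fraction of
   levels at which its cluster holds at least 5% of the bundle; streamlines
   with score >= `alpha` (default 0.6) are kept. The rule is monotone in
   `alpha` — `alpha = 0` keeps everything — and its recall/retention
   behavior is measured against generator truth rather than assumed.

**Voxel occupancy** (`bundleOccupancy()`) records the voxels visited by a
bundle for metric averaging. The default method marches each segment
exactly through the voxel lattice (Amanatides-Woo traversal), so the voxel
set is independent of any sampling density; a `"points"` method reproduces
the resampled-point rule of assignment when consistency with that
convention is preferred. `bundleMeanFeature()` then averages a scalar map
over the mask, excluding NaN voxels with a logged count.

# Tensor fitting

`fitTensor()` estimates the diffusion tensor by log-linear least squares on
`ln S = ln S0 - b g' D g`, **restricted to measurements with
b <= 1500 s/mm^2** — higher shells are excluded before any computation, so
their values cannot influence the result (verified bit-for-bit in the
tests). Weighting matters for log-linear fits because the log transform
makes low-signal measurements noisier; the package takes one reweighting
pass with weights equal to the squared predicted signals, which recovers
near-nonlinear accuracy at a fraction of the cost. Whether the original
tool used ordinary or weighted least squares is not documented; one
reweighting pass is this package's choice. Negative eigenvalues are clamped
to zero before deriving the scalars so that FA = sqrt(3/2) ||lambda -
MD|| / ||lambda|| stays in [0, 1]; MD, AD and RD are the mean, largest, and
mean-of-two-smaller eigenvalues. At least 7 usable measurements including
one b = 0 are required; rank-deficient direction sets and nonpositive
signals are rejected or excluded with a count.

The signal simulator (`simulateDwiSignal()`) is the standard single-tensor
forward model with the study's two-shell protocol (b = 1500 and
3000 s/mm^2) as the natural fixture. Noise is Gaussian on the magnitude by
default, with a Rician option; the tensor tests run noiseless or at high
SNR where the distinction is immaterial.

# The developmental model

Every bundle feature is modeled as

`feature = b0 + b1*Age + b2*Sex + b3*Age*Sex + b4*zTICV`

with Age in raw years, Sex coded 0 = female / 1 = male, and TICV
z-transformed. Features are z-transformed per bundle-feature column
(sample-SD convention, n - 1), so coefficients read in SD units and b1 in
SD/year. Age deliberately stays in years — that is what makes "SD change
per year" interpretable. With this coding b1 is the female age slope and
b1 + b3 the male one; the TICV sub-model (`fitTICVModel()`) is the worked
example of the contract: with generator coefficients (-0.04 age, +0.09
sex, +0.07 age-by-sex) the male slope is -0.04 + 0.07 = 0.03 SD/year, and
the package recovers it exactly on a noiseless cohort.

Fitting is by iteratively reweighted least squares with the Tukey bisquare
weight, `w = (1 - (r/(c s))^2)^2` for |r| < c s and 0 beyond, started at
OLS with the robust scale `s = median(|r|)/0.6745` re-estimated each
iteration. The tuning constant c = 4.685 (95% Gaussian efficiency) is the
universal default for bisquare; the original analysis names the weight
function but no constant. Exactly linear data (robust scale 0) return the
OLS solution unchanged. Standard errors use the Huber-corrected robust
covariance (the `MASS::rlm` / statsmodels form)
`s^2 [sum psi(u)^2/(n-p)] / [mean psi'(u)]^2` with Huber's small-sample
correction and `(X'X)^{-1}`; p-values are two-tailed from t(n - p). The
weighted-`(X'W X)^{-1}` variant was considered and rejected: for bisquare
weights on clean Gaussian data it undercovers noticeably, while the Huber
form holds the nominal 95% coverage in the package's replicate tests.

`fitAllBundles()` applies the model to every (pathway, tier, feature)
cell, with Benjamini-Hochberg FDR applied per coefficient within each
tier's pathway-by-feature matrix — one family per effect-matrix panel, the
most conservative reading consistent with how such matrices are reported.
`relPercentChangeTable()` refits on the raw scale and reports
`100 * b1 / mean(feature)` percent per year (the female-model slope, by
the sex coding). `compareTiers()` contrasts a coefficient between the SAF
and LR fits of the same pathway with
`t = (bA - bB)/sqrt(seA^2 + seB^2)` against a standard normal — the
reference distribution for a difference of two robust estimates has no
exact small-sample form, and at n = 616 the normal approximation is
negligible. TICV-by-age and TICV-by-sex interaction screening can be added
as extended design columns by the user; the primary model keeps TICV
additive.

# Coupling specificity

Partial correlations (`partialCorrelation()`) residualize both variables
on [1, Age, Sex, zTICV] and take Pearson on the residuals, with p-values
from t on n - 2 - k degrees of freedom. `interFeatureMatrices()` builds
the three 7x7 matrices per pathway (within-SAF, within-LR, cross-tier);
FDR runs within each matrix (unique off-diagonal pairs for the symmetric
ones, all 49 cells for the cross matrix).

`runSpecificity()` asks, per LR pathway and feature, whether the
correlation with its associated SAF bundle stands out: Hypothesis 1
compares it against the mean Fisher-z correlation with the other SAF
bundles, Hypothesis 2 against the mean with the other LR bundles. All
correlations are Fisher z-transformed (`atanh`), the comparison statistic
is `Z = (z_assoc - mean(z_others)) * sqrt(N - k - 3)` — the standard error
of a single z-transformed partial correlation with k = 3 covariates — and
p-values are one-tailed in the "associated is stronger" direction, because
that is the hypothesis. The arithmetic mean is taken on the z scale (not
back-transformed), the variance-stabilized scale where averaging is
natural. The statistical dependence among correlations sharing the same LR
bundle is deliberately ignored — the test is an approximation by
construction, and no Steiger-type correction is applied — so its null
calibration is verified empirically against the exchangeable null of the
generator rather than assumed. FDR is applied across pathways within each
feature-by-hypothesis family.

# The synthetic-data generator

`simulateCohort()` draws ages uniform on 5.6-21.9 years and sex Bernoulli
with 279/616 male — the demographics of the developmental cohort the
package emulates — and simulates TICV from its own sub-model (defaults
-0.04 SD/yr age, +0.09 sex, +0.07 SD/yr age-by-sex). Bundle values are the
linear predictor plus latent coupling plus correlated noise:

* Design betas are defined **on the standardized feature scale** and the
  generator emits features on that scale. Identity checks at zero noise
  therefore fit the generated values directly (`standardize = FALSE`); an
  empirical re-z-transform would rescale the betas by the sample SD and
  exactness would be unattainable by construction. The default analysis
  path z-transforms, as real data require.
* Latent coupling: each participant gets one standard-normal factor per
  pathway, loaded with `sqrt(a^2 - c^2)` onto both tiers of that pathway,
  plus one global factor loaded with `c` onto every bundle
  (`a = couplingAssoc`, `c = couplingNonassoc`). The added covariance is
  `a^2` within an associated SAF-LR pair and `c^2` between any other pair,
  so `a = c` gives an exactly exchangeable null — the property the
  specificity calibration tests need — while `a > c` gives controllably
  stronger associated coupling.
* Residuals are multivariate normal across the seven features with a
  user-supplied correlation (PSD with unit diagonal, enforced), scaled by
  `noiseSd`; gross-outlier participants (fraction `contaminationRate`)
  have their residuals inflated tenfold.

`simulatePhantom()` builds tube masks (radius 2 voxels) along gently
sinusoidal centerlines, U-shaped arcs (semicircles, so arc length = pi r
controls the length band) whose bottoms pass through the tube and whose
endpoints straddle it, distractor arcs floated outside the volume's mask
region, and outlier arcs displaced ~40-50 mm — far beyond the clustering
ladder — with recorded flags. Bundle spread comes from rigid per-streamline
offsets rather than pointwise noise, so recorded lengths stay inside the
requested band. Anchors sit in a narrow window along each centerline to
keep bundles compact relative to the ladder.

What the generator does **not** emulate: partial-volume averaging, spatial
autocorrelation of metric maps, crossing-fiber geometry, site or motion
artifacts, non-Gaussian residuals other than the contamination mixture,
and nonlinear growth trajectories. Passing tests therefore demonstrate the
correctness and calibration of the computations under the stated model,
not the robustness of the pipeline to real acquisition physics.

# Numerical choices and degenerate inputs

* World-voxel mapping is pinned: NIfTI affine, 0-based indices, nearest
  voxel, voxel i owning the half-open cube [i - 0.5, i + 0.5).
* Robust scale below `1e-10 * max|y|` is treated as exact linearity (OLS
  returned); all-zero bisquare weights raise an error rather than a
  silent degenerate fit.
* Fisher z clips |r| to 1 - 1e-15 with a message; correlations of
  residuals numerically inside the covariate span raise a zero-variance
  error.
* Eigenvalue clamping happens only for scalar derivation; the unclamped
  eigenvalues are reported.
* Seeds: every generator takes an explicit integer seed and is
  bit-reproducible; the pipeline derives per-stage seeds from one master
  seed (`deriveSeed()`, kept below 2^31).

# Problem sizes in the shipped checks

The validation suites run cohorts of n = 616 (the emulated study size)
with 1-8 pathways, 500 replicates for coverage, 100 replicates for the
contamination comparison, 20 seeds for null calibration and phantom
pruning, and 100 small phantoms (24^3 voxels) for the exact-oracle
assignment check — sizes chosen so every claim is measured at meaningful
precision while the whole suite stays desk-scale.

# Known limitations

* The outlier-rejection rule is a documented re-specification, not a
  reimplementation of any specific toolkit's undocumented procedure;
  absolute agreement with a particular external pipeline is not claimed.
* The specificity Z-test inherits the dependence approximation discussed
  above; its empirical null calibration in the tests is conservative.
* Under symmetric 10% x10-noise contamination the bisquare estimator beats
  OLS per-fit in roughly three quarters to four fifths of replicates (OLS
  remains unbiased under symmetric contamination, so single-replicate wins
  are not near-certain even though the robust estimator's error is far
  smaller in distribution); the median-error comparison favors bisquare
  decisively. Both facts are measured by the suite.
* NODDI features are consumed (or synthesized) at feature level; no NODDI
  model fitting is provided.

# A minimal end-to-end run

```{r, eval = FALSE}
design <- SimDesign(nParticipants = 616, pathways = paste0("P", 1:8),
                    couplingAssoc = 0.6, couplingNonassoc = 0.2, seed = 1)
cfg <- makeRunConfig(design = design, seed = 1)
runPipeline(cfg, "saf-run")
```

The output directory holds the effect matrices per term and tier, the
relative-percent-change table, the three correlation matrices per pathway,
the specificity table, the phantom classification JSON, and a manifest
sufficient to reproduce the run bit-for-bit.
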