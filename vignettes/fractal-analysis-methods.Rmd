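---
title: "Methods: 3D fractal features and the radiogenomic modelling pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D fractal features and the radiogenomic modelling pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

voxfract quantifies the geometric complexity of binary 3D segmentation
masks — typically tumour masks drawn on postcontrast T1-weighted MRI — and
implements the statistical pipeline used to relate those features to a
binary molecular label, such as TERT-promoter (TERTp) mutation status in
grade 2 meningioma. This vignette explains the models and algorithms, the
parameters that matter, the synthetic-data generators used for validation,
and the numerical and design choices that were genuinely open.

## Box-counting fractal dimension

The mask is cropped to the tight bounding box of its foreground and
partitioned by a fixed, non-overlapping lattice of cubic boxes with edge
length $r$ voxels, anchored at the bounding-box corner; each axis is
zero-padded to a multiple of $r$ (padding can never create an occupied
box). $N(r)$ is the number of lattice boxes containing at least one
foreground voxel. Across a ladder of sizes the box-counting dimension is
the slope of the log–log relation

$$\widehat{FD} = -\,\frac{d\,\log N(r)}{d\,\log r},$$

estimated by ordinary least squares of $\log N(r)$ on $\log(1/r)$
(`fd_method = "ols"`, the default). A second estimator, the mean of the
local slopes of consecutive size pairs (`"mean-local-slope"`), is provided
because "mean FD" is ambiguous in parts of the literature; the two agree
exactly whenever $N(r)$ is an exact power law, which the test suite
verifies on solid cubes ($FD = 3$), one-voxel slabs ($FD = 2$), lines
($FD = 1$) and level-4 Menger sponges ($FD = \log 20 / \log 3 \approx
2.7268$).

**Box-size ladder.** The default is dyadic, $r \in \{2, 4, 8, 16, 32, 64,
128\}$ isotropic voxels. Dyadic ladders are the standard box-counting
choice; a triadic ladder ($\{3, 9, 27\}$) is the natural configuration for
Menger-sponge fixtures and is available through `feature_config`. Sizes
exceeding the longest bounding-box axis always yield a single occupied box,
which carries no scaling information and would flatten the fit; they are
skipped and reported (`skip_oversized = FALSE` keeps them when within-box
occupancy of very small masks is itself of interest).

**Isotropy.** Box counting is defined on isotropic voxels. Clinical masks
segmented on thick slices are anisotropic, so `resample_isotropic`
nearest-neighbour-resamples onto an isotropic grid at the smallest input
spacing by default. Nearest-neighbour (not linear) interpolation keeps the
mask strictly binary. The resampling target is a package choice: the
upstream acquisition convention does not fix one.

**Lattice anchoring.** With a fixed anchor, counts are exactly invariant
under axis permutations but only approximately invariant under rotations
that include a reflection, because reflection moves the anchor to the
opposite bounding-box corner; on random blobs the induced FD perturbation
is a few percent. This anchor sensitivity is inherent to fixed-grid box
counting and is the reason `offset_averaging` exists: it pools counts over
up to four diagonal lattice offsets per size.

## Lacunarity

Lacunarity measures the gappiness/translational heterogeneity of the mask
via the variability of box occupancy. Let $m_{i}(r)$ be the foreground
voxel count ("mass") of occupied box $i$ at size $r$. Two literal readings
of "the squared coefficients of variation of the occupied boxes, averaged"
are implemented:

* **Across-box CV (default).** At each size with at least two occupied
  boxes, $CV^2(r) = \left(\sigma_r / \mu_r\right)^2$ over the occupied-box
  masses, with the population (divide-by-$n$) standard deviation; the
  summary is the mean of $CV^2(r)$ over contributing sizes. This is the
  classical gliding-box quantity $\Lambda(r) - 1$ restricted to occupied
  boxes. Sizes with fewer than two occupied boxes are degenerate (the CV of
  one value) and are excluded and reported.
* **Within-box CV.** Each occupied box with fill fraction $p = m / r^3$
  contributes $CV^2 = (1-p)/p$, the closed form for 0/1 voxel values under
  population variance; per-size means are averaged over sizes.

Population variance is used throughout so the fixtures have exact closed
forms: a solid object gives 0 under both methods, a box pair with masses
$\{2, 6\}$ gives $CV^2 = 0.25$, a single voxel in an $r = 2$ box gives
$(1 - 1/8)/(1/8) = 7$.

Absolute lacunarity values depend on whether counting is done on the
cropped bounding box (as here) or a whole-image grid, so cross-study
comparisons of raw values are not meaningful; within-study contrasts (the
use case) are unaffected. The monotonicity that matters — more gappiness,
higher lacunarity — is verified by carving spherical gaps into digital
balls: mean lacunarity across ten seeds increases strictly with the deleted
volume fraction over $q \in \{0.1, \dots, 0.7\}$ (Spearman $\rho > 0.9$).

## Auxiliary shape features

**Sphericity** is $\pi^{1/3} (6V)^{2/3} / S$ with $V$ the foreground volume
and $S$ the area of the 0.5 iso-surface, triangulated by marching
tetrahedra (six tetrahedra per 2×2×2 cell, linear interpolation along tet
edges). Meshing the raw 0/1 field traces the voxel staircase and
overestimates curved areas by roughly 8–27% depending on the mesher, so the
binary field is first smoothed with a 1-voxel Gaussian — a standard
anti-aliasing step when extracting surfaces from label maps. A digital ball
of radius 20 voxels then measures sphericity within about 1% of 1. The
cost is a small bias for sharp-edged objects: corner rounding makes a
solid cube read about 0.85 instead of the analytic $(\pi/6)^{1/3} \approx
0.806$. For the smooth, blob-like anatomical masks this package targets,
the smoothing choice is the right trade; for polyhedral phantoms,
`surface_area(mask, smooth_sigma = 0)` meshes the raw field. Masks so thin
that smoothing removes every 0.5 crossing automatically fall back to the
unsmoothed mesh. This sphericity is the package's surface-regularity
measure; it is defined here, not imported from any external protocol.

**Maximum diameter** is the exact maximum Euclidean distance between
foreground voxel centres (0-based index × spacing), reported in cm. The
search reduces the candidate set to per-column extreme voxels (a superset
of the convex-hull vertices) and prunes with a farthest-point lower bound
before the pairwise scan, so it is exact but fast even for 10^5-voxel
masks; tests compare against brute force over all voxel pairs on small
masks.

**Volume** is the foreground voxel count times the voxel volume (mm³).

## Synthetic phantoms and cohorts

The study conditions this package emulates come from a 48-patient grade 2
meningioma cohort (41 TERTp-wildtype, 7 TERTp-mutant) whose imaging data
are not public, so validation runs entirely on synthetic data.

**Phantoms.** `make_primitive` produces exact cubes, slabs, lines and
centre-thresholded digital balls; `make_menger_sponge` builds the
level-$L$ sponge with exactly $20^L$ voxels and known dimension.
`make_blob` emulates a tumour-like mask: a digital ball whose border is
carved inward by a fine-scale (1.5-voxel bandwidth) Gaussian random field
scaled by `irregularity`, and whose interior is punctured by spherical gaps
until about `gap_fraction` of the volume is removed. Carving acts inward
only so the coarse-scale envelope is preserved; outward lobes would enlarge
the coarse-scale footprint and lower the measured FD, the opposite of the
intended "irregular border raises FD" behaviour. The mask is reduced to its
largest connected component, and every generator is a pure function of its
arguments including `seed`.

**Cohorts.** `generate_cohort` draws a per-subject table from per-group
Gaussians (continuous variables) and Bernoullis (binary variables) with
exact group sizes. The defaults are the published group distributions:
FD 1.74 ± 0.16 vs 1.88 ± 0.16, lacunarity 5.51 ± 0.41 vs 6.01 ± 0.64,
age 56.3 ± 15.0 vs 69.6 ± 10.3 years, diameter 4.82 ± 1.48 vs 6.15 ± 1.33
cm, and the corresponding binary-covariate proportions, at 7/48
prevalence. Within-group correlation between FD and lacunarity defaults to
0 because only marginals are published; real features are plausibly
correlated, so the `fd_lac_correlation` knob exposes the assumption. Draws
are clipped to feature domains (FD in [1, 3], lacunarity > 0) by
resampling, which perturbs realised moments negligibly at these parameter
values.

What the generators deliberately do **not** emulate: MRI intensities, the
segmentation process and its interobserver variability, within-subject
coupling between mask geometry and the tabulated features (cohort tables
and phantom masks are generated independently), or any survival/prognostic
structure. Passing tests therefore demonstrate correctness of the
computations and internal consistency of the published distributions — not
clinical validity on real images.

## Statistical pipeline

The pipeline mirrors the published analysis order: group comparisons, a
univariable logistic screen, multivariable modelling with backward
elimination, then ROC analysis.

* **Group comparisons.** Continuous variables: Shapiro–Wilk per group at
  α = 0.05 (the operationalisation of "according to normality"; no specific
  normality test is prescribed upstream); if both groups pass, a Welch
  unequal-variance t-test (safer than the pooled-variance test and equal to
  it asymptotically under equal variances), otherwise a two-sided
  Mann–Whitney U test, exact when the smaller group has ≤ 20 observations
  and no ties, tie-corrected normal approximation otherwise. Categorical
  variables: Fisher's exact test when any expected cell count is below 5,
  chi-square with continuity correction otherwise.
* **Logistic modelling.** Fits are maximum likelihood via IRLS
  (`stats::glm`, the same engine the original analysis used). Each term is
  screened for one-dimensional complete/quasi-complete separation (disjoint
  or boundary-touching predictor ranges across outcome classes); separated
  terms are flagged and reported with `NA` odds ratios instead of the
  divergent estimates a monotone likelihood produces — the same behaviour
  clinical reports show when a covariate present in only one outcome class
  makes its univariable model unestimable. Penalised (Firth) fitting is
  deliberately not the default; flagging preserves that reporting
  convention.
* **Backward elimination.** Candidates are terms with univariable Wald
  p < 0.05; the multivariable model repeatedly drops the term with the
  largest likelihood-ratio p until all remaining terms have LR p < 0.05.
  VIFs (1/(1−R²) on the candidate design matrix) are reported, with ≥ 10
  flagged, matching the conventional multicollinearity screen; flagged
  terms are reported, not auto-removed. The full elimination trace is kept.
* **ROC analysis.** AUC by the midrank formula, identical to
  Mann–Whitney $U/(n_1 n_0)$ (asserted to 1e-12 against a pairwise-
  comparison oracle). The operating point maximises Youden's J, with the
  lowest threshold taken on ties — the upstream report does not state how
  its operating point was chosen, so Youden is a documented package choice.
  The AUC confidence interval is a class-stratified percentile bootstrap
  (2,000 replicates by default) behind an explicit seed; no interval
  method is prescribed upstream.
* **Agreement.** Cohen's κ with marginal-product chance agreement and a
  large-sample Wald interval; ICC(2,1) — two-way random effects, absolute
  agreement, single measurement — from the two-way ANOVA decomposition with
  McGraw–Wong F-based intervals. "Two-way interclass correlation" does not
  pin the variant; ICC(2,1) is assumed and the absolute-agreement choice
  (which penalises systematic rater shifts) is tested explicitly.

Odds-ratio scaling for continuous predictors is per unit (per year, per
cm, per unit of FD or lacunarity); no standardisation is applied.

## Problem sizes used in validation

The shipped tests and the acceptance script use: 64³ cubes and slabs, the
level-4 Menger sponge (81³), balls of radius 10–20 voxels, blobs of radius
12–16 voxels, 50 random masks up to 32³ for brute-force box-count
equivalence, 100 random instances for the AUC/U identity, n = 5,000 for
coefficient recovery from the generating model
$\mathrm{logit}\,p = -1.768 + 3.482\,FD + 3.022\,\Lambda$, a 24,000-subject
cohort (7/48 prevalence preserved) for the distribution-implied AUC, and
1,000 simulated 48-subject cohorts for the null calibration of the
univariable screen. These sizes give stable Monte-Carlo estimates while
keeping a full validation run within a few minutes on one CPU.

The covariate distributions used for coefficient recovery (FD ~ N(0.5,
0.35²), lacunarity ~ N(0, 0.35²)) are centred so the linear predictor
spans the informative range; at the published raw feature scales the
printed intercept would place every subject's event probability near 1, so
those scales cannot have been the printed equation's covariate coding, and
recovery is demonstrated on a coding where the model is identifiable in
practice.

## Known limitations

* Absolute lacunarity values are grid-convention-dependent (bounding-box
  cropping here); only contrasts are comparable across implementations.
* Sphericity inherits a small upward bias for sharp-edged objects from the
  pre-smoothing, and a single-voxel mask is below the resolution at which
  an iso-surface is meaningful.
* Fixed-anchor box counts are not exactly reflection-invariant (see
  above); use `offset_averaging` when this matters.
* The univariable Wald screen at 7 events in 48 subjects is slightly
  conservative (simulated type-I error ≈ 0.04); this matches the study
  conditions rather than an asymptotic ideal.
* Synthetic cohorts assume within-group independence of FD and lacunarity
  unless `fd_lac_correlation` is set; downstream AUC claims inherit that
  assumption.
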