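# voxfract

Three-dimensional fractal analysis of binary segmentation masks, with the
statistical pipeline used in radiogenomic studies.

Tumours with high proliferative activity tend to have irregular borders
and internal gaps (necrosis, cystic change) that Euclidean descriptors
miss. Two scale-aware descriptors capture them: the **box-counting fractal
dimension** (FD), the exponent with which the number of boxes intersecting
the mask grows as the box size shrinks, and **lacunarity**, the averaged
squared coefficient of variation of box occupancy, which measures
gappiness. In grade 2 meningioma these features have been reported to
predict TERT-promoter (TERTp) mutation status — a marker that upgrades a
tumour to grade 3 in the 2021 WHO classification — from routine
postcontrast T1-weighted MRI segmentations. voxfract reimplements that
analysis end to end as a tested, reusable package for researchers working
with 3D masks:

* **Features** from NIfTI masks: box-count curves over a dyadic
  (2<sup>1</sup>…2<sup>7</sup> voxel) or custom size ladder, FD as the OLS
  log–log slope (mean-local-slope alternative), lacunarity in two
  documented variants, plus sphericity (marching-tetrahedra iso-surface),
  exact maximum diameter (cm) and volume (mm³).
* **Synthetic fixtures** with known answers: cubes, slabs, lines, digital
  balls, Menger sponges (FD = log 20 / log 3), tumour-like blobs with
  tunable border irregularity and gap fraction, and cohort tables drawn
  from the published group distributions (41 TERTp-wildtype vs 7 mutant;
  FD 1.74 ± 0.16 vs 1.88 ± 0.16; lacunarity 5.51 ± 0.41 vs 6.01 ± 0.64).
* **Statistics**: normality-routed group comparisons (Welch t /
  Mann–Whitney; chi-square / Fisher), univariable logistic screening with
  complete-separation flagging, backward likelihood-ratio elimination with
  VIF reporting, ROC analysis (AUC = Mann–Whitney U/(n₁n₀), stratified
  bootstrap CI, Youden operating point), Cohen's kappa and ICC(2,1).

The model at the core is the multivariable logistic model

```
ln(p / (1 - p)) = b0 + b1 * FD + b2 * lacunarity
```

whose published coefficients (−1.768, 3.482, 3.022) the package recovers
from simulated cohorts, and whose discrimination (published AUC 0.84) is
reproduced by simulation from the published group distributions alone.

## Worked example

```r
library(voxfract)

# a phantom with a known answer: level-4 Menger sponge, triadic boxes
extract_features(make_menger_sponge(4), feature_config(box_sizes = c(3, 9, 27)))
#> <fractal_features> menger4
#>   fd 2.7268 (R2 1.0000)  lacunarity 0.0000  sphericity 0.1233
#>   max diameter 13.86 cm  volume 160000 mm3  (160000 voxels)
```

The FD matches log 20 / log 3 = 2.726833 exactly; lacunarity is 0 because
the sponge is exactly self-similar (all occupied boxes carry equal mass on
the triadic lattice).

```r
# a tumour-like blob: irregular border, 25% of the volume carved out as gaps
tumour <- make_blob(radius_mm = 14, irregularity = 0.7, gap_fraction = 0.25, seed = 11)
extract_features(tumour, feature_config(c(2, 4, 8, 16)))
#> <fractal_features> blob_r14_i0.7_g0.25_s11
#>   fd 2.4123 (R2 0.9992)  lacunarity 0.4202  sphericity 0.5338
#>   max diameter 2.80 cm  volume 6882 mm3  (6882 voxels)
```

Relative to a plain ball (FD ≈ 2.59 at these scales, lacunarity 0,
sphericity ≈ 1), the carved border and gaps lower sphericity and raise
lacunarity; the per-size diagnostics are in the returned object.

```r
# a synthetic cohort at the published group distributions (10x study size),
# analysed with the full pipeline
cohort <- generate_cohort(cohort_spec(n_total = 480, n_mutant = 70, seed = 1))
report <- run_analysis(cohort, outcome = "mutant", n_boot = 500, seed = 7)
report$roc
#> <roc> AUC 0.974 (95% CI 0.956-0.989), n = 70/410 pos/neg
#>   Youden threshold 0.126: sens 0.929, spec 0.905, acc 0.908
```

Here the selection step retained nine covariates (at tenfold the study
size nearly every published group difference is significant, and the AUC
rises accordingly); `report$comparisons` holds the group-comparison table
and `report$selection` the univariable screen, VIFs and elimination trace.

Masks on disk go through `read_mask()` / `resample_isotropic()` /
`run_features()`; `inst/scripts/voxfract-cli.R` wraps simulate / features /
analyze / full as shell subcommands.

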