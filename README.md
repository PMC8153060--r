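# claustrseg

Landmark-based automatic segmentation of the human **dorsal claustrum** from
high-resolution T1-weighted MRI, with the evaluation metric, structural
measures, and structural-covariance analysis that go with it.

## The problem

The claustrum is a thin curtain of gray matter wedged between the putamen and
the insular cortex — 1–2 voxels thick at 0.7 mm isotropic resolution, with a
huge surface-to-volume ratio. Standard subcortical segmentation tools
(FreeSurfer, FSL FIRST) do not label it at all, and atlas-registration
approaches perform poorly on a structure this thin. `claustrseg` implements a
fully automatic, deterministic procedure that exploits the claustrum's fixed
anatomical neighbourhood instead of its (barely visible) boundary contrast.
It is aimed at neuroimaging researchers who already have co-registered T1w
images plus putamen and CSF segmentations (e.g. from FIRST and a
tissue-typing tool) and need a reproducible claustrum label per hemisphere.

## The algorithm

All volumes live in one canonical frame (first axis left→right, second
posterior→anterior, third inferior→superior). Per hemisphere:

1. **Putamen lateral edge** — for every (PA, IS) grid column, the single
   most-lateral putamen voxel.
2. **Lateral expansion** — each edge voxel grows `n = round(5 mm / Δx)`
   voxels laterally toward the insula (the putamen itself is excluded).
3. **CSF exclusion** — every ROI voxel within a Euclidean distance of 5
   voxels from CSF is removed; the sulcal CSF tracks the insular surface and
   so cuts away insular cortex, whose intensities mimic the claustrum.
4. **Intensity clustering** — two-cluster k-means on the T1w values of the
   remaining ROI separates the claustrum from the brighter extreme/external
   capsule white matter; the lower-centroid cluster is kept. In 1-D with
   k = 2 the optimum is a threshold in sorted order, and the package solves
   it exactly (exhaustive split scan), so the step is deterministic.
5. **Sagittal smoothing** — per left-right slice, a truncated Gaussian
   (σ = 1 voxel) is applied to the 0/1 values and re-binarized at 0.25,
   removing speckles while preserving 1-voxel-thick sheets.
6. **ROI restriction** — the smoothed mask is intersected with the ROI from
   step 3.

Evaluation and measurement use the Dice coefficient
`Dice(A, B) = 2|A∩B| / (|A| + |B|)`, mask volume (voxel count × voxel
volume), the myelin-sensitive T1w/T2w ratio, and mean diffusivity
`MD = trace(D)/3` from a log-linear least-squares tensor fit. The covariance
module z-scores each subject's regional measures across regions (removing
per-subject affine biases), correlates a seed region with every other region
across subjects (Pearson r, two-sided p, pairwise-complete), and applies
Bonferroni (default) or Benjamini–Hochberg correction.

A deterministic phantom generator builds synthetic hemispheres — convex
putamen, offset claustrum sheet with puddle widenings, white matter, insular
band, CSF band, Gaussian noise — plus multi-subject cohort tables with
planted correlations, so the entire pipeline is testable without any
external data.

## Worked example

```r
library(claustrseg)

ph  <- generate_phantom(phantom_spec(seed = 1))        # 96^3 @ 0.7 mm
res <- segment_claustrum(ph$t1w, ph$putamen, ph$csf, hemisphere("right"))
res$report
#> <segmentation_report>
#>   edge                   1625 voxels
#>   roi_expanded           11375 voxels
#>   roi_csf_excluded       10075 voxels
#>   initial_cluster        2541 voxels
#>   smoothed               3420 voxels
#>   final                  3335 voxels
#>   centroids: lower 69.85, upper 110.1 (threshold 88.82)

dice(res$mask, ph$truth_claustrum)   # 0.842
mask_volume(res$mask)                # 1143.9 mm^3 (truth sheet: 906.5 mm^3)
region_mean(ratio_image(ph$t1w, ph$t2w), res$mask)   # 1.563 (a.u.)
```

The per-step counts are the quality-control trail: the ROI shrinks
monotonically to the final mask (smoothing may transiently add voxels before
the final intersection), and the two cluster centroids (69.9 vs 110.1 here)
show whether a claustrum-like low-intensity cluster was actually present —
their separation collapses to ~1.6× the noise sd when it is not.

Covariance analysis on a generated cohort with a planted claustrum–claustrum
correlation of 0.6:

```r
C <- diag(40); C[1, 21] <- C[21, 1] <- 0.6
regions <- c(sprintf("reg%02d.L", 1:20), sprintf("reg%02d.R", 1:20))
regions[1] <- "claustrum.L"; regions[21] <- "claustrum.R"
tab <- generate_cohort(cohort_spec(500, regions, correlation = C, seed = 11))
net <- correct_significance(covariance_network(tab, "claustrum.L"), alpha = 0.01)
glance(net)
#>   seed        n_regions alpha n_tests method     n_significant
#> 1 claustrum.L        39  0.01     234 bonferroni             1
```

The one significant region is the contralateral claustrum (r = 0.524,
p ≈ 1.5e-36); `autoplot(net)` draws the network.

A command-line interface wraps the same functions
(`inst/cli/claustrseg segment|dice|measure|covary|phantom`), writing NIfTI
masks, JSON reports and a `config.json` echo of every run; exit codes are 0
(success), 2 (usage/I-O), 3 (domain error).

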