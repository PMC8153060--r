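---
title: "Landmark-based segmentation of the dorsal claustrum: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based segmentation of the dorsal claustrum: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claustrseg)
```

## The model

The dorsal claustrum cannot be segmented by boundary contrast: at 0.7 mm
isotropic resolution it is a 1–2 voxel sheet whose intensity sits between
the neighbouring white matter and the insular gray matter. What *is*
reliable is its topology — it always lies a few millimetres lateral to the
putamen, medial to the insula, with white matter on both sides. The
procedure therefore treats segmentation as a sequence of set operations on
that neighbourhood rather than a voxel-classification problem:

1. the lateral edge of a putamen mask seeds the search (one extreme-lateral
   voxel per posterior–anterior × inferior–superior column);
2. the edge is expanded 5 mm laterally, which at 0.7 mm spacing is
   `round(5/0.7) = 7` voxels — wide enough to contain the sheet and its
   puddle-like widenings, narrow enough to stop short of deep insular gray;
3. voxels within a 5-voxel Euclidean distance of CSF are removed, because
   sulcal CSF follows the insular surface and thereby excises insular
   cortex without requiring an insula segmentation (which is itself
   error-prone in exactly this region);
4. the surviving region-of-interest holds essentially two tissues —
   claustrum gray and capsule white matter — so a two-cluster split of the
   T1w intensities isolates the claustrum as the lower-centroid cluster;
5. per-sagittal-slice Gaussian smoothing enforces sheet continuity;
6. intersection with the ROI of step 3 undoes any smoothing spill-over.

The assumptions this encodes: inputs are co-registered; the putamen mask is
correct (an inaccurate putamen is the dominant observed failure mode, since
every later step inherits its lateral edge); the claustrum is the darkest
substantial tissue class inside the ROI; and the sheet is continuous in the
sagittal plane. The anterior–superior claustrum segment that bends over the
insula lies outside the putamen's dorsoventral range and is out of scope,
as is the fragmented ventral claustrum.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `expansion_mm` | 5 | mm | covers sheet offset (≤ 3.5 mm) plus maximal sheet thickness with margin |
| `csf_margin_voxels` | 5 | voxels | reaches through the insular cortex band from its sulcal surface |
| `k` | 2 | – | the ROI is constructed to contain two tissue classes |
| `smooth_sigma_voxels` | 1 | voxels | kernel scale of the thinnest structure to preserve |
| `smooth_threshold` | 0.25 | – | see below: separates sheets from speckles for σ = 1 |
| `max_cluster_iter` | 100 | – | interface cap only; the exact solver is non-iterative |

All are exposed in `seg_params()`; the distance rule is **inclusive**
(distance ≤ margin removes a voxel), and mask binarization on read is
inclusive at its threshold (≥ 0.5 by default). Chebyshev distance would be
a defensible alternative reading of a "5-voxel range"; Euclidean was chosen
as the stricter isotropic interpretation and is pinned by tests against an
all-pairs oracle.

## Numerical choices

**Exact 1-D clustering.** For one-dimensional data with k = 2, the optimal
k-means partition is a threshold in sorted order, so the global optimum can
be found by scanning the n−1 sorted splits with cumulative sums — O(n log n)
and deterministic. Lloyd iterations from any fixed initialization are a
strictly weaker choice here: in experiments with skewed instances they
converge to local optima in a noticeable fraction of cases, and they add an
initialization convention without buying anything. The test suite verifies
the scan against an independent brute-force split evaluation on random
instances. Splits are only allowed between strictly different sorted values
(equal intensities can never straddle a k-means boundary), ties in the
within-cluster sum of squares break to the smallest split index, and two
degenerate situations — all-identical intensities, or centroid separation
below 1e-9 of the intensity range — raise errors rather than returning an
arbitrary half-split. That failure mode is real: a large blood vessel
through the claustrum can destroy the bimodality the step relies on, and
the cluster-centroid separation reported in every `segmentation_report` is
the quantity to inspect. When the ROI contains only white-matter noise, the
optimal split of a Gaussian sample gives a separation of
`2·sqrt(2/π)·sd ≈ 1.6 sd` (the two half-normal means) — an order of
magnitude below the gray/white contrast, and asserted as the ablation
signature in the tests.

**Smoothing kernel.** The continuity step is a per-slice convolution with a
normalized Gaussian truncated at 3σ, applied to the 0/1 values, then
re-binarized. With σ = 1 the kernel's central weight is ≈ 0.400 per axis,
so an isolated voxel smooths to ≈ 0.16 (= 0.400²) and a 1-voxel-thick
in-plane line to ≈ 0.40; a threshold of 0.25 sits between the two, which is
precisely the behaviour wanted — despeckle without eating the sheet. A
line's lateral neighbours smooth to ≈ 0.24, just below threshold, so thin
sheets are not dilated either. Slices are processed independently: nothing
mixes across the lateral axis, preserving the sheet's thin profile.

**Orientation.** Every volume is reoriented on read to left→right /
posterior→anterior / inferior→superior using the NIfTI header transform,
and `hemisphere()` carries the sign of "lateral" along the first axis. All
operations are exactly mirror-symmetric; the suite asserts that flipping
all inputs and the hemisphere yields the bit-exact mirrored output.

**Tensor fit.** MD comes from a plain log-linear least-squares fit of
`ln S = ln S₀ − b gᵀDg` (QR factorization, all voxels solved in one
multi-RHS call), chosen for determinism and because it is exactly
invertible on noiseless forward-model data — the closed-form check in the
tests demands relative error below 1e-9. Voxels with non-positive signals
yield NaN; negative fitted MD is reported with a warning, not clamped,
supporting the usual subject-exclusion QC.

## The z-scoring caveat

Standardizing each subject's row across regions removes per-subject affine
biases *exactly* (a multiplicative bias cancels algebraically; the tests
assert recovery of the bias-free correlations to machine precision). The
price is that subtracting each row's mean couples every pair of region
columns by approximately −1/(p−1): with p = 8 regions the mean pairwise
null correlation is −0.143, while at the realistic p = 80 it is −0.013.
Consequences drawn here: the covariance default standardizes (that is the
analysis the pipeline exists for, and at realistic region counts the
coupling is negligible), but the type-I calibration of the correlation
machinery is asserted on un-standardized null cohorts, where the
independence premise actually holds. Missing values are handled
pairwise-complete with the effective n reported per region; the correction
default is Bonferroni over `2 × targets × measures` tests (the strictest
defensible reading of an unnamed familywise correction), with
Benjamini–Hochberg available, and the family size is always computed from
the actual table dimensions and recorded in the output.

## What the phantom does and does not show

`generate_phantom()` builds the geometric premise by construction: an
ellipsoidal putamen (convex lateral face), a ground-truth sheet placed as
an offset surface of that face (offset 1.5–3.5 mm, thickness 1–2 voxels,
three puddle widenings), white matter around it, an insular gray band, and
a CSF band tracking the insular surface, at 96³ × 0.7 mm with additive
Gaussian noise (sd 5 against a 40-unit gray/white contrast — comparable
separation-to-noise to real T1w). Defaults: T1w means CSF 30 < gray 70 <
putamen 75 < white 110 (a.u.). Everything is deterministic given the seed,
and a left-hemisphere phantom is the exact mirror of the right one.

The recovery suite (seeds 1–10, default parameters) requires Dice ≥ 0.7
against the ground-truth sheet, disjointness from the putamen and the CSF
margin zone, and exact mirror symmetry. What this validates: the landmark
logic, the exactness of each geometric operator (each is also tested
against a brute-force oracle), the clustering, and the smoothing behaviour
on sheet-like structures. What it does not validate: robustness to putamen
segmentation errors (the dominant real-world failure), bias fields,
partial-volume mixing at real tissue interfaces, anatomical variability of
the sheet's offset and curvature, or motion/registration artifacts — the
phantom deliberately grants the algorithm its geometric premise. Phantom
Dice values should therefore be read as an upper bound on real-data
performance, where agreement in the 0.5–0.7 range against manual raters is
the realistic regime for a structure this thin.

Problem sizes used throughout the suite and the acceptance script — 96³
phantoms, 10 seeds, 200-point clustering instances, cohorts of 60–2000
subjects over 8–40 regions, 200 null repetitions — were chosen so every
statistical assertion has comfortable margin (bounds at 3.5+ standard
errors) while the whole suite stays interactive.

## Known limitations

* The putamen edge is taken per grid column; a putamen mask with holes on
  its lateral face produces edge voxels medial to the true face. Masks from
  well-behaved tools are smooth enough in practice.
* The lateral expansion is directional, not a 3-D dilation; a strongly
  oblique claustrum-putamen geometry (far from the canonical orientation)
  would be under-covered. Reorientation on read mitigates this.
* Regional T1w/T2w means are volumetric-mask means; surface-based sampling
  along the cortical mid-thickness is out of scope, so cortical values are
  approximations to surface-sampled ones.
* The both-empty Dice is an error by design; callers comparing possibly
  empty masks must handle that condition.
* The CLI's bilateral mode splits the putamen by connected components and
  centroid side; a single component spanning the midplane (a mask defect)
  is assigned to one side rather than split.
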