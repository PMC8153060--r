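#' Hemisphere descriptor
#'
#' The segmentation is phrased in lateral terms, so each hemisphere carries
#' the sign of "lateral" along the canonical left-to-right axis: -1 for the
#' left hemisphere (lateral = decreasing index), +1 for the right.
#'
#' @param side `"left"` or `"right"`.
#' @return An object of class `hemisphere` with fields `side` and
#'   `lateral_sign`.
#' @export
hemisphere <- function(side = c("right", "left")) {
  side <- match.arg(side)
  structure(
    list(side = side, lateral_sign = if (side == "left") -1L else 1L),
    class = "hemisphere"
  )
}

#' @export
print.hemisphere <- function(x, ...) {
  cat(sprintf("<hemisphere> %s (lateral sign %+d)\n", x$side, x$lateral_sign))
  invisible(x)
}

#' Segmentation parameters
#'
#' Tunables of the landmark-based pipeline, with the published defaults:
#' the putamen edge is expanded laterally by 5 mm, voxels within a 5-voxel
#' Euclidean range of CSF are excluded, and the ROI intensities are split
#' into k = 2 clusters. The smoothing kernel of the continuity step is not
#' pinned down by the procedure's description; this implementation uses a
#' per-sagittal-slice Gaussian (sigma 1 voxel, truncated at 3 sigma) with
#' re-binarization at 0.25, chosen so isolated speckles are removed (central
#' response ~0.16) while 1-voxel-thick sheets survive (~0.40). Both are
#' exposed here.
#'
#' @param expansion_mm Lateral expansion distance in mm (> 0). Default 5.
#' @param csf_margin_voxels CSF exclusion radius in voxel units (>= 0).
#'   Default 5.
#' @param k Number of intensity clusters; fixed at 2.
#' @param smooth_sigma_voxels Gaussian width, in voxels, of the in-plane
#'   smoothing. Default 1.
#' @param smooth_threshold Re-binarization level in (0, 1). Default 0.25.
#' @param max_cluster_iter Iteration cap for the clustering step. The exact
#'   1-D solver used here is non-iterative, so this is an upper bound kept
#'   for interface stability. Default 100.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(expansion_mm = 5, csf_margin_voxels = 5, k = 2,
                       smooth_sigma_voxels = 1, smooth_threshold = 0.25,
                       max_cluster_iter = 100) {
  if (!is.numeric(expansion_mm) || expansion_mm <= 0) {
    abort_domain("expansion_mm must be > 0")
  }
  if (!is.numeric(csf_margin_voxels) || csf_margin_voxels < 0) {
    abort_domain("csf_margin_voxels must be >= 0")
  }
  if (k != 2) {
    abort_domain("k is fixed at 2 (lower cluster = claustrum, upper = white matter)")
  }
  if (!is.numeric(smooth_sigma_voxels) || smooth_sigma_voxels <= 0) {
    abort_domain("smooth_sigma_voxels must be > 0")
  }
  if (!is.numeric(smooth_threshold) || smooth_threshold <= 0 || smooth_threshold >= 1) {
    abort_domain("smooth_threshold must lie in (0, 1)")
  }
  if (!is.numeric(max_cluster_iter) || max_cluster_iter < 1) {
    abort_domain("max_cluster_iter must be >= 1")
  }
  structure(
    list(
      expansion_mm = as.numeric(expansion_mm),
      csf_margin_voxels = as.numeric(csf_margin_voxels),
      k = 2L,
      smooth_sigma_voxels = as.numeric(smooth_sigma_voxels),
      smooth_threshold = as.numeric(smooth_threshold),
      max_cluster_iter = as.integer(max_cluster_iter)
    ),
    class = "seg_params"
  )
}

#' @export
print.seg_params <- function(x, ...) {
  cat(sprintf(
    "<seg_params> expand %.3g mm | CSF margin %.3g vox | k = %d | smooth sigma %.3g vox @ %.3g\n",
    x$expansion_mm, x$csf_margin_voxels, x$k, x$smooth_sigma_voxels, x$smooth_threshold
  ))
  invisible(x)
}
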