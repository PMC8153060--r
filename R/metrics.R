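#' Dice overlap coefficient
#'
#' Overlap between two segmentations of the same grid, `2|A n B| / (|A| +
#' |B|)`, where A and B are the voxel sets of the two masks. Symmetric,
#' bounded in \[0, 1\], 1 for identical non-empty masks and 0 for disjoint
#' ones. Two empty masks have no defined overlap and raise an error rather
#' than silently returning a convention value.
#'
#' @param a,b Aligned [binary_mask()] objects, not both empty.
#' @return A number in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!is_binary_mask(a) || !is_binary_mask(b)) {
    abort_domain("dice expects two binary_mask objects")
  }
  check_aligned(a, b, "masks")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) {
    abort_domain("Dice is undefined: both masks are empty")
  }
  2 * sum(a$data & b$data) / (na + nb)
}

#' Mask volume in cubic millimetres
#'
#' Number of voxels in the mask multiplied by the voxel volume (the product
#' of the three spacings). At the 0.7 mm isotropic resolution the pipeline
#' targets, each voxel contributes 0.343 mm^3.
#'
#' @param mask A [binary_mask()].
#' @return Volume in mm^3 (0 for an empty mask).
#' @export
mask_volume <- function(mask) {
  if (!is_binary_mask(mask)) abort_domain("mask_volume expects a binary_mask")
  sum(mask$data) * prod(mask$spacing)
}

#' Mean of a scalar map over a mask
#'
#' Mean of the finite voxel values under the mask, the per-region reduction
#' used for regional volume/T1w-T2w/MD tables. `NaN` voxels (e.g. undefined
#' ratio voxels) are excluded and reported in a warning rather than
#' propagated.
#'
#' @param volume A [scalar_volume()].
#' @param mask Aligned non-empty [binary_mask()] with at least one finite
#'   voxel underneath.
#' @return The mean value.
#' @export
region_mean <- function(volume, mask) {
  if (!is_scalar_volume(volume) || !is_binary_mask(mask)) {
    abort_domain("region_mean expects a scalar_volume and a binary_mask")
  }
  check_aligned(volume, mask, "volume and mask")
  if (!any(mask$data)) abort_domain("mask is empty")
  vals <- volume$data[mask$data]
  bad <- !is.finite(vals)
  if (all(bad)) abort_domain("no finite voxels under the mask")
  if (any(bad)) {
    warning(sprintf("region_mean: %d non-finite voxel(s) excluded", sum(bad)))
  }
  mean(vals[!bad])
}
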