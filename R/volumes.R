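#' Scalar volume in the canonical anatomical frame
#'
#' A `scalar_volume` holds a 3-D grid of real intensities together with its
#' voxel spacing in mm. All volumes in this package live in one fixed
#' orientation: the first array axis runs left to right, the second posterior
#' to anterior, and the third inferior to superior (RAS). Files stored in
#' other orientations are reoriented on read, so every downstream operation
#' can speak in lateral/anterior/dorsal terms without per-call ambiguity.
#'
#' @param data Numeric 3-D array. Infinities are rejected; `NaN` is allowed
#'   (it marks voxels explicitly excluded, e.g. undefined ratio voxels).
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all positive.
#' @return An object of class `scalar_volume` with fields `data` and
#'   `spacing`.
#' @seealso [binary_mask()], [read_volume()], [ratio_image()]
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_domain("scalar_volume data must be a 3-D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_domain("spacing must be three positive voxel sizes in mm")
  }
  storage.mode(data) <- "double"
  if (any(is.infinite(data))) {
    abort_domain("volume contains infinite values")
  }
  structure(list(data = data, spacing = spacing), class = "scalar_volume")
}

#' Binary mask aligned to a scalar volume
#'
#' A `binary_mask` is a 3-D boolean grid with the same spacing/orientation
#' contract as [scalar_volume()]. Masks carry putamen, CSF, ROI and claustrum
#' segmentations; two masks (or a mask and a volume) are "aligned" when their
#' shapes match exactly and their spacings agree within 1e-3 mm.
#'
#' @param data Logical (or coercible 0/1 numeric) 3-D array. `NA`/`NaN`
#'   voxels become `FALSE`.
#' @param spacing Numeric length-3 voxel sizes in mm.
#' @return An object of class `binary_mask` with fields `data` and `spacing`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_domain("binary_mask data must be a 3-D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_domain("spacing must be three positive voxel sizes in mm")
  }
  d <- dim(data)
  data <- as.logical(data)
  data[is.na(data)] <- FALSE
  dim(data) <- d
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.scalar_volume <- function(x, ...) {
  fin <- x$data[is.finite(x$data)]
  cat(sprintf(
    "<scalar_volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x"),
    if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA
  ))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %s voxels @ %s mm, %d set\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x"),
    sum(x$data)
  ))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' @export
dim.binary_mask <- function(x) dim(x$data)

is_scalar_volume <- function(x) inherits(x, "scalar_volume")
is_binary_mask <- function(x) inherits(x, "binary_mask")

# Alignment contract: identical shape, spacing within 1e-3 mm. Inputs are
# assumed co-registered; full spatial registration checking is out of scope.
check_aligned <- function(a, b, what = "grids") {
  da <- dim(a$data); db <- dim(b$data)
  if (!identical(da, db)) {
    abort_domain("%s are not aligned: shapes %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x"))
  }
  if (any(abs(a$spacing - b$spacing) > 1e-3)) {
    abort_domain("%s are not aligned: spacings differ by more than 1e-3 mm", what)
  }
  invisible(TRUE)
}

# Reorient a niftiImage to the canonical RAS frame. Files without any
# qform/sform are taken to already be canonical (there is nothing to go by).
canonical_nifti <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0L || hdr$sform_code > 0L) {
    RNifti::orientation(img) <- "RAS"
  }
  img
}

read_nifti_checked <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort_io("path must be a single file path")
  }
  if (!file.exists(path)) {
    abort_io("file not found: %s", path)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_io("not a NIfTI volume: %s (%s)", path, conditionMessage(e)))
  canonical_nifti(img)
}

#' Read a NIfTI scalar volume
#'
#' Reads a 3-D NIfTI-1 image (`.nii` or `.nii.gz`), reorients it to the
#' canonical left-to-right / posterior-to-anterior / inferior-to-superior
#' frame using the file's qform/sform, and returns a [scalar_volume()] with
#' spacing taken from the header.
#'
#' @param path Path to a readable NIfTI-1 file.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  img <- read_nifti_checked(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) > 3L) {
    abort_io("expected a 3-D volume, got %d dimensions (use read_dwi for 4-D series): %s",
             length(d), path)
  }
  sp <- RNifti::pixdim(img)
  sp <- c(sp, rep(1, 3L))[1:3]
  arr <- as.array(img)
  attributes(arr) <- NULL
  # trailing singleton dimensions are dropped by the reader; restore them
  dim(arr) <- c(d, rep(1L, 3L - length(d)))
  scalar_volume(arr, sp)
}

#' Read a binary or probabilistic mask
#'
#' Reads a mask volume and binarizes it: voxels with value `>= threshold` are
#' set. Hard 0/1 masks pass through unchanged at the default threshold;
#' probabilistic masks (e.g. tissue posteriors) are cut at the threshold,
#' boundary inclusive.
#'
#' @param path Path to a NIfTI-1 mask file.
#' @param threshold Binarization level in (0, 1); default 0.5.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    abort_domain("threshold must be a single number in (0, 1)")
  }
  vol <- read_volume(path)
  if (all(is.na(vol$data))) {
    abort_domain("mask is all-NaN: %s", path)
  }
  binary_mask(!is.na(vol$data) & vol$data >= threshold, vol$spacing)
}

as_nifti_object <- function(data, spacing, datatype) {
  attr(data, "pixdim") <- spacing
  img <- RNifti::asNifti(data, datatype = datatype)
  RNifti::qform(img) <- structure(diag(c(spacing, 1)), code = 2L)
  img
}

#' Write a scalar volume to NIfTI
#'
#' @param volume A [scalar_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!is_scalar_volume(volume)) abort_domain("expected a scalar_volume")
  if (!dir.exists(dirname(path))) abort_io("directory does not exist: %s", dirname(path))
  img <- as_nifti_object(volume$data, volume$spacing, "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit 0/1 volumes; [read_mask()] on the
#' written file returns an identical mask (bit-exact round trip).
#'
#' @param mask A [binary_mask()].
#' @param path Output path; parent directory must exist.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is_binary_mask(mask)) abort_domain("expected a binary_mask")
  if (!dir.exists(dirname(path))) abort_io("directory does not exist: %s", dirname(path))
  data <- mask$data
  storage.mode(data) <- "integer"
  img <- as_nifti_object(data, mask$spacing, "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' T1w/T2w ratio image
#'
#' Divides a T1-weighted by a co-registered T2-weighted volume. The ratio is
#' a semiquantitative myelin-sensitive contrast: biases shared by the two
#' acquisitions (receive-coil inhomogeneity, global scaling) cancel, so
#' `ratio_image(a * t1w, a * t2w)` equals `ratio_image(t1w, t2w)` for any
#' positive field `a`. Voxels where the T2w value is non-positive (or either
#' input is NaN) are undefined and set to `NaN`.
#'
#' @param t1w,t2w Aligned [scalar_volume()] objects.
#' @return A [scalar_volume()] of voxelwise T1w/T2w values.
#' @export
ratio_image <- function(t1w, t2w) {
  if (!is_scalar_volume(t1w) || !is_scalar_volume(t2w)) {
    abort_domain("ratio_image expects two scalar_volume objects")
  }
  check_aligned(t1w, t2w, "T1w and T2w volumes")
  out <- t1w$data / t2w$data
  out[!is.na(t2w$data) & t2w$data <= 0] <- NaN
  out[is.infinite(out)] <- NaN
  scalar_volume(out, t1w$spacing)
}

#' Mirror a volume or mask across the sagittal midplane
#'
#' Reverses the left-to-right axis. Useful for hemisphere-symmetry checks:
#' the segmentation of mirrored inputs with the flipped hemisphere equals the
#' mirror of the original output.
#'
#' @param x A [scalar_volume()] or [binary_mask()].
#' @return An object of the same class, flipped along the first axis.
#' @export
flip_lateral <- function(x) {
  if (is_scalar_volume(x)) {
    scalar_volume(x$data[dim(x$data)[1]:1, , , drop = FALSE], x$spacing)
  } else if (is_binary_mask(x)) {
    binary_mask(x$data[dim(x$data)[1]:1, , , drop = FALSE], x$spacing)
  } else {
    abort_domain("flip_lateral expects a scalar_volume or binary_mask")
  }
}
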