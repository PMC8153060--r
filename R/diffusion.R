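#' Diffusion acquisition protocol
#'
#' Pairs per-volume b-factors with unit gradient directions. A tensor fit
#' needs at least one b = 0 volume and six non-collinear nonzero-b
#' directions (the tensor has six free elements); both are checked here.
#' Directions of b = 0 volumes may be zero vectors.
#'
#' @param b_values Numeric vector of b-factors in s/mm^2, one per volume.
#' @param directions 3 x n or n x 3 matrix of gradient directions; rows (or
#'   columns) for nonzero b must have unit norm within 1e-6.
#' @return An object of class `dwi_protocol` with fields `b_values` and
#'   `directions` (n x 3).
#' @export
dwi_protocol <- function(b_values, directions) {
  b_values <- as.numeric(b_values)
  directions <- as.matrix(directions)
  if (nrow(directions) == 3L && ncol(directions) != 3L) {
    directions <- t(directions)
  }
  if (ncol(directions) != 3L || nrow(directions) != length(b_values)) {
    abort_domain("directions must be one 3-vector per b-value")
  }
  if (!any(b_values == 0)) {
    abort_domain("protocol needs at least one b = 0 volume")
  }
  nz <- b_values > 0
  norms <- sqrt(rowSums(directions[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort_domain("nonzero-b gradient directions must have unit norm (tolerance 1e-6)")
  }
  if (sum(nz) < 6L || qr(tensor_design(b_values, directions)[, -1, drop = FALSE])$rank < 6L) {
    abort_domain("at least 6 non-collinear nonzero-b directions are required for a tensor fit")
  }
  structure(list(b_values = b_values, directions = directions),
            class = "dwi_protocol")
}

#' Read b-values and gradient directions in the FSL text dialect
#'
#' One whitespace-separated row of b-values in the `.bval` file; three rows
#' of direction components in the `.bvec` file.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A [dwi_protocol()].
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path)) {
    if (!file.exists(p)) abort_io("file not found: %s", p)
  }
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvecs) != 3L) abort_io("bvec file must have exactly 3 rows")
  dwi_protocol(bvals, t(bvecs))
}

#' Read a 4-D diffusion-weighted series
#'
#' @param path Path to a 4-D NIfTI-1 file.
#' @return A list with `data` (4-D array, canonical orientation) and
#'   `spacing` (mm).
#' @export
read_dwi <- function(path) {
  img <- read_nifti_checked(path)
  d <- dim(img)
  if (length(d) != 4L) {
    abort_io("expected a 4-D DWI series, got %d dimensions: %s", length(d), path)
  }
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, spacing = sp)
}

# Design matrix of the log-linear tensor model:
# ln S = ln S0 - b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                   + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
# Columns: intercept (ln S0), then the six tensor elements in the order
# Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
tensor_design <- function(b, g) {
  cbind(
    1,
    -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3], -2 * b * g[, 2] * g[, 3]
  )
}

#' Mean diffusivity from a log-linear tensor fit
#'
#' Fits the diffusion tensor per voxel by ordinary least squares on the
#' log-signals and returns the mean diffusivity, MD = trace(D) / 3, in the
#' units implied by the b-values (mm^2/s for b in s/mm^2). Voxels with any
#' non-positive signal cannot be log-transformed and yield `NaN`. The fit is
#' invariant to scaling all signals by a positive constant (the intercept
#' absorbs it). Negative fitted MD values are possible on pathological data
#' and are reported with a warning rather than clamped, supporting the same
#' quality-control exclusion used for subjects with negative MD.
#'
#' @param dwi 4-D numeric array of signals (x, y, z, volume), or a list with
#'   fields `data` and `spacing` as returned by [read_dwi()].
#' @param protocol A [dwi_protocol()] whose length matches the 4th
#'   dimension.
#' @param spacing Voxel spacing in mm for the output map; ignored when `dwi`
#'   carries its own.
#' @return A [scalar_volume()] MD map.
#' @export
fit_md <- function(dwi, protocol, spacing = c(1, 1, 1)) {
  if (is.list(dwi) && !is.null(dwi$data)) {
    spacing <- dwi$spacing
    dwi <- dwi$data
  }
  if (!is.array(dwi) || length(dim(dwi)) != 4L) {
    abort_domain("dwi must be a 4-D array")
  }
  if (!inherits(protocol, "dwi_protocol")) {
    abort_domain("protocol must be a dwi_protocol")
  }
  n <- dim(dwi)[4]
  if (n != length(protocol$b_values)) {
    abort_domain("DWI has %d volumes but protocol lists %d", n, length(protocol$b_values))
  }
  if (n < 7L) abort_domain("fewer than 7 volumes: tensor fit is underdetermined")
  X <- tensor_design(protocol$b_values, protocol$directions)
  d3 <- dim(dwi)[1:3]
  S <- matrix(dwi, nrow = prod(d3), ncol = n)
  usable <- rowSums(S <= 0 | !is.finite(S)) == 0L
  md <- rep(NaN, prod(d3))
  if (any(usable)) {
    coef <- qr.coef(qr(X), t(log(S[usable, , drop = FALSE])))
    md[usable] <- (coef[2, ] + coef[3, ] + coef[4, ]) / 3
  }
  if (any(usable) && any(md[usable] < 0)) {
    warning(sprintf("fit_md: %d voxel(s) with negative MD", sum(md[usable] < 0)))
  }
  dim(md) <- d3
  scalar_volume(md, spacing)
}

#' Forward-simulate diffusion signals from diagonal tensors
#'
#' Generates noiseless signals `S = s0 * exp(-b g' D g)` from per-voxel
#' diagonal tensors, the forward model whose inverse [fit_md()] computes.
#' Used to build diffusion phantoms with known ground-truth MD.
#'
#' @param diag_tensors 4-D array (x, y, z, 3) of the diagonal tensor entries
#'   Dxx, Dyy, Dzz (mm^2/s).
#' @param protocol A [dwi_protocol()].
#' @param s0 Baseline signal (scalar or 3-D array).
#' @return A 4-D signal array (x, y, z, volume).
#' @export
simulate_dwi <- function(diag_tensors, protocol, s0 = 1) {
  if (!is.array(diag_tensors) || length(dim(diag_tensors)) != 4L ||
      dim(diag_tensors)[4] != 3L) {
    abort_domain("diag_tensors must be an (x, y, z, 3) array")
  }
  if (!inherits(protocol, "dwi_protocol")) {
    abort_domain("protocol must be a dwi_protocol")
  }
  d3 <- dim(diag_tensors)[1:3]
  n <- length(protocol$b_values)
  D <- matrix(diag_tensors, nrow = prod(d3), ncol = 3L)
  g2 <- protocol$directions^2
  # attenuation exponent per voxel x volume: b * (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz)
  expo <- D %*% t(g2 * protocol$b_values)
  S <- as.vector(s0) * exp(-expo)
  array(S, dim = c(d3, n))
}
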