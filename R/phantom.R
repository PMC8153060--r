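# Synthetic single-hemisphere phantoms. The geometry encodes the anatomical
# premise of the segmentation: a lateral-convex putamen body, a thin
# gray-matter sheet 1.5-3.5 mm lateral to it (the ground-truth claustrum,
# with occasional puddle widenings toward the insula), brighter white matter
# between and around, an insular gray band further lateral, and a CSF band
# following the insular surface. Everything is deterministic given the seed.

#' Phantom specification
#'
#' Defines the geometry, tissue intensities, and noise of a synthetic
#' claustrum phantom. Default T1w means (CSF 30 < gray 70 < putamen 75 <
#' white 110, arbitrary units, noise sd 5) give a gray/white separation
#' comparable to real T1w contrast, so the intensity-clustering step is
#' challenged but solvable; T2w means run the other way (CSF brightest).
#'
#' @param shape Grid dimensions; default `c(96, 96, 96)`.
#' @param spacing Voxel size in mm; default 0.7 isotropic.
#' @param side `"right"` or `"left"` hemisphere.
#' @param t1_means,t2_means Named tissue means (`csf`, `gray`, `putamen`,
#'   `white`), arbitrary units. Gray must be darker than white and CSF
#'   darkest on T1w: that is the contrast the clustering step exploits.
#' @param noise_sd Additive Gaussian noise sd per channel (>= 0).
#' @param sheet_thickness_voxels Range (min, max) of claustrum sheet
#'   thickness in voxels; default 1-2. A maximum of 0 produces an empty
#'   truth sheet (degenerate phantom).
#' @param lateral_offset_mm Range of the sheet's lateral offset from the
#'   putamen edge, in mm; default 1.5-3.5.
#' @param n_puddles Number of local sheet widenings; default 3.
#' @param seed Integer RNG seed; the phantom is fully reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing = rep(0.7, 3),
                         side = c("right", "left"),
                         t1_means = c(csf = 30, gray = 70, putamen = 75, white = 110),
                         t2_means = c(csf = 120, gray = 60, putamen = 55, white = 40),
                         noise_sd = 5,
                         sheet_thickness_voxels = c(1, 2),
                         lateral_offset_mm = c(1.5, 3.5),
                         n_puddles = 3,
                         seed = 1) {
  side <- match.arg(side)
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  need <- c("csf", "gray", "putamen", "white")
  if (!all(need %in% names(t1_means)) || !all(need %in% names(t2_means))) {
    abort_domain("t1_means and t2_means need entries csf, gray, putamen, white")
  }
  if (!(t1_means[["gray"]] < t1_means[["white"]])) {
    abort_domain("gray-matter T1w mean must be below white-matter T1w mean")
  }
  if (t1_means[["csf"]] >= min(t1_means[c("gray", "putamen", "white")])) {
    abort_domain("CSF must have the lowest T1w mean")
  }
  if (noise_sd < 0) abort_domain("noise_sd must be >= 0")
  if (length(shape) != 3L || any(shape < 32L)) {
    abort_domain("shape must be three dimensions of at least 32 voxels")
  }
  if (length(sheet_thickness_voxels) != 2L || any(sheet_thickness_voxels < 0)) {
    abort_domain("sheet_thickness_voxels must be a non-negative (min, max) pair")
  }
  if (length(lateral_offset_mm) != 2L || any(lateral_offset_mm <= 0)) {
    abort_domain("lateral_offset_mm must be a positive (min, max) pair")
  }
  structure(
    list(shape = shape, spacing = spacing, side = side,
         t1_means = t1_means, t2_means = t2_means, noise_sd = noise_sd,
         sheet_thickness_voxels = as.numeric(sheet_thickness_voxels),
         lateral_offset_mm = as.numeric(lateral_offset_mm),
         n_puddles = as.integer(n_puddles), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Evaluate user code with a local RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Binary erosion of a 2-D logical matrix by a 4-neighbourhood, used to pull
# the truth sheet back from the ragged rim of the putamen footprint.
erode4 <- function(m, times = 1L) {
  for (it in seq_len(times)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m & up & dn & lf & rt
  }
  m
}

#' Generate a synthetic claustrum phantom
#'
#' Builds, in order: an ellipsoidal putamen with a convex lateral face; a
#' curved gray-matter sheet at a smoothly varying lateral offset from the
#' putamen's lateral edge (the ground-truth claustrum), locally widened into
#' puddles; white matter between and around; an insular gray band further
#' lateral; and a CSF band following the insular surface. Gaussian noise is
#' added per channel. A left-hemisphere phantom is the exact mirror image of
#' the right-hemisphere phantom with the same spec, noise included.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_bundle`: scalar volumes `t1w`, `t2w`;
#'   masks `putamen`, `csf`, `insula`, `truth_claustrum`; the `spec`. The
#'   truth sheet is disjoint from putamen and CSF, lies strictly lateral to
#'   the putamen edge, and sits within the default lateral expansion range.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) abort_domain("spec must be a phantom_spec")
  d <- spec$shape
  sp <- spec$spacing

  # Internal frame is always right-hemisphere (lateral = +x); flip at the end.
  cx <- round(d[1] * 0.35); cy <- round(d[2] / 2); cz <- round(d[3] / 2)
  ax <- round(d[1] * 0.10); ay <- round(d[2] * 0.27); az <- round(d[3] * 0.21)
  xg <- slice.index(array(0L, d), 1)
  yg <- slice.index(array(0L, d), 2)
  zg <- slice.index(array(0L, d), 3)
  putamen <- ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 + ((zg - cz) / az)^2 <= 1

  # Lateral edge index per (y, z) column of the putamen footprint.
  pidx <- which(putamen, arr.ind = TRUE)
  key <- pidx[, 2] + (pidx[, 3] - 1L) * d[2]
  edge_x <- tapply(pidx[, 1], key, max)
  depth <- tapply(pidx[, 1], key, length)
  keys <- as.integer(names(edge_x))
  ey <- ((keys - 1L) %% d[2]) + 1L
  ez <- ((keys - 1L) %/% d[2]) + 1L

  footprint <- matrix(FALSE, d[2], d[3])
  footprint[cbind(ey, ez)] <- TRUE
  emap <- matrix(NA_integer_, d[2], d[3])
  emap[cbind(ey, ez)] <- as.integer(edge_x)

  # The truth sheet lives on an eroded footprint (away from the ragged rim,
  # where the edge surface is steep) and only over columns with real putamen
  # depth, keeping the sheet a connected 2-D region in the (y, z) sense.
  core <- matrix(FALSE, d[2], d[3])
  core[cbind(ey, ez)] <- depth >= 3
  core <- core & erode4(footprint, 2L)

  off_lo <- spec$lateral_offset_mm[1]; off_hi <- spec$lateral_offset_mm[2]
  th_lo <- spec$sheet_thickness_voxels[1]; th_hi <- spec$sheet_thickness_voxels[2]

  bundle <- with_local_seed(spec$seed, {
    # Smooth deterministic fields over (y, z): lateral offset and thickness.
    phase <- stats::runif(4, 0, 2 * pi)
    yy <- matrix(seq_len(d[2]), d[2], d[3])
    zz <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
    field <- (sin(2 * pi * yy / d[2] + phase[1]) * cos(2 * pi * zz / d[3] + phase[2]) + 1) / 2
    field2 <- (cos(2 * pi * yy / d[2] + phase[3]) * sin(2 * pi * zz / d[3] + phase[4]) + 1) / 2
    offset_mm <- off_lo + (off_hi - off_lo) * field
    offset_vox <- matrix(pmax(1L, as.integer(round(offset_mm / sp[1]))), d[2], d[3])
    thickness <- matrix(as.integer(round(th_lo + (th_hi - th_lo) * field2)), d[2], d[3])

    # Puddles: local widenings of the sheet toward the insula.
    if (spec$n_puddles > 0 && any(core)) {
      centers <- which(core)
      centers <- centers[sample.int(length(centers), min(spec$n_puddles, length(centers)))]
      py <- ((centers - 1L) %% d[2]) + 1L
      pz <- ((centers - 1L) %/% d[2]) + 1L
      for (q in seq_along(py)) {
        patch <- (yy - py[q])^2 + (zz - pz[q])^2 <= 16
        thickness[patch] <- thickness[patch] + 2L
      }
    }

    truth <- array(FALSE, d)
    max_sheet_x <- emap + 7L  # stay within the 5 mm expansion at 0.7 mm
    if (th_hi > 0) {
      cols <- which(core, arr.ind = TRUE)
      for (q in seq_len(nrow(cols))) {
        j <- cols[q, 1]; k <- cols[q, 2]
        th <- thickness[j, k]
        if (th < 1L) next
        x0 <- emap[j, k] + offset_vox[j, k]
        x1 <- min(x0 + th - 1L, max_sheet_x[j, k], d[1])
        if (x0 > x1) next
        truth[x0:x1, j, k] <- TRUE
      }
    }

    # Insular gray band and CSF band, offset surfaces of the putamen edge
    # over a slightly dilated footprint so they wrap the ROI laterally.
    wrap <- !erode4(!footprint, 2L)  # dilate by 2
    emap_fill <- emap
    # fill edge heights outside the footprint from the nearest column inside
    if (any(wrap & !footprint)) {
      fill_cols <- which(wrap & !footprint, arr.ind = TRUE)
      inside <- which(footprint, arr.ind = TRUE)
      for (q in seq_len(nrow(fill_cols))) {
        dy <- inside[, 1] - fill_cols[q, 1]
        dz <- inside[, 2] - fill_cols[q, 2]
        nn <- which.min(dy * dy + dz * dz)
        emap_fill[fill_cols[q, 1], fill_cols[q, 2]] <- emap[inside[nn, 1], inside[nn, 2]]
      }
    }
    insula <- array(FALSE, d)
    csf <- array(FALSE, d)
    wcols <- which(wrap, arr.ind = TRUE)
    for (q in seq_len(nrow(wcols))) {
      j <- wcols[q, 1]; k <- wcols[q, 2]
      e <- emap_fill[j, k]
      ins <- (e + 10L):(e + 12L); ins <- ins[ins >= 1L & ins <= d[1]]
      cs <- (e + 13L):(e + 14L); cs <- cs[cs >= 1L & cs <= d[1]]
      insula[ins, j, k] <- TRUE
      csf[cs, j, k] <- TRUE
    }

    label <- array("white", d)
    label[insula] <- "gray"
    label[truth] <- "gray"
    label[putamen] <- "putamen"
    label[csf] <- "csf"

    t1 <- array(spec$t1_means[label], d) + stats::rnorm(prod(d), 0, spec$noise_sd)
    t2 <- array(spec$t2_means[label], d) + stats::rnorm(prod(d), 0, spec$noise_sd)
    list(t1 = t1, t2 = t2, putamen = putamen, csf = csf, insula = insula,
         truth = truth)
  })

  if (spec$side == "left") {
    rev1 <- function(a) a[d[1]:1, , , drop = FALSE]
    bundle <- lapply(bundle, rev1)
  }

  structure(
    list(
      t1w = scalar_volume(bundle$t1, sp),
      t2w = scalar_volume(bundle$t2, sp),
      putamen = binary_mask(bundle$putamen, sp),
      csf = binary_mask(bundle$csf, sp),
      insula = binary_mask(bundle$insula, sp),
      truth_claustrum = binary_mask(bundle$truth, sp),
      spec = spec
    ),
    class = "phantom_bundle"
  )
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf(
    "<phantom_bundle> %s hemisphere, %s voxels @ %.3g mm, truth %d voxels (%.0f mm^3)\n",
    x$spec$side, paste(dim(x$t1w$data), collapse = "x"), x$spec$spacing[1],
    sum(x$truth_claustrum$data), mask_volume(x$truth_claustrum)
  ))
  invisible(x)
}

#' Write a phantom bundle to a directory
#'
#' Writes `t1w.nii.gz`, `t2w.nii.gz`, `putamen.nii.gz`, `csf.nii.gz`,
#' `insula.nii.gz`, `truth_claustrum.nii.gz` and a `spec.json` echo.
#'
#' @param bundle A `phantom_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  if (!inherits(bundle, "phantom_bundle")) abort_domain("bundle must be a phantom_bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$t1w, file.path(dir, "t1w.nii.gz"))
  write_volume(bundle$t2w, file.path(dir, "t2w.nii.gz"))
  write_mask(bundle$putamen, file.path(dir, "putamen.nii.gz"))
  write_mask(bundle$csf, file.path(dir, "csf.nii.gz"))
  write_mask(bundle$insula, file.path(dir, "insula.nii.gz"))
  write_mask(bundle$truth_claustrum, file.path(dir, "truth_claustrum.nii.gz"))
  jsonlite::write_json(bundle$spec[setdiff(names(bundle$spec), character(0))],
                       file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
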