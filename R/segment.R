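#' Lateral edge of the putamen
#'
#' The claustrum lies immediately lateral to the putamen, so the pipeline is
#' seeded at the putamen's lateral border. For every (posterior-anterior,
#' inferior-superior) grid column that intersects the putamen, exactly the
#' single most-lateral putamen voxel is kept: the extreme index along the
#' left-to-right axis, in the direction given by the hemisphere.
#'
#' @param putamen Non-empty single-hemisphere [binary_mask()].
#' @param hemi A [hemisphere()].
#' @return A [binary_mask()]; one voxel per occupied column, subset of
#'   `putamen`.
#' @export
putamen_lateral_edge <- function(putamen, hemi) {
  if (!is_binary_mask(putamen)) abort_domain("putamen must be a binary_mask")
  if (!inherits(hemi, "hemisphere")) abort_domain("hemi must be a hemisphere")
  idx <- which(putamen$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort_domain("putamen mask is empty")
  d <- dim(putamen$data)
  col_key <- idx[, 2] + (idx[, 3] - 1L) * d[2]
  pick <- if (hemi$lateral_sign > 0) max else min
  extreme <- tapply(idx[, 1], col_key, pick)
  keys <- as.integer(names(extreme))
  j <- ((keys - 1L) %% d[2]) + 1L
  k <- ((keys - 1L) %/% d[2]) + 1L
  out <- array(FALSE, dim = d)
  out[cbind(as.integer(extreme), j, k)] <- TRUE
  binary_mask(out, putamen$spacing)
}

#' Expand the putamen edge laterally
#'
#' Expands the edge toward the insular cortex by a fixed physical distance:
#' each edge voxel contributes the `n` voxels at lateral offsets `1..n` along
#' the left-to-right axis, where `n = round(expansion_mm / spacing_x)`
#' (minimum 1). The putamen edge voxels themselves are not part of the
#' result: the claustrum sits between the putamen and the insula, so the ROI
#' starts one voxel lateral to the known putamen. Offsets falling outside
#' the grid are dropped.
#'
#' @param edge Edge mask from [putamen_lateral_edge()].
#' @param hemi A [hemisphere()].
#' @param expansion_mm Lateral distance in mm (default 5).
#' @return A [binary_mask()] slab lateral to the edge.
#' @export
expand_lateral <- function(edge, hemi, expansion_mm = 5) {
  if (!is_binary_mask(edge)) abort_domain("edge must be a binary_mask")
  if (!inherits(hemi, "hemisphere")) abort_domain("hemi must be a hemisphere")
  if (!is.numeric(expansion_mm) || expansion_mm <= 0) {
    abort_domain("expansion_mm must be > 0")
  }
  d <- dim(edge$data)
  n <- max(1L, as.integer(round(expansion_mm / edge$spacing[1])))
  idx <- which(edge$data, arr.ind = TRUE)
  out <- array(FALSE, dim = d)
  if (nrow(idx) == 0L) return(binary_mask(out, edge$spacing))
  for (off in seq_len(n)) {
    x <- idx[, 1] + hemi$lateral_sign * off
    keep <- x >= 1L & x <= d[1]
    if (any(keep)) {
      out[cbind(x[keep], idx[keep, 2], idx[keep, 3])] <- TRUE
    }
  }
  binary_mask(out, edge$spacing)
}

# Integer offsets within a Euclidean ball of the given radius (voxel units),
# excluding the origin.
ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-12, , drop = FALSE]
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE])
}

#' Exclude ROI voxels near cerebrospinal fluid
#'
#' The expanded ROI can reach insular cortex, whose intensities resemble the
#' claustrum. Rather than relying on an insula segmentation, every ROI voxel
#' whose Euclidean distance (in voxel units) to the nearest CSF voxel is
#' `<= margin_voxels` is removed: the sulcal CSF follows the insular surface
#' and delimits the ROI laterally.
#'
#' @param roi ROI [binary_mask()].
#' @param csf CSF [binary_mask()], aligned to `roi`. An empty CSF mask
#'   leaves the ROI unchanged.
#' @param margin_voxels Exclusion radius in voxel units (default 5),
#'   inclusive.
#' @return A [binary_mask()], subset of `roi`.
#' @export
exclude_near_csf <- function(roi, csf, margin_voxels = 5) {
  if (!is_binary_mask(roi) || !is_binary_mask(csf)) {
    abort_domain("roi and csf must be binary_mask objects")
  }
  check_aligned(roi, csf, "ROI and CSF masks")
  if (!is.numeric(margin_voxels) || margin_voxels < 0) {
    abort_domain("margin_voxels must be >= 0")
  }
  ci <- which(csf$data, arr.ind = TRUE)
  if (nrow(ci) == 0L) return(binary_mask(roi$data, roi$spacing))
  d <- dim(roi$data)
  near <- csf$data
  if (margin_voxels > 0) {
    offsets <- ball_offsets_cached(margin_voxels)
    for (row in seq_len(nrow(offsets))) {
      off <- offsets[row, ]
      x <- ci[, 1] + off[1]; y <- ci[, 2] + off[2]; z <- ci[, 3] + off[3]
      keep <- x >= 1L & x <= d[1] & y >= 1L & y <= d[2] & z >= 1L & z <= d[3]
      if (any(keep)) near[cbind(x[keep], y[keep], z[keep])] <- TRUE
    }
  }
  binary_mask(roi$data & !near, roi$spacing)
}

# Memoise ball offsets per radius: the dilation loop touches this repeatedly.
ball_cache <- new.env(parent = emptyenv())
ball_offsets_cached <- function(radius) {
  key <- format(radius, digits = 15)
  if (is.null(ball_cache[[key]])) ball_cache[[key]] <- ball_offsets(radius)
  ball_cache[[key]]
}

# Exact 1-D two-cluster k-means. The global optimum of 1-D k = 2 clustering
# is a threshold in sorted order; scanning all valid split points with
# cumulative sums finds it directly, with no iteration and no initialization
# sensitivity. Ties in within-cluster sum of squares break to the smallest
# split index. Returns sorted-order split index and the threshold value.
kmeans1d_split <- function(values) {
  xs <- sort(values)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs * xs)
  j <- seq_len(n - 1L)
  valid <- xs[j] < xs[j + 1L]
  if (!any(valid)) {
    abort_domain("degenerate intensity distribution: all ROI intensities identical")
  }
  ss_left <- cs2[j] - cs[j]^2 / j
  ss_right <- (cs2[n] - cs2[j]) - (cs[n] - cs[j])^2 / (n - j)
  wcss <- ss_left + ss_right
  wcss[!valid] <- Inf
  jbest <- which.min(wcss)
  list(
    split = jbest,
    threshold = (xs[jbest] + xs[jbest + 1L]) / 2,
    lower_centroid = cs[jbest] / jbest,
    upper_centroid = (cs[n] - cs[jbest]) / (n - jbest),
    wcss = wcss[jbest]
  )
}

#' Two-cluster intensity split of the ROI
#'
#' After CSF exclusion the ROI contains mostly claustrum gray matter and the
#' brighter white matter of the extreme/external capsules. A two-cluster
#' k-means on the T1w intensities separates them; the cluster with the lower
#' centroid is the initial claustrum segmentation. Because the intensities
#' are one-dimensional and k = 2, the globally optimal partition is a
#' threshold in sorted order; it is found exactly by an exhaustive scan over
#' split points (cumulative-sum evaluation of the within-cluster sum of
#' squares), which is deterministic and free of initialization effects.
#'
#' @param roi Non-empty [binary_mask()] delimiting the voxels to cluster.
#' @param t1w Aligned T1w [scalar_volume()], finite on the ROI.
#' @param params A [seg_params()]; `max_cluster_iter` is honoured as an
#'   upper bound (the exact solver needs a single pass).
#' @return A list: `mask` (lower cluster, a [binary_mask()]), `centroids`
#'   (named lower/upper mean intensities), `threshold`.
#' @export
cluster_t1w <- function(roi, t1w, params = seg_params()) {
  if (!is_binary_mask(roi)) abort_domain("roi must be a binary_mask")
  if (!is_scalar_volume(t1w)) abort_domain("t1w must be a scalar_volume")
  check_aligned(roi, t1w, "ROI and T1w volume")
  sel <- which(roi$data)
  if (length(sel) == 0L) abort_domain("ROI is empty: nothing to cluster")
  vals <- t1w$data[sel]
  if (any(!is.finite(vals))) {
    abort_domain("T1w intensities are not finite everywhere on the ROI")
  }
  fit <- kmeans1d_split(vals)
  rng <- diff(range(vals))
  if ((fit$upper_centroid - fit$lower_centroid) < 1e-9 * rng) {
    abort_domain("degenerate intensity distribution: cluster centroids are not separated")
  }
  out <- array(FALSE, dim = dim(roi$data))
  out[sel[vals <= fit$threshold]] <- TRUE
  list(
    mask = binary_mask(out, roi$spacing),
    centroids = c(lower = fit$lower_centroid, upper = fit$upper_centroid),
    threshold = fit$threshold
  )
}

# 1-D truncated, normalized Gaussian kernel.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(round(3 * sigma)))
  g <- stats::dnorm(-r:r, sd = sigma)
  g / sum(g)
}

# Banded convolution matrix (zero boundary) for a symmetric 1-D kernel.
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    keep <- j >= 1L & j <= n
    K[cbind(i[keep], j[keep])] <- kernel[off + r + 1L]
  }
  K
}

#' Smooth a mask within each sagittal plane
#'
#' The initial cluster can be speckled; to obtain a continuous sheet the mask
#' is smoothed two-dimensionally along the anterior-posterior and
#' ventral-dorsal axes. For each fixed left-right index, the 2-D slice is
#' convolved (zero boundary) with a normalized Gaussian truncated at 3 sigma
#' applied to the 0/1 values, then re-binarized at `smooth_threshold`.
#' Slices are processed independently; nothing mixes across the lateral axis,
#' which preserves the sheet's thin lateral profile.
#'
#' @param mask A [binary_mask()].
#' @param params A [seg_params()] supplying `smooth_sigma_voxels` and
#'   `smooth_threshold`.
#' @return A [binary_mask()].
#' @export
smooth_in_sagittal_plane <- function(mask, params = seg_params()) {
  if (!is_binary_mask(mask)) abort_domain("mask must be a binary_mask")
  d <- dim(mask$data)
  g <- gaussian_kernel(params$smooth_sigma_voxels)
  Ky <- conv_band_matrix(d[2], g)
  Kz <- conv_band_matrix(d[3], g)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) {
    slice <- mask$data[i, , ]
    if (!any(slice)) next
    sm <- Ky %*% slice %*% Kz
    out[i, , ] <- sm >= params$smooth_threshold
  }
  binary_mask(out, mask$spacing)
}

new_segmentation_report <- function(counts, centroids, threshold, warnings) {
  structure(
    list(counts = counts, centroids = centroids, threshold = threshold,
         warnings = warnings),
    class = "segmentation_report"
  )
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat("<segmentation_report>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d voxels\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  centroids: lower %.4g, upper %.4g (threshold %.4g)\n",
              x$centroids[["lower"]], x$centroids[["upper"]], x$threshold))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segmentation report into per-step voxel counts
#'
#' @param x A `segmentation_report`.
#' @param ... Unused.
#' @return A tibble with columns `step` and `voxels`, in pipeline order.
#' @export
tidy.segmentation_report <- function(x, ...) {
  tibble::tibble(step = names(x$counts), voxels = unname(unlist(x$counts)))
}

#' One-row summary of a segmentation report
#'
#' @param x A `segmentation_report`.
#' @param ... Unused.
#' @return A one-row tibble: final voxel count, the two cluster centroids,
#'   the intensity threshold, and the number of warnings.
#' @export
glance.segmentation_report <- function(x, ...) {
  tibble::tibble(
    final_voxels = x$counts$final,
    lower_centroid = x$centroids[["lower"]],
    upper_centroid = x$centroids[["upper"]],
    threshold = x$threshold,
    n_warnings = length(x$warnings)
  )
}

#' Segment the dorsal claustrum in one hemisphere
#'
#' Runs the landmark-based pipeline end to end: (A) detect the lateral edge
#' of the putamen, (B) expand it laterally by `expansion_mm` toward the
#' insula, (C) exclude voxels within `csf_margin_voxels` of CSF, (D) split
#' the remaining ROI intensities into two clusters and keep the lower
#' (claustrum vs white matter), (E) smooth per sagittal plane for
#' continuity, and (F) restrict the smoothed mask to the ROI of step C,
#' since the smoothing of a curved sheet can spill outside it.
#'
#' @param t1w T1w [scalar_volume()].
#' @param putamen Non-empty putamen [binary_mask()] for this hemisphere.
#' @param csf CSF [binary_mask()].
#' @param hemi A [hemisphere()].
#' @param params A [seg_params()].
#' @return A list with `mask` (the final claustrum [binary_mask()]) and
#'   `report` (a `segmentation_report` of per-step voxel counts, cluster
#'   centroids, and warnings).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1))
#' res <- segment_claustrum(ph$t1w, ph$putamen, ph$csf, hemisphere("right"))
#' dice(res$mask, ph$truth_claustrum)
#' @export
segment_claustrum <- function(t1w, putamen, csf, hemi, params = seg_params()) {
  if (!is_scalar_volume(t1w)) abort_domain("t1w must be a scalar_volume")
  check_aligned(t1w, putamen, "T1w and putamen")
  check_aligned(t1w, csf, "T1w and CSF")
  edge <- putamen_lateral_edge(putamen, hemi)
  roi_expanded <- expand_lateral(edge, hemi, params$expansion_mm)
  roi <- exclude_near_csf(roi_expanded, csf, params$csf_margin_voxels)
  clus <- cluster_t1w(roi, t1w, params)
  smoothed <- smooth_in_sagittal_plane(clus$mask, params)
  final <- binary_mask(smoothed$data & roi$data, t1w$spacing)
  warnings <- character(0)
  if (!any(final$data)) warnings <- c(warnings, "empty final segmentation")
  report <- new_segmentation_report(
    counts = list(
      edge = sum(edge$data),
      roi_expanded = sum(roi_expanded$data),
      roi_csf_excluded = sum(roi$data),
      initial_cluster = sum(clus$mask$data),
      smoothed = sum(smoothed$data),
      final = sum(final$data)
    ),
    centroids = clus$centroids,
    threshold = clus$threshold,
    warnings = warnings
  )
  list(mask = final, report = report)
}
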