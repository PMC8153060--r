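# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (triple loops, all-pairs scans, O(n^2) split
# evaluation) so they share no code path with the implementation.

mask_from_indices <- function(dim, idx, spacing = c(1, 1, 1)) {
  a <- array(FALSE, dim = dim)
  if (length(idx)) a[idx] <- TRUE
  binary_mask(a, spacing)
}

random_small_mask <- function(dim, n_set, spacing = c(1, 1, 1)) {
  mask_from_indices(dim, sample.int(prod(dim), n_set), spacing)
}

# Per-column exhaustive scan for the extreme lateral putamen voxel.
oracle_lateral_edge <- function(arr, lateral_sign) {
  d <- dim(arr)
  out <- array(FALSE, dim = d)
  for (j in seq_len(d[2])) {
    for (k in seq_len(d[3])) {
      xs <- which(arr[, j, k])
      if (length(xs) == 0L) next
      pick <- if (lateral_sign > 0) max(xs) else min(xs)
      out[pick, j, k] <- TRUE
    }
  }
  out
}

# All-pairs minimum-distance filter for the CSF exclusion zone.
oracle_exclude_near_csf <- function(roi_arr, csf_arr, margin) {
  ri <- which(roi_arr, arr.ind = TRUE)
  ci <- which(csf_arr, arr.ind = TRUE)
  out <- array(FALSE, dim = dim(roi_arr))
  if (nrow(ri) == 0L) return(out)
  for (q in seq_len(nrow(ri))) {
    if (nrow(ci) == 0L) {
      out[ri[q, 1], ri[q, 2], ri[q, 3]] <- TRUE
      next
    }
    d2 <- (ci[, 1] - ri[q, 1])^2 + (ci[, 2] - ri[q, 2])^2 + (ci[, 3] - ri[q, 3])^2
    if (min(d2) > margin^2) out[ri[q, 1], ri[q, 2], ri[q, 3]] <- TRUE
  }
  out
}

# Exhaustive 1-D two-cluster optimum by direct evaluation of every sorted
# split (no cumulative sums). Returns the lower-cluster membership (logical,
# in input order) and the within-cluster sum of squares. Ties break to the
# smallest split index, matching the declared rule.
oracle_kmeans1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- list(wcss = Inf, split = NA_integer_)
  for (j in seq_len(n - 1L)) {
    if (xs[j] >= xs[j + 1L]) next
    left <- xs[1:j]; right <- xs[(j + 1L):n]
    wcss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (wcss < best$wcss - 1e-12) best <- list(wcss = wcss, split = j)
  }
  thr <- (xs[best$split] + xs[best$split + 1L]) / 2
  list(lower = x <= thr, wcss = best$wcss, threshold = thr)
}

# Regular 12-direction scheme (icosahedral-ish, normalized) plus b0 volumes.
test_protocol <- function(b = 1000, n_b0 = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi),
    c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0),
    c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1),
    c(1, 1, 1), c(1, -1, 1), c(-1, 1, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  dwi_protocol(c(rep(0, n_b0), rep(b, nrow(v))),
               rbind(matrix(0, n_b0, 3), v))
}
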