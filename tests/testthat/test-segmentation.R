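test_that("lateral edge keeps one extreme voxel per occupied column", {
  single <- mask_from_indices(c(5, 5, 5), 63)
  edge <- putamen_lateral_edge(single, hemisphere("right"))
  expect_identical(edge$data, single$data)

  cube <- binary_mask(array(FALSE, dim = c(7, 7, 7)))
  cube$data[3:5, 3:5, 3:5] <- TRUE
  right_face <- putamen_lateral_edge(cube, hemisphere("right"))
  expect_identical(sum(right_face$data), 9L)
  expect_true(all(which(right_face$data, arr.ind = TRUE)[, 1] == 5))
  left_face <- putamen_lateral_edge(cube, hemisphere("left"))
  expect_true(all(which(left_face$data, arr.ind = TRUE)[, 1] == 3))

  expect_error(putamen_lateral_edge(mask_from_indices(c(3, 3, 3), integer(0)),
                                    hemisphere("right")),
               "empty")
})

test_that("lateral edge matches the brute-force per-column scan on random blobs", {
  set.seed(21)
  for (rep in 1:20) {
    d <- sample(6:14, 3, replace = TRUE)
    m <- random_small_mask(d, min(200, prod(d) %/% 2))
    for (side in c("left", "right")) {
      h <- hemisphere(side)
      got <- putamen_lateral_edge(m, h)
      expect_identical(got$data, oracle_lateral_edge(m$data, h$lateral_sign))
      expect_true(all(m$data[got$data]))  # edge is a subset of the putamen
    }
  }
})

test_that("lateral expansion covers exactly round(mm/spacing) voxels beyond the edge", {
  e <- mask_from_indices(c(24, 3, 3), cbind(10, 2, 2), spacing = c(0.7, 0.7, 0.7))
  ex <- expand_lateral(e, hemisphere("right"), 5)
  hit <- which(ex$data, arr.ind = TRUE)
  expect_identical(sort(hit[, 1]), 11:17)  # n = round(5 / 0.7) = 7
  expect_false(any(ex$data & e$data))      # the edge itself is excluded

  # truncation at the grid boundary, no error
  eb <- mask_from_indices(c(12, 3, 3), cbind(10, 2, 2), spacing = c(0.7, 0.7, 0.7))
  exb <- expand_lateral(eb, hemisphere("right"), 5)
  expect_identical(sort(which(exb$data, arr.ind = TRUE)[, 1]), 11:12)

  # a 3x3 edge face becomes a 3x3x7 slab
  face <- binary_mask(array(FALSE, dim = c(24, 5, 5)), c(0.7, 0.7, 0.7))
  face$data[10, 2:4, 2:4] <- TRUE
  slab <- expand_lateral(face, hemisphere("right"), 5)
  expect_identical(sum(slab$data), 9L * 7L)

  empty <- mask_from_indices(c(5, 5, 5), integer(0))
  expect_identical(sum(expand_lateral(empty, hemisphere("right"), 5)$data), 0L)
})

test_that("CSF exclusion removes voxels within the margin, boundary inclusive", {
  d <- c(30, 3, 3)
  csf <- binary_mask(array(FALSE, d)); csf$data[20, , ] <- TRUE
  roi <- mask_from_indices(d, rbind(cbind(25, 2, 2), cbind(26, 2, 2)))
  kept <- exclude_near_csf(roi, csf, 5)
  expect_false(kept$data[25, 2, 2])  # distance 5 <= 5: removed
  expect_true(kept$data[26, 2, 2])   # distance 6: kept

  # empty CSF leaves the ROI untouched
  none <- binary_mask(array(FALSE, d))
  expect_identical(exclude_near_csf(roi, none, 5)$data, roi$data)
})

test_that("CSF exclusion matches the all-pairs distance oracle on random grids", {
  set.seed(22)
  for (rep in 1:20) {
    d <- sample(6:12, 3, replace = TRUE)
    roi <- random_small_mask(d, prod(d) %/% 4)
    csf <- random_small_mask(d, max(1, prod(d) %/% 10))
    margin <- sample(c(1, 2, 3, 5), 1)
    got <- exclude_near_csf(roi, csf, margin)
    expect_identical(got$data, oracle_exclude_near_csf(roi$data, csf$data, margin))
    expect_true(all(roi$data[got$data]))  # result is a subset of the ROI
  }
})

test_that("intensity clustering returns the lower cluster of a separated mixture", {
  d <- c(6, 1, 1)
  roi <- binary_mask(array(TRUE, d))
  t1 <- scalar_volume(array(c(1, 1, 1, 10, 10, 10), d))
  out <- cluster_t1w(roi, t1)
  expect_identical(as.vector(out$mask$data), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(out$centroids), c(1, 10))
  expect_lt(out$centroids[["lower"]], out$centroids[["upper"]])

  const <- scalar_volume(array(7, d))
  expect_error(cluster_t1w(roi, const), "degenerate")
})

test_that("clustering equals the exhaustive split-scan optimum on random instances", {
  set.seed(23)
  for (rep in 1:25) {
    n <- 200
    x <- switch(rep %% 4 + 1,
      c(rnorm(n / 2, 70, 5), rnorm(n / 2, 110, 5)),
      runif(n, 0, 100),
      rexp(n, 1 / 30),
      c(rnorm(n * 0.8, 50, 10), rnorm(n * 0.2, 90, 3))
    )
    d <- c(n, 1, 1)
    roi <- binary_mask(array(TRUE, d))
    got <- cluster_t1w(roi, scalar_volume(array(x, d)))
    want <- oracle_kmeans1d(x)
    expect_identical(as.vector(got$mask$data), want$lower)
  }
})

test_that("sagittal smoothing removes speckles but preserves sheets", {
  params <- seg_params()
  # expected responses derived from the truncated normalized kernel itself
  w <- dnorm(-3:3); w <- w / sum(w)
  central2d <- w[4]^2     # isolated voxel
  line <- w[4]            # 1-voxel-thick in-plane line
  expect_lt(central2d, params$smooth_threshold)
  expect_gte(line, params$smooth_threshold)

  d <- c(3, 21, 21)
  speck <- mask_from_indices(d, cbind(2, 11, 11))
  expect_identical(sum(smooth_in_sagittal_plane(speck, params)$data), 0L)

  sheet <- binary_mask(array(FALSE, d)); sheet$data[2, 11, ] <- TRUE
  sm <- smooth_in_sagittal_plane(sheet, params)
  expect_true(all(sm$data[2, 11, 4:18]))   # line interior survives
  expect_false(any(sm$data[c(1, 3), , ]))  # slices stay independent

  slab <- binary_mask(array(FALSE, d)); slab$data[2, 5:17, 5:17] <- TRUE
  smslab <- smooth_in_sagittal_plane(slab, params)
  expect_true(all(smslab$data[2, 8:14, 8:14]))  # interior of a solid slab unchanged
})

test_that("end-to-end segmentation obeys the subset chain and exclusion zones", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  h <- hemisphere("right")
  params <- seg_params()
  edge <- putamen_lateral_edge(ph$putamen, h)
  roi_exp <- expand_lateral(edge, h, params$expansion_mm)
  roi <- exclude_near_csf(roi_exp, ph$csf, params$csf_margin_voxels)
  res <- segment_claustrum(ph$t1w, ph$putamen, ph$csf, h, params)

  expect_true(all(roi_exp$data[res$mask$data]))
  expect_true(all(roi$data[res$mask$data]))
  expect_false(any(res$mask$data & ph$putamen$data))
  margin_zone <- binary_mask(roi_exp$data & !roi$data, roi$spacing)
  expect_false(any(res$mask$data & margin_zone$data))
  expect_false(any(res$mask$data & ph$csf$data))
  expect_lt(res$report$centroids[["lower"]], res$report$centroids[["upper"]])
  counts <- res$report$counts
  expect_gte(counts$roi_expanded, counts$roi_csf_excluded)
  expect_gte(counts$roi_csf_excluded, counts$initial_cluster)
  expect_gte(counts$smoothed, 0L)
  expect_lte(counts$final, counts$smoothed)

  expect_error(segment_claustrum(ph$t1w, mask_from_indices(dim(ph$t1w$data), integer(0),
                                                           ph$t1w$spacing),
                                 ph$csf, h), "empty")
})

test_that("segmentation is deterministic and mirror-symmetric", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  h <- hemisphere("right")
  a <- segment_claustrum(ph$t1w, ph$putamen, ph$csf, h)
  b <- segment_claustrum(ph$t1w, ph$putamen, ph$csf, h)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$report$counts, b$report$counts)

  mirr <- segment_claustrum(flip_lateral(ph$t1w), flip_lateral(ph$putamen),
                            flip_lateral(ph$csf), hemisphere("left"))
  expect_identical(mirr$mask$data, flip_lateral(a$mask)$data)
})

test_that("a phantom without the claustrum sheet collapses the cluster separation", {
  # with no gray sheet the ROI holds only white-matter noise; the optimal
  # two-cluster split of pure Gaussian noise has centroid separation
  # 2*sqrt(2/pi)*sd (half-normal means), a QC signature the report exposes
  spec0 <- phantom_spec(seed = 1, sheet_thickness_voxels = c(0, 0))
  ph0 <- generate_phantom(spec0)
  expect_identical(sum(ph0$truth_claustrum$data), 0L)
  res0 <- segment_claustrum(ph0$t1w, ph0$putamen, ph0$csf, hemisphere("right"))
  sep0 <- diff(unname(res0$report$centroids))
  expect_equal(sep0, 2 * sqrt(2 / pi) * spec0$noise_sd, tolerance = 0.15)

  ph <- generate_phantom(phantom_spec(seed = 1))
  res <- segment_claustrum(ph$t1w, ph$putamen, ph$csf, hemisphere("right"))
  sep <- diff(unname(res$report$centroids))
  expect_gt(sep, 6 * spec0$noise_sd)  # real gray/white contrast dominates noise
})

test_that("segmentation reports tidy into per-step counts", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  res <- segment_claustrum(ph$t1w, ph$putamen, ph$csf, hemisphere("right"))
  td <- tidy(res$report)
  expect_identical(td$step[1], "edge")
  expect_identical(td$step[nrow(td)], "final")
  expect_true(all(td$voxels >= 0))
  gl <- glance(res$report)
  expect_identical(gl$final_voxels, res$report$counts$final)
  expect_identical(gl$n_warnings, 0L)
})
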