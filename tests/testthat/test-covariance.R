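cohort_table <- function(values, regions = NULL) {
  if (is.null(regions)) regions <- sprintf("r%02d", seq_len(ncol(values)))
  colnames(values) <- regions
  out <- data.frame(subject = sprintf("s%03d", seq_len(nrow(values))), values,
                    check.names = FALSE)
  tibble::as_tibble(out)
}

test_that("per-subject z-scoring standardizes rows and is affine-invariant", {
  tab <- cohort_table(rbind(c(1, 2, 3), c(10, 20, 60)))
  z <- zscore_across_regions(tab)
  expect_equal(unlist(z[1, -1], use.names = FALSE), c(-1, 0, 1))
  m <- as.matrix(z[, -1])
  expect_equal(rowMeans(m), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(m, 1, sd), c(1, 1), tolerance = 1e-10)

  shifted <- tab; shifted[1, -1] <- shifted[1, -1] + 7
  expect_equal(as.matrix(zscore_across_regions(shifted)[, -1]), m, tolerance = 1e-12)
  scaled <- tab; scaled[2, -1] <- scaled[2, -1] * 3
  expect_equal(as.matrix(zscore_across_regions(scaled)[, -1]), m, tolerance = 1e-12)

  const <- cohort_table(rbind(c(1, 2, 3), c(4, 4, 4)))
  expect_error(zscore_across_regions(const), "s002")
})

test_that("network correlations hit the exact-copy endpoints", {
  set.seed(51)
  n <- 30
  seed_vals <- rnorm(n)
  tab <- cohort_table(cbind(
    claustrum.L = seed_vals,
    pos = 2 * seed_vals + 5,
    neg = -0.5 * seed_vals + 1,
    noise = rnorm(n)
  ), regions = c("claustrum.L", "pos.R", "neg.L", "noise.R"))
  res <- covariance_network(tab, "claustrum.L", standardize = FALSE)
  expect_setequal(res$region, c("pos.R", "neg.L", "noise.R"))
  expect_equal(res$r[res$region == "pos.R"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$region == "neg.L"], -1, tolerance = 1e-12)
  expect_identical(res$hemisphere, c("right", "left", "right"))
  expect_error(covariance_network(tab, "amygdala.L"), "not in table")
})

test_that("pairwise-complete handling reports per-region effective n", {
  set.seed(52)
  v <- matrix(rnorm(40), 10, 4)
  v[1:8, 3] <- NA   # only 2 complete pairs for region 3
  v[1:3, 4] <- NA   # 7 complete pairs for region 4
  tab <- cohort_table(v)
  res <- covariance_network(tab, "r01", standardize = FALSE)
  expect_identical(res$n[res$region == "r03"], 2L)
  expect_true(is.nan(res$r[res$region == "r03"]))
  expect_identical(res$n[res$region == "r04"], 7L)
  expect_true(is.finite(res$r[res$region == "r04"]))
})

test_that("Pearson r is invariant to standardization; bias removal needs it", {
  # 40 regions per hemisphere-analysis: the row-mean coupling introduced by
  # per-subject z-scoring is then O(1/40) and negligible
  p <- 40
  C <- diag(p); C[1, 2] <- C[2, 1] <- 0.6
  regions <- sprintf("reg%02d", 1:p)
  clean <- generate_cohort(cohort_spec(200, regions, correlation = C,
                                       bias_sdlog = 0, seed = 7))
  raw <- covariance_network(clean, "reg01", standardize = FALSE)
  std <- covariance_network(clean, "reg01", standardize = TRUE)
  # Pearson r is exactly invariant to per-column affine maps ...
  shifted <- clean
  shifted[["reg02"]] <- 3 * shifted[["reg02"]] + 40
  raw_aff <- covariance_network(shifted, "reg01", standardize = FALSE)
  expect_equal(raw_aff$r, raw$r, tolerance = 1e-12)
  # ... while per-subject z-scoring perturbs r only by the row-mean/row-sd
  # coupling it introduces, O(1/sqrt(p)) at p regions
  expect_lt(max(abs(raw$r - std$r)), 0.12)
  expect_lt(abs(mean(raw$r - std$r)), 0.06)

  biased <- generate_cohort(cohort_spec(200, regions, correlation = C,
                                        bias_sdlog = 0.3, seed = 7))
  raw_b <- covariance_network(biased, "reg01", standardize = FALSE)
  std_b <- covariance_network(biased, "reg01", standardize = TRUE)
  # multiplicative subject bias inflates raw correlations everywhere;
  # z-scoring restores the bias-free values (exactly: the row scale cancels)
  expect_gt(mean(raw_b$r) - mean(raw$r), 0.2)
  expect_equal(std_b$r, std$r, tolerance = 1e-8)
})

test_that("a planted correlation is recovered within twice its standard error", {
  p <- 40
  C <- diag(p); C[1, 21] <- C[21, 1] <- 0.6
  regions <- c(sprintf("reg%02d.L", 1:20), sprintf("reg%02d.R", 1:20))
  regions[1] <- "claustrum.L"; regions[21] <- "claustrum.R"
  spec <- cohort_spec(500, regions, correlation = C, seed = 11)
  res <- covariance_network(generate_cohort(spec), "claustrum.L")
  got <- res$r[res$region == "claustrum.R"]
  expect_lt(abs(got - 0.6), 0.08)  # ~2 x (1 - rho^2) / sqrt(n)
  expect_lt(res$p[res$region == "claustrum.R"], 1e-6)
})

test_that("the Bonferroni rule flags exactly the sub-threshold p-values", {
  set.seed(53)
  tab <- cohort_table(matrix(rnorm(20 * 5), 20, 5))
  res <- covariance_network(tab, "r01")
  res$p <- c(0.01 / 445, 0.009, 0.5, 0.002)  # planted p-values
  out <- correct_significance(res, alpha = 0.01, n_tests = 444)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(attr(out, "n_tests"), 444L)

  # n_tests = 1 reduces to the uncorrected threshold
  out1 <- correct_significance(res, alpha = 0.01, n_tests = 1)
  expect_identical(out1$significant, c(TRUE, TRUE, FALSE, TRUE))

  # default family: 2 hemispheres x targets x 3 measures
  outd <- correct_significance(res, alpha = 0.01)
  expect_identical(attr(outd, "n_tests"), 2L * 4L * 3L)
  expect_error(correct_significance(res, alpha = 1.2), "alpha")
})

test_that("covariance results tidy, glance and plot", {
  set.seed(54)
  tab <- cohort_table(matrix(rnorm(30 * 6), 30, 6))
  res <- correct_significance(covariance_network(tab, "r02"), alpha = 0.05)
  td <- tidy(res)
  expect_named(td, c("region", "hemisphere", "r", "p", "n", "significant"))
  gl <- glance(res)
  expect_identical(gl$seed, "r02")
  expect_identical(gl$n_regions, 5L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
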