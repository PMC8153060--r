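#' Cohort specification for the covariance analysis
#'
#' Describes a synthetic subjects-by-regions table: values are drawn from a
#' multivariate normal with a planted cross-region correlation matrix, then
#' each subject's row is multiplied by a per-subject bias scalar. The bias
#' emulates global subject effects (head size, residual intensity scaling)
#' that per-subject z-scoring across regions is designed to neutralize.
#'
#' @param n_subjects Number of subjects (>= 2; 1 is rejected because all
#'   downstream correlations would be undefined).
#' @param regions Character vector of region labels (may carry `.L`/`.R`
#'   hemisphere suffixes).
#' @param correlation Planted correlation matrix (symmetric positive
#'   semi-definite, unit diagonal); default identity.
#' @param region_means Mean value per region; default 10 for all regions (a
#'   multiplicative bias only distorts correlations when means are non-zero,
#'   which is the realistic regime for volumes and ratio values).
#' @param noise_sd Scale of the correlated fluctuations around the means.
#' @param bias_sdlog Log-sd of the lognormal per-subject multiplicative
#'   bias; 0 disables the bias.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, regions, correlation = NULL,
                        region_means = NULL, noise_sd = 1, bias_sdlog = 0,
                        seed = 1) {
  if (n_subjects < 2L) {
    abort_domain("n_subjects must be >= 2: correlations are undefined for a single subject")
  }
  regions <- as.character(regions)
  p <- length(regions)
  if (p < 2L || anyDuplicated(regions)) {
    abort_domain("regions must be >= 2 distinct labels")
  }
  if (is.null(correlation)) correlation <- diag(p)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)) ||
      any(abs(diag(correlation) - 1) > 1e-8)) {
    abort_domain("correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_domain("correlation matrix is not positive semi-definite")
  }
  if (is.null(region_means)) region_means <- rep(10, p)
  if (length(region_means) == 1L) region_means <- rep(region_means, p)
  if (length(region_means) != p) {
    abort_domain("region_means must have one entry per region")
  }
  if (noise_sd <= 0) abort_domain("noise_sd must be > 0")
  if (bias_sdlog < 0) abort_domain("bias_sdlog must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), regions = regions,
         correlation = correlation, region_means = as.numeric(region_means),
         noise_sd = as.numeric(noise_sd), bias_sdlog = as.numeric(bias_sdlog),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort table
#'
#' Draws the subjects-by-regions matrix described by a [cohort_spec()]:
#' correlated Gaussian fluctuations (via the symmetric matrix square root of
#' the planted correlation) around the region means, each row then scaled by
#' its subject's multiplicative bias. Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with a `subject` column and one numeric column per
#'   region.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort_domain("spec must be a cohort_spec")
  p <- length(spec$regions)
  ed <- eigen(spec$correlation, symmetric = TRUE)
  root <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p) %*% t(ed$vectors)
  with_local_seed(spec$seed, {
    z <- matrix(stats::rnorm(spec$n_subjects * p), spec$n_subjects, p) %*% root
    values <- sweep(z * spec$noise_sd, 2L, spec$region_means, `+`)
    if (spec$bias_sdlog > 0) {
      bias <- stats::rlnorm(spec$n_subjects, meanlog = 0, sdlog = spec$bias_sdlog)
      values <- values * bias
    }
    colnames(values) <- spec$regions
    out <- data.frame(subject = sprintf("sub-%04d", seq_len(spec$n_subjects)),
                      values, check.names = FALSE)
    tibble::as_tibble(out)
  })
}
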