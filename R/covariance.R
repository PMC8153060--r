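# A region-measure table is an ordinary data frame / tibble: one subject-ID
# column plus one numeric column per region, region labels carrying an
# optional hemisphere suffix ".L"/".R". This keeps the covariance layer
# pipe-friendly and lets cohorts come straight from CSV.

measure_matrix <- function(table, subject_col = "subject") {
  if (!is.data.frame(table)) abort_domain("table must be a data frame")
  if (!subject_col %in% names(table)) {
    abort_io("table has no '%s' column", subject_col)
  }
  regions <- setdiff(names(table), subject_col)
  if (anyDuplicated(regions)) abort_domain("duplicate region labels")
  if (length(regions) < 2L) abort_domain("need at least 2 region columns")
  m <- as.matrix(table[regions])
  if (!is.numeric(m)) abort_domain("region columns must be numeric")
  rownames(m) <- as.character(table[[subject_col]])
  m
}

region_hemisphere <- function(labels) {
  ifelse(grepl("\\.L$", labels), "left",
         ifelse(grepl("\\.R$", labels), "right", NA_character_))
}

#' Z-score each subject's measurements across regions
#'
#' Structural covariance is sensitive to subject-specific global biases
#' (overall head size, residual intensity scaling): such biases move all of a
#' subject's regional values together and manufacture spurious positive
#' correlations. Standardizing each subject's row across regions - subtract
#' the row mean, divide by the row standard deviation (sample, n - 1
#' convention) - removes any per-subject affine bias before regions are
#' correlated across subjects.
#'
#' @param table Data frame: one subject-ID column plus numeric region
#'   columns. Missing values stay missing; each row needs at least 2
#'   distinct finite values.
#' @param subject_col Name of the subject-ID column (default `"subject"`).
#' @return A tibble of the same shape with standardized region values: every
#'   row has mean 0 and sd 1 over its finite entries.
#' @export
zscore_across_regions <- function(table, subject_col = "subject") {
  m <- measure_matrix(table, subject_col)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    fin <- is.finite(x)
    if (sum(fin) < 2L || length(unique(x[fin])) < 2L) {
      abort_domain("subject '%s' has a constant (or near-empty) row: z-score undefined",
                   rownames(m)[i])
    }
    m[i, fin] <- (x[fin] - mean(x[fin])) / stats::sd(x[fin])
  }
  out <- data.frame(table[[subject_col]], as.data.frame(m), check.names = FALSE)
  names(out)[1] <- subject_col
  tibble::as_tibble(out)
}

#' Seed-based structural covariance network
#'
#' Correlates one seed region (here, typically a claustrum) with every other
#' region across subjects: for each non-seed region the Pearson r and
#' two-sided p-value over subjects, with pairwise-complete handling of
#' missing values and the effective n reported per region. Regions with
#' fewer than 3 complete pairs get an `NaN` correlation and are flagged. The input is
#' standardized per subject first (Pearson r itself is affine-invariant, so
#' this only matters through cross-subject bias removal); set
#' `standardize = FALSE` if the table already went through
#' [zscore_across_regions()].
#'
#' @param table Data frame as for [zscore_across_regions()], with at least 3
#'   subjects.
#' @param seed Region label of the seed column.
#' @param subject_col Name of the subject-ID column.
#' @param standardize Apply [zscore_across_regions()] first? Default `TRUE`.
#' @return A `covariance_result`: a tibble with columns `region`,
#'   `hemisphere`, `r`, `p`, `n`, and attribute metadata (seed label,
#'   standardization flag). Pass to [correct_significance()] to add the
#'   `significant` flag.
#' @export
covariance_network <- function(table, seed, subject_col = "subject",
                               standardize = TRUE) {
  if (standardize) table <- zscore_across_regions(table, subject_col)
  m <- measure_matrix(table, subject_col)
  if (!seed %in% colnames(m)) abort_domain("seed region '%s' not in table", seed)
  if (nrow(m) < 3L) abort_domain("need at least 3 subjects for correlations")
  targets <- setdiff(colnames(m), seed)
  x <- m[, seed]
  r <- p <- rep(NA_real_, length(targets))
  n <- integer(length(targets))
  for (i in seq_along(targets)) {
    y <- m[, targets[i]]
    ok <- is.finite(x) & is.finite(y)
    n[i] <- sum(ok)
    if (n[i] < 3L) {
      r[i] <- NaN
      p[i] <- NaN
      next
    }
    r[i] <- stats::cor(x[ok], y[ok])
    # two-sided p from the t transform of Pearson r
    tt <- r[i] * sqrt((n[i] - 2) / (1 - r[i]^2))
    p[i] <- 2 * stats::pt(-abs(tt), df = n[i] - 2)
  }
  out <- tibble::tibble(
    region = targets,
    hemisphere = region_hemisphere(targets),
    r = r, p = p, n = n
  )
  structure(out,
            class = c("covariance_result", class(out)),
            seed = seed, standardized = TRUE)
}

#' Flag significant correlations after multiple-comparison correction
#'
#' Applies a family-wise correction over the full analysis family. The
#' default family size follows the scheme of correcting over both
#' hemispheres' seeds and all measures analyzed: `n_tests = 2 x (target
#' regions in this result) x n_measures`. With the Bonferroni rule a region
#' is significant iff `p < alpha / n_tests` (the strictest defensible
#' reading of an unnamed correction); Benjamini-Hochberg is available as a
#' less conservative alternative.
#'
#' @param result A `covariance_result` from [covariance_network()].
#' @param alpha Family-wise level in (0, 1); default 0.01.
#' @param n_tests Family size; default `2 * nrow(result) * n_measures`.
#' @param n_measures Number of measures in the family (default 3: volume,
#'   T1w/T2w, MD), used only for the default `n_tests`.
#' @param method `"bonferroni"` (default) or `"bh"`.
#' @return The result tibble with a logical `significant` column and
#'   attributes `alpha`, `n_tests`, `method`.
#' @export
correct_significance <- function(result, alpha = 0.01, n_tests = NULL,
                                 n_measures = 3, method = c("bonferroni", "bh")) {
  if (!inherits(result, "covariance_result")) {
    abort_domain("result must come from covariance_network()")
  }
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_domain("alpha must lie in (0, 1)")
  }
  if (is.null(n_tests)) n_tests <- 2L * nrow(result) * n_measures
  if (n_tests < 1L) abort_domain("n_tests must be >= 1")
  sig <- if (method == "bonferroni") {
    result$p < alpha / n_tests
  } else {
    # BH over the family: pad the observed p-values to the declared family
    # size so the correction is not anti-conservative for a sub-family.
    stats::p.adjust(result$p, method = "BH", n = max(n_tests, sum(is.finite(result$p)))) < alpha
  }
  sig[!is.finite(result$p)] <- NA
  result$significant <- sig
  attr(result, "alpha") <- alpha
  attr(result, "n_tests") <- as.integer(n_tests)
  attr(result, "method") <- method
  result
}

#' Tidy a covariance result
#'
#' @param x A `covariance_result`.
#' @param ... Unused.
#' @return The per-region tibble (region, hemisphere, r, p, n, and
#'   `significant` when correction has been applied).
#' @export
tidy.covariance_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("region", "hemisphere", "r", "p", "n",
                                 intersect("significant", names(x)))])
}

#' One-row summary of a covariance result
#'
#' @param x A `covariance_result`.
#' @param ... Unused.
#' @return A tibble with the seed label, region count, correction settings,
#'   and number of significant regions (NA before correction).
#' @export
glance.covariance_result <- function(x, ...) {
  tibble::tibble(
    seed = attr(x, "seed"),
    n_regions = nrow(x),
    alpha = attr(x, "alpha") %||% NA_real_,
    n_tests = attr(x, "n_tests") %||% NA_integer_,
    method = attr(x, "method") %||% NA_character_,
    n_significant = if ("significant" %in% names(x)) sum(x$significant, na.rm = TRUE) else NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a covariance network result
#'
#' Dot plot of Pearson r per target region, ordered by correlation strength,
#' with significant regions (if correction has been applied) filled.
#'
#' @param object A `covariance_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.covariance_result <- function(object, ...) {
  df <- tidy(object)
  df$region <- stats::reorder(df$region, df$r)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = r, y = region)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60")
  if ("significant" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = significant))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(
    x = "Pearson r (across subjects)",
    y = NULL,
    title = sprintf("Structural covariance with seed '%s'", attr(object, "seed"))
  )
}

#' @export
ggplot2::autoplot
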