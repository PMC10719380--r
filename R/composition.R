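#' Direction ratio of excluded vs included events
#'
#' The headline composition statistic for a contrast: the ratio of the
#' number of significantly excluded events (negative delta-PSI) to the
#' number of significantly included ones (positive delta-PSI), or the
#' reciprocal. A ratio above 1 in the excluded-over-included orientation
#' means exclusions dominate. Both orientations are used in practice
#' (treatment summaries typically report excluded/included, tumor-vs-normal
#' summaries included/excluded), so the orientation is always explicit.
#'
#' @param n_excluded,n_included Non-negative event counts.
#' @param orientation `"excluded_over_included"` (default) or
#'   `"included_over_excluded"`.
#' @return The ratio; `Inf` when only the numerator is nonzero, `NaN`
#'   (undefined) for 0/0. Vectorised.
#' @examples
#' direction_ratio(327, 64)   # ~5.11, exclusions dominate
#' @export
direction_ratio <- function(n_excluded, n_included,
                            orientation = c("excluded_over_included",
                                            "included_over_excluded")) {
  orientation <- match.arg(orientation)
  if (any(n_excluded < 0) || any(n_included < 0)) {
    stop("event counts must be non-negative", call. = FALSE)
  }
  if (orientation == "excluded_over_included") {
    n_excluded / n_included
  } else {
    n_included / n_excluded
  }
}

# Two-proportion test of (x1 of n1) vs (x2 of n2): pooled-variance z-test
# (equivalently 1-df chi-square without continuity correction), replaced by
# Fisher's exact test when any cell of the 2x2 table is below 5.
.two_prop_p <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) return(NA_real_)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2)
  if (any(tab < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    # observed cells are all >= 5; prop.test's expected-count warning is
    # handled by the Fisher fallback rule above
    suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value
    )
  }
}

#' Category proportion test (category vs complement)
#'
#' Tests, per event category, whether the category's rate of significant
#' events among tested events differs from the rate in all remaining
#' categories pooled. A two-sided two-proportion test with pooled variance
#' is used, with Fisher's exact test as the small-count fallback (any 2x2
#' cell < 5). P-values are Bonferroni-adjusted by the number of categories
#' with at least one tested event, capped at 1.
#'
#' @param composition Tibble with columns `category`, `n_significant`,
#'   `n_tested` (one row per category).
#' @return The input with `p_proportion` (raw) and `p_proportion_adj`
#'   columns added; categories with no tested events or an empty complement
#'   get `NA` (untested marker).
#' @export
category_proportion_test <- function(composition) {
  stopifnot(all(c("category", "n_significant", "n_tested") %in%
                  names(composition)))
  stopifnot(all(composition$n_significant <= composition$n_tested))
  N_sig <- sum(composition$n_significant)
  N_test <- sum(composition$n_tested)
  p <- vapply(seq_len(nrow(composition)), function(i) {
    n1 <- composition$n_tested[i]
    x1 <- composition$n_significant[i]
    n2 <- N_test - n1
    x2 <- N_sig - x1
    .two_prop_p(x1, n1, x2, n2)
  }, numeric(1))
  m <- sum(composition$n_tested > 0)
  composition$p_proportion <- p
  composition$p_proportion_adj <- pmin(1, p * m)
  composition
}

#' Included-vs-excluded imbalance test per category
#'
#' Tests, per category, whether significant events split evenly between the
#' included and excluded directions. With 20 or more significant events a
#' one-sample chi-square test (1 df) against a 50:50 split is used, with
#' Yates continuity correction so the large-sample branch tracks the exact
#' test; below 20 the exact two-sided binomial test is substituted.
#' Bonferroni adjustment is over the categories with at least one
#' significant event.
#'
#' @param composition Tibble with columns `category`, `n_included`,
#'   `n_excluded`.
#' @param exact_below Sample size below which the exact binomial branch is
#'   used (default 20).
#' @return The input with `p_imbalance` and `p_imbalance_adj` added;
#'   categories with no significant events get `NA`.
#' @export
inclusion_imbalance_test <- function(composition, exact_below = 20) {
  stopifnot(all(c("category", "n_included", "n_excluded") %in%
                  names(composition)))
  p <- vapply(seq_len(nrow(composition)), function(i) {
    a <- composition$n_included[i]
    b <- composition$n_excluded[i]
    n <- a + b
    if (n < 1) return(NA_real_)
    if (n < exact_below) {
      stats::binom.test(a, n, p = 0.5)$p.value
    } else {
      # continuity-corrected 1-df chi-square against a 50:50 split
      stat <- max(0, abs(a - b) - 1)^2 / n
      stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }, numeric(1))
  m <- sum(composition$n_included + composition$n_excluded >= 1)
  composition$p_imbalance <- p
  composition$p_imbalance_adj <- pmin(1, p * m)
  composition
}

#' Per-category composition summary of a contrast
#'
#' Aggregates a contrast's calls by event category — tested, significant,
#' included and excluded counts, the direction ratio — and applies both the
#' category-vs-complement proportion test and the included-vs-excluded
#' imbalance test with Bonferroni correction.
#'
#' @param contrast A `splice_contrast` (or tibble with `category`,
#'   `testable`, `significant`, `direction` columns).
#' @param ratio_orientation Orientation passed to [direction_ratio()].
#' @return A tibble with one row per category present in the contrast.
#' @export
composition_summary <- function(contrast,
                                ratio_orientation = "excluded_over_included") {
  comp <- tibble::as_tibble(contrast) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_tested = sum(.data$testable),
      n_significant = sum(.data$significant),
      n_included = sum(.data$direction == "included"),
      n_excluded = sum(.data$direction == "excluded"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio = direction_ratio(.data$n_excluded, .data$n_included,
                              orientation = ratio_orientation)
    )
  comp <- category_proportion_test(comp)
  inclusion_imbalance_test(comp)
}

#' PSI concordance between two measurement methods
#'
#' Ordinary least-squares regression of one set of PSI measurements on
#' another (e.g. RT-PCR isoform quantification vs RNA-seq estimates for the
#' same events), reporting slope, intercept and R-squared (squared Pearson
#' correlation). Used to validate sequencing-based PSI estimates against an
#' orthogonal assay.
#'
#' @param data A data frame of paired measurements.
#' @param method1,method2 Column names (tidyselect) holding the two PSI
#'   measurements, each in \[0, 1\]. `method2` is regressed on `method1`.
#' @return An object of class `psi_concordance` with fields `slope`,
#'   `intercept`, `r_squared`, `n_points`, `undefined` and the underlying
#'   `lm` fit; `tidy()` and `glance()` methods are provided. Zero variance
#'   in either coordinate yields `undefined = TRUE` with `NA` statistics.
#' @examples
#' d <- tibble::tibble(rtpcr = c(.1, .4, .5, .8, .9),
#'                     rnaseq = c(.15, .38, .55, .78, .88))
#' glance(psi_concordance(d, rtpcr, rnaseq))
#' @export
psi_concordance <- function(data, method1, method2) {
  x <- dplyr::pull(data, {{ method1 }})
  y <- dplyr::pull(data, {{ method2 }})
  if (length(x) < 3) stop("at least 3 pairs are required", call. = FALSE)
  if (any(x < 0 | x > 1 | y < 0 | y > 1, na.rm = TRUE)) {
    stop("PSI values must lie in [0, 1]", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(
      list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
           n_points = length(x), undefined = TRUE, fit = NULL),
      class = "psi_concordance"
    ))
  }
  fit <- stats::lm(y ~ x)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = unname(stats::cor(x, y)^2),
      n_points = length(x),
      undefined = FALSE,
      fit = fit
    ),
    class = "psi_concordance"
  )
}

#' @export
print.psi_concordance <- function(x, ...) {
  if (x$undefined) {
    cat("<psi_concordance> undefined (zero variance), n =", x$n_points, "\n")
  } else {
    cat(sprintf(
      "<psi_concordance> R^2 = %.3f, slope = %.3f, intercept = %.3f, n = %d\n",
      x$r_squared, x$slope, x$intercept, x$n_points
    ))
  }
  invisible(x)
}

#' @rdname psi_concordance
#' @param x A `psi_concordance` object.
#' @param ... Unused.
#' @method tidy psi_concordance
#' @export
tidy.psi_concordance <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname psi_concordance
#' @method glance psi_concordance
#' @export
glance.psi_concordance <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    n_points = x$n_points,
    undefined = x$undefined
  )
}
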