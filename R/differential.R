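#' Pool replicate read counts within conditions
#'
#' Sums inclusion- and exclusion-supporting counts over the replicates of
#' each condition, per event. The Bayes factor for a contrast is computed on
#' these pooled counts; replicate-level information re-enters through the
#' direction-consistency rule of [call_contrast()].
#'
#' @param counts Counts tibble with columns `event_id`, `condition`,
#'   `n_inc`, `n_exc` (replicate-level rows).
#' @return Tibble with one row per event and condition: `event_id`,
#'   `condition`, `n_inc`, `n_exc`, `n_total`, `n_replicates`.
#' @examples
#' x <- tibble::tibble(event_id = "e1", condition = "A",
#'                     replicate = 1:2, n_inc = c(3L, 2L), n_exc = c(7L, 8L))
#' pool_replicates(x)
#' @export
pool_replicates <- function(counts) {
  stopifnot(all(c("event_id", "condition", "n_inc", "n_exc") %in%
                  names(counts)))
  counts |>
    dplyr::group_by(.data$event_id, .data$condition) |>
    dplyr::summarise(
      n_inc = sum(.data$n_inc),
      n_exc = sum(.data$n_exc),
      n_total = sum(.data$n_inc) + sum(.data$n_exc),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Replicate direction-consistency rule
#'
#' The two-part calling rule for a differential splicing event: the Bayes
#' factor on the pooled data must reach `bf_threshold`, and every
#' per-replicate delta-PSI must share the sign of the pooled delta-PSI.
#' A per-replicate delta-PSI of exactly 0 (or within `epsilon` of 0) counts
#' as inconsistent, as does a pooled delta-PSI of 0.
#'
#' @param bf Pooled Bayes factor (NA for untestable events).
#' @param delta_psi_pooled Pooled delta-PSI.
#' @param replicate_delta_psi Numeric vector of per-replicate delta-PSI
#'   point-estimate differences.
#' @param bf_threshold Bayes-factor calling threshold (default 20).
#' @param epsilon Half-width of the zero band for sign determination
#'   (default 0: strict signs).
#' @return Logical: does the event pass both parts of the rule?
#' @examples
#' replicate_consistent(25, 0.15, c(0.10, 0.20, 0.15))   # TRUE
#' replicate_consistent(25, 0.10, c(0.10, -0.05, 0.20))  # FALSE: mixed signs
#' replicate_consistent(19.9, 0.15, c(0.10, 0.20, 0.15)) # FALSE: BF < 20
#' @export
replicate_consistent <- function(bf, delta_psi_pooled, replicate_delta_psi,
                                 bf_threshold = 20, epsilon = 0) {
  if (is.na(bf) || bf < bf_threshold) return(FALSE)
  sgn <- function(x) (x > epsilon) - (x < -epsilon)
  s0 <- sgn(delta_psi_pooled)
  if (s0 == 0) return(FALSE)
  all(sgn(replicate_delta_psi) == s0)
}

#' Call differential splicing events for one contrast
#'
#' Runs the full per-contrast calling procedure on replicate-level junction
#' counts: replicates are pooled within each condition, a Bayes factor and
#' pooled delta-PSI are computed per event, per-replicate delta-PSI values
#' are computed by pairing replicate i of condition B with replicate i of
#' condition A, and an event is called significant when the pooled Bayes
#' factor reaches `bf_threshold` and all replicate delta-PSIs share the sign
#' of the pooled delta-PSI. Significant events with positive delta-PSI are
#' direction `"included"`, negative `"excluded"`.
#'
#' Events with pooled depth below `min_info` in either condition are
#' untestable: they are reported with `testable = FALSE`, `bf = NA`,
#' direction `"none"`, and are excluded from the `n_tested` denominator.
#'
#' @param counts Replicate-level counts tibble (`event_id`, `sample_id`,
#'   `condition`, `replicate`, `n_inc`, `n_exc`).
#' @param catalog Event catalog tibble supplying `gene_id`, `category` and
#'   effective lengths per event.
#' @param conditions Length-2 character vector `c(A, B)`; delta-PSI is
#'   condition B minus condition A.
#' @param bf_threshold Bayes-factor threshold (default 20).
#' @param min_info Minimum pooled read depth per condition for an event to
#'   be testable (default 10).
#' @param grid_size Quadrature grid size passed to the PSI engine.
#' @param epsilon Zero band for the sign-consistency rule (default 0).
#' @param contrast_label Free-text label stored with the result.
#' @return A tibble of class `splice_contrast`, one row per event:
#'   `event_id`, `gene_id`, `category`, pooled depths `n_total_a`/`n_total_b`,
#'   `testable`, posterior means `psi_a`/`psi_b`, `bf`, `delta_psi`,
#'   list-column `replicate_delta_psi`, `consistent`, `significant`,
#'   `direction`. Attributes record the contrast label, conditions,
#'   thresholds, `n_tested` and `n_significant`.
#' @export
call_contrast <- function(counts, catalog, conditions,
                          bf_threshold = 20, min_info = 10,
                          grid_size = 1001, epsilon = 0,
                          contrast_label = paste(conditions[2], "vs",
                                                 conditions[1])) {
  stopifnot(length(conditions) == 2)
  cond_a <- conditions[1]
  cond_b <- conditions[2]
  cc <- dplyr::filter(counts, .data$condition %in% conditions)
  if (nrow(cc) == 0) {
    stop("no counts found for conditions ", paste(conditions, collapse = ", "),
         call. = FALSE)
  }
  reps_a <- sort(unique(cc$replicate[cc$condition == cond_a]))
  reps_b <- sort(unique(cc$replicate[cc$condition == cond_b]))
  if (!identical(reps_a, reps_b)) {
    stop("replicate structure differs between conditions; replicates are ",
         "paired by index and must match", call. = FALSE)
  }
  n_rep <- length(reps_a)

  events <- catalog[catalog$event_id %in% unique(cc$event_id), ]
  ord <- events$event_id
  n_ev <- length(ord)
  grid <- .psi_grid(grid_size)

  pooled <- pool_replicates(cc)
  get_pooled <- function(cond) {
    p <- pooled[pooled$condition == cond, ]
    p <- p[match(ord, p$event_id), ]
    # events never observed in a condition count as zero reads
    p$n_inc[is.na(p$n_inc)] <- 0L
    p$n_exc[is.na(p$n_exc)] <- 0L
    p
  }
  pa <- get_pooled(cond_a)
  pb <- get_pooled(cond_b)
  testable <- (pa$n_inc + pa$n_exc >= min_info) &
    (pb$n_inc + pb$n_exc >= min_info)

  L_inc <- events$L_inc
  L_exc <- events$L_exc

  bf <- rep(NA_real_, n_ev)
  psi_a <- rep(NA_real_, n_ev)
  psi_b <- rep(NA_real_, n_ev)
  ti <- which(testable)
  if (length(ti)) {
    bres <- bayes_factor(pa$n_inc[ti], pa$n_exc[ti],
                         pb$n_inc[ti], pb$n_exc[ti],
                         L_inc[ti], L_exc[ti], grid_size = grid_size)
    bf[ti] <- bres$bf
    psi_a[ti] <- bres$psi_a
    psi_b[ti] <- bres$psi_b
  }
  delta <- psi_b - psi_a

  # per-replicate posterior-mean delta-PSI, replicate i of B minus i of A
  rep_mat <- matrix(NA_real_, n_ev, n_rep)
  for (j in seq_len(n_rep)) {
    ra <- cc[cc$condition == cond_a & cc$replicate == reps_a[j], ]
    rb <- cc[cc$condition == cond_b & cc$replicate == reps_b[j], ]
    ia <- match(ord, ra$event_id)
    ib <- match(ord, rb$event_id)
    for (i in ti) {
      ma <- .psi_post(
        if (is.na(ia[i])) 0L else ra$n_inc[ia[i]],
        if (is.na(ia[i])) 0L else ra$n_exc[ia[i]],
        L_inc[i], L_exc[i], grid, want_ci = FALSE
      )[1]
      mb <- .psi_post(
        if (is.na(ib[i])) 0L else rb$n_inc[ib[i]],
        if (is.na(ib[i])) 0L else rb$n_exc[ib[i]],
        L_inc[i], L_exc[i], grid, want_ci = FALSE
      )[1]
      rep_mat[i, j] <- mb - ma
    }
  }

  consistent <- vapply(seq_len(n_ev), function(i) {
    if (!testable[i]) return(FALSE)
    replicate_consistent(bf[i], delta[i], rep_mat[i, ],
                         bf_threshold = -Inf, epsilon = epsilon)
  }, logical(1))
  significant <- testable & !is.na(bf) & bf >= bf_threshold & consistent
  direction <- dplyr::case_when(
    significant & delta > 0 ~ "included",
    significant & delta < 0 ~ "excluded",
    .default = "none"
  )

  out <- tibble::tibble(
    event_id = ord,
    gene_id = events$gene_id,
    category = events$category,
    n_total_a = as.integer(pa$n_inc + pa$n_exc),
    n_total_b = as.integer(pb$n_inc + pb$n_exc),
    testable = testable,
    psi_a = psi_a,
    psi_b = psi_b,
    bf = bf,
    delta_psi = delta,
    replicate_delta_psi = lapply(seq_len(n_ev), function(i) rep_mat[i, ]),
    consistent = consistent,
    significant = significant,
    direction = direction
  )
  new_splice_contrast(out, contrast_label = contrast_label,
                      conditions = stats::setNames(conditions, c("a", "b")),
                      bf_threshold = bf_threshold, min_info = min_info)
}

new_splice_contrast <- function(x, contrast_label, conditions,
                                bf_threshold, min_info) {
  structure(
    x,
    class = c("splice_contrast", class(tibble::tibble())),
    contrast_label = contrast_label,
    conditions = conditions,
    bf_threshold = bf_threshold,
    min_info = min_info,
    n_tested = sum(x$testable),
    n_significant = sum(x$significant)
  )
}

#' @export
print.splice_contrast <- function(x, ...) {
  cat(sprintf(
    "<splice_contrast> %s: %d events, %d tested, %d significant (BF >= %s)\n",
    attr(x, "contrast_label"), nrow(x), attr(x, "n_tested"),
    attr(x, "n_significant"), format(attr(x, "bf_threshold"))
  ))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contrast result into a plain tibble
#'
#' @param x A `splice_contrast` object.
#' @param ... Unused.
#' @return The calls as a plain tibble (attributes dropped).
#' @method tidy splice_contrast
#' @export
tidy.splice_contrast <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "contrast_label") <- NULL
  out
}

#' One-row summary of a contrast result
#'
#' @param x A `splice_contrast` object.
#' @param ... Unused.
#' @return A one-row tibble with the event funnel: events in, tested,
#'   significant, included/excluded counts and thresholds.
#' @method glance splice_contrast
#' @export
glance.splice_contrast <- function(x, ...) {
  tibble::tibble(
    contrast = attr(x, "contrast_label"),
    n_events = nrow(x),
    n_tested = attr(x, "n_tested"),
    n_significant = attr(x, "n_significant"),
    n_included = sum(x$direction == "included"),
    n_excluded = sum(x$direction == "excluded"),
    bf_threshold = attr(x, "bf_threshold"),
    min_info = attr(x, "min_info")
  )
}
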