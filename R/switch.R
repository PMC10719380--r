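#' Intersect treatment and disease contrasts
#'
#' Joins, by event id, the events called significant in both a treatment
#' contrast (e.g. apigenin vs control in tumor cells) and a disease contrast
#' (tumor vs normal tissue), attaching both pooled delta-PSI values. The
#' disease delta-PSI follows the tumor-minus-normal orientation of its
#' contrast. An attribute `overlap_enrichment` records a hypergeometric test
#' of the shared-set size at event granularity: universe = events testable
#' in both contrasts, drawing the treatment-significant events against the
#' disease-significant ones.
#'
#' @param treatment,disease `splice_contrast` results over the same
#'   event-id space.
#' @return A tibble with one row per shared significant event: `event_id`,
#'   `gene_id`, `category`, `treat_dpsi`, `disease_dpsi`. Disjoint event-id
#'   spaces give an empty result with a warning.
#' @export
intersect_contrasts <- function(treatment, disease) {
  tt <- tibble::as_tibble(treatment)
  dd <- tibble::as_tibble(disease)
  if (length(intersect(tt$event_id, dd$event_id)) == 0) {
    warning("the two contrasts share no event ids; empty intersection",
            call. = FALSE)
  }
  shared <- dplyr::inner_join(
    dplyr::select(dplyr::filter(tt, .data$significant),
                  "event_id", "gene_id", "category",
                  treat_dpsi = "delta_psi"),
    dplyr::select(dplyr::filter(dd, .data$significant),
                  "event_id", disease_dpsi = "delta_psi"),
    by = "event_id"
  )
  universe <- intersect(tt$event_id[tt$testable], dd$event_id[dd$testable])
  if (length(universe) > 0) {
    enr <- hypergeometric_enrichment(
      intersect(tt$event_id[tt$significant], universe),
      list(disease_significant = intersect(dd$event_id[dd$significant],
                                           universe)),
      universe
    )
    attr(shared, "overlap_enrichment") <- enr
  }
  shared
}

#' Classify shared events as switched toward the non-tumor profile
#'
#' A shared event is "switched" when the treatment moves its splicing in the
#' direction opposite to the tumor-vs-normal difference: the sign of the
#' treatment delta-PSI is the negative of the sign of the disease delta-PSI
#' (tumor minus normal), both nonzero. In other words, the treatment pushes
#' the event back toward its non-tumor level. The default classification is
#' sign-only; the stricter `"restore"` mode additionally requires the
#' treatment magnitude to be within `restore_tol` of the disease magnitude.
#'
#' @param shared Tibble from [intersect_contrasts()] (columns `treat_dpsi`,
#'   `disease_dpsi`).
#' @param mode `"sign"` (default) or `"restore"`.
#' @param restore_tol Allowed absolute difference between |treat_dpsi| and
#'   |disease_dpsi| in `"restore"` mode (default 0.2).
#' @return The input with a logical `switched` column added.
#' @examples
#' classify_switch(tibble::tibble(treat_dpsi = c(-0.3, 0.3),
#'                                disease_dpsi = c(0.4, 0.4)))
#' @export
classify_switch <- function(shared, mode = c("sign", "restore"),
                            restore_tol = 0.2) {
  mode <- match.arg(mode)
  stopifnot(all(c("treat_dpsi", "disease_dpsi") %in% names(shared)))
  sw <- sign(shared$treat_dpsi) == -sign(shared$disease_dpsi) &
    shared$treat_dpsi != 0 & shared$disease_dpsi != 0
  if (mode == "restore") {
    sw <- sw &
      abs(abs(shared$treat_dpsi) - abs(shared$disease_dpsi)) <= restore_tol
  }
  dplyr::mutate(shared, switched = sw)
}

.count_of <- function(x) {
  if (is.numeric(x) && length(x) == 1) return(as.integer(x))
  if (is.data.frame(x)) {
    if ("switched" %in% names(x)) return(sum(x$switched))
    if ("significant" %in% names(x)) return(sum(x$significant))
    return(nrow(x))
  }
  stop("expected a count or a calls table", call. = FALSE)
}

#' Summarise the treatment/disease switch analysis
#'
#' Computes the headline switch percentages: the share of
#' treatment-affected events that are also disease-dysregulated
#' (`pct_shared_of_treatment`), and the share of those shared events that
#' the treatment switches toward the non-tumor profile
#' (`pct_switched_of_shared`). Arguments may be the result tables
#' (significant/switched rows are counted) or plain counts, so published
#' event tallies can be summarised directly.
#'
#' @param treatment Treatment `splice_contrast` or count of
#'   treatment-significant events.
#' @param shared Shared-event tibble or count.
#' @param switched Switch-call tibble (counts `switched` rows) or count.
#' @return One-row tibble: `n_treatment_significant`, `n_shared`,
#'   `n_switched`, `pct_shared_of_treatment`, `pct_switched_of_shared`
#'   (percent scale; `NA` when a denominator is zero).
#' @examples
#' switch_summary(2409, 406, 254)  # ~17% shared, ~63% switched
#' @export
switch_summary <- function(treatment, shared, switched) {
  n_t <- .count_of(treatment)
  n_sh <- if (is.data.frame(shared)) nrow(shared) else as.integer(shared)
  n_sw <- .count_of(switched)
  if (n_sw > n_sh || n_sh > n_t) {
    stop("expected n_switched <= n_shared <= n_treatment_significant",
         call. = FALSE)
  }
  tibble::tibble(
    n_treatment_significant = n_t,
    n_shared = n_sh,
    n_switched = n_sw,
    pct_shared_of_treatment = if (n_t > 0) 100 * n_sh / n_t else NA_real_,
    pct_switched_of_shared = if (n_sh > 0) 100 * n_sw / n_sh else NA_real_
  )
}

#' Category enrichment among switched events
#'
#' Compares, per event category, the proportion of switched events falling
#' in that category against the proportion of disease-dysregulated events in
#' the same category, with a two-sided two-proportion test (Fisher's exact
#' fallback for small cells) and Bonferroni correction over categories. A
#' category over-represented among switched events relative to the disease
#' set indicates the treatment preferentially reverts that class of event.
#'
#' @param switch_calls Tibble from [classify_switch()] (needs `category`,
#'   `switched`).
#' @param disease Disease `splice_contrast`, or a tibble with `category` and
#'   `n_significant` per-category counts.
#' @return Tibble with one row per category: `n_switched`, `n_disease`,
#'   `p_value`, `p_adj`. All-`NA` p-values (with a message) when there are
#'   no switched events at all.
#' @export
switched_category_enrichment <- function(switch_calls, disease) {
  sw <- switch_calls[switch_calls$switched, , drop = FALSE]
  if (is.data.frame(disease) && "n_significant" %in% names(disease) &&
      !"significant" %in% names(disease)) {
    dis_counts <- disease[, c("category", "n_significant")]
    names(dis_counts)[2] <- "n_disease"
  } else {
    dd <- tibble::as_tibble(disease)
    dis_counts <- dd |>
      dplyr::filter(.data$significant) |>
      dplyr::count(.data$category, name = "n_disease")
  }
  cats <- sort(unique(c(sw$category, dis_counts$category)))
  out <- tibble::tibble(category = cats) |>
    dplyr::left_join(dplyr::count(sw, .data$category, name = "n_switched"),
                     by = "category") |>
    dplyr::left_join(dis_counts, by = "category") |>
    dplyr::mutate(dplyr::across(c("n_switched", "n_disease"),
                                \(x) tidyr::replace_na(x, 0L)))
  n_sw_tot <- sum(out$n_switched)
  n_dis_tot <- sum(out$n_disease)
  if (n_sw_tot == 0) {
    message("no switched events; category enrichment untested")
    out$p_value <- NA_real_
    out$p_adj <- NA_real_
    return(out)
  }
  p <- vapply(seq_len(nrow(out)), function(i) {
    if (out$n_switched[i] + out$n_disease[i] == 0) return(NA_real_)
    .two_prop_p(out$n_switched[i], n_sw_tot, out$n_disease[i], n_dis_tot)
  }, numeric(1))
  m <- sum(!is.na(p))
  out$p_value <- p
  out$p_adj <- pmin(1, p * m)
  out
}
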