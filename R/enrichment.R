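# Normalise gene-set input: a named list of character vectors, or a tibble
# with set_name and a `genes` list-column (the read_gene_sets() shape), or a
# single character vector (given a default name).
.as_gene_set_list <- function(gene_sets) {
  if (is.data.frame(gene_sets)) {
    stopifnot(all(c("set_name", "genes") %in% names(gene_sets)))
    return(stats::setNames(gene_sets$genes, gene_sets$set_name))
  }
  if (is.character(gene_sets)) return(list(gene_set = gene_sets))
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  gene_sets
}

#' Hypergeometric enrichment of gene sets among differential genes
#'
#' Tests whether the genes carrying differential splicing events overlap a
#' gene set (e.g. CLIP-defined RBP substrates, tumor suppressors, oncogenes,
#' cancer drivers) more than expected by chance, using the upper-tail
#' hypergeometric test. With a universe of `N` genes of which `K` belong to
#' the set, and `n` differential genes of which `k` are in the set,
#' \deqn{p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n).}
#'
#' Genes are deduplicated (a gene counts once however many events it has),
#' and sets are intersected with the universe before testing. The natural
#' universe is the genes with at least one testable event in the contrast;
#' see [contrast_gene_universe()].
#'
#' @param differential_genes Character vector of differential gene ids
#'   (genes outside the universe are dropped).
#' @param gene_sets Named list of gene-id vectors, or a tibble from
#'   [read_gene_sets()], or a single character vector.
#' @param universe Character vector of eligible gene ids (non-empty).
#' @return A tibble with one row per set: `set_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value`.
#' @examples
#' hypergeometric_enrichment(paste0("g", 1:4),
#'                           list(s = paste0("g", c(1:4, 6))),
#'                           paste0("g", 1:10))
#' @export
hypergeometric_enrichment <- function(differential_genes, gene_sets,
                                      universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("`universe` must be non-empty",
                                  call. = FALSE)
  sets <- .as_gene_set_list(gene_sets)
  diff_g <- intersect(unique(differential_genes), universe)
  N <- length(universe)
  n <- length(diff_g)
  purrr::map_dfr(names(sets), function(nm) {
    set_g <- intersect(unique(sets[[nm]]), universe)
    K <- length(set_g)
    k <- length(intersect(diff_g, set_g))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expected <- n * K / N
    tibble::tibble(
      set_name = nm, k = k, n = n, K = K, N = N,
      fold_enrichment = if (expected > 0) k / expected else NA_real_,
      p_value = p
    )
  })
}

#' Gene universe of a contrast
#'
#' The genes with at least one testable event in a contrast — the population
#' actually eligible to be called differentially spliced, used as the
#' default universe for [hypergeometric_enrichment()].
#'
#' @param contrast A `splice_contrast` tibble.
#' @return Character vector of gene ids.
#' @export
contrast_gene_universe <- function(contrast) {
  unique(contrast$gene_id[contrast$testable])
}

#' Genes with significant events in a contrast
#'
#' @param contrast A `splice_contrast` tibble.
#' @return Character vector of gene ids carrying at least one significant
#'   event.
#' @export
contrast_differential_genes <- function(contrast) {
  unique(contrast$gene_id[contrast$significant])
}

#' Kolmogorov-Smirnov comparison of delta-PSI distributions
#'
#' For each gene set, splits the differential events of a contrast into
#' substrate events (gene in the set) and non-substrate events, and compares
#' the two delta-PSI distributions with a two-sample Kolmogorov-Smirnov
#' test. By default the comparison is on |delta-PSI| (effect magnitude); a
#' signed mode compares the raw delta-PSI distributions instead. Event-level
#' granularity is kept (each event contributes one value, however many
#' events its gene has).
#'
#' The p-value is exact when both groups have at most 25 values and there
#' are no ties, asymptotic otherwise (the behaviour of [stats::ks.test()]).
#'
#' @param calls A `splice_contrast` or tibble of calls with `gene_id`,
#'   `delta_psi` and (optionally) `significant`; when a `significant` column
#'   is present only significant events are used.
#' @param gene_sets Named list / tibble of gene sets (see
#'   [hypergeometric_enrichment()]).
#' @param magnitude_mode `"absolute"` (default, compares |delta-PSI|) or
#'   `"signed"`.
#' @return A tibble with one row per set: `set_name`,
#'   `n_substrate_events`, `n_other_events`, `d_statistic`, `p_value`,
#'   `magnitude_mode`. Sets leaving either group empty get `NA` statistics
#'   (untested marker).
#' @export
ks_delta_psi <- function(calls, gene_sets,
                         magnitude_mode = c("absolute", "signed")) {
  magnitude_mode <- match.arg(magnitude_mode)
  df <- tibble::as_tibble(calls)
  if ("significant" %in% names(df)) df <- df[df$significant, ]
  sets <- .as_gene_set_list(gene_sets)
  vals <- if (magnitude_mode == "absolute") abs(df$delta_psi) else df$delta_psi
  purrr::map_dfr(names(sets), function(nm) {
    in_set <- df$gene_id %in% sets[[nm]]
    x <- vals[in_set]
    y <- vals[!in_set]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(
        set_name = nm, n_substrate_events = length(x),
        n_other_events = length(y), d_statistic = NA_real_,
        p_value = NA_real_, magnitude_mode = magnitude_mode
      ))
    }
    kt <- suppressWarnings(stats::ks.test(x, y))
    tibble::tibble(
      set_name = nm,
      n_substrate_events = length(x),
      n_other_events = length(y),
      d_statistic = unname(kt$statistic),
      p_value = kt$p.value,
      magnitude_mode = magnitude_mode
    )
  })
}
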