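#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.direction_colours <- c(included = "#E6B800", excluded = "#2C7FB8",
                        none = "grey70")

#' Volcano plot of a contrast
#'
#' Delta-PSI against log10 Bayes factor, with significantly included events
#' in yellow and excluded events in blue, the field's conventional colouring
#' for splicing volcano plots.
#'
#' @param contrast A `splice_contrast`.
#' @param bf_cap Bayes factors are capped at this value before the log
#'   transform to keep the axis readable (default 1e12).
#' @return A ggplot object.
#' @export
plot_volcano <- function(contrast, bf_cap = 1e12) {
  df <- tibble::as_tibble(contrast) |>
    dplyr::filter(.data$testable) |>
    dplyr::mutate(log_bf = log10(pmin(.data$bf, bf_cap)))
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_psi, .data$log_bf,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = .direction_colours) +
    ggplot2::geom_hline(yintercept = log10(attr(contrast, "bf_threshold")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      title = attr(contrast, "contrast_label"),
      x = expression(Delta * PSI), y = expression(log[10] ~ "Bayes factor"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot splice_contrast
#' @export
autoplot.splice_contrast <- function(object, ...) plot_volcano(object, ...)

#' Included/excluded composition by event category
#'
#' Stacked bar chart of significantly included and excluded events per
#' category, the companion view to [composition_summary()].
#'
#' @param composition Tibble from [composition_summary()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  df <- composition |>
    dplyr::select("category", "n_included", "n_excluded") |>
    tidyr::pivot_longer(c("n_included", "n_excluded"),
                        names_to = "direction", values_to = "n") |>
    dplyr::mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = .direction_colours) +
    ggplot2::labs(x = NULL, y = "significant events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Cumulative delta-PSI distributions for a gene set
#'
#' Empirical cumulative distributions of (absolute) delta-PSI for substrate
#' events (gene in the set, yellow) versus non-substrate events (blue) —
#' the visual companion of the K-S comparison in [ks_delta_psi()].
#'
#' @param calls A `splice_contrast` or calls tibble.
#' @param gene_set Character vector of gene ids (one set).
#' @param set_name Label used in the legend.
#' @param magnitude_mode `"absolute"` or `"signed"`.
#' @return A ggplot object.
#' @export
plot_delta_psi_ecdf <- function(calls, gene_set, set_name = "substrate",
                                magnitude_mode = c("absolute", "signed")) {
  magnitude_mode <- match.arg(magnitude_mode)
  df <- tibble::as_tibble(calls)
  if ("significant" %in% names(df)) df <- df[df$significant, ]
  df <- df |>
    dplyr::mutate(
      value = if (magnitude_mode == "absolute") abs(.data$delta_psi)
              else .data$delta_psi,
      group = ifelse(.data$gene_id %in% gene_set, set_name,
                     paste0("non-", set_name))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$value, colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(c("#E6B800", "#2C7FB8"),
                               c(set_name, paste0("non-", set_name)))
    ) +
    ggplot2::labs(
      x = if (magnitude_mode == "absolute") expression("|" * Delta * PSI * "|")
          else expression(Delta * PSI),
      y = "cumulative fraction", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Treatment vs disease delta-PSI scatter with switch colouring
#'
#' Each shared event is plotted at (disease delta-PSI, treatment delta-PSI);
#' events switched toward the non-tumor profile (opposed signs) fall in the
#' off-diagonal quadrants and are drawn in red, non-switched events in
#' black.
#'
#' @param switch_calls Tibble from [classify_switch()].
#' @return A ggplot object.
#' @export
plot_switch <- function(switch_calls) {
  ggplot2::ggplot(switch_calls,
                  ggplot2::aes(.data$disease_dpsi, .data$treat_dpsi,
                               colour = .data$switched)) +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#C0392B", `FALSE` = "black"),
      labels = c(`TRUE` = "switched", `FALSE` = "not switched")
    ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      x = expression(Delta * PSI ~ "(tumor - normal)"),
      y = expression(Delta * PSI ~ "(treatment)"), colour = NULL
    ) +
    ggplot2::theme_minimal()
}
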