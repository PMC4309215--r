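#' Boxplot-style QC plot of per-array value distributions
#'
#' Draws, per array, the median, the quartile box and whiskers at the 9th
#' and 91st percentile — the standard first-look QC display for a set of
#' hybridized arrays.
#'
#' @param x An expression table.
#' @param design Optional `refstab_design`; arrays are then coloured by
#'   condition.
#' @return A ggplot object.
#' @export
plot_array_boxes <- function(x, design = NULL) {
  bs <- boxplot_summary(x)
  if (!is.null(design)) {
    bs <- dplyr::left_join(bs, tibble::as_tibble(design), by = "array_id")
  }
  bs$array_id <- factor(bs$array_id, levels = bs$array_id)
  p <- ggplot2::ggplot(bs, ggplot2::aes(x = .data$array_id)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p09, ymax = .data$p91),
                           width = 0.3) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$p50, ymin = .data$p25, ymax = .data$p75,
                   fill = if (is.null(design)) NULL else .data$condition),
      width = 0.7) +
    ggplot2::labs(x = NULL, y = "fluorescence intensity", fill = "condition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  p
}

#' CV profile plot
#'
#' Bar chart of per-gene coefficients of variation with the homogeneous
#' (25%) and heterogeneous (50%) acceptability thresholds.
#'
#' @param cv_records Output of [cv_screen()].
#' @param thresholds Threshold lines to draw, in percent.
#' @return A ggplot object.
#' @export
plot_cv_profile <- function(cv_records, thresholds = c(25, 50)) {
  ggplot2::ggplot(cv_records,
                  ggplot2::aes(x = stats::reorder(.data$gene_symbol,
                                                  .data$cv_percent),
                               y = .data$cv_percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$campaign), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "CV (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a stability ranking
#'
#' Dot plot of per-method ranks per gene, ordered by the composite ranking
#' (most stable gene first).
#'
#' @param object A `stability_ranking` from [rank_stability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_ranking
#' @export
autoplot.stability_ranking <- function(object, ...) {
  long <- object$scores |>
    dplyr::select(dplyr::all_of(c("gene_symbol", "overall_rank")),
                  dplyr::starts_with("rank_")) |>
    tidyr::pivot_longer(dplyr::starts_with("rank_"),
                        names_to = "method", values_to = "rank",
                        names_prefix = "rank_")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$gene_symbol,
                                                  .data$overall_rank),
                               y = .data$rank, colour = .data$method)) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = NULL, y = "stability rank (1 = most stable)",
                  colour = "method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot geNorm pairwise variation
#'
#' @param pv The `pairwise_variation` tibble from [genorm()] or
#'   [rank_stability()], with the conventional 0.15 guide line for deciding
#'   whether adding an (n+1)-th reference gene is worthwhile.
#' @return A ggplot object.
#' @export
plot_pairwise_variation <- function(pv) {
  ggplot2::ggplot(pv, ggplot2::aes(x = factor(paste0("V", .data$n, "/",
                                                     .data$n + 1),
                                              levels = paste0("V", .data$n,
                                                              "/",
                                                              .data$n + 1)),
                                   y = .data$v)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0.15, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "pairwise variation V(n/n+1)") +
    ggplot2::theme_minimal()
}
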