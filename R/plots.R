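#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a group ranking
#'
#' Bar chart of summed composite scores per group, ordered by rank, with
#' the naive-predictor baseline drawn as a horizontal line when present —
#' the standard way refinement rankings are presented.
#'
#' @param object A `ranking_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranking_result <- function(object, ...) {
  g <- object$groups
  p <- ggplot2::ggplot(g, ggplot2::aes(
    x = stats::reorder(.data$group_id, .data$rank), y = .data$total)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "summed score",
                  title = "Group ranking") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(object$baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = object$baseline$total,
                                 colour = "red", linetype = "dashed")
  }
  p
}

#' Plot good/bad region summaries
#'
#' Grouped bars of the per-region backbone torsion, side-chain torsion,
#' and Ca RMSD summaries, faceted by quantity and by change-from-start
#' versus residual-vs-target.
#'
#' @param object A `region_summary` from [region_summaries()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("backbone_deg", "sidechain_deg", "ca_rmsd"),
    names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("backbone_deg", "sidechain_deg", "ca_rmsd"),
                          labels = c("backbone torsion (deg)",
                                     "side-chain torsion (deg)",
                                     "Ca RMSD (A)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$value,
                                     fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(quantity ~ comparison, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(good = "darkblue", bad = "firebrick")) +
    ggplot2::labs(x = "start-model backbone region", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-group fractions improved over the start model
#'
#' @param fractions Tibble from [fraction_improved()].
#' @return A ggplot object.
#' @export
plot_fraction_improved <- function(fractions) {
  ggplot2::ggplot(fractions, ggplot2::aes(
    x = stats::reorder(.data$group_id, -.data$fraction_improved),
    y = .data$fraction_improved)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "fraction of targets improved") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
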