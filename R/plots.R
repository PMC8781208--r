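#' Plot a ligand-water-DNA contact network
#'
#' Force-directed layout (deterministic: the layout seed is fixed) with
#' nodes colored by residue category and edges drawn per hydrogen bond;
#' edge labels show distances in angstroms.
#'
#' @param hbonds Hydrogen-bond tibble.
#' @param label_distances Draw distance labels on edges.
#' @return A ggplot object.
#' @export
#' @examples
#' plot_contact_graph(load_contact_table(mm41_contacts()))
plot_contact_graph <- function(hbonds, label_distances = TRUE) {
  g <- build_contact_graph(hbonds)
  lay <- with_scene_seed(42, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(
    name = igraph::V(g)$name, category = igraph::V(g)$category,
    x = lay[, 1], y = lay[, 2])
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$name)],
    y = nodes$y[match(el[, 1], nodes$name)],
    xend = nodes$x[match(el[, 2], nodes$name)],
    yend = nodes$y[match(el[, 2], nodes$name)],
    distance = igraph::E(g)$distance)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey55", linetype = "22") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     color = .data$category), size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1.1, size = 3) +
    ggplot2::scale_color_manual(values = c(
      ligand = "#c0392b", water = "#2980b9", nucleotide = "#27ae60",
      ion = "#8e44ad", other = "grey40")) +
    ggplot2::theme_void() +
    ggplot2::labs(color = NULL)
  if (label_distances) {
    p <- p + ggplot2::geom_text(
      data = edges,
      ggplot2::aes((.data$x + .data$xend) / 2, (.data$y + .data$yend) / 2,
                   label = sprintf("%.1f", .data$distance)),
      size = 2.6, color = "grey30")
  }
  p
}

#' Plot group mobility summaries
#'
#' Mean B factor per group with the min-max range, secondary-axis labeled in
#' RMS displacement.
#'
#' @param summary Output of [group_mobility()] with a grouping column.
#' @param group Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_mobility <- function(summary, group = names(summary)[1]) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data[[group]], y = .data$mean_b)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$min_b,
                                          ymax = .data$max_b)) +
    ggplot2::scale_y_continuous(
      "B factor (Å²)",
      sec.axis = ggplot2::sec_axis(~ sqrt(. / (8 * pi^2)),
                                   name = "<U> (Å)")) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot gq_superposition
#' @rdname fit_quartets
#' @param object A `gq_superposition`.
#' @param ... Unused.
autoplot.gq_superposition <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(x = .data$atom, y = .data$deviation,
                               color = .data$residue_a)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$rmsd, linetype = "dashed") +
    ggplot2::labs(y = "post-fit deviation (Å)", x = NULL,
                  color = "residue") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
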