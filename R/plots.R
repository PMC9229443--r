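# ggplot2 displays for the main result types.

#' @export
autoplot.marker_panel_summary <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(dplyr::any_of(c("gene_diversity", "pic")),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$value,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Per-locus diversity",
                  subtitle = "dashed line: highly-informative threshold (PIC > 0.5)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.gd_dist <- function(object, ...) {
  long <- tibble::as_tibble(as.data.frame(as.table(unclass(object)))) |>
    stats::setNames(c("line1", "line2", "distance"))
  ggplot2::ggplot(long, ggplot2::aes(.data$line1, .data$line2,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "GD",
                  title = "Pairwise genetic distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.heterosis_tbl <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("hmp_pct", "hbp_pct"), names_to = "basis",
                        values_to = "heterosis_pct") |>
    dplyr::mutate(basis = dplyr::if_else(.data$basis == "hmp_pct",
                                         "mid-parent", "better-parent"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cross_id,
                                     y = .data$heterosis_pct,
                                     colour = .data$basis)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "heterosis (%)",
                  title = "Mid- and better-parent heterosis by cross") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' @export
autoplot.gd_cor <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$gd, y = .data$heterosis_pct,
                                      colour = .data$basis)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
    ggplot2::labs(x = "parental genetic distance", y = "heterosis (%)",
                  title = "Genetic distance vs heterosis") +
    ggplot2::theme_minimal()
}

#' Plot a UPGMA dendrogram with ggplot2
#'
#' Draws the ultrametric tree from [upgma()]; node heights are half the
#' merge distance, so the vertical axis is on the scale of the input
#' distances divided by two.
#'
#' @param tree A tree from [upgma()] (a `phylo` carrying its `hclust`).
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree) {
  hc <- attr(tree, "hclust")
  if (is.null(hc)) stop_bad("tree must come from upgma()")
  n <- length(hc$labels)
  leaf_x <- setNames(seq_len(n), hc$order)   # position of each leaf index
  node_x <- numeric(n - 1)
  node_y <- hc$height / 2
  child_xy <- function(id) {
    if (id < 0) c(leaf_x[[as.character(-id)]], 0) else c(node_x[id], node_y[id])
  }
  segs <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    a <- child_xy(hc$merge[k, 1]); b <- child_xy(hc$merge[k, 2])
    node_x[k] <- (a[1] + b[1]) / 2
    segs[[k]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_y[k]), yend = c(node_y[k], node_y[k], node_y[k])
    )
  }
  labs_df <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs_df,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "height", title = "UPGMA dendrogram") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
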