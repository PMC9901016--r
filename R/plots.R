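#' Plot a population dendrogram
#'
#' @param object A `pop_dendrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot pop_dendrogram
autoplot.pop_dendrogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  # x position of every leaf in plotting order, then of every merge
  leaf_x <- setNames(seq_len(n), hc$order)
  xpos <- numeric(nrow(hc$merge))
  ypos <- hc$height
  node_x <- function(i) if (i < 0) leaf_x[[as.character(-i)]] else xpos[i]
  node_y <- function(i) if (i < 0) 0 else ypos[i]
  segs <- purrr::map_dfr(seq_len(nrow(hc$merge)), function(i) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b)
    xpos[i] <<- (xa + xb) / 2
    tibble::tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_y(a), ypos[i], node_y(b)),
      yend = c(ypos[i], ypos[i], ypos[i])
    )
  })
  labs <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.05, size = 3) +
    ggplot2::scale_y_continuous(name = paste0("height (", object$metric, ")"),
                                expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Heatmap of a heteroplasmy table
#'
#' @param m A `heteroplasmy_tbl`.
#' @param sqrt_scale Plot `sqrt(af)` (default) to make low fractions
#'   visible.
#' @return A ggplot of populations x variants allele fractions.
#' @export
plot_heteroplasmy <- function(m, sqrt_scale = TRUE) {
  pops <- attr(m, "populations") %||% unique(m$population)
  df <- dplyr::mutate(m,
                      population = factor(.data$population, levels = rev(pops)),
                      value = if (sqrt_scale) sqrt(.data$af) else .data$af)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$variant, .data$position),
                                   y = .data$population, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (sqrt_scale) "sqrt(AF)" else "AF") +
    ggplot2::labs(x = "variant (genome order)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a nearest-neighbour composition
#'
#' @param object A `neighbor_result`.
#' @param ... Unused.
#' @return A ggplot of neighbour probabilities per ROI, with z-scores in
#'   the fill when present.
#' @export
#' @method autoplot neighbor_result
autoplot.neighbor_result <- function(object, ...) {
  df <- dplyr::filter(object, !.data$degenerate)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$neighbor_type,
                                        y = .data$prob))
  p <- if ("z" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$z)) +
      ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                    mid = "grey85", midpoint = 0)
  } else {
    p + ggplot2::geom_col(fill = "grey40")
  }
  p + ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "nearest-neighbour type",
                  y = "P(type is nearest neighbour of focal cell)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot gated subset percentages
#'
#' @param object A `subset_report`.
#' @param ... Unused.
#' @return A ggplot of percent-of-parent per gate node.
#' @export
#' @method autoplot subset_report
autoplot.subset_report <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$parent))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$pct_parent)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "% of parent gate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("sample" %in% names(df)) p <- p + ggplot2::facet_wrap(~sample)
  p
}

#' Plot a consistency null distribution
#'
#' @param object A `consistency_result`.
#' @param ... Unused.
#' @return A ggplot: histogram of relabeling-null scores with the observed
#'   score marked.
#' @export
#' @method autoplot consistency_result
autoplot.consistency_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(score = object$null_scores),
                  ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$score, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "transmission-consistency score",
                  y = "relabelings",
                  subtitle = sprintf("observed %.3f, p = %.3g",
                                     object$score, object$p_value)) +
    ggplot2::theme_minimal()
}
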