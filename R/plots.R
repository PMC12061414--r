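#' Plot an arc-strength table
#'
#' Horizontal bar chart of bootstrap adjacency strengths, one bar per
#' undirected arc, with the model-averaging threshold drawn as a dashed
#' line.
#'
#' @param object An `arc_strength` tibble from [bootstrap_arc_strength()].
#' @param threshold Threshold line position (default 0.75).
#' @param top_n Show only the strongest `top_n` arcs (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arc_strength <- function(object, threshold = 0.75, top_n = NULL, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$strength))
  if (!is.null(top_n)) d <- utils::head(d, top_n)
  d$arc <- paste(d$from, "—", d$to)
  d$arc <- factor(d$arc, levels = rev(d$arc))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strength, y = .data$arc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "bootstrap adjacency strength", y = NULL,
                  title = "Arc strengths") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a weighted ROC curve
#'
#' @param object An `ir_roc` object from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ir_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a scenario table
#'
#' Line-and-point chart of the conditional outcome probability across
#' quartile groups, faceted by the extra conditioning variable when one is
#' present, with approximate 95% error bars from the Monte Carlo standard
#' errors.
#'
#' @param object A `scenario_table` tibble from [scenario_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  index <- d$index[1]
  outcome <- d$outcome[1]
  has_extra <- !all(is.na(d$extra))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$quartile, y = .data$prob,
                                       group = 1)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = index, y = sprintf("P(%s | evidence)", outcome)) +
    ggplot2::theme_minimal()
  if (all(is.finite(d$se)) && any(d$se > 0))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$prob - 1.96 * .data$se),
                   ymax = pmin(1, .data$prob + 1.96 * .data$se)),
      width = 0.1, colour = "steelblue")
  if (has_extra)
    p <- p + ggplot2::facet_wrap(~ extra_level)
  p
}

#' Plot a learned network
#'
#' Draws the DAG with nodes on a deterministic circular layout (topological
#' order around the circle) and directed edges as arrows; no external graph
#' library is needed, so plots are reproducible anywhere the package runs.
#'
#' @param object A `bn_dag`.
#' @param label_size Node label size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_dag <- function(object, label_size = 3, ...) {
  ord <- topo_sort(object)
  p <- length(ord)
  theta <- 2 * pi * (seq_len(p) - 1) / p
  pos <- tibble::tibble(node = ord, x = cos(theta), y = sin(theta))
  g <- ggplot2::ggplot() +
    ggplot2::theme_void() +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3))
  if (nrow(object$arcs)) {
    seg <- tibble::tibble(
      x = pos$x[match(object$arcs[, 1], pos$node)],
      y = pos$y[match(object$arcs[, 1], pos$node)],
      xend = pos$x[match(object$arcs[, 2], pos$node)],
      yend = pos$y[match(object$arcs[, 2], pos$node)])
    # stop arrows short of the node label
    shrink <- 0.12
    dx <- seg$xend - seg$x; dy <- seg$yend - seg$y
    len <- sqrt(dx^2 + dy^2)
    seg$x <- seg$x + shrink * dx / len
    seg$y <- seg$y + shrink * dy / len
    seg$xend <- seg$xend - shrink * dx / len
    seg$yend <- seg$yend - shrink * dy / len
    g <- g + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"), type = "closed"),
      colour = "grey40", linewidth = 0.4)
  }
  g + ggplot2::geom_label(
    data = pos,
    ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
    size = label_size, label.size = 0.2)
}
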