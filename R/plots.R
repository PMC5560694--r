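#' Plot a network structure as a layered arc diagram
#'
#' Nodes are laid out left-to-right within layers given by their number of
#' attribute parents (tree-derived structures therefore read root-down);
#' attribute arcs are drawn as segments. Class arcs are omitted (the class
#' parents every node).
#'
#' @param object A [bn_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_structure <- function(object, ...) {
  n <- object$n
  nms <- object$names %||% paste0("X", seq_len(n))
  depth <- compute_layer(object)
  pos <- unlist(lapply(split(seq_len(n), depth), seq_along))[order(order(depth, seq_len(n)))]
  nodes <- tibble::tibble(id = seq_len(n), name = nms,
                          x = as.numeric(pos), y = -as.numeric(depth))
  arcs <- tidy.bn_structure(object)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(arcs)) {
    seg <- dplyr::left_join(arcs, nodes, by = c(parent = "id")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(nodes, by = c(child = "id"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50")
  }
  p + ggplot2::geom_point(size = 8, colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), size = 3) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(paste0("k = ", object$k,
                            if (!is.na(object$root))
                              paste0(", root ", nms[object$root]) else ""))
}

compute_layer <- function(st) {
  # layer = longest attribute-parent chain above the node
  layer <- rep(NA_integer_, st$n)
  assign_layer <- function(j) {
    if (!is.na(layer[j])) return(layer[j])
    pa <- st$parents[[j]]
    layer[j] <<- if (length(pa) == 0L) 0L else
      1L + max(vapply(pa, assign_layer, integer(1)))
    layer[j]
  }
  for (j in seq_len(st$n)) assign_layer(j)
  layer
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot bar chart with the mean accuracy as a dashed line.
#' @export
autoplot.bnc_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("%s, %d-fold CV: mean accuracy %.3f",
                                  object$model, object$n_folds,
                                  object$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot Markov-blanket sizes per attribute and model
#'
#' @param object A [mb_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot grouped bar chart of blanket sizes.
#' @export
autoplot.mb_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$attribute, y = .data$mb_size,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Markov blanket size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
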