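#' Plot a drug ranking
#'
#' Horizontal bars of replaceable scores with the flagging threshold drawn
#' as a dashed line; flagged drugs are filled darker.
#'
#' @param object A `drug_ranking` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drug_ranking
#' @export
autoplot.drug_ranking <- function(object, ...) {
  threshold <- attr(object, "threshold") %||% 1
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$replaceable,
    y = stats::reorder(.data$drug, .data$replaceable),
    fill = .data$needs_alternative
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25", `FALSE` = "grey70")) +
    ggplot2::labs(
      x = "replaceable score (rate_se / indication score)", y = NULL,
      title = "Drugs ranked by replaceable score"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a substitutability ranking
#'
#' @param object A `substitutability` tibble.
#' @param k Number of herbs shown; default 10.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot substitutability
#' @export
autoplot.substitutability <- function(object, k = 10, ...) {
  df <- tidy(rank_alternatives(object, k = k))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$herb, .data$score),
    fill = .data$mode
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "substitutability (D x N)", y = NULL, fill = "mode",
      title = "Herbs ranked by substitutability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an HITD graph as a layered diagram
#'
#' Nodes are laid out in four columns (herb, ingredient, target, disease)
#' and edges drawn as segments between layers.
#'
#' @param object An `hitd_graph` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hitd_graph
#' @export
autoplot.hitd_graph <- function(object, ...) {
  layer_x <- c(herb = 1, ingredient = 2, target = 3, disease = 4)
  nodes <- object$nodes |>
    mutate(x = layer_x[.data$type]) |>
    group_by(.data$type) |>
    mutate(y = (row_number() - 1) / max(1L, n() - 1L)) |>
    ungroup()
  pos <- nodes[c("node", "x", "y")]
  edges <- object$edges |>
    left_join(rename(pos, from = "node", x0 = "x", y0 = "y"), by = "from") |>
    left_join(rename(pos, to = "node", x1 = "x", y1 = "y"), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type), size = 3
    ) +
    ggplot2::scale_x_continuous(
      breaks = unname(layer_x), labels = names(layer_x), limits = c(0.5, 4.5)
    ) +
    ggplot2::labs(x = NULL, y = NULL, colour = "node type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
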