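#' Plot methods
#'
#' ggplot2 front-ends for the main result types: the accuracy grid of a
#' fusion experiment, the alpha profile of a single operator/family, and a
#' connectivity heat map.
#'
#' @name plots
NULL

#' @describeIn plots Accuracy of every grid cell, faceted by operator, with
#'   the best individual classifier as a reference line.
#' @param object A `fusion_experiment`.
#' @param ... Unused.
#' @export
autoplot.fusion_experiment <- function(object, ...) {
  grid <- object$grid |>
    dplyr::mutate(family = dplyr::coalesce(.data$family, "none"))
  best_ind <- max(object$individual$accuracy)
  ggplot2::ggplot(
    grid[!is.na(grid$alpha), ],
    ggplot2::aes(x = .data$alpha, y = .data$accuracy,
                 colour = .data$family, group = .data$family)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = best_ind, linetype = "dashed") +
    ggplot2::facet_wrap(~operator) +
    ggplot2::labs(x = expression(alpha), y = "pooled accuracy",
                  colour = "t-norm family",
                  caption = "dashed line: best individual classifier") +
    ggplot2::theme_minimal()
}

#' @describeIn plots Accuracy against alpha for one operator and family.
#' @param experiment A `fusion_experiment`.
#' @param operator,family Cell coordinates to profile.
#' @export
plot_alpha_profile <- function(experiment, operator, family) {
  grid <- experiment$grid |>
    dplyr::filter(.data$operator == !!operator,
                  .data$family == as.character(!!family))
  if (nrow(grid) == 0) stop("no grid cells for that operator/family",
                            call. = FALSE)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$alpha, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste0(operator, ", family ", family),
                  x = expression(alpha), y = "pooled accuracy") +
    ggplot2::theme_minimal()
}

#' @describeIn plots Heat map of a directed connectivity matrix
#'   (column channel drives row channel).
#' @param W Square weight matrix.
#' @export
plot_connectivity <- function(W) {
  stopifnot(is.matrix(W))
  ch <- rownames(W)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(W)))
  df <- tidyr::expand_grid(to = ch, from = ch)
  df$weight <- as.vector(W[cbind(match(df$to, ch), match(df$from, ch))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "source channel", y = "target channel",
                  fill = "GC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
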