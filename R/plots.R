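#' Plot a root mask
#'
#' @param object A [root_mask()].
#' @param ... Unused.
#' @return A ggplot: root pixels dark on light ground, y axis flipped so
#'   the origin sits at the top-left as in image coordinates.
#' @export
autoplot.root_mask <- function(object, ...) {
  idx <- which(object$pixels)
  df <- tibble::tibble(
    x = (idx - 1L) %/% object$height,
    y = (idx - 1L) %% object$height
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(fill = "grey15") +
    ggplot2::scale_y_reverse(limits = c(object$height - 1, 0)) +
    ggplot2::xlim(0, object$width - 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = object$sample_id,
      x = "x (column)", y = "y (row)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot gain and lift curves of an evaluation
#'
#' @param object A `rootart_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot of the cumulative gain curve with the random diagonal.
#' @export
autoplot.rootart_eval <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(.data$fraction, .data$gain)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.9) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "fraction of samples (ranked by predicted probability)",
      y = "fraction of positives captured", title = "Cumulative gain"
    ) +
    ggplot2::theme_minimal()
}

#' Plot genotype rank scores
#'
#' @param object A `rootart_rank` from [rank_scores()].
#' @param ... Unused.
#' @return A ggplot of the three rank scores per genotype (lower = more
#'   tolerant).
#' @export
autoplot.rootart_rank <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("rank1", "rank2", "rank3"),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$score, y = .data$value,
    group = .data$genotype, colour = .data$genotype
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "weighted rank score (lower = more tolerant)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of permutation importances
#'
#' @param importance Tibble from [permutation_importance()].
#' @return A ggplot.
#' @export
plot_importance <- function(importance) {
  df <- dplyr::mutate(importance, term = stats::reorder(.data$term, .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean metric drop when permuted", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
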