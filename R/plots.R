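#' Plot an effect summary
#'
#' Point-range plot of the median percentage change per category with the
#' 2.5th and 97.5th percentile interval; a category whose interval misses
#' the zero line differs credibly from the reference.
#'
#' @param object a `bd_effect_summary` from [effect_summary_pct_change()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bd_effect_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$category, y = .data$median)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi)) +
    ggplot2::labs(x = NULL, y = "% change vs reference") +
    ggplot2::theme_minimal()
}

#' Map a per-pixel change surface
#'
#' Raster map of the percentage change per pixel; for RCAR the sign-flipped
#' display column is used when present, so warm colours consistently mean
#' worse biodiversity outcomes.
#'
#' @param object a `bd_change_map` from [pct_change_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bd_change_map <- function(object, ...) {
  val <- if ("display" %in% names(object)) object$display else
    object$pct_change
  df <- tibble::tibble(row = object$row, col = object$col, value = val)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "% change", x = NULL, y = NULL,
                  title = attr(object, "metric")) +
    ggplot2::theme_void()
}

#' Map the winning strategy per pixel
#'
#' @param result a `bd_scenario_result` from [compare_strategies()].
#' @param metric metric whose winner map to draw.
#' @return a ggplot object.
#' @export
plot_winner_map <- function(result, metric = "richness") {
  col <- paste0("winner_", metric)
  if (!col %in% names(result)) {
    abort(sprintf("no winner column for metric '%s'", metric))
  }
  df <- tibble::tibble(row = result$row, col = result$col,
                       winner = ifelse(result$valid, result[[col]],
                                       NA_character_))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$winner)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(expansion = "#2166ac", intensification = "#b2182b",
                 tie = "grey80"), na.value = "grey95") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "better strategy", x = NULL, y = NULL,
                  title = paste(attr(result, "crop"), metric)) +
    ggplot2::theme_void()
}
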