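#' Plot the seasonal condition smooth
#'
#' Scaled condition against day-of-year with the fitted population-level
#' seasonal trend per sex and the pre-incubation cutoff marked.
#'
#' @param object a `condition_smooth`.
#' @param cutoff `"MM-DD"` pre-incubation cutoff to mark (NULL to omit).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot condition_smooth
#' @export
autoplot.condition_smooth <- function(object, cutoff = "05-02", ...) {
  d <- object$index
  grid <- tidyr::expand_grid(doy = 1:365,
                             sex = factor(levels(factor(d$sex))))
  grid$bird <- factor(d$bird_id[1], levels = levels(factor(d$bird_id)))
  grid$trend <- as.numeric(stats::predict(object$fit, newdata = grid,
                                          exclude = "s(bird)"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$doy)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$condition_z,
                                     colour = .data$sex),
                        alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$trend, colour = .data$sex),
                       linewidth = 0.9) +
    ggplot2::labs(x = "day of year", y = "scaled mass / P8",
                  colour = "sex") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    cut_doy <- day_of_year(as.Date(paste0("2001-", cutoff)))
    p <- p + ggplot2::geom_vline(xintercept = cut_doy, linetype = "dotted")
  }
  p
}

#' Plot seasonal NDVI trends by area
#'
#' @param object a `seasonal_smooth`.
#' @param ... unused.
#' @return a ggplot of the fitted per-area seasonal trend with peak dates
#'   marked.
#' @method autoplot seasonal_smooth
#' @export
autoplot.seasonal_smooth <- function(object, ...) {
  d <- object$data
  grid <- tidyr::expand_grid(doy = 1:365, area = factor(levels(d$area)))
  grid$pixel <- d$pixel[1]
  if ("area_o" %in% names(d)) grid$area_o <- as.ordered(grid$area)
  grid$trend <- as.numeric(stats::predict(object$fit, newdata = grid,
                                          exclude = "s(pixel)"))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$doy, y = .data$trend,
                                     colour = .data$area)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_vline(data = object$peaks,
                        ggplot2::aes(xintercept = .data$peak_doy,
                                     colour = .data$area),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "day of year", y = "fitted NDVI", colour = "area") +
    ggplot2::theme_minimal()
}

#' Plot a model-selection ranking
#'
#' Criterion deltas per candidate model, with the competitive (delta <= 2)
#' subset and the selected final model highlighted.
#'
#' @param object a `selection_table`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot selection_table
#' @export
autoplot.selection_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$model <- factor(d$model, levels = rev(d$model))
  d$status <- dplyr::case_when(d$final ~ "final",
                               d$in_delta2 ~ "competitive (Δ2)",
                               .default = "other")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta, y = .data$model,
                                  fill = .data$status)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_vline(xintercept = 2, linetype = "dotted") +
    ggplot2::labs(x = paste0("Δ", attr(object, "criterion_name")),
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot strategy calls through time
#'
#' One row per individual, tiles coloured by the called strategy, conflicts
#' outlined -- a quick audit of classification coverage and consistency.
#'
#' @param calls a strategy-call tibble from [reconcile_strategies()].
#' @return a ggplot.
#' @export
plot_strategy_calls <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = factor(.data$year),
                                      y = .data$bird_id,
                                      fill = .data$strategy)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$conflict),
                       linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = NA),
                                 guide = "none") +
    ggplot2::scale_fill_manual(values = c(migrant = "#d95f02",
                                          resident = "#1b9e77",
                                          unknown = "grey80")) +
    ggplot2::labs(x = "breeding year", y = NULL, fill = "strategy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
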