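## ggplot2 views of the main result objects.

#' @export
autoplot.soi_weights <- function(object, coords = NULL, ...) {
  if (is.null(coords)) {
    abort("supply the centroid coordinates used to build the graph")
  }
  m <- as.matrix(coords[, 1:2])
  idx <- which(object$adjacency & upper.tri(object$adjacency),
               arr.ind = TRUE)
  seg <- tibble(x = m[idx[, 1], 1], y = m[idx[, 1], 2],
                xend = m[idx[, 2], 1], yend = m[idx[, 2], 2])
  pts <- tibble(x = m[, 1], y = m[, 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          linewidth = 0.2, colour = "grey50") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Sphere-of-influence neighbor graph",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spatial_fit <- function(object, ...) {
  imp <- object$impacts |>
    tidyr::pivot_longer(
      cols = c("direct", "indirect", "total"),
      names_to = "impact", values_to = "estimate") |>
    dplyr::mutate(se = dplyr::case_when(
      .data$impact == "direct" ~ .data$direct_se,
      .data$impact == "indirect" ~ .data$indirect_se,
      TRUE ~ .data$total_se)) |>
    dplyr::filter(!is.na(.data$estimate))
  ggplot2::ggplot(imp,
                  ggplot2::aes(x = .data$estimate, y = .data$variable,
                               colour = .data$impact)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(title = paste0(object$kind,
                                 " impacts (linearized scale)"),
                  subtitle = "Signs reverse on the forest-cover scale",
                  x = "estimate ± 1.96 SE", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-cover response curve implied by a fitted model
#'
#' Plots observed forest cover against the fitted linear predictor,
#' overlaid with the inverse-logistic curve `FC = 1/(1 + exp(FC*))` that
#' links the two scales.
#'
#' @param run A `sample_run` object.
#' @return A ggplot object.
#' @export
plot_response_curve <- function(run) {
  d <- tibble(trend = run$final$fitted, FC = run$frame$FC)
  curve <- tibble(trend = seq(min(d$trend), max(d$trend),
                              length.out = 200))
  curve$FC <- 1 / (1 + exp(curve$trend))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trend, y = .data$FC)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "fitted linear predictor (FC* scale)",
                  y = "forest cover",
                  title = "Sigmoid response implied by the fitted trend") +
    ggplot2::theme_minimal()
}
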