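# ggplot2 views of the result objects.

#' @export
autoplot.pm_bias_result <- function(object, ...) {
  df <- tibble(outcome = factor(c("shape", "texture", "neither"),
                                levels = c("shape", "texture", "neither")),
               fraction = c(object$fraction_shape, object$fraction_texture,
                            object$fraction_neither))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$fraction,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(y = "fraction of incongruent stimuli", x = NULL,
                  title = "Cue-conflict classification outcomes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pm_ablation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "ablated fraction of first-layer units",
                  y = "evaluation metric",
                  title = sprintf("Ablation by %s (%s)",
                                  attr(object, "metric") %||% "metric",
                                  attr(object, "direction") %||% "")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of joint colour and frequency tuning
#'
#' One point per first-layer unit; jointly low colour and low frequency
#' (lower-left) is the magnocellular-like corner, with orientation
#' selectivity mapped to the point colour.
#'
#' @param records metric tibble from [rf_metrics()].
#' @return a ggplot.
#' @export
plot_rf_scatter <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$waf, y = .data$color_rgb,
                                        colour = .data$orient_R)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "weighted average frequency (cycles/pixel)",
                  y = "colour metric (RGB discrepancy)",
                  colour = "orientation\nselectivity R") +
    ggplot2::theme_minimal()
}

#' Gallery of first-layer receptive fields
#'
#' Filters are min-max rescaled to the display range individually.
#'
#' @param rfs tibble from [extract_first_layer_rfs()] (2D models).
#' @param ncol facets per row.
#' @return a ggplot.
#' @export
plot_rfs <- function(rfs, ncol = 8) {
  df <- purrr::map2_dfr(rfs$weights, rfs$unit_id, function(w, id) {
    z <- rescale01(w)
    k <- dim(w)[1]
    tibble(unit_id = id,
           x = rep(seq_len(dim(w)[2]), each = k),
           y = rep(rev(seq_len(k)), dim(w)[2]),
           fill = grDevices::rgb(as.vector(z[, , 1]), as.vector(z[, , 2]),
                                 as.vector(z[, , 3])))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_wrap(~unit_id, ncol = ncol) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Box plots of invariance correlations per layer
#'
#' @param invariance a `pm_invariance` tibble (optionally with extra
#'   grouping columns such as `regimen`).
#' @return a ggplot.
#' @export
plot_invariance <- function(invariance) {
  aes <- if ("regimen" %in% names(invariance)) {
    ggplot2::aes(x = .data$layer, y = .data$correlation,
                 fill = .data$regimen)
  } else {
    ggplot2::aes(x = .data$layer, y = .data$correlation)
  }
  ggplot2::ggplot(invariance, aes) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(y = "correlation (undegraded vs degraded activations)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pm_regimen_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_seed,
                            c("mean_color_rgb", "mean_waf", "fraction_shape",
                              "invariance_grayscale", "invariance_blur"),
                            names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regimen, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal()
}
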