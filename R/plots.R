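# ggplot2 figure helpers for the main result types.

#' Marker map of particles over the layer contours
#'
#' Reproduces the point-marker section plots: every particle centroid as
#' a dot over the traced layer contours.
#'
#' @param particles Layer-labelled particle tibble.
#' @param layers A [layer_map()].
#' @return A ggplot object.
#' @export
plot_density_map <- function(particles, layers) {
  ring_df <- function(r, layer, ring_id) {
    tibble::tibble(x = c(r[, 1], r[1, 1]), y = c(r[, 2], r[1, 2]),
                   layer = layer, ring = ring_id)
  }
  contours <- purrr::map_dfr(seq_len(nrow(layers)), function(i) {
    p <- layers$polygon[[i]]
    dplyr::bind_rows(
      ring_df(p$outer, layers$layer[i], paste0(layers$layer[i], "_outer")),
      purrr::imap_dfr(p$holes, function(h, k)
        ring_df(h, layers$layer[i], paste0(layers$layer[i], "_hole", k))))
  })
  ggplot2::ggplot() +
    ggplot2::geom_path(data = contours,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$ring),
                       color = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(data = particles,
                        ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                     color = .data$layer), size = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (\u00b5m)", y = "y (\u00b5m)", color = "layer") +
    ggplot2::theme_minimal()
}

#' Per-layer density bar summary
#'
#' Mean density per layer with SEM error bars across preparations, one
#' point per preparation.
#'
#' @param density Density table (possibly several sections bound
#'   together).
#' @return A ggplot object.
#' @export
plot_layer_density <- function(density) {
  d <- dplyr::filter(density, !.data$layer %in% c("outside", "whole"))
  per_prep <- d |>
    dplyr::group_by(.data$layer, .data$preparation) |>
    dplyr::summarise(density = mean(.data$density_per_mm2), .groups = "drop")
  summ <- mean_sem(per_prep, "density", by = "layer")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$layer, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::geom_point(data = per_prep,
                        ggplot2::aes(y = .data$density), size = 1.5) +
    ggplot2::labs(x = "OB layer", y = "labeled processes / mm\u00b2") +
    ggplot2::theme_classic()
}

#' Sorted-size and derivative diagnostic panels for a size threshold
#'
#' Left-to-right: the sorted size distribution and the adjacent-difference
#' "derivative" with the detected peak and the k x mean-derivative level.
#'
#' @param x A `size_threshold`.
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @export
autoplot.size_threshold <- function(x, ...) {
  n <- x$n
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "sorted areas", index = seq_len(n),
                   value = x$areas_sorted),
    tibble::tibble(panel = "derivative", index = seq_len(n - 1),
                   value = x$derivative))
  hl <- tibble::tibble(panel = "derivative",
                       yintercept = x$k * x$mean_derivative)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = hl,
                        ggplot2::aes(yintercept = .data$yintercept),
                        linetype = "dashed", color = "red") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "sorted process index", y = "area (\u00b5m\u00b2)") +
    ggplot2::theme_classic()
  if (!is.na(x$threshold_um2)) {
    p <- p + ggplot2::geom_vline(
      data = tibble::tibble(panel = "derivative", x = x$peak_index),
      ggplot2::aes(xintercept = .data$x), linetype = "dotted")
  }
  p
}

#' @rdname autoplot.size_threshold
#' @export
plot_size_transition <- function(x, ...) autoplot.size_threshold(x, ...)

#' Category proportion bars
#'
#' Mean per-image percentage per VGLUT category with SEM error bars.
#'
#' @param x A `proportion_table`. @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proportion_table <- function(x, ...) {
  ggplot2::ggplot(x$summary,
                  ggplot2::aes(x = .data$category, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                                        ymax = .data$mean_pct + .data$sem_pct),
                           width = 0.2) +
    ggplot2::labs(x = "VGLUT category", y = "% of putative terminals") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
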