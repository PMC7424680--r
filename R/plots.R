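#' Plot dispersion curves of a normalization
#'
#' Mean area with a ±SD ribbon per day, before and after developmental
#' normalization — the standard visual check that normalization tightened
#' the population without distorting the growth trend.
#'
#' @param object A `dapd_normalization` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dapd_normalization
#' @export
autoplot.dapd_normalization <- function(object, ...) {
  raw <- dispersion_curves(object$series)
  nrm <- dispersion_curves(object$normalized)
  d <- dplyr::bind_rows(
    dplyr::mutate(raw, set = "non-normalized"),
    dplyr::mutate(nrm, set = "normalized")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      fill = "#b6a6d8", alpha = 0.6
    ) +
    ggplot2::geom_line(color = "#2c4b9b", linewidth = 0.8) +
    ggplot2::facet_wrap(~set) +
    ggplot2::labs(x = "day", y = "projected rosette area",
                  title = "Area dispersion before and after normalization") +
    ggplot2::theme_minimal()
}

#' Plot an MSD profile
#'
#' MSD against candidate day shift; the selected shift is the minimum
#' (ties broken toward zero).
#'
#' @param object An [msd_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msd_profile
#' @export
autoplot.msd_profile <- function(object, ...) {
  s <- select_shift(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$k, y = .data$msd)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = s, linetype = 2, color = "#b02428") +
    ggplot2::labs(x = "candidate shift k (days)", y = "MSD",
                  title = sprintf("MSD profile (%s), s = %d",
                                  attr(object, "plant_id") %||% "plant", s)) +
    ggplot2::theme_minimal()
}

#' Display a mask or label image
#'
#' @param x Logical mask, integer label matrix, or `leaf_labels` object.
#' @return A ggplot raster plot.
#' @export
plot_mask <- function(x) {
  if (inherits(x, "leaf_labels")) x <- x$labels
  d <- tidyr::expand_grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
  d$value <- as.vector(t(x))  # expand_grid varies col fastest
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (is.logical(x[1])) {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_manual(values = c("grey15", "#6fbf4c"),
                                 guide = "none")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_viridis_d(option = "turbo", guide = "none")
  }
}
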