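# ggplot2 visualisations for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ERSP map
#'
#' @param object An [ersp()] map.
#' @param ... Unused.
#' @return A ggplot raster of dB values over time and frequency.
#' @export
autoplot.ersp_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$freq, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "dB") +
    ggplot2::labs(
      x = "time relative to cue (s)", y = "frequency (Hz)",
      title = sprintf("ERSP at %s, %s (N = %d)", object$channel,
                      object$condition, object$n_trials)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-permutation result
#'
#' Time-frequency results show the significance-masked mean difference
#' (non-significant bins zeroed); electrode results show per-electrode t
#' values on the montage, significant cluster members emphasised.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, ...) {
  if (object$space == "electrodes") {
    mont <- montage_1020()
    df <- tibble::tibble(electrode = object$electrodes,
                         t = object$t_map,
                         significant = seq_along(object$electrodes) %in%
                           unlist(object$members[object$clusters$significant]))
    df <- dplyr::inner_join(df, mont, by = c(electrode = "channel"))
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$t,
                                         shape = .data$significant), size = 5) +
        ggplot2::geom_text(ggplot2::aes(label = .data$electrode),
                           vjust = -1.2, size = 3) +
        ggplot2::scale_colour_gradient2(low = "#2166ac", high = "#b2182b") +
        ggplot2::coord_equal() +
        ggplot2::theme_void() +
        ggplot2::labs(title = "electrode-space cluster test")
    )
  }
  tibble::tibble(
    freq = rep(object$freq, times = length(object$time)),
    time = rep(object$time, each = length(object$freq)),
    diff = as.vector(object$mask)
  ) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$freq, fill = .data$diff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "dB diff") +
    ggplot2::labs(x = "time relative to cue (s)", y = "frequency (Hz)",
                  title = "cluster-masked condition difference") +
    ggplot2::theme_minimal()
}

#' Plot an energy curve
#'
#' @param object An [energy_curve()] tibble (optionally with a
#'   `condition` column for grouped curves).
#' @param ... Unused.
#' @return A ggplot line chart.
#' @export
autoplot.energy_curve <- function(object, ...) {
  xlab <- if (object$mode[1] == "over_time") "frequency (Hz)" else "time (s)"
  aes <- if ("condition" %in% names(object))
    ggplot2::aes(.data$axis, .data$energy, colour = .data$condition)
  else ggplot2::aes(.data$axis, .data$energy)
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "energy (dB)") +
    ggplot2::theme_minimal()
}

#' Plot a TBR series
#'
#' @param object A `tbr_series` tibble (offline or online).
#' @param ... Unused.
#' @return A ggplot line chart of TBR against time.
#' @export
autoplot.tbr_series <- function(object, ...) {
  aes <- if ("condition" %in% names(object))
    ggplot2::aes(.data$time, .data$tbr, colour = .data$condition)
  else ggplot2::aes(.data$time, .data$tbr)
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "theta/beta ratio") +
    ggplot2::theme_minimal()
}

#' Plot a scalp topography
#'
#' @param object A [topography()] map.
#' @param ... Unused.
#' @return A ggplot raster with electrode markers.
#' @export
autoplot.topo_map <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = object$values, size = 1) +
    ggplot2::geom_text(data = object$values,
                       ggplot2::aes(label = .data$electrode),
                       vjust = -1, size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "transparent") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
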