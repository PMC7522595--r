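#' Plot a multichannel recording
#'
#' Faceted time-series view of all (or selected) channels.
#'
#' @param object A [recording()].
#' @param channels Channels to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coro_recording
#' @export
autoplot.coro_recording <- function(object, channels = NULL, ...) {
  channels <- channels %||% names(object$channels)
  df <- purrr::map_dfr(channels, function(ch) {
    tr <- get_channel(object, ch)
    dplyr::mutate(as_tibble(tr),
                  panel = sprintf("%s [%s]", tr$label, tr$unit))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("animal %s, condition %s",
                                  object$animal_id, object$condition)) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble-averaged beat
#'
#' @param object A [ensemble_average()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coro_beat
#' @export
autoplot.coro_beat <- function(object, ...) {
  df <- tibble::tibble(
    time = (seq_along(object$mean_waveform) - 1) / object$fs,
    value = object$mean_waveform)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time in beat (s)",
                  y = sprintf("%s (%s)", object$label, object$unit),
                  title = sprintf("ensemble of %d beats", object$n_cycles)) +
    ggplot2::theme_minimal()
}

#' Pressure-volume loop plot
#'
#' Draws the closed P-V trajectories of the analysis beats.
#'
#' @param p LV pressure [trace()] (mmHg).
#' @param v Calibrated LV volume [trace()] (ml), aligned with `p`.
#' @param cycles A [detect_cycles()] result.
#' @param n,offset Beats to draw, as in [pv_metrics()].
#' @return A ggplot.
#' @export
plot_pv_loop <- function(p, v, cycles, n = 10, offset = 0) {
  stopifnot(inherits(p, "coro_trace"), inherits(v, "coro_trace"),
            inherits(cycles, "coro_cycles"))
  b <- cycles$boundaries
  df <- purrr::map_dfr((offset + 1L):(offset + n), function(k) {
    idx <- b[k]:(b[k + 1L] - 1L)
    tibble::tibble(beat = k, volume = v$samples[idx], pressure = p$samples[idx])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume, y = .data$pressure,
                                   group = .data$beat)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "LV volume (ml)", y = "LV pressure (mmHg)") +
    ggplot2::theme_minimal()
}
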