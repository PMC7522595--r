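#' Single-channel physiological trace
#'
#' A `coro_trace` is a uniformly sampled single-channel signal: a numeric
#' vector of samples together with its sampling rate, physical unit and a
#' channel label. Time is implicit (`(i - 1) / fs` seconds for sample `i`);
#' there is no time column.
#'
#' @param samples Numeric vector of at least two finite values.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param unit Unit string, one of `"mmHg"`, `"cm/s"`, `"ml"`, `"L/min"`,
#'   `"degC"`, `"a.u."`.
#' @param label Channel name.
#'
#' @return A `coro_trace` object.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 200)), fs = 100, unit = "mmHg",
#'             label = "demo")
#' tr
#' @export
trace <- function(samples, fs, unit = "a.u.", label = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    abort("a trace needs at least 2 samples", class = "corohemo_validation_error")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    abort(sprintf("non-finite sample at index %d in channel '%s'", bad, label),
          class = "corohemo_validation_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("fs must be a positive finite scalar (Hz)",
          class = "corohemo_validation_error")
  }
  unit <- as.character(unit)[1L]
  allowed <- c("mmHg", "cm/s", "ml", "L/min", "degC", "a.u.")
  if (!unit %in% allowed) {
    abort(sprintf("unknown unit '%s' (expected one of %s)", unit,
                  paste(allowed, collapse = ", ")),
          class = "corohemo_validation_error")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), unit = unit,
         label = as.character(label)[1L]),
    class = "coro_trace"
  )
}

#' @export
print.coro_trace <- function(x, ...) {
  cat(sprintf("<coro_trace> '%s': %d samples @ %g Hz [%s] (%.3f s)\n",
              x$label, length(x$samples), x$fs, x$unit,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.coro_trace <- function(x) length(x$samples)

#' Implicit time axis of a trace
#'
#' @param x A [trace()].
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "coro_trace"))
  (seq_along(x$samples) - 1) / x$fs
}

#' @describeIn trace Coerce a trace to a tibble with `time` (s) and `value`
#'   columns.
#' @param x A `coro_trace`.
#' @param ... Unused.
#' @method as_tibble coro_trace
#' @export
as_tibble.coro_trace <- function(x, ...) {
  tibble::tibble(time = trace_time(x), value = x$samples,
                 channel = x$label, unit = x$unit)
}

is_trace <- function(x) inherits(x, "coro_trace")

#' Multichannel physiological recording
#'
#' A `coro_recording` bundles several [trace()] channels that share one
#' sampling rate, together with protocol metadata: the animal/subject id and
#' the protocol condition. Conditions follow the pump-support protocol:
#' `baseline` and `post_dissection` bracket the creation of the coronary
#' lesion, and `P0` (no support) / `P8` (maximal pump flow) are the paired
#' support states under comparison.
#'
#' @param channels Named list of [trace()] objects, all with the same `fs`.
#' @param animal_id Subject identifier.
#' @param condition One of `"P0"`, `"P8"`, `"baseline"`, `"post_dissection"`.
#' @param meta Optional named list of free-form metadata.
#'
#' @return A `coro_recording` object.
#' @export
recording <- function(channels, animal_id = "unknown", condition = "P0",
                      meta = list()) {
  if (!is.list(channels) || length(channels) == 0L) {
    abort("channels must be a non-empty named list of traces",
          class = "corohemo_validation_error")
  }
  labs <- names(channels)
  if (is.null(labs) || any(labs == "") || anyDuplicated(labs)) {
    abort("channel labels must be unique and non-empty",
          class = "corohemo_validation_error")
  }
  ok <- vapply(channels, is_trace, logical(1))
  if (!all(ok)) {
    abort(sprintf("channel '%s' is not a trace", labs[!ok][1L]),
          class = "corohemo_validation_error")
  }
  fss <- vapply(channels, function(tr) tr$fs, numeric(1))
  if (length(unique(fss)) != 1L) {
    abort("all channels must share one sampling rate",
          class = "corohemo_validation_error")
  }
  condition <- match.arg(condition, c("P0", "P8", "baseline", "post_dissection"))
  for (lab in labs) channels[[lab]]$label <- lab
  structure(
    list(channels = channels, animal_id = as.character(animal_id)[1L],
         condition = condition, meta = meta),
    class = "coro_recording"
  )
}

#' @export
print.coro_recording <- function(x, ...) {
  fs <- recording_fs(x)
  n <- length(x$channels[[1]]$samples)
  cat(sprintf("<coro_recording> animal '%s', condition %s: %d channels @ %g Hz, %.2f s\n",
              x$animal_id, x$condition, length(x$channels), fs, n / fs))
  for (tr in x$channels) {
    cat(sprintf("  %-28s %8d samples [%s]\n", tr$label,
                length(tr$samples), tr$unit))
  }
  invisible(x)
}

#' Sampling rate shared by a recording's channels
#'
#' @param rec A [recording()].
#' @return Sampling rate in Hz.
#' @export
recording_fs <- function(rec) {
  stopifnot(inherits(rec, "coro_recording"))
  rec$channels[[1]]$fs
}

#' Extract one channel from a recording
#'
#' @param rec A [recording()].
#' @param label Channel label.
#' @return The requested [trace()].
#' @export
get_channel <- function(rec, label) {
  stopifnot(inherits(rec, "coro_recording"))
  if (!label %in% names(rec$channels)) {
    abort(sprintf("recording has no channel '%s' (has: %s)", label,
                  paste(names(rec$channels), collapse = ", ")),
          class = "corohemo_validation_error")
  }
  rec$channels[[label]]
}

#' @describeIn recording Coerce a recording to a long tibble with `time`,
#'   `channel`, `value` and `unit` columns.
#' @param x A `coro_recording`.
#' @param ... Unused.
#' @method as_tibble coro_recording
#' @export
as_tibble.coro_recording <- function(x, ...) {
  purrr::map_dfr(x$channels, as_tibble.coro_trace)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
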