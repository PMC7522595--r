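#' Anti-aliased down-sampling of a trace
#'
#' Reduces the sampling rate by an integer factor, applying a zero-phase FIR
#' low-pass before decimation so out-of-band noise cannot alias into the
#' retained band. The filter is a Hamming-window FIR with cutoff at 80% of
#' the output Nyquist frequency, renormalized to unit DC gain so constant
#' (and slowly varying) levels pass unchanged; edges are padded by sample
#' replication. The acquisition protocol records at 1 kHz and analyses at
#' 200 Hz, a factor of 5.
#'
#' @param t A [trace()].
#' @param target_fs Target sampling rate in Hz; `t$fs` must be an integer
#'   multiple of it (no interpolating resampler is provided).
#' @return A [trace()] at `target_fs` with the same unit and label.
#' @export
downsample <- function(t, target_fs = 200) {
  stopifnot(inherits(t, "coro_trace"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    abort("target_fs must be a positive scalar", class = "corohemo_param_error")
  }
  ratio <- t$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf("fs (%g Hz) is not an integer multiple of target_fs (%g Hz)",
                  t$fs, target_fs),
          class = "corohemo_param_error")
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(t)
  x <- t$samples
  ord <- 10L * ratio            # even order -> odd symmetric filter
  h <- signal::fir1(ord, 0.8 / ratio)
  h <- h / sum(h)               # exact unit DC gain
  half <- ord %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, h, sides = 2)
  y <- as.numeric(y[(half + 1L):(half + length(x))])
  keep <- seq(1L, length(y), by = ratio)
  trace(y[keep], fs = target_fs, unit = t$unit, label = t$label)
}

#' Savitzky-Golay smoothing of a trace
#'
#' Least-squares polynomial smoothing: each output sample is the value, at
#' the window's centre point, of the polynomial of the given order fitted to
#' the samples in a sliding window (the first and last half-windows are
#' served by the fits to the first and last full windows, evaluated
#' off-centre). The analysis protocol uses window 11 and order 3 on 200 Hz
#' traces, which passes any cubic segment unchanged while suppressing
#' high-frequency noise.
#'
#' @param t A [trace()].
#' @param window Odd window length in samples (default 11).
#' @param order Polynomial order, strictly less than `window` (default 3).
#' @return A smoothed [trace()] with unchanged length, fs and unit.
#' @export
sg_smooth <- function(t, window = 11, order = 3) {
  stopifnot(inherits(t, "coro_trace"))
  if (window %% 2 != 1 || window < 3) {
    abort("window must be an odd integer >= 3", class = "corohemo_param_error")
  }
  if (order >= window || order < 0) {
    abort("order must satisfy 0 <= order < window",
          class = "corohemo_param_error")
  }
  if (length(t$samples) < window) {
    abort(sprintf("trace length %d is shorter than the window (%d)",
                  length(t$samples), window),
          class = "corohemo_param_error")
  }
  y <- signal::sgolayfilt(t$samples, p = order, n = window)
  trace(as.numeric(y), fs = t$fs, unit = t$unit, label = t$label)
}

#' Cardiac-cycle boundaries from a pressure trace
#'
#' Each cardiac cycle is delimited by a local minimum of the (smoothed)
#' pressure trace. Candidate minima are screened by topographic prominence
#' (relative to the overall trace range) and by a refractory distance so
#' dicrotic notches and noise wiggles do not split beats. A cycle spans
#' `[boundary_i, boundary_i+1)`; the trailing partial cycle is discarded by
#' consumers.
#'
#' @param pressure A [trace()], typically LV or coronary pressure at 200 Hz
#'   after [sg_smooth()].
#' @param min_period_s Minimum admissible cycle period in seconds (default
#'   0.3 s, a 200 beats/min ceiling).
#' @param prominence_frac Minimum prominence of a boundary minimum as a
#'   fraction of the trace's total range (default 0.2).
#' @return A `coro_cycles` object with fields `boundaries` (strictly
#'   increasing sample indices) and `fs`.
#' @export
detect_cycles <- function(pressure, min_period_s = 0.3, prominence_frac = 0.2) {
  stopifnot(inherits(pressure, "coro_trace"))
  if (min_period_s <= 0) {
    abort("min_period_s must be positive", class = "corohemo_param_error")
  }
  x <- pressure$samples
  n <- length(x)
  rng <- max(x) - min(x)
  # strict rise on the right avoids double-counting flat-bottomed minima
  cand <- which(x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  if (rng > 0 && length(cand) > 0) {
    prom <- vapply(cand, function(i) .min_prominence(x, i), numeric(1))
    cand <- cand[prom >= prominence_frac * rng]
  } else {
    cand <- integer(0)
  }
  min_dist <- min_period_s * pressure$fs
  # deepest minima win when two candidates fall within the refractory distance
  keep <- integer(0)
  for (i in cand[order(x[cand])]) {
    if (all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 2L) {
    abort(sprintf("no cycles: %d qualifying pressure minima found (need >= 2)",
                  length(keep)),
          class = "corohemo_no_cycles_error")
  }
  structure(list(boundaries = keep, fs = pressure$fs), class = "coro_cycles")
}

# topographic prominence of the local minimum at index i:
# walk out on each side until a strictly lower sample (or the edge), take the
# maximum seen on each side, and measure up to the lower of the two maxima
.min_prominence <- function(x, i) {
  lo <- x[i]
  left <- x[seq_len(i - 1L)]
  below_l <- which(left < lo)
  lmax <- if (length(below_l)) max(left[(max(below_l) + 1L):(i - 1L)]) else max(left)
  right <- x[(i + 1L):length(x)]
  below_r <- which(right < lo)
  rmax <- if (length(below_r)) max(right[seq_len(min(below_r) - 1L)]) else max(right)
  min(lmax, rmax) - lo
}

#' @export
print.coro_cycles <- function(x, ...) {
  cat(sprintf("<coro_cycles> %d boundaries (%d complete cycles) @ %g Hz\n",
              length(x$boundaries), length(x$boundaries) - 1L, x$fs))
  invisible(x)
}

#' Number of complete cycles in a cycle set
#'
#' @param cycles A [detect_cycles()] result.
#' @return Integer count of complete cycles.
#' @export
n_cycles <- function(cycles) {
  stopifnot(inherits(cycles, "coro_cycles"))
  length(cycles$boundaries) - 1L
}

#' Ensemble-average consecutive cardiac cycles
#'
#' Takes `n` consecutive cycles of a trace (the protocol uses ten), resamples
#' each by linear interpolation to the median cycle length, and averages them
#' pointwise into one representative beat. Averaging suppresses zero-mean
#' beat-to-beat noise by a factor of about `sqrt(n)`.
#'
#' @param t A [trace()] at the cycle set's sampling rate.
#' @param cycles A [detect_cycles()] result derived from the paired pressure
#'   trace.
#' @param n Number of consecutive cycles to average (default 10).
#' @param offset Number of leading complete cycles to skip before taking the
#'   `n` cycles (default 0).
#' @return A `coro_beat` object: fields `mean_waveform`, `n_cycles`, `fs`,
#'   `unit`, `label`.
#' @export
ensemble_average <- function(t, cycles, n = 10, offset = 0) {
  stopifnot(inherits(t, "coro_trace"), inherits(cycles, "coro_cycles"))
  if (abs(t$fs - cycles$fs) > 1e-9) {
    abort("trace and cycle set have different sampling rates",
          class = "corohemo_param_error")
  }
  if (n < 2) abort("n must be >= 2", class = "corohemo_param_error")
  avail <- n_cycles(cycles) - offset
  if (avail < n) {
    abort(sprintf("only %d complete cycles available, need %d", max(avail, 0), n),
          class = "corohemo_param_error")
  }
  b <- cycles$boundaries
  idx <- (offset + 1L):(offset + n)
  segs <- lapply(idx, function(k) t$samples[b[k]:(b[k + 1L] - 1L)])
  len <- as.integer(round(median(lengths(segs))))
  resampled <- lapply(segs, function(s) {
    if (length(s) == len) return(s)
    approx(x = seq(0, 1, length.out = length(s)), y = s,
           xout = seq(0, 1, length.out = len))$y
  })
  structure(
    list(mean_waveform = Reduce(`+`, resampled) / n, n_cycles = as.integer(n),
         fs = t$fs, unit = t$unit, label = t$label),
    class = "coro_beat"
  )
}

#' @export
print.coro_beat <- function(x, ...) {
  cat(sprintf("<coro_beat> '%s': mean of %d cycles, %d samples @ %g Hz [%s]\n",
              x$label, x$n_cycles, length(x$mean_waveform), x$fs, x$unit))
  invisible(x)
}

#' Maximum, minimum and mean of an ensemble beat
#'
#' @param b A [ensemble_average()] result (or a [trace()], whose samples are
#'   summarized directly).
#' @return A one-row tibble with columns `channel`, `unit`, `maximum`,
#'   `minimum`, `mean`.
#' @export
beat_stats <- function(b) {
  w <- if (inherits(b, "coro_beat")) b$mean_waveform
       else if (inherits(b, "coro_trace")) b$samples
       else abort("beat_stats expects a coro_beat or coro_trace",
                  class = "corohemo_param_error")
  if (length(w) == 0L) {
    abort("empty waveform", class = "corohemo_param_error")
  }
  tibble::tibble(channel = b$label, unit = b$unit,
                 maximum = max(w), minimum = min(w), mean = mean(w))
}

#' Full waveform-conditioning pipeline for a trace
#'
#' Convenience wrapper chaining [downsample()] and [sg_smooth()] with the
#' protocol defaults (1 kHz to 200 Hz; window 11, order 3).
#'
#' @inheritParams downsample
#' @inheritParams sg_smooth
#' @param smooth If `FALSE`, skip the Savitzky-Golay step (ensemble averaging
#'   of raw beats).
#' @return A conditioned [trace()].
#' @export
condition_trace <- function(t, target_fs = 200, window = 11, order = 3,
                            smooth = TRUE) {
  out <- downsample(t, target_fs)
  if (smooth) out <- sg_smooth(out, window = window, order = order)
  out
}

#' Per-channel beat statistics for a whole recording
#'
#' Runs the full conditioning pipeline on every requested channel of a
#' recording — down-sample, smooth, detect cycles on the gating pressure
#' channel, ensemble-average `n` consecutive beats — and tabulates
#' maximum/minimum/mean per channel.
#'
#' @param rec A [recording()].
#' @param gating_channel Channel whose pressure minima define the cycles
#'   (default `"lv_pressure"`).
#' @param channels Channels to summarize (default: all).
#' @param n Number of consecutive cycles to ensemble-average (default 10).
#' @param offset Leading complete cycles to skip (default 0).
#' @inheritParams condition_trace
#' @param min_period_s,prominence_frac Passed to [detect_cycles()].
#' @return A tibble with one row per channel: `animal_id`, `condition`,
#'   `channel`, `unit`, `maximum`, `minimum`, `mean`, `n_cycles`.
#' @export
beat_summary <- function(rec, gating_channel = "lv_pressure", channels = NULL,
                         n = 10, offset = 0, target_fs = 200, window = 11,
                         order = 3, smooth = TRUE, min_period_s = 0.3,
                         prominence_frac = 0.2) {
  stopifnot(inherits(rec, "coro_recording"))
  channels <- channels %||% names(rec$channels)
  gate <- condition_trace(get_channel(rec, gating_channel), target_fs,
                          window, order, smooth = TRUE)
  cyc <- detect_cycles(gate, min_period_s, prominence_frac)
  purrr::map_dfr(channels, function(ch) {
    tr <- condition_trace(get_channel(rec, ch), target_fs, window, order,
                          smooth = smooth)
    eb <- ensemble_average(tr, cyc, n = n, offset = offset)
    dplyr::mutate(beat_stats(eb),
                  animal_id = rec$animal_id, condition = rec$condition,
                  n_cycles = n, .before = 1L)
  })
}
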