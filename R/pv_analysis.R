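#' Thermodilution cardiac output (Stewart-Hamilton)
#'
#' Computes cardiac output from the temperature washout curve of a cold
#' saline bolus injected into the right atrium:
#' `CO = V_i * (T_blood - T_inj) * K / integral(dT dt)`, the integral taken
#' by the trapezoid rule over the thermistor deviation curve. The protocol
#' injects roughly 0.25 ml per kg body weight of cold saline.
#'
#' @param injectate_volume Injectate volume in ml.
#' @param blood_temp Blood temperature in degrees C.
#' @param injectate_temp Injectate temperature in degrees C (must be colder
#'   than blood).
#' @param thermistor_curve A [trace()] of temperature deviation (degC) versus
#'   time; must have decayed to at most 5% of its peak by its end, otherwise
#'   the washout integral is truncated and CO overestimated.
#' @param computation_constant Device/catheter constant folding in injectate
#'   and blood heat capacities (dimensionless, default 1).
#' @return Cardiac output in L/min.
#' @export
thermodilution_co <- function(injectate_volume, blood_temp, injectate_temp,
                              thermistor_curve, computation_constant = 1) {
  stopifnot(inherits(thermistor_curve, "coro_trace"))
  if (blood_temp <= injectate_temp) {
    abort("blood_temp must exceed injectate_temp",
          class = "corohemo_param_error")
  }
  if (injectate_volume <= 0) {
    abort("injectate_volume must be positive", class = "corohemo_param_error")
  }
  y <- thermistor_curve$samples
  if (tail(y, 1L) > 0.05 * max(y)) {
    abort("thermistor curve has not returned to <= 5% of its peak",
          class = "corohemo_param_error")
  }
  auc <- pracma::trapz(trace_time(thermistor_curve), y)  # degC * s
  if (!is.finite(auc) || auc <= 0) {
    abort("non-positive washout integral", class = "corohemo_param_error")
  }
  co_ml_s <- injectate_volume * (blood_temp - injectate_temp) *
    computation_constant / auc
  co_ml_s * 60 / 1000
}

#' Conductance-catheter gain from thermodilution
#'
#' The conductance gain `alpha` is the ratio of cardiac output measured by
#' thermodilution to cardiac output computed from the uncalibrated
#' conductance volume channel (stroke volume times heart rate on the raw
#' trace).
#'
#' @param co_thermo Thermodilution cardiac output, L/min.
#' @param co_conductance_raw Cardiac output from the raw conductance channel,
#'   L/min (same units; only the ratio matters).
#' @return The dimensionless gain `alpha`.
#' @export
calibrate_alpha <- function(co_thermo, co_conductance_raw) {
  if (!is.finite(co_thermo) || co_thermo <= 0 ||
      !is.finite(co_conductance_raw) || co_conductance_raw <= 0) {
    abort("cardiac outputs must be positive and finite",
          class = "corohemo_param_error")
  }
  co_thermo / co_conductance_raw
}

#' Parallel-volume offset from echocardiographic EDV
#'
#' After gain scaling, the conductance volume still carries a parallel
#' conductance offset. It is fixed by matching the scaled end-diastolic
#' volume to the end-diastolic volume from three-dimensional
#' echocardiography: the offset subtracted from the alpha-scaled trace is
#' `edv_scaled - edv_echo`.
#'
#' @param edv_echo End-diastolic volume from 3D echo, ml.
#' @param edv_scaled End-diastolic volume of the alpha-scaled conductance
#'   trace, ml.
#' @return Parallel volume offset in ml (may be negative).
#' @export
calibrate_parallel <- function(edv_echo, edv_scaled) {
  if (!is.finite(edv_echo) || !is.finite(edv_scaled)) {
    abort("volumes must be finite", class = "corohemo_param_error")
  }
  edv_scaled - edv_echo
}

#' Bundle conductance calibration factors
#'
#' @param alpha Dimensionless conductance gain (> 0).
#' @param v_parallel Parallel volume offset in ml.
#' @return A `coro_calibration` object.
#' @export
calibration_factors <- function(alpha, v_parallel) {
  if (!is.finite(alpha) || alpha <= 0) {
    abort("alpha must be positive and finite", class = "corohemo_param_error")
  }
  if (!is.finite(v_parallel)) {
    abort("v_parallel must be finite", class = "corohemo_param_error")
  }
  structure(list(alpha = alpha, v_parallel = v_parallel),
            class = "coro_calibration")
}

#' @export
print.coro_calibration <- function(x, ...) {
  cat(sprintf("<coro_calibration> alpha = %.6g, v_parallel = %.6g ml\n",
              x$alpha, x$v_parallel))
  invisible(x)
}

#' Apply conductance calibration to a raw volume channel
#'
#' Scales first, then subtracts the parallel volume:
#' `V = alpha * v_raw - v_parallel`, so that `alpha` matches cardiac output
#' (a scale-only quantity) independently of the offset.
#'
#' @param v_raw Raw conductance volume [trace()] (unit `"a.u."` or `"ml"`).
#' @param f A [calibration_factors()].
#' @return A calibrated [trace()] with unit `"ml"`.
#' @export
apply_calibration <- function(v_raw, f) {
  stopifnot(inherits(v_raw, "coro_trace"), inherits(f, "coro_calibration"))
  if (!v_raw$unit %in% c("a.u.", "ml")) {
    abort(sprintf("cannot calibrate a channel in '%s' (expected a.u. or ml)",
                  v_raw$unit),
          class = "corohemo_param_error")
  }
  trace(f$alpha * v_raw$samples - f$v_parallel, fs = v_raw$fs, unit = "ml",
        label = v_raw$label)
}

# unsigned shoelace area of the closed polygon (v, p); the loop is closed by
# joining the last point back to the first
.loop_area <- function(p, v) {
  v2 <- c(v[-1L], v[1L])
  p2 <- c(p[-1L], p[1L])
  abs(sum(v * p2 - v2 * p)) / 2
}

#' Pressure-volume loop metrics per condition
#'
#' Computes the standard left-ventricular metric set from aligned pressure
#' and calibrated volume traces, cycle by cycle, then averages over the same
#' consecutive beats used for ensemble averaging elsewhere (ten by default).
#' End-diastole is taken as the sample of maximal volume within a cycle and
#' end-systole as the sample of minimal volume; these landmarks are robust
#' without ECG gating. Stroke work is the unsigned shoelace area of the
#' closed P-V polygon.
#'
#' By construction `sv = edv - esv` and `co = sv * hr / 1000` hold exactly
#' for the reported (cycle-averaged) values.
#'
#' @param p LV pressure [trace()] (mmHg).
#' @param v Calibrated LV volume [trace()] (ml), same length and fs as `p`.
#' @param cycles A [detect_cycles()] result from the LV pressure trace.
#' @param n Number of consecutive cycles to average (default 10).
#' @param offset Leading complete cycles to skip (default 0).
#' @return A one-row tibble: `edp`, `esp` (mmHg), `edv`, `esv`, `sv` (ml),
#'   `sw` (mmHg*ml), `hr` (beats/min), `co` (L/min), `n_cycles`.
#' @export
pv_metrics <- function(p, v, cycles, n = 10, offset = 0) {
  stopifnot(inherits(p, "coro_trace"), inherits(v, "coro_trace"),
            inherits(cycles, "coro_cycles"))
  if (length(p$samples) != length(v$samples) || abs(p$fs - v$fs) > 1e-9) {
    abort("pressure and volume traces must be aligned (same length and fs)",
          class = "corohemo_param_error")
  }
  avail <- n_cycles(cycles) - offset
  if (avail < n) {
    abort(sprintf("only %d complete cycles available, need %d",
                  max(avail, 0), n),
          class = "corohemo_param_error")
  }
  b <- cycles$boundaries
  per <- purrr::map_dfr((offset + 1L):(offset + n), function(k) {
    idx <- b[k]:(b[k + 1L] - 1L)
    if (length(idx) < 8L) {
      abort(sprintf("degenerate loop: cycle %d has %d points (< 8)",
                    k, length(idx)),
            class = "corohemo_param_error")
    }
    pp <- p$samples[idx]
    vv <- v$samples[idx]
    ied <- which.max(vv)
    ies <- which.min(vv)
    tibble::tibble(edp = pp[ied], esp = pp[ies], edv = vv[ied], esv = vv[ies],
                   sw = .loop_area(pp, vv), len = length(idx))
  })
  out <- dplyr::summarise(per,
    edp = mean(.data$edp), esp = mean(.data$esp),
    edv = mean(.data$edv), esv = mean(.data$esv),
    sw = mean(.data$sw), hr = 60 * cycles$fs / mean(.data$len))
  out$sv <- out$edv - out$esv
  out$co <- out$sv * out$hr / 1000
  dplyr::select(dplyr::mutate(out, n_cycles = n),
                "edp", "esp", "edv", "esv", "sv", "sw", "hr", "co", "n_cycles")
}

#' PV metrics straight from a recording
#'
#' Conditions the LV pressure and conductance channels (down-sample, smooth),
#' detects cycles on the pressure channel, applies the conductance
#' calibration, and tabulates [pv_metrics()].
#'
#' @param rec A [recording()] with the given pressure and conductance
#'   channels.
#' @param cal A [calibration_factors()]; if `NULL`, the conductance channel
#'   is assumed already calibrated in ml.
#' @param pressure_channel,volume_channel Channel labels (defaults
#'   `"lv_pressure"`, `"lv_conductance"`).
#' @inheritParams beat_summary
#' @return A one-row tibble as [pv_metrics()], prefixed with `animal_id` and
#'   `condition`.
#' @export
pv_from_recording <- function(rec, cal = NULL,
                              pressure_channel = "lv_pressure",
                              volume_channel = "lv_conductance",
                              n = 10, offset = 0, target_fs = 200,
                              window = 11, order = 3,
                              min_period_s = 0.3, prominence_frac = 0.2) {
  stopifnot(inherits(rec, "coro_recording"))
  p <- condition_trace(get_channel(rec, pressure_channel), target_fs, window, order)
  vr <- condition_trace(get_channel(rec, volume_channel), target_fs, window, order)
  if (!is.null(cal)) vr <- apply_calibration(vr, cal)
  cyc <- detect_cycles(p, min_period_s, prominence_frac)
  dplyr::mutate(pv_metrics(p, vr, cyc, n = n, offset = offset),
                animal_id = rec$animal_id, condition = rec$condition,
                .before = 1L)
}

#' Derive conductance calibration factors from a recording
#'
#' Implements the two-step calibration: the gain `alpha` is the ratio of a
#' reference cardiac output (thermodilution) to the cardiac output computed
#' from the raw conductance channel (uncalibrated stroke volume times heart
#' rate over the analysis beats), and the parallel volume then matches the
#' alpha-scaled end-diastolic volume to a reference EDV (3D echo).
#'
#' @param rec A [recording()].
#' @param co_ref Reference cardiac output (thermodilution), L/min.
#' @param edv_ref Reference end-diastolic volume (3D echo), ml.
#' @inheritParams pv_from_recording
#' @inheritParams raw_volume_metrics
#' @return A [calibration_factors()].
#' @export
calibrate_from_recording <- function(rec, co_ref, edv_ref,
                                     pressure_channel = "lv_pressure",
                                     volume_channel = "lv_conductance",
                                     n = 10, offset = 0, target_fs = 200,
                                     window = 11, order = 3,
                                     min_period_s = 0.3,
                                     prominence_frac = 0.2,
                                     extremum_window = 7) {
  stopifnot(inherits(rec, "coro_recording"))
  p <- condition_trace(get_channel(rec, pressure_channel), target_fs, window, order)
  vr <- condition_trace(get_channel(rec, volume_channel), target_fs, window, order)
  cyc <- detect_cycles(p, min_period_s, prominence_frac)
  raw <- raw_volume_metrics(vr, cyc, n = n, offset = offset,
                            extremum_window = extremum_window)
  alpha <- calibrate_alpha(co_ref, raw$co)
  v_parallel <- calibrate_parallel(edv_ref, alpha * raw$edv)
  calibration_factors(alpha, v_parallel)
}

#' Raw volume-channel metrics from an ensemble-averaged beat
#'
#' Estimates the end-diastolic/end-systolic levels, stroke volume, heart
#' rate and cardiac output of a (possibly uncalibrated) volume trace from
#' the ensemble average of `n` consecutive beats. Because the volume
#' extremes sit on the isovolumic plateaus, the ensemble beat is
#' re-smoothed (circularly, so the beat's wrap point is not an edge) before
#' the extrema are read; this suppresses the upward bias that the extremum
#' of a noisy trace would otherwise carry into the calibration gain.
#'
#' @param v Volume [trace()] (any volume-proportional unit).
#' @param cycles A [detect_cycles()] result at the same fs.
#' @param n,offset Beats to use, as in [ensemble_average()].
#' @param extremum_window Odd Savitzky-Golay window (samples) for the
#'   re-smoothing of the ensemble beat (order 3; default 7, skipped for
#'   beats shorter than the window).
#' @return A one-row tibble: `edv`, `esv`, `sv` (trace units), `hr`
#'   (beats/min) and `co` (`sv * hr / 1000`).
#' @export
raw_volume_metrics <- function(v, cycles, n = 10, offset = 0,
                               extremum_window = 7) {
  eb <- ensemble_average(v, cycles, n = n, offset = offset)
  w <- eb$mean_waveform
  if (extremum_window >= 5 && length(w) >= extremum_window) {
    k <- (extremum_window - 1L) %/% 2L
    wx <- c(tail(w, k), w, head(w, k))  # circular pad: beats are periodic
    wx <- signal::sgolayfilt(wx, p = 3, n = extremum_window)
    w <- wx[(k + 1L):(k + length(w))]
  }
  b <- cycles$boundaries
  hr <- 60 * cycles$fs * n / (b[offset + n + 1L] - b[offset + 1L])
  sv <- max(w) - min(w)
  tibble::tibble(edv = max(w), esv = min(w), sv = sv, hr = hr,
                 co = sv * hr / 1000)
}
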