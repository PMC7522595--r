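#' Angiographic flow delay time (DT)
#'
#' The delay-time statistic quantifies flow delay in the left anterior
#' descending artery (LAD) relative to the left circumflex (LCX) after a
#' single even contrast injection into both:
#' `DT = (LAD contrast filling time) - (LCX contrast filling time)`,
#' each filling time being the first-fill frame index divided by the
#' acquisition frame rate (30 frames/s in the protocol). DT is negative if
#' the LAD fills first, and is invariant to any common frame offset.
#'
#' @param a A [angio_annotation()] containing `LAD` and `LCX` entries.
#' @return A one-row tibble: `dt_seconds` (full precision; round to 2
#'   decimals for reporting), `lad_fill_frame`, `lcx_fill_frame`,
#'   `frame_rate`.
#' @examples
#' compute_dt(angio_annotation(c(LAD = 42, LCX = 10), frame_rate = 30))
#' @export
compute_dt <- function(a) {
  stopifnot(inherits(a, "coro_angio"))
  for (v in c("LAD", "LCX")) {
    if (!v %in% names(a$fills)) {
      abort(sprintf("annotation is missing vessel '%s'", v),
            class = "corohemo_validation_error")
    }
  }
  lad <- a$fills[["LAD"]]
  lcx <- a$fills[["LCX"]]
  tibble::tibble(dt_seconds = (lad - lcx) / a$frame_rate,
                 lad_fill_frame = lad, lcx_fill_frame = lcx,
                 frame_rate = a$frame_rate)
}

#' First-fill frame from a per-frame opacification trace
#'
#' Stand-in for visual frame reading: given a per-frame opacification
#' intensity trace for one vessel, the first-fill frame is the first frame
#' at which intensity reaches a fraction of the fully opacified plateau,
#' the plateau being estimated as the mean intensity over the last 10% of
#' frames.
#'
#' @param intensity A [trace()] of non-negative per-frame opacification
#'   (arbitrary units) sampled at the angiographic frame rate; frame 0 is
#'   the first sample.
#' @param threshold_frac Fraction of the plateau counted as "filled"
#'   (default 0.5).
#' @return Integer first-fill frame index (0-based).
#' @export
fill_frame_from_intensity <- function(intensity, threshold_frac = 0.5) {
  stopifnot(inherits(intensity, "coro_trace"))
  if (threshold_frac <= 0 || threshold_frac > 1) {
    abort("threshold_frac must lie in (0, 1]", class = "corohemo_param_error")
  }
  y <- intensity$samples
  if (any(y < 0)) {
    abort("opacification intensity must be non-negative",
          class = "corohemo_validation_error")
  }
  n <- length(y)
  tail_n <- max(1L, ceiling(0.1 * n))
  plateau <- mean(y[(n - tail_n + 1L):n])
  if (plateau <= 0) {
    abort("intensity trace has no opacification plateau",
          class = "corohemo_validation_error")
  }
  hit <- which(y >= threshold_frac * plateau)
  if (length(hit) == 0L) {
    abort(sprintf("intensity never reaches %.0f%% of its plateau",
                  100 * threshold_frac),
          class = "corohemo_validation_error")
  }
  as.integer(hit[1L] - 1L)  # frames are 0-based
}

#' DT from per-vessel opacification traces
#'
#' Convenience wrapper: reads the first-fill frame of each vessel with
#' [fill_frame_from_intensity()] and computes [compute_dt()].
#'
#' @param lad,lcx Opacification [trace()]s for LAD and LCX at the same frame
#'   rate (`fs` = frames/s).
#' @inheritParams fill_frame_from_intensity
#' @return As [compute_dt()].
#' @export
dt_from_intensity <- function(lad, lcx, threshold_frac = 0.5) {
  stopifnot(inherits(lad, "coro_trace"), inherits(lcx, "coro_trace"))
  if (abs(lad$fs - lcx$fs) > 1e-9) {
    abort("LAD and LCX traces must share one frame rate",
          class = "corohemo_param_error")
  }
  fills <- c(LAD = fill_frame_from_intensity(lad, threshold_frac),
             LCX = fill_frame_from_intensity(lcx, threshold_frac))
  compute_dt(angio_annotation(fills, frame_rate = lad$fs))
}
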