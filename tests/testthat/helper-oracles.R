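# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (per-window least squares, numerical
# integration of densities) so they share no code with the implementation.

# brute-force sliding least-squares polynomial fit, evaluated at each point;
# the leading/trailing half-windows use the first/last full window's fit
# evaluated off-centre
sg_oracle <- function(x, window = 11, order = 3) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, min(i - h, n - window + 1L))
    d <- lo:(lo + window - 1L)
    co <- stats::lm.fit(outer(d - i, 0:order, "^"), x[d])$coefficients
    unname(co[1L])
  }, numeric(1))
}

# two-sided p-value from Student's t by numerical integration of the density
t_p_oracle <- function(t_stat, df) {
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-10)$value
}

# cycle set with known boundaries, bypassing detection
planted_cycles <- function(boundaries, fs) {
  structure(list(boundaries = as.integer(boundaries), fs = fs),
            class = "coro_cycles")
}

# periodic pressure-like beat train with minima planted at known samples:
# sharp diastolic trough, rounded systolic hump
beat_train <- function(n_beats, period_samples, fs = 200, baseline = 80,
                       amplitude = 40) {
  ph <- (seq_len(n_beats * period_samples) - 1) %% period_samples /
    period_samples
  baseline + amplitude * (0.5 - 0.5 * cos(2 * pi * ph))^1.5
}
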