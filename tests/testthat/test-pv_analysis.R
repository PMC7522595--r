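# closed rectangular loop: V 60->130 ml along the bottom, P 10->110 mmHg up
# the right side; area must be 70 * 100 = 7000 mmHg*ml
rect_loop <- function(pts_per_edge = 50) {
  v <- c(seq(60, 130, length.out = pts_per_edge),
         rep(130, pts_per_edge),
         seq(130, 60, length.out = pts_per_edge),
         rep(60, pts_per_edge))
  p <- c(rep(10, pts_per_edge),
         seq(10, 110, length.out = pts_per_edge),
         rep(110, pts_per_edge),
         seq(110, 10, length.out = pts_per_edge))
  list(p = p, v = v)
}

test_that("thermodilution CO matches closed-form washout integrals", {
  fs <- 1000
  rect <- trace(c(rep(0.5, 6 * fs), rep(0, 2 * fs)), fs, "degC")
  co <- thermodilution_co(10, 37, 7, rect)  # 10 ml, dT_bi = 30 degC
  expect_equal(co, 6.0, tolerance = 1e-3)   # 10*30/3 ml/s = 6 L/min
  expect_equal(thermodilution_co(20, 37, 7, rect), 2 * co, tolerance = 1e-12)

  # triangular washout, coarse sampling: trapezoid is exact on piecewise
  # linear curves, so 50 Hz must match a 5 kHz oracle
  tri_curve <- function(fs) {
    tt <- (0:(10 * fs)) / fs
    pmax(0, ifelse(tt < 3, 0.8 * tt / 3, 0.8 * (1 - (tt - 3) / 5)))
  }
  co_coarse <- thermodilution_co(10, 37, 7, trace(tri_curve(50), 50, "degC"))
  co_fine <- thermodilution_co(10, 37, 7, trace(tri_curve(5000), 5000, "degC"))
  expect_equal(co_coarse, co_fine, tolerance = 1e-3)

  expect_error(thermodilution_co(10, 7, 37, rect), class = "corohemo_param_error")
  tail_high <- trace(rep(0.5, 100), 10, "degC")
  expect_error(thermodilution_co(10, 37, 7, tail_high),
               class = "corohemo_param_error")
})

test_that("gain and parallel-volume calibration follow their definitions", {
  expect_equal(calibrate_alpha(5.0, 4.0), 1.25)
  expect_equal(calibrate_alpha(3.3, 3.3), 1.0)
  expect_error(calibrate_alpha(0, 4), class = "corohemo_param_error")
  expect_error(calibrate_alpha(4, -1), class = "corohemo_param_error")

  expect_equal(calibrate_parallel(100, 130), 30)
  expect_equal(calibrate_parallel(100, 100), 0)

  raw <- trace(rep(60, 10), 200, "a.u.")
  expect_equal(apply_calibration(raw, calibration_factors(1, 0))$samples,
               rep(60, 10))
  cal <- apply_calibration(raw, calibration_factors(2, 10))
  expect_equal(cal$samples, rep(110, 10))
  expect_identical(cal$unit, "ml")
  expect_error(apply_calibration(trace(rep(60, 10), 200, "mmHg"),
                                 calibration_factors(2, 10)),
               class = "corohemo_param_error")
  expect_error(calibration_factors(-1, 0), class = "corohemo_param_error")
})

test_that("stroke work equals polygon area for rectangle and ellipse loops", {
  rl <- rect_loop()
  p <- trace(rep(rl$p, 10), 200, "mmHg")
  v <- trace(rep(rl$v, 10), 200, "ml")
  cyc <- planted_cycles(seq(1, 2001, by = 200), 200)
  pv <- pv_metrics(p, v, cyc, n = 10)
  expect_equal(pv$sw, 7000, tolerance = 1e-9)
  expect_equal(pv$sv, 70, tolerance = 1e-9)
  expect_equal(pv$edv, 130)
  expect_equal(pv$esv, 60)

  th <- 2 * pi * (0:399) / 400
  a <- 30; b <- 50
  pe <- trace(rep(60 + b * sin(th), 10), 200, "mmHg")
  ve <- trace(rep(95 + a * cos(th), 10), 200, "ml")
  cyc2 <- planted_cycles(seq(1, 4001, by = 400), 200)
  expect_equal(pv_metrics(pe, ve, cyc2, n = 10)$sw, pi * a * b,
               tolerance = 0.005)
})

test_that("loop area is invariant to starting index and orientation", {
  rl <- rect_loop()
  area0 <- corohemo:::.loop_area(rl$p, rl$v)
  for (shift in c(13, 57, 101, 190)) {
    idx <- c((shift + 1):200, 1:shift)
    expect_equal(corohemo:::.loop_area(rl$p[idx], rl$v[idx]), area0)
  }
  expect_equal(corohemo:::.loop_area(rev(rl$p), rev(rl$v)), area0)
})

test_that("reported cardiac output is exactly sv * hr / 1000", {
  rl <- rect_loop()
  p <- trace(rep(rl$p, 12), 200, "mmHg")
  v <- trace(rep(rl$v, 12), 200, "ml")
  cyc <- planted_cycles(seq(1, 2401, by = 200), 200)
  pv <- pv_metrics(p, v, cyc, n = 10)
  expect_identical(pv$co, pv$sv * pv$hr / 1000)
  expect_error(pv_metrics(p, v, cyc, n = 13), "12",
               class = "corohemo_param_error")
})
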