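test_that("downsampling preserves DC, length and in-band sine content", {
  const <- trace(rep(100, 3000), fs = 1000, unit = "mmHg")
  d <- downsample(const, 200)
  expect_equal(d$fs, 200)
  expect_length(d$samples, 600)
  expect_equal(d$samples, rep(100, 600), tolerance = 1e-12)
  expect_identical(d$unit, "mmHg")

  tt <- (0:4999) / 1000
  s <- trace(sin(2 * pi * 10 * tt), fs = 1000)
  ds <- downsample(s, 200)
  analytic <- sin(2 * pi * 10 * (seq_along(ds$samples) - 1) / 200)
  interior <- 20:(length(ds$samples) - 20)
  expect_lt(max(abs(ds$samples[interior] - analytic[interior])), 0.01)
  expect_lt(abs(max(abs(ds$samples[interior])) - 1), 0.01)

  expect_error(downsample(s, 300), "integer multiple",
               class = "corohemo_param_error")
})

test_that("Savitzky-Golay smoothing equals the sliding least-squares oracle", {
  # an order-3 filter passes any cubic unchanged, edges included
  x <- (1:80) / 10
  cubic <- trace(0.3 * x^3 - 2 * x^2 + x - 4, fs = 200)
  expect_equal(sg_smooth(cubic)$samples, cubic$samples, tolerance = 1e-11)

  const <- trace(rep(7, 50), fs = 200)
  expect_equal(sg_smooth(const)$samples, const$samples, tolerance = 1e-12)

  set.seed(21)
  noise <- trace(rnorm(120), fs = 200)
  expect_lt(max(abs(sg_smooth(noise)$samples - sg_oracle(noise$samples))),
            1e-9)

  expect_error(sg_smooth(noise, window = 10), class = "corohemo_param_error")
  expect_error(sg_smooth(noise, window = 11, order = 11),
               class = "corohemo_param_error")
  expect_error(sg_smooth(trace(rnorm(5), 200), window = 11),
               class = "corohemo_param_error")
})

test_that("Savitzky-Golay smoothing is linear", {
  set.seed(22)
  for (rep in 1:5) {
    x <- rnorm(100)
    y <- rnorm(100)
    a <- runif(1, -3, 3)
    b <- runif(1, -3, 3)
    lhs <- sg_smooth(trace(a * x + b * y, 200))$samples
    rhs <- a * sg_smooth(trace(x, 200))$samples +
      b * sg_smooth(trace(y, 200))$samples
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("cycle detection finds planted pressure minima", {
  fs <- 200
  p <- trace(beat_train(12, 200, fs), fs, "mmHg")
  cyc <- detect_cycles(p)
  expect_s3_class(cyc, "coro_cycles")
  expect_true(length(cyc$boundaries) %in% c(11, 12))
  expect_true(all(abs(diff(cyc$boundaries) - 200) <= 1))
  planted <- 1 + 200 * (1:11)
  for (b in cyc$boundaries) {
    expect_lte(min(abs(planted - b)), 1)
  }

  expect_error(detect_cycles(trace(seq(1, 50, length.out = 400), fs)),
               "no cycles", class = "corohemo_no_cycles_error")
})

test_that("refractory distance suppresses sub-period wiggles", {
  fs <- 200
  base <- beat_train(12, 200, fs)
  # add a shallow dicrotic dip mid-beat: low prominence, must be ignored
  dip <- -3 * exp(-((((seq_along(base) - 1) %% 200) - 120) / 6)^2)
  cyc <- detect_cycles(trace(base + dip, fs, "mmHg"))
  expect_true(all(diff(cyc$boundaries) >= 0.3 * fs))
  expect_true(all(abs(diff(cyc$boundaries) - 200) <= 1))
})

test_that("ensemble averaging reduces to the template and counts cycles", {
  template <- 80 + 40 * sin(pi * (0:199) / 200)
  t10 <- trace(rep(template, 10), fs = 200, unit = "mmHg")
  cyc <- planted_cycles(seq(1, 2001, by = 200), 200)
  eb <- ensemble_average(t10, cyc, n = 10)
  expect_s3_class(eb, "coro_beat")
  expect_equal(eb$n_cycles, 10L)
  expect_equal(eb$fs, 200)
  expect_identical(eb$unit, "mmHg")
  expect_equal(eb$mean_waveform, template, tolerance = 1e-12)

  cyc7 <- planted_cycles(seq(1, 1401, by = 200), 200)
  expect_error(ensemble_average(t10, cyc7, n = 10), "7",
               class = "corohemo_param_error")
})

test_that("ensemble averaging shrinks iid noise by about sqrt(n)", {
  template <- 80 + 40 * sin(pi * (0:199) / 200)
  cyc <- planted_cycles(seq(1, 2001, by = 200), 200)
  sigma <- 2
  set.seed(31)
  resid_sd <- replicate(40, {
    noisy <- trace(rep(template, 10) + rnorm(2000, 0, sigma), 200)
    sd(ensemble_average(noisy, cyc, n = 10)$mean_waveform - template)
  })
  expect_lt(abs(mean(resid_sd) - sigma / sqrt(10)) / (sigma / sqrt(10)), 0.2)
})

test_that("beat statistics match closed forms", {
  expect_equal(
    beat_stats(trace(c(80, 120, 100), 200, "mmHg"))[, c("maximum", "minimum", "mean")],
    tibble::tibble(maximum = 120, minimum = 80, mean = 100))
  bs <- beat_stats(trace(rep(50, 10), 200))
  expect_true(all(c(bs$maximum, bs$minimum, bs$mean) == 50))

  # half-sinusoid of amplitude A on baseline B averages to B + 2A/pi
  A <- 30; B <- 40
  half <- trace(B + A * sin(pi * (0:399) / 400), 200, "cm/s")
  expect_equal(beat_stats(half)$mean, B + 2 * A / pi, tolerance = 0.005)
  expect_true(with(beat_stats(half), minimum <= mean && mean <= maximum))
})
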