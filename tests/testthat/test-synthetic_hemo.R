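noiseless <- list(pressure = 0, velocity = 0, conductance = 0)

test_that("identical configurations give bit-identical recordings", {
  cfg <- sim_config(seed = 9, duration_s = 12, hr = 72)
  a <- simulate_hemo(cfg)
  b <- simulate_hemo(cfg)
  for (ch in names(a$recording$channels)) {
    expect_identical(a$recording$channels[[ch]]$samples,
                     b$recording$channels[[ch]]$samples)
  }
  expect_identical(a$ground_truth$pv, b$ground_truth$pv)
})

test_that("the model settles to a periodic steady state after five beats", {
  sim <- simulate_hemo(sim_config(noise_sd = noiseless))
  traj <- sim$ground_truth$trajectory
  spb <- 60 / 72 * 1000
  edv_beat <- vapply(6:15, function(k) {
    max(traj$v_lv[(floor((k - 1) * spb) + 1):floor(k * spb)])
  }, numeric(1))
  expect_lt((max(edv_beat) - min(edv_beat)) / mean(edv_beat), 0.005)
})

test_that("volume is conserved over steady-state beats at no support", {
  sim <- simulate_hemo(sim_config(noise_sd = noiseless))
  traj <- sim$ground_truth$trajectory
  spb <- 60 / 72 * 1000
  idx <- (floor(5 * spb) + 1):floor(15 * spb)
  inflow <- sum(traj$q_in[idx])
  outflow <- sum(traj$q_out[idx] + traj$q_imp[idx])
  expect_lt(abs(inflow - outflow) / inflow, 0.01)
})

test_that("maximal support unloads the ventricle and raises aortic pressure", {
  s0 <- simulate_hemo(sim_config(pump_level = "P0", noise_sd = noiseless))
  s8 <- simulate_hemo(sim_config(pump_level = "P8", noise_sd = noiseless))
  expect_gt(s8$ground_truth$pump_flow_l_min, 2.4)
  expect_lt(s8$ground_truth$pump_flow_l_min, 3.0)
  for (m in c("edp", "edv", "sv", "sw")) {
    expect_lt(s8$ground_truth$pv[[m]], s0$ground_truth$pv[[m]])
  }
  expect_gt(s8$ground_truth$mean_aortic_pressure,
            s0$ground_truth$mean_aortic_pressure)
  # total output (native + pump) rises even though native output falls
  expect_gt(s8$ground_truth$pv$co + s8$ground_truth$pump_flow_l_min,
            s0$ground_truth$pv$co)
})

test_that("flap severity flips the distal true-lumen pressure response", {
  delta_cp <- function(gamma) {
    s0 <- simulate_hemo(sim_config(pump_level = "P0", flap_gamma = gamma,
                                   noise_sd = noiseless))
    s8 <- simulate_hemo(sim_config(pump_level = "P8", flap_gamma = gamma,
                                   noise_sd = noiseless))
    list(d_true = s8$ground_truth$coronary$mean[1] -
           s0$ground_truth$coronary$mean[1],
         d_false = s8$ground_truth$mean_false_lumen_pressure -
           s0$ground_truth$mean_false_lumen_pressure)
  }
  small <- delta_cp(0)
  large <- delta_cp(50)
  expect_gt(small$d_true, 0)   # small flap: distal pressure rises with AoP
  expect_lt(large$d_true, 0)   # large flap: distal pressure falls
  expect_gt(large$d_false, 0)  # while the false lumen is pressurized
})

test_that("configuration validation rejects impossible setups", {
  expect_error(sim_config(duration_s = 5), "12", class = "corohemo_param_error")
  expect_error(sim_config(e_max = 0.1, e_min = 0.2),
               class = "corohemo_param_error")
  expect_error(sim_config(flap_gamma = -1), class = "corohemo_param_error")
  expect_error(sim_config(noise_sd = list(pressure = 1, velocity = 1)),
               class = "corohemo_param_error")
})

test_that("paired cohorts are deterministic and hold physiology fixed", {
  coh <- make_paired_cohort(3, seed = 5)
  expect_equal(nrow(coh), 6L)
  expect_equal(sort(unique(coh$condition)), c("P0", "P8"))
  expect_equal(dplyr::count(coh, subject)$n, rep(2L, 3))

  coh2 <- make_paired_cohort(3, seed = 5)
  expect_identical(
    coh$recording[[1]]$channels$lv_pressure$samples,
    coh2$recording[[1]]$channels$lv_pressure$samples)

  expect_error(make_paired_cohort(1), class = "corohemo_param_error")
  expect_error(make_paired_cohort(3, inter_subject_sd = c(nope = 0.1)),
               class = "corohemo_param_error")
})

test_that("angio generator plants recoverable first-fill frames", {
  ang <- make_angio_traces(c(LAD = 42, LCX = 10))
  expect_equal(fill_frame_from_intensity(ang$traces$LAD), 42L)
  expect_equal(fill_frame_from_intensity(ang$traces$LCX), 10L)
  dt <- compute_dt(ang$annotation)
  expect_equal(round(dt$dt_seconds, 2), 1.07)
  expect_equal(round(compute_dt(make_angio_traces(
    c(LAD = 76, LCX = 0))$annotation)$dt_seconds, 4), round(76 / 30, 4))
  expect_equal(compute_dt(make_angio_traces(
    c(LAD = 12, LCX = 12))$annotation)$dt_seconds, 0)
})

test_that("noiseless pipeline recovers true coronary beat statistics", {
  sim <- simulate_hemo(sim_config(noise_sd = noiseless))
  bs <- beat_summary(sim$recording,
                     channels = c("coronary_pressure_true",
                                  "coronary_flow_velocity"),
                     n = 10, offset = 5)
  gt <- sim$ground_truth$coronary
  for (i in 1:2) {
    row <- dplyr::filter(bs, channel == gt$channel[i])
    for (m in c("maximum", "minimum", "mean")) {
      expect_lt(abs(row[[m]] - gt[[m]][i]) / abs(gt[[m]][i]), 0.02)
    }
  }
})

test_that("conductance calibration inverts the planted gain and offset", {
  cfg <- sim_config(noise_sd = noiseless)
  sim <- simulate_hemo(cfg)
  traj <- sim$ground_truth$trajectory

  # reference CO and EDV measured from the true volume trace through the
  # same (linear) conditioning pipeline the raw channel goes through
  p <- condition_trace(trace(traj$p_lv, cfg$fs, "mmHg"))
  vt <- condition_trace(trace(traj$v_lv, cfg$fs, "ml"))
  cyc <- detect_cycles(p)
  ref <- raw_volume_metrics(vt, cyc, n = 10, offset = 5)
  cal <- calibrate_from_recording(sim$recording, co_ref = ref$co,
                                  edv_ref = ref$edv, n = 10, offset = 5)
  expect_lt(abs(cal$alpha - cfg$alpha_true) / cfg$alpha_true, 1e-6)
  expect_lt(abs(cal$v_parallel - cfg$v_parallel_true) /
              cfg$v_parallel_true, 1e-6)
})

test_that("pipeline stroke work agrees with the simulator's own loop area", {
  cfg <- sim_config(noise_sd = noiseless)
  sim <- simulate_hemo(cfg)
  traj <- sim$ground_truth$trajectory
  p <- condition_trace(trace(traj$p_lv, cfg$fs, "mmHg"))
  vt <- condition_trace(trace(traj$v_lv, cfg$fs, "ml"))
  cyc <- detect_cycles(p)
  pv <- pv_metrics(p, vt, cyc, n = 10, offset = 5)
  expect_lt(abs(pv$sw - sim$ground_truth$pv$sw) / sim$ground_truth$pv$sw, 0.05)
})
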