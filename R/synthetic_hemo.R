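#' Simulator configuration
#'
#' Parameters for the lumped-parameter hemodynamic simulator: a time-varying
#' elastance left ventricle with diode mitral/aortic valves, a two-element
#' systemic Windkessel, a transaortic microaxial pump with a linear
#' pressure-difference-clipped flow curve, and a dissected coronary branch
#' in which the false lumen relaxes toward aortic pressure and a
#' pressure-dependent flap resistance can throttle true-lumen inflow.
#'
#' The default parameter set describes a roughly 50 kg pig after creation of
#' a proximal LAD dissection: at no support it settles near an end-diastolic
#' volume of 126 ml, stroke volume 65 ml, end-systolic pressure 111 mmHg and
#' heart rate 72 beats/min; mitral inflow is deliberately flow-limited so
#' that preload responds to continuous pump drainage (unloading is then an
#' emergent property of the model, not an input); `q_nominal_p8` is calibrated once so that the maximal
#' support level delivers a time-averaged pump flow of about 2.7 L/min at
#' this operating point, and is shipped frozen.
#'
#' @param hr Heart rate, beats/min.
#' @param e_max,e_min End-systolic / end-diastolic elastance, mmHg/ml.
#' @param v0 Unstressed LV volume, ml.
#' @param r_mitral,r_aortic,r_systemic Valve and systemic resistances,
#'   mmHg*s/ml.
#' @param c_aorta Aortic (Windkessel) compliance, ml/mmHg.
#' @param p_atrium,p_venous Left atrial and systemic venous pressures, mmHg.
#' @param pump_level `"P0"` (pump off) or `"P8"` (maximal flow).
#' @param q_nominal_p8 Pump flow at zero head pressure at maximal support,
#'   L/min.
#' @param k_p Pump curve slope, (L/min)/mmHg of aorta-minus-LV head.
#' @param flap_gamma Dimensionless flap severity (>= 0); 0 models the
#'   no-flap / small-flap case, large values a flow-limiting flap.
#' @param r_coronary_base True-lumen inlet resistance with an unloaded flap,
#'   mmHg*s/ml.
#' @param r_micro_sys,r_micro_dia Coronary microvascular resistance at peak
#'   systole / in diastole, mmHg*s/ml (systolic compression makes
#'   `r_micro_sys` the larger).
#' @param vessel_area LAD cross-sectional area, cm^2 (converts flow in ml/s
#'   to velocity in cm/s).
#' @param tau_false Time constant (s) of false-lumen pressure relaxation
#'   toward aortic pressure (flap-communication resistance times false-lumen
#'   compliance).
#' @param sys_frac,relax_frac Fractions of the cycle spent in the rising and
#'   falling limbs of the two-cosine activation.
#' @param alpha_true,v_parallel_true Planted conductance-channel gain and
#'   parallel volume: the raw channel is emitted as
#'   `(V_lv + v_parallel_true) / alpha_true`.
#' @param noise_sd Named list of additive Gaussian noise SDs per channel
#'   class: `pressure` (mmHg), `velocity` (cm/s), `conductance` (raw units).
#' @param seed Integer seed for the channel noise.
#' @param fs Sampling rate, Hz (acquisition protocol: 1000).
#' @param duration_s Record duration, s; must cover at least 12 cycles so
#'   ten consecutive steady beats are available (the default 20 s leaves
#'   room for the 5-beat startup transient plus ten analysis beats even for
#'   slow-heart-rate subjects).
#' @return A validated `coro_sim_config` list.
#' @export
sim_config <- function(hr = 72, e_max = 2.2, e_min = 0.15, v0 = 10,
                       r_mitral = 0.1, r_aortic = 0.015, r_systemic = 1.15,
                       c_aorta = 1.3, p_atrium = 26, p_venous = 5,
                       pump_level = c("P0", "P8"), q_nominal_p8 = 3.34,
                       k_p = 0.01, flap_gamma = 0, r_coronary_base = 4,
                       r_micro_sys = 110, r_micro_dia = 35,
                       vessel_area = 0.035, tau_false = 1.5,
                       sys_frac = 0.3, relax_frac = 0.15,
                       alpha_true = 1.25, v_parallel_true = 30,
                       noise_sd = list(pressure = 1.5, velocity = 2,
                                       conductance = 0.8),
                       seed = 1L, fs = 1000, duration_s = 20) {
  pump_level <- match.arg(pump_level)
  cfg <- list(hr = hr, e_max = e_max, e_min = e_min, v0 = v0,
              r_mitral = r_mitral, r_aortic = r_aortic,
              r_systemic = r_systemic, c_aorta = c_aorta,
              p_atrium = p_atrium, p_venous = p_venous,
              pump_level = pump_level, q_nominal_p8 = q_nominal_p8,
              k_p = k_p, flap_gamma = flap_gamma,
              r_coronary_base = r_coronary_base, r_micro_sys = r_micro_sys,
              r_micro_dia = r_micro_dia, vessel_area = vessel_area,
              tau_false = tau_false, sys_frac = sys_frac,
              relax_frac = relax_frac, alpha_true = alpha_true,
              v_parallel_true = v_parallel_true, noise_sd = noise_sd,
              seed = as.integer(seed), fs = fs, duration_s = duration_s)
  .validate_sim_config(cfg)
  structure(cfg, class = "coro_sim_config")
}

.validate_sim_config <- function(cfg) {
  if (!(cfg$e_max > cfg$e_min && cfg$e_min > 0)) {
    abort("need e_max > e_min > 0", class = "corohemo_param_error")
  }
  pos <- c("hr", "r_mitral", "r_aortic", "r_systemic", "c_aorta",
           "r_coronary_base", "r_micro_sys", "r_micro_dia", "vessel_area",
           "tau_false", "alpha_true", "fs", "duration_s")
  for (nm in pos) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(sprintf("%s must be positive and finite", nm),
            class = "corohemo_param_error")
    }
  }
  if (cfg$flap_gamma < 0) {
    abort("flap_gamma must be >= 0", class = "corohemo_param_error")
  }
  n_beats <- floor(cfg$duration_s * cfg$hr / 60)
  if (n_beats < 12) {
    abort(sprintf(
      "duration_s covers only %d complete cycles; at least 12 are required",
      n_beats), class = "corohemo_param_error")
  }
  for (nm in c("pressure", "velocity", "conductance")) {
    if (is.null(cfg$noise_sd[[nm]]) || cfg$noise_sd[[nm]] < 0) {
      abort(sprintf("noise_sd$%s must be a non-negative number", nm),
            class = "corohemo_param_error")
    }
  }
  invisible(cfg)
}

#' @export
print.coro_sim_config <- function(x, ...) {
  cat(sprintf(
    "<coro_sim_config> hr %g bpm, pump %s, flap_gamma %g, %g s @ %g Hz, seed %d\n",
    x$hr, x$pump_level, x$flap_gamma, x$duration_s, x$fs, x$seed))
  invisible(x)
}

# run an expression with a locally seeded RNG, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# per-beat metrics from the noiseless trajectory over the steady-state beats
.gt_metrics <- function(traj, cfg, beats) {
  fs <- cfg$fs
  spb <- 60 / cfg$hr * fs  # samples per beat (not necessarily integer)
  per <- purrr::map_dfr(beats, function(k) {
    i0 <- floor((k - 1) * spb) + 1
    i1 <- floor(k * spb)
    idx <- i0:i1
    vv <- traj$v_lv[idx]; pp <- traj$p_lv[idx]
    ied <- which.max(vv); ies <- which.min(vv)
    tibble::tibble(
      edp = pp[ied], esp = pp[ies], edv = vv[ied], esv = vv[ies],
      sw = .loop_area(pp, vv),
      cp_max = max(traj$p_true[idx]), cp_min = min(traj$p_true[idx]),
      cp_mean = mean(traj$p_true[idx]),
      vel_max = max(traj$velocity[idx]), vel_min = min(traj$velocity[idx]),
      vel_mean = mean(traj$velocity[idx]),
      fp_mean = mean(traj$p_false[idx]), ao_mean = mean(traj$p_ao[idx]),
      q_imp = mean(traj$q_imp[idx]))
  })
  m <- dplyr::summarise(per, dplyr::across(dplyr::everything(), mean))
  pv <- tibble::tibble(
    edp = m$edp, esp = m$esp, edv = m$edv, esv = m$esv,
    sv = m$edv - m$esv, sw = m$sw, hr = cfg$hr,
    co = (m$edv - m$esv) * cfg$hr / 1000)
  list(
    pv = pv,
    coronary = tibble::tibble(
      channel = c("coronary_pressure_true", "coronary_flow_velocity"),
      unit = c("mmHg", "cm/s"),
      maximum = c(m$cp_max, m$vel_max),
      minimum = c(m$cp_min, m$vel_min),
      mean = c(m$cp_mean, m$vel_mean)),
    mean_false_lumen_pressure = m$fp_mean,
    mean_aortic_pressure = m$ao_mean,
    pump_flow_l_min = m$q_imp * 60 / 1000)
}

#' Simulate one multichannel recording with ground truth
#'
#' Integrates the lumped-parameter model of [sim_config()] with fixed-step
#' fourth-order Runge-Kutta at the acquisition rate and emits (i) a noisy
#' 1 kHz [recording()] with channels `lv_pressure`, `lv_conductance` (raw,
#' emitted as `(V_lv + v_parallel_true) / alpha_true`), `aortic_pressure`,
#' `coronary_pressure_true`, `coronary_pressure_false` and
#' `coronary_flow_velocity`, and (ii) a ground-truth object derived from the
#' noiseless state trajectory: per-condition PV metrics, coronary beat
#' statistics, mean pump flow, and the planted calibration factors. Ground
#' truth is averaged over steady-state beats 6-15 (or up to the last
#' complete beat if the record is shorter), the transient of the first five
#' beats being discarded.
#'
#' @param cfg A [sim_config()].
#' @param animal_id Subject identifier attached to the recording.
#' @return A list with elements `recording` ([recording()]) and
#'   `ground_truth` (a `coro_ground_truth`: fields `pv`, `coronary`,
#'   `pump_flow_l_min`, `mean_aortic_pressure`,
#'   `mean_false_lumen_pressure`, `alpha_true`, `v_parallel_true`,
#'   `beats_used`, `trajectory`).
#' @examples
#' \donttest{
#' sim <- simulate_hemo(sim_config(pump_level = "P8", duration_s = 13))
#' sim$ground_truth$pump_flow_l_min
#' }
#' @export
simulate_hemo <- function(cfg, animal_id = "sim") {
  stopifnot(inherits(cfg, "coro_sim_config"))
  .validate_sim_config(cfg)
  dt <- 1 / cfg$fs
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  qnom <- if (cfg$pump_level == "P8") cfg$q_nominal_p8 * 1000 / 60 else 0
  par <- list(T = 60 / cfg$hr, e_min = cfg$e_min, e_max = cfg$e_max,
              v0 = cfg$v0, sys_frac = cfg$sys_frac,
              relax_frac = cfg$relax_frac, r_mitral = cfg$r_mitral,
              r_aortic = cfg$r_aortic, r_systemic = cfg$r_systemic,
              c_aorta = cfg$c_aorta, p_atrium = cfg$p_atrium,
              p_venous = cfg$p_venous, qnom_ml_s = qnom,
              kp_ml_s_mmhg = cfg$k_p * 1000 / 60,
              flap_gamma = cfg$flap_gamma,
              r_coronary_base = cfg$r_coronary_base,
              r_micro_sys = cfg$r_micro_sys, r_micro_dia = cfg$r_micro_dia,
              tau_false = cfg$tau_false)
  m <- .sim_core(par, n, dt, 130, 85, 85)
  traj <- tibble::as_tibble(as.data.frame(m))
  traj$velocity <- traj$q_cor / cfg$vessel_area
  traj$time <- (seq_len(n) - 1) * dt

  n_beats <- floor(cfg$duration_s * cfg$hr / 60)
  beats <- 6:min(15, n_beats)
  gt <- .gt_metrics(traj, cfg, beats)
  gt$alpha_true <- cfg$alpha_true
  gt$v_parallel_true <- cfg$v_parallel_true
  gt$beats_used <- beats
  gt$trajectory <- traj
  class(gt) <- "coro_ground_truth"

  conduct <- (traj$v_lv + cfg$v_parallel_true) / cfg$alpha_true
  ns <- cfg$noise_sd
  channels <- .with_seed(cfg$seed, list(
    lv_pressure = trace(traj$p_lv + rnorm(n, 0, ns$pressure),
                        cfg$fs, "mmHg", "lv_pressure"),
    lv_conductance = trace(conduct + rnorm(n, 0, ns$conductance),
                           cfg$fs, "a.u.", "lv_conductance"),
    aortic_pressure = trace(traj$p_ao + rnorm(n, 0, ns$pressure),
                            cfg$fs, "mmHg", "aortic_pressure"),
    coronary_pressure_true = trace(traj$p_true + rnorm(n, 0, ns$pressure),
                                   cfg$fs, "mmHg", "coronary_pressure_true"),
    coronary_pressure_false = trace(traj$p_false + rnorm(n, 0, ns$pressure),
                                    cfg$fs, "mmHg", "coronary_pressure_false"),
    coronary_flow_velocity = trace(traj$velocity + rnorm(n, 0, ns$velocity),
                                   cfg$fs, "cm/s", "coronary_flow_velocity")
  ))
  rec <- recording(channels, animal_id = animal_id,
                   condition = cfg$pump_level,
                   meta = list(flap_gamma = cfg$flap_gamma))
  list(recording = rec, ground_truth = gt)
}

#' @export
print.coro_ground_truth <- function(x, ...) {
  cat("<coro_ground_truth> (noiseless trajectory, beats",
      paste(range(x$beats_used), collapse = "-"), ")\n")
  print(x$pv)
  cat(sprintf("mean pump flow %.2f L/min; mean AoP %.1f mmHg\n",
              x$pump_flow_l_min, x$mean_aortic_pressure))
  invisible(x)
}

#' Simulate a paired no-support / maximal-support cohort
#'
#' Draws `n_subjects` parameter sets as seeded lognormal jitter around a
#' base configuration, holds each subject's physiology fixed across both
#' pump levels, and simulates the paired recordings. Heart-rate reduction
#' under support is not emergent in the model, so a per-condition heart-rate
#' ratio reproduces the observed slowing (default 0.91, matching the
#' reported 71.4 to 64.9 beats/min).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param base_cfg Base [sim_config()]; its `pump_level` is overridden.
#' @param inter_subject_sd Named numeric vector of lognormal SDs (on the log
#'   scale) for the jittered parameters; names must be `sim_config` fields.
#' @param seed Integer master seed; the same seed reproduces the cohort
#'   bit-for-bit.
#' @param hr_p8_ratio Heart rate at maximal support as a fraction of the
#'   subject's no-support heart rate.
#' @param animal_prefix Prefix for generated subject ids.
#' @return A tibble with one row per subject x condition: `subject`,
#'   `condition`, and list-columns `recording` and `ground_truth`.
#' @export
make_paired_cohort <- function(n_subjects, base_cfg = sim_config(),
                               inter_subject_sd = c(e_max = 0.12,
                                                    e_min = 0.12,
                                                    r_systemic = 0.08,
                                                    c_aorta = 0.08,
                                                    p_atrium = 0.08,
                                                    hr = 0.06),
                               seed = 1L, hr_p8_ratio = 0.91,
                               animal_prefix = "pig") {
  stopifnot(inherits(base_cfg, "coro_sim_config"))
  if (n_subjects < 2) {
    abort("n_subjects must be >= 2", class = "corohemo_param_error")
  }
  if (is.null(names(inter_subject_sd)) ||
      !all(names(inter_subject_sd) %in% names(base_cfg)) ||
      any(inter_subject_sd < 0) || any(!is.finite(inter_subject_sd))) {
    abort("inter_subject_sd must be named non-negative SDs of sim_config fields",
          class = "corohemo_param_error")
  }
  draws <- .with_seed(seed, {
    mult <- matrix(rlnorm(n_subjects * length(inter_subject_sd), 0,
                          rep(inter_subject_sd, each = n_subjects)),
                   nrow = n_subjects)
    list(mult = mult,
         seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                   2L * n_subjects),
                        nrow = n_subjects))
  })
  colnames(draws$mult) <- names(inter_subject_sd)
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    cfg_s <- base_cfg
    for (nm in names(inter_subject_sd)) {
      cfg_s[[nm]] <- cfg_s[[nm]] * draws$mult[s, nm]
    }
    id <- sprintf("%s%02d", animal_prefix, s)
    purrr::map_dfr(c("P0", "P8"), function(lvl) {
      cfg <- cfg_s
      cfg$pump_level <- lvl
      if (lvl == "P8") cfg$hr <- cfg$hr * hr_p8_ratio
      cfg$seed <- draws$seeds[s, if (lvl == "P0") 1L else 2L]
      .validate_sim_config(cfg)
      sim <- simulate_hemo(cfg, animal_id = id)
      tibble::tibble(subject = id, condition = lvl,
                     recording = list(sim$recording),
                     ground_truth = list(sim$ground_truth))
    })
  })
}

#' Pipeline PV metrics for a simulated cohort, in long format
#'
#' Runs the full measurement pipeline on every recording of a
#' [make_paired_cohort()] tibble: conductance calibration against the
#' subject's reference cardiac output and end-diastolic volume (standing in
#' for thermodilution and 3D echo; taken from the per-recording ground
#' truth), then [pv_from_recording()]. Returns a long tibble ready for
#' [compare_conditions()].
#'
#' @param cohort A [make_paired_cohort()] tibble.
#' @param metrics Which PV metrics to keep (default all eight).
#' @param n Number of consecutive analysis beats (default 10).
#' @param offset Leading detected cycles to skip (default 5, discarding the
#'   simulator's startup transient so the analysed beats are the
#'   steady-state ones the ground truth describes).
#' @return A tibble with columns `subject`, `condition`, `metric`, `value`.
#' @export
cohort_pv_metrics <- function(cohort,
                              metrics = c("edp", "esp", "edv", "esv", "sv",
                                          "sw", "hr", "co"),
                              n = 10, offset = 5) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    rec <- cohort$recording[[i]]
    gt <- cohort$ground_truth[[i]]
    p <- condition_trace(get_channel(rec, "lv_pressure"))
    vr <- condition_trace(get_channel(rec, "lv_conductance"))
    cyc <- detect_cycles(p)
    raw <- raw_volume_metrics(vr, cyc, n = n, offset = offset)
    alpha <- calibrate_alpha(gt$pv$co, raw$co)
    cal <- calibration_factors(
      alpha, calibrate_parallel(gt$pv$edv, alpha * raw$edv))
    pv <- pv_metrics(p, apply_calibration(vr, cal), cyc, n = n, offset = offset)
    tidyr::pivot_longer(
      dplyr::mutate(dplyr::select(pv, dplyr::all_of(metrics)),
                    subject = rec$animal_id, condition = rec$condition),
      dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  })
}

#' Synthetic angiographic opacification traces
#'
#' Generates per-vessel sigmoid opacification curves at the angiographic
#' frame rate with planted first-fill frames, plus the matching annotation
#' ground truth. The sigmoid midpoint sits exactly on the planted frame, so
#' a half-plateau threshold reader recovers it.
#'
#' @param fill_frames Named integer vector of planted first-fill frames
#'   (e.g. `c(LAD = 42, LCX = 10)`).
#' @param frame_rate Frames per second (default 30).
#' @param n_frames Total frames; default covers the latest fill plus 2 s.
#' @param steepness Sigmoid rise scale in frames (default 2).
#' @return A list with `traces` (named list of [trace()]s, `fs` = frame
#'   rate) and `annotation` (the planted [angio_annotation()]).
#' @export
make_angio_traces <- function(fill_frames, frame_rate = 30, n_frames = NULL,
                              steepness = 2) {
  if (any(fill_frames < 0)) {
    abort("fill frames must be >= 0", class = "corohemo_param_error")
  }
  ann <- angio_annotation(fill_frames, frame_rate = frame_rate)
  n_frames <- n_frames %||% (max(ann$fills) + as.integer(2 * frame_rate))
  f <- 0:(n_frames - 1L)
  traces <- lapply(names(ann$fills), function(v) {
    y <- 1 / (1 + exp(-(f - ann$fills[[v]]) / steepness))
    trace(y, fs = frame_rate, unit = "a.u.", label = v)
  })
  list(traces = setNames(traces, names(ann$fills)), annotation = ann)
}
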