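#' Configuration for the synthetic shuttle-run generator
#'
#' Collects every parameter of the synthetic 5 m shuttle-run trial: protocol
#' geometry and pace, the shape of the centre-of-mass (CoM) path through each
#' 180-degree turn, gait oscillations, and the sensor error model (noise,
#' static biases, gyroscope drift, clock offset between the inertial unit and
#' the motion-capture system).
#'
#' The default values reproduce the study conditions the package emulates:
#' a 5 m lane run at an average pace of 2.5 m/s with 72 turns per trial, a
#' CoM vertical dip of about 0.4 m around each turn, and an unknown clock
#' offset drawn uniformly in +/-2 s so the synchronization stage is always
#' exercised. The turn shape parameters (`turn_duration`, `turn_radius`,
#' `step_amplitude`, `impact_amplitude`) are calibrated once so that the
#' cohort means of the generated approach speed and positive external work
#' match the reference cohort (2.60 m/s and 8.49 J/kg); see the package
#' vignette for the calibration rationale.
#'
#' @param lane_length lane length, m (> 0).
#' @param avg_speed average shuttle pace over a full lane traversal, m/s.
#' @param n_turns number of 180-degree turns in the trial (>= 1).
#' @param step_frequency step (not stride) frequency, Hz.
#' @param vertical_dip_depth CoM lowering at the turn apex, m.
#' @param dip_half_width half-width of the raised-cosine CoM dip, s.
#' @param turn_duration duration of the CoM velocity reversal, s.
#' @param turn_radius lateral CoM excursion at mid-turn, m.
#' @param step_amplitude half-amplitude of the vertical CoM step oscillation, m.
#' @param sway_amplitude half-amplitude of the lateral CoM sway at stride
#'   frequency, m.
#' @param impact_amplitude peak of the Gaussian-windowed step-impact transient
#'   added to the sensor-frame vertical accelerometer, m/s^2.
#' @param impact_width standard deviation of the impact transient, s.
#' @param roll_rate_amp,pitch_rate_amp amplitude of the gait-driven pelvic
#'   angular-velocity oscillations about the sensor x (roll) and z (pitch)
#'   axes, deg/s.
#' @param direction_policy `"alternating"` pivots (left, right, left, ...) or
#'   `"random"` with probability `p_left` of a left turn.
#' @param p_left probability of a left turn under the random policy.
#' @param speed_jitter_turn per-leg standard deviation of the running speed, m/s.
#' @param dip_jitter per-turn standard deviation of the dip depth, m.
#' @param acc_noise_sd accelerometer white-noise standard deviation, m/s^2.
#' @param gyro_noise_sd gyroscope white-noise standard deviation, deg/s.
#' @param baro_noise_sd barometer noise, expressed in metres of equivalent
#'   altitude.
#' @param acc_bias,gyro_bias per-axis static biases (length-3, m/s^2 and deg/s).
#' @param gyro_drift_rate linear gyroscope drift, deg/s per minute, applied to
#'   every axis.
#' @param clock_offset IMU clock minus mocap clock, s; `NULL` draws it
#'   uniformly in +/-2 s.
#' @param site_altitude altitude of the laboratory above mean sea level, m.
#' @param subject_mass,subject_height subject anthropometrics (kg, m). Mass is
#'   recorded in the trial metadata but never enters the signals: all
#'   energetics are mass-specific.
#' @param lateral_sign +1 or -1; -1 mirrors every lateral (left/right)
#'   component of the gait model, used to build mirror-image trials.
#' @param fs_mocap,fs_imu,fs_baro sampling rates of the three streams, Hz.
#' @param seed integer seed; the same seed yields a bit-identical trial.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_trial()], [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_turns = 6, seed = 7)
#' cfg$avg_speed
sim_config <- function(lane_length = 5,
                       avg_speed = 2.5,
                       n_turns = 72,
                       step_frequency = 2.9,
                       vertical_dip_depth = 0.375,
                       dip_half_width = 0.8,
                       turn_duration = 0.9,
                       turn_radius = 0.20,
                       step_amplitude = 0.008,
                       sway_amplitude = 0.02,
                       impact_amplitude = 50,
                       impact_width = 0.005,
                       roll_rate_amp = 40,
                       pitch_rate_amp = 30,
                       direction_policy = c("alternating", "random"),
                       p_left = 0.5,
                       speed_jitter_turn = 0.15,
                       dip_jitter = 0.05,
                       acc_noise_sd = 0.05,
                       gyro_noise_sd = 0.5,
                       baro_noise_sd = 0.05,
                       acc_bias = c(0.15, -0.10, 0.08),
                       gyro_bias = c(0.30, -0.20, 0.25),
                       gyro_drift_rate = 0.5,
                       clock_offset = NULL,
                       site_altitude = 120,
                       subject_mass = 59,
                       subject_height = 1.66,
                       lateral_sign = 1,
                       fs_mocap = 100,
                       fs_imu = 512,
                       fs_baro = 64,
                       seed = 1L) {
  direction_policy <- match.arg(direction_policy)
  cfg <- list(
    lane_length = lane_length, avg_speed = avg_speed, n_turns = as.integer(n_turns),
    step_frequency = step_frequency, vertical_dip_depth = vertical_dip_depth,
    dip_half_width = dip_half_width, turn_duration = turn_duration,
    turn_radius = turn_radius, step_amplitude = step_amplitude,
    sway_amplitude = sway_amplitude, impact_amplitude = impact_amplitude,
    impact_width = impact_width, roll_rate_amp = roll_rate_amp,
    pitch_rate_amp = pitch_rate_amp, direction_policy = direction_policy,
    p_left = p_left, speed_jitter_turn = speed_jitter_turn,
    dip_jitter = dip_jitter, acc_noise_sd = acc_noise_sd,
    gyro_noise_sd = gyro_noise_sd, baro_noise_sd = baro_noise_sd,
    acc_bias = acc_bias, gyro_bias = gyro_bias,
    gyro_drift_rate = gyro_drift_rate, clock_offset = clock_offset,
    site_altitude = site_altitude, subject_mass = subject_mass,
    subject_height = subject_height, lateral_sign = lateral_sign,
    fs_mocap = fs_mocap, fs_imu = fs_imu, fs_baro = fs_baro,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$lane_length <= 0) abort("lane_length must be > 0")
  if (cfg$avg_speed <= 0) abort("avg_speed must be > 0")
  if (cfg$n_turns < 1) abort("n_turns must be >= 1")
  if (cfg$turn_duration <= 0) abort("turn_duration must be > 0")
  sds <- c(cfg$acc_noise_sd, cfg$gyro_noise_sd, cfg$baro_noise_sd,
           cfg$speed_jitter_turn, cfg$dip_jitter)
  if (any(sds < 0)) abort("noise/jitter standard deviations must be >= 0")
  if (length(cfg$acc_bias) != 3 || length(cfg$gyro_bias) != 3) {
    abort("acc_bias and gyro_bias must be length-3 (per-axis)")
  }
  if (!cfg$lateral_sign %in% c(-1, 1)) abort("lateral_sign must be +1 or -1")
  if (!is.null(cfg$clock_offset) && abs(cfg$clock_offset) > 10) {
    abort("clock_offset beyond +/-10 s is not supported")
  }
  # the turn must fit inside a lane traversal
  leg_speed_nominal(cfg)
  invisible(cfg)
}

# nominal leg (cruise) speed implied by the average pace: during each turn the
# raised-cosine reversal covers less ground than cruising would, so the legs
# must be run faster than the average pace to hold it.
leg_speed_nominal <- function(cfg) {
  denom <- cfg$lane_length / cfg$avg_speed - cfg$turn_duration * (1 - 2 / pi)
  if (denom <= 0) {
    abort("turn_duration too long: turns would overlap the lane traversal")
  }
  v <- cfg$lane_length / denom
  # cruise distance must stay positive at the nominal speed
  if (cfg$lane_length - 2 * v * cfg$turn_duration / pi <= 0) {
    abort("turn_duration too long: no cruise phase left between turns")
  }
  v
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  lane %g m @ %g m/s, %d turns (%s policy)\n",
              x$lane_length, x$avg_speed, x$n_turns, x$direction_policy))
  cat(sprintf("  dip %g m, turn %g s, step %g Hz\n",
              x$vertical_dip_depth, x$turn_duration, x$step_frequency))
  cat(sprintf("  noise: acc %g m/s^2, gyro %g deg/s, baro %g m; offset %s; seed %d\n",
              x$acc_noise_sd, x$gyro_noise_sd, x$baro_noise_sd,
              if (is.null(x$clock_offset)) "U(-2,2)" else sprintf("%g s", x$clock_offset),
              x$seed))
  invisible(x)
}
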