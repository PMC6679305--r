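# Synthetic shuttle-run generator.
#
# The CoM path is piecewise analytic: constant-speed cruise legs joined by
# raised-cosine velocity reversals, a raised-cosine vertical dip around every
# turn apex, sinusoidal step/sway oscillations and a lateral arc through the
# turn. Position, velocity and acceleration are all available in closed form,
# which is what makes exact ground-truth energetics possible.

# ---- random draws ----------------------------------------------------------

draw_trial_params <- function(cfg) {
  n <- cfg$n_turns
  v_nom <- leg_speed_nominal(cfg)
  leg_speeds <- pmax(0.5, v_nom + rnorm(n + 1, 0, cfg$speed_jitter_turn))
  sides <- switch(cfg$direction_policy,
    alternating = rep_len(c(1L, -1L), n) * cfg$lateral_sign,
    random = sample(c(1L, -1L), n, replace = TRUE,
                    prob = c(cfg$p_left, 1 - cfg$p_left))
  )
  dips <- pmax(0.05, cfg$vertical_dip_depth + rnorm(n, 0, cfg$dip_jitter))
  offset <- cfg$clock_offset %||% runif(1, -2, 2)
  list(leg_speeds = leg_speeds, sides = sides, dips = dips, clock_offset = offset)
}

# ---- path construction -----------------------------------------------------

# Builds the piecewise description of the trial: a cruise/turn segment table
# and a per-turn table (event time, side, dip, incoming/outgoing speeds).
build_path <- function(cfg, draws) {
  n <- cfg$n_turns
  Tt <- cfg$turn_duration
  L <- cfg$lane_length
  v <- draws$leg_speeds

  seg_type <- character(0); seg_t0 <- seg_t1 <- seg_x0 <- seg_vx <- numeric(0)
  seg_turn <- integer(0)
  turn <- vector("list", n)

  t_cur <- 0; x_cur <- 0; dir_cur <- 1; carry <- 0; psi <- 0
  for (k in seq_len(n)) {
    v_in <- v[k]; v_out <- v[k + 1]
    m <- (v_in - v_out) / 2; A <- (v_in + v_out) / 2
    tau_star <- Tt / pi * acos(pmin(1, pmax(-1, -m / A)))
    d_in <- m * tau_star + A * Tt / pi * sin(pi * tau_star / Tt)
    d_out <- abs(m * (Tt - tau_star) - A * Tt / pi * sin(pi * tau_star / Tt))
    cruise <- L - carry - d_in
    if (cruise <= 0) abort("turn_duration too long: turns overlap within a lane")
    # cruise segment
    seg_type <- c(seg_type, "cruise"); seg_t0 <- c(seg_t0, t_cur)
    seg_t1 <- c(seg_t1, t_cur + cruise / v_in)
    seg_x0 <- c(seg_x0, x_cur); seg_vx <- c(seg_vx, dir_cur * v_in)
    seg_turn <- c(seg_turn, NA_integer_)
    t_cur <- t_cur + cruise / v_in; x_cur <- x_cur + dir_cur * cruise
    # turn segment
    seg_type <- c(seg_type, "turn"); seg_t0 <- c(seg_t0, t_cur)
    seg_t1 <- c(seg_t1, t_cur + Tt)
    seg_x0 <- c(seg_x0, x_cur); seg_vx <- c(seg_vx, NA_real_)
    seg_turn <- c(seg_turn, k)
    turn[[k]] <- list(
      k = k, t0 = t_cur, t_star = t_cur + tau_star, Tt = Tt,
      dir = dir_cur, v_in = v_in, v_out = v_out, m = m, A = A,
      side = draws$sides[k], dip = draws$dips[k], psi0 = psi
    )
    psi <- psi + draws$sides[k] * 180
    t_cur <- t_cur + Tt
    x_cur <- x_cur + dir_cur * (d_in - d_out)
    dir_cur <- -dir_cur
    carry <- d_out
  }
  # final cruise back across the lane (full margin after the last turn)
  seg_type <- c(seg_type, "cruise"); seg_t0 <- c(seg_t0, t_cur)
  seg_t1 <- c(seg_t1, t_cur + (L - carry) / v[n + 1])
  seg_x0 <- c(seg_x0, x_cur); seg_vx <- c(seg_vx, dir_cur * v[n + 1])
  seg_turn <- c(seg_turn, NA_integer_)

  list(
    segments = tibble(type = seg_type, t0 = seg_t0, t1 = seg_t1,
                      x0 = seg_x0, vx = seg_vx, turn = seg_turn),
    turns = dplyr::bind_rows(lapply(turn, tibble::as_tibble_row)),
    duration = seg_t1[length(seg_t1)],
    cfg = cfg
  )
}

# ---- analytic evaluation ---------------------------------------------------

# x-axis (running direction) position/velocity/acceleration at times t
eval_path_x <- function(path, t) {
  seg <- path$segments
  idx <- findInterval(t, seg$t0, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  x <- vx <- ax <- numeric(length(t))
  cruise <- seg$type[idx] == "cruise"
  if (any(cruise)) {
    i <- idx[cruise]
    dt <- t[cruise] - seg$t0[i]
    x[cruise] <- seg$x0[i] + seg$vx[i] * dt
    vx[cruise] <- seg$vx[i]
  }
  if (any(!cruise)) {
    i <- idx[!cruise]
    tr <- path$turns[seg$turn[i], ]
    tau <- t[!cruise] - tr$t0
    w <- pi * tau / tr$Tt
    x[!cruise] <- seg$x0[i] + tr$dir * (tr$m * tau + tr$A * tr$Tt / pi * sin(w))
    vx[!cruise] <- tr$dir * (tr$m + tr$A * cos(w))
    ax[!cruise] <- -tr$dir * tr$A * pi / tr$Tt * sin(w)
  }
  list(x = x, vx = vx, ax = ax)
}

# lateral position: stride-frequency sway plus the arc through each turn
eval_path_y <- function(path, t) {
  cfg <- path$cfg
  wsw <- pi * cfg$step_frequency  # sway at stride frequency = step_frequency/2
  s <- cfg$lateral_sign * cfg$sway_amplitude
  y <- s * sin(wsw * t); vy <- s * wsw * cos(wsw * t)
  ay <- -s * wsw^2 * sin(wsw * t)
  for (k in seq_len(nrow(path$turns))) {
    tr <- path$turns[k, ]
    sel <- t >= tr$t0 & t <= tr$t0 + tr$Tt
    if (!any(sel)) next
    u <- (t[sel] - tr$t0) / tr$Tt
    r <- tr$side * cfg$turn_radius
    y[sel] <- y[sel] + r * (1 - cos(2 * pi * u)) / 2
    vy[sel] <- vy[sel] + r * pi / tr$Tt * sin(2 * pi * u)
    ay[sel] <- ay[sel] + r * 2 * pi^2 / tr$Tt^2 * cos(2 * pi * u)
  }
  list(y = y, vy = vy, ay = ay)
}

# vertical position: standing CoM height + step oscillation - turn dips
eval_path_z <- function(path, t) {
  cfg <- path$cfg
  z0 <- 0.55 * cfg$subject_height
  ws <- 2 * pi * cfg$step_frequency
  z <- z0 + cfg$step_amplitude * sin(ws * t)
  vz <- cfg$step_amplitude * ws * cos(ws * t)
  az <- -cfg$step_amplitude * ws^2 * sin(ws * t)
  Tz <- cfg$dip_half_width
  for (k in seq_len(nrow(path$turns))) {
    tr <- path$turns[k, ]
    sel <- abs(t - tr$t_star) <= Tz
    if (!any(sel)) next
    w <- pi * (t[sel] - tr$t_star) / Tz
    z[sel] <- z[sel] - tr$dip * (1 + cos(w)) / 2
    vz[sel] <- vz[sel] + tr$dip * pi / (2 * Tz) * sin(w)
    az[sel] <- az[sel] + tr$dip * pi^2 / (2 * Tz^2) * cos(w)
  }
  list(z = z, vz = vz, az = az)
}

# pelvis heading (deg, 0 = +x) and yaw rate (deg/s); Hann-shaped rate pulse
eval_path_yaw <- function(path, t) {
  psi <- numeric(length(t)); rate <- numeric(length(t))
  for (k in seq_len(nrow(path$turns))) {
    tr <- path$turns[k, ]
    after <- t > tr$t0 + tr$Tt
    psi[after] <- psi[after] + tr$side * 180
    sel <- t >= tr$t0 & t <= tr$t0 + tr$Tt
    if (!any(sel)) next
    u <- (t[sel] - tr$t0) / tr$Tt
    psi[sel] <- psi[sel] + tr$side * 180 * (u - sin(2 * pi * u) / (2 * pi))
    rate[sel] <- tr$side * 180 / tr$Tt * (1 - cos(2 * pi * u))
  }
  list(psi = psi, rate = rate)
}

eval_com <- function(path, t) {
  px <- eval_path_x(path, t); py <- eval_path_y(path, t); pz <- eval_path_z(path, t)
  tibble(t = t, x = px$x, y = py$y, z = pz$z,
         vx = px$vx, vy = py$vy, vz = pz$vz,
         ax = px$ax, ay = py$ay, az = pz$az)
}

# ---- ground truth ----------------------------------------------------------

# Closed-form responses per turn, computed from the analytic profile on a
# fine grid (1 kHz): no filtering, sampling or sensor model involved.
path_ground_truth <- function(path, cfg, clock_offset) {
  fs <- 1000
  rows <- lapply(seq_len(nrow(path$turns)), function(k) {
    tr <- path$turns[k, ]
    tt <- seq(tr$t_star - 1, tr$t_star + 1, by = 1 / fs)
    com <- eval_com(path, tt)
    speed <- sqrt(com$vx^2 + com$vy^2 + com$vz^2)
    e <- 0.5 * speed^2 + GRAVITY * com$z
    de <- diff(e)
    half <- tt <= tr$t_star
    tibble(
      turn = tr$k, t_star = tr$t_star,
      side = if (tr$side > 0) "left" else "right",
      v_before = mean(speed[half]), v_after = mean(speed[!half]),
      w_plus = sum(pmax(de, 0)), w_minus = -sum(pmin(de, 0))
    )
  })
  truth <- dplyr::bind_rows(rows)
  attr(truth, "clock_offset") <- clock_offset
  truth
}

# ---- sensor sampling -------------------------------------------------------

# Gaussian-windowed step-impact transients in the sensor frame. Footfalls
# alternate left/right, which alternates the sign of the lateral component.
step_impacts <- function(cfg, t) {
  n <- length(t)
  imp_y <- numeric(n); imp_z <- numeric(n); imp_x <- numeric(n)
  if (cfg$impact_amplitude <= 0) return(list(x = imp_x, y = imp_y, z = imp_z))
  sdt <- cfg$impact_width
  t_steps <- seq(0, max(t), by = 1 / cfg$step_frequency)
  for (i in seq_along(t_steps)) {
    sel <- abs(t - t_steps[i]) <= 4 * sdt
    if (!any(sel)) next
    g <- cfg$impact_amplitude * exp(-(t[sel] - t_steps[i])^2 / (2 * sdt^2))
    imp_y[sel] <- imp_y[sel] + g
    imp_z[sel] <- imp_z[sel] + 0.35 * cfg$lateral_sign * (-1)^i * g
    imp_x[sel] <- imp_x[sel] + 0.25 * g
  }
  list(x = imp_x, y = imp_y, z = imp_z)
}

sample_streams <- function(path, cfg, draws) {
  dur <- path$duration
  offset <- draws$clock_offset

  # --- motion capture: CoM trajectory in the laboratory frame @ fs_mocap
  t_m <- seq(0, dur, by = 1 / cfg$fs_mocap)
  com <- eval_com(path, t_m)
  mocap <- com[, c("t", "x", "y", "z")]

  # --- inertial unit @ fs_imu, timestamps on the IMU clock
  t_i <- seq(0, dur, by = 1 / cfg$fs_imu)
  ci <- eval_com(path, t_i)
  yaw <- eval_path_yaw(path, t_i)
  psi <- yaw$psi * pi / 180
  # specific force in the laboratory frame (z up): f = a - g_vec
  fx <- ci$ax; fy <- ci$ay; fz <- ci$az + GRAVITY
  # sensor frame: x backward, y up, z to the subject's left
  a_sx <- -(fx * cos(psi) + fy * sin(psi))
  a_sy <- fz
  a_sz <- -fx * sin(psi) + fy * cos(psi)
  imp <- step_impacts(cfg, t_i)
  a_sx <- a_sx + imp$x; a_sy <- a_sy + imp$y; a_sz <- a_sz + imp$z

  ws <- 2 * pi * cfg$step_frequency
  g_x <- cfg$lateral_sign * cfg$roll_rate_amp * sin(ws / 2 * t_i)
  g_y <- yaw$rate
  g_z <- cfg$pitch_rate_amp * sin(ws * t_i + pi / 6)

  drift <- cfg$gyro_drift_rate * t_i / 60
  n_i <- length(t_i)
  imu <- tibble(
    t = t_i + offset,
    ax = a_sx + cfg$acc_bias[1] + rnorm(n_i, 0, cfg$acc_noise_sd),
    ay = a_sy + cfg$acc_bias[2] + rnorm(n_i, 0, cfg$acc_noise_sd),
    az = a_sz + cfg$acc_bias[3] + rnorm(n_i, 0, cfg$acc_noise_sd),
    gx = g_x + cfg$gyro_bias[1] + drift + rnorm(n_i, 0, cfg$gyro_noise_sd),
    gy = g_y + cfg$gyro_bias[2] + drift + rnorm(n_i, 0, cfg$gyro_noise_sd),
    gz = g_z + cfg$gyro_bias[3] + drift + rnorm(n_i, 0, cfg$gyro_noise_sd)
  )
  acc_lim <- 16 * GRAVITY
  imu <- dplyr::mutate(
    imu,
    across(c("ax", "ay", "az"), ~ pmin(pmax(.x, -acc_lim), acc_lim)),
    across(c("gx", "gy", "gz"), ~ pmin(pmax(.x, -2000), 2000))
  )

  # --- barometer @ fs_baro, IMU clock
  t_b <- seq(0, dur, by = 1 / cfg$fs_baro)
  zb <- eval_path_z(path, t_b)$z
  h <- cfg$site_altitude + zb + rnorm(length(t_b), 0, cfg$baro_noise_sd)
  baro <- tibble(t = t_b + offset, p = pressure_from_altitude(h))

  structure(
    list(
      mocap = mocap, imu = imu, baro = baro,
      meta = list(
        subject_mass = cfg$subject_mass, subject_height = cfg$subject_height,
        site_altitude = cfg$site_altitude,
        fs_mocap = cfg$fs_mocap, fs_imu = cfg$fs_imu, fs_baro = cfg$fs_baro,
        n_turns = cfg$n_turns, seed = cfg$seed,
        config_hash = rlang::hash(unclass(cfg))
      )
    ),
    class = "cod_trial"
  )
}

# ---- public API ------------------------------------------------------------

#' Simulate one synthetic shuttle-run trial
#'
#' Generates a multi-rate recording of a 5 m shuttle run with alternating
#' 180-degree turns: CoM trajectory at the mocap rate, sensor-frame
#' accelerometer/gyroscope at the IMU rate (with static bias, drift and white
#' noise) and barometric pressure encoding CoM height, with the IMU/barometer
#' timestamps shifted by an unknown clock offset. Ground-truth per-turn
#' responses (event time, side, approach/exit speed, positive/negative
#' external work) are computed in closed form from the generating profile.
#'
#' @param config a [sim_config()].
#' @return a list with elements `trial` (class `cod_trial`: tibbles `mocap`,
#'   `imu`, `baro` plus `meta`) and `truth` (one row per turn; the true clock
#'   offset is stored in `attr(truth, "clock_offset")`).
#' @export
#' @examples
#' sim <- simulate_trial(sim_config(n_turns = 4, seed = 3))
#' sim$truth
simulate_trial <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  withr::with_seed(config$seed, {
    draws <- draw_trial_params(config)
    path <- build_path(config, draws)
    truth <- path_ground_truth(path, config, draws$clock_offset)
    trial <- sample_streams(path, config, draws)
  })
  list(trial = trial, truth = truth)
}

#' Simulate a cohort of shuttle-run trials
#'
#' Per-subject configurations are jittered around the cohort means (running
#' pace sd 0.2 m/s, body mass sd 7.3 kg, height sd 0.05 m, dip depth sd
#' 0.03 m) and each subject receives an independently drawn clock offset and
#' a deterministic sub-seed derived from the master seed.
#'
#' @param config cohort-level [sim_config()]; `config$seed` is the master seed.
#' @param n_subjects number of subjects (>= 1).
#' @return a tibble with one row per subject: `subject`, `config`, `trial`,
#'   `truth` (list-columns).
#' @export
simulate_cohort <- function(config, n_subjects = 13) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  subj_cfgs <- withr::with_seed(config$seed, {
    lapply(seq_len(n_subjects), function(i) {
      cfg_i <- unclass(config)
      cfg_i$seed <- sample.int(.Machine$integer.max - 1L, 1)
      cfg_i$avg_speed <- max(1, config$avg_speed + rnorm(1, 0, 0.2))
      cfg_i$subject_mass <- max(40, config$subject_mass + rnorm(1, 0, 7.3))
      cfg_i$subject_height <- max(1.4, config$subject_height + rnorm(1, 0, 0.05))
      cfg_i$vertical_dip_depth <- max(0.1, config$vertical_dip_depth + rnorm(1, 0, 0.03))
      structure(cfg_i, class = "sim_config")
    })
  })
  sims <- lapply(subj_cfgs, simulate_trial)
  tibble(
    subject = seq_len(n_subjects),
    config = subj_cfgs,
    trial = lapply(sims, `[[`, "trial"),
    truth = lapply(sims, `[[`, "truth")
  )
}

#' Simulate a stationary (still) IMU recording
#'
#' Emulates the bench test used to estimate static sensor biases: the unit
#' lies still with its y axis up, so the accelerometer reads gravity plus
#' bias and noise, and the gyroscope reads bias, drift and noise.
#'
#' @param config a [sim_config()]; only the sensor error model is used.
#' @param duration recording length, s.
#' @return a tibble with columns `t, ax, ay, az, gx, gy, gz`.
#' @export
simulate_still <- function(config, duration = 60) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  withr::with_seed(config$seed + 1L, {
    t <- seq(0, duration, by = 1 / config$fs_imu)
    n <- length(t)
    drift <- config$gyro_drift_rate * t / 60
    tibble(
      t = t,
      ax = config$acc_bias[1] + rnorm(n, 0, config$acc_noise_sd),
      ay = GRAVITY + config$acc_bias[2] + rnorm(n, 0, config$acc_noise_sd),
      az = config$acc_bias[3] + rnorm(n, 0, config$acc_noise_sd),
      gx = config$gyro_bias[1] + drift + rnorm(n, 0, config$gyro_noise_sd),
      gy = config$gyro_bias[2] + drift + rnorm(n, 0, config$gyro_noise_sd),
      gz = config$gyro_bias[3] + drift + rnorm(n, 0, config$gyro_noise_sd)
    )
  })
}

#' Mirror a trial left/right
#'
#' Reflects a recording about the sagittal plane: the laboratory lateral
#' coordinate, the sensor-frame lateral accelerometer axis (z, pointing left)
#' and the yaw (y) and roll (x) gyroscope channels change sign; everything
#' else is untouched. Useful for checking left/right equivariance of the
#' pipeline and for data augmentation.
#'
#' @param trial a `cod_trial`.
#' @return the mirrored `cod_trial`.
#' @export
mirror_trial <- function(trial) {
  stopifnot(inherits(trial, "cod_trial"))
  trial$mocap$y <- -trial$mocap$y
  trial$imu$az <- -trial$imu$az
  trial$imu$gx <- -trial$imu$gx
  trial$imu$gy <- -trial$imu$gy
  trial
}

#' @export
print.cod_trial <- function(x, ...) {
  cat("<cod_trial>\n")
  cat(sprintf("  mocap: %d samples @ %g Hz\n", nrow(x$mocap), x$meta$fs_mocap))
  cat(sprintf("  imu:   %d samples @ %g Hz\n", nrow(x$imu), x$meta$fs_imu))
  cat(sprintf("  baro:  %d samples @ %g Hz\n", nrow(x$baro), x$meta$fs_baro))
  cat(sprintf("  subject: %.1f kg, %.2f m; %d turns\n",
              x$meta$subject_mass, x$meta$subject_height, x$meta$n_turns))
  invisible(x)
}
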