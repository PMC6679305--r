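# The 18 per-turn inertial predictors. Canonical numbering:
#   F1       player load (A.U.)
#   F2-F4    trapezoidal integrals of positive acceleration, x/y/z (m/s)
#   F5-F7    trapezoidal integrals of negative acceleration, x/y/z (m/s, <= 0)
#   F8-F10   RMS, skewness, kurtosis of the acceleration norm
#   F11-F13  gyroscope integrals, x/y/z (rad)
#   F14-F16  RMS, skewness, kurtosis of the gyroscope norm (rad/s based)
#   F17-F18  barometric altitude change over the second before/after the turn (m)

#' Player load of an acceleration window
#'
#' Sum of the Euclidean norms of consecutive three-axis acceleration
#' differences, the standard accelerometer-based activity-intensity metric.
#' A window of n samples contributes n - 1 terms.
#'
#' @param acc tibble/data frame with columns `ax, ay, az` (m/s^2).
#' @param expected_n if given, the window must contain exactly this many
#'   samples (the pipeline uses 1024, i.e. 2 s at 512 Hz).
#' @return scalar, arbitrary units.
#' @export
#' @examples
#' player_load(data.frame(ax = c(0, 1), ay = 0, az = 0))  # 1
player_load <- function(acc, expected_n = NULL) {
  check_cols(acc, c("ax", "ay", "az"), "acceleration window")
  if (!is.null(expected_n) && nrow(acc) != expected_n) {
    abort(sprintf("window has %d samples, expected %d", nrow(acc), expected_n))
  }
  sum(sqrt(diff(acc$ax)^2 + diff(acc$ay)^2 + diff(acc$az)^2))
}

#' Trapezoidal integrals of the positive and negative part of a signal
#'
#' The signal is clipped at zero from below (positive part) and above
#' (negative part) before trapezoidal integration, so
#' `positive + negative` equals the plain trapezoidal integral wherever the
#' signal does not change sign within a sampling step.
#'
#' @param x numeric window.
#' @param dt sampling step, s.
#' @return named numeric `c(positive =, negative =)`; `negative <= 0`.
#' @export
signed_integrals <- function(x, dt) {
  if (dt <= 0) abort("dt must be > 0")
  c(positive = pracma::trapz(pmax(x, 0)) * dt,
    negative = pracma::trapz(pmin(x, 0)) * dt)
}

#' RMS and population skewness/kurtosis of a window
#'
#' Third and fourth standardized population moments (denominator n, no
#' small-sample or excess-kurtosis correction): `skewness = E(x - xbar)^3 /
#' sigma^3`, `kurtosis = E(x - xbar)^4 / sigma^4`, so a Gaussian has
#' kurtosis 3 and every distribution has kurtosis >= 1.
#'
#' @param x numeric window with positive standard deviation.
#' @return named numeric `c(rms =, skewness =, kurtosis =)`.
#' @export
moment_stats <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) abort("moments undefined: window is constant (sigma = 0)")
  c(rms = sqrt(mean(x^2)),
    skewness = mean((x - m)^3) / s2^1.5,
    kurtosis = mean((x - m)^4) / s2^2)
}

#' Barometric altitude series from raw pressure
#'
#' Low-pass filters the pressure (default: zero-lag 10th-order Butterworth,
#' 1 Hz cut-off) and converts it to mean-sea-level altitude with the
#' international barometric formula.
#'
#' @param baro tibble `t, p` (s, Pa).
#' @param fc,order pressure filter settings.
#' @return tibble `t, h` (altitude, m).
#' @export
baro_altitude <- function(baro, fc = 1, order = 10) {
  check_cols(baro, c("t", "p"), "baro")
  fs <- sampling_rate(baro$t)
  p_f <- lowpass_zero_lag(baro$p, fs, fc, order)
  tibble(t = baro$t, h = altitude_from_pressure(p_f))
}

#' Altitude change before and after a turn
#'
#' `delta_before = h(t*) - h(t* - 1 s)` and
#' `delta_after = h(t* + 1 s) - h(t*)`: a CoM dip at the turn makes the
#' first negative and the second positive.
#'
#' @param altitude tibble from [baro_altitude()].
#' @param t_star event time on the altitude stream's clock, s.
#' @param half margin, s.
#' @return named numeric `c(delta_before =, delta_after =)`, m; `NA`s when a
#'   margin falls outside the recording.
#' @export
baro_deltas <- function(altitude, t_star, half = 1) {
  tt <- c(t_star - half, t_star, t_star + half)
  if (tt[1] < min(altitude$t) || tt[3] > max(altitude$t)) {
    return(c(delta_before = NA_real_, delta_after = NA_real_))
  }
  h <- approx(altitude$t, altitude$h, xout = tt)$y
  c(delta_before = h[2] - h[1], delta_after = h[3] - h[2])
}

#' Extract the 18 inertial features for one turn
#'
#' Assembles the full predictor vector over the 2 s window centred on the
#' event: player load, signed acceleration integrals, acceleration-norm
#' moments, gyroscope integrals (converted deg -> rad before integration),
#' gyroscope-norm moments, and the barometric altitude deltas. The stream
#' must already be bias-corrected and pre-filtered (see
#' [prepare_imu_stream()]).
#'
#' @param imu bias-corrected, pre-filtered IMU tibble (IMU clock).
#' @param altitude tibble from [baro_altitude()] (IMU clock).
#' @param t_star event time on the IMU clock, s.
#' @param window window length, s.
#' @return one-row tibble `F1 ... F18`, or `NULL` when the window is
#'   truncated by the recording bounds.
#' @export
extract_features <- function(imu, altitude, t_star, window = 2) {
  fs <- sampling_rate(imu$t)
  n_w <- round(window * fs)
  start <- which(imu$t >= t_star - window / 2)[1]
  if (is.na(start) || start + n_w - 1 > nrow(imu)) return(NULL)
  w <- imu[start:(start + n_w - 1), ]
  dt <- 1 / fs

  # player load follows the accelerometry convention of g-scaled differences
  pl <- player_load(w[, c("ax", "ay", "az")] / GRAVITY)
  ix <- signed_integrals(w$ax, dt); iy <- signed_integrals(w$ay, dt)
  iz <- signed_integrals(w$az, dt)
  acc_norm <- sqrt(w$ax^2 + w$ay^2 + w$az^2)
  ma <- moment_stats(acc_norm)
  to_rad <- pi / 180
  g_int <- c(pracma::trapz(w$gx) * dt, pracma::trapz(w$gy) * dt,
             pracma::trapz(w$gz) * dt) * to_rad
  gyro_norm <- sqrt(w$gx^2 + w$gy^2 + w$gz^2) * to_rad
  mg <- moment_stats(gyro_norm)
  bd <- baro_deltas(altitude, t_star, half = window / 2)
  if (any(is.na(bd))) return(NULL)

  tibble(
    F1 = pl,
    F2 = ix[["positive"]], F3 = iy[["positive"]], F4 = iz[["positive"]],
    F5 = ix[["negative"]], F6 = iy[["negative"]], F7 = iz[["negative"]],
    F8 = ma[["rms"]], F9 = ma[["skewness"]], F10 = ma[["kurtosis"]],
    F11 = g_int[1], F12 = g_int[2], F13 = g_int[3],
    F14 = mg[["rms"]], F15 = mg[["skewness"]], F16 = mg[["kurtosis"]],
    F17 = bd[["delta_before"]], F18 = bd[["delta_after"]]
  )
}

#' Bias-correct and pre-filter an IMU stream
#'
#' Subtracts the static biases and applies the zero-lag 4th-order 128 Hz
#' low-pass filter to the six inertial channels, as done before feature
#' extraction.
#'
#' @param imu raw IMU tibble.
#' @param biases output of [estimate_static_bias()]; `NULL` skips correction.
#' @param fc,order pre-filter settings.
#' @return the prepared tibble.
#' @export
prepare_imu_stream <- function(imu, biases = NULL, fc = 128, order = 4) {
  if (!is.null(biases)) imu <- apply_bias(imu, biases)
  fs <- sampling_rate(imu$t)
  for (col in c("ax", "ay", "az", "gx", "gy", "gz")) {
    imu[[col]] <- lowpass_zero_lag(imu[[col]], fs, fc, order)
  }
  imu
}
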