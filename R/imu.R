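# IMU-side processing: static bias removal, turn detection on the smoothed
# vertical-axis gyroscope, and cross-correlation synchronization to mocap.

#' Estimate static sensor biases from a still recording
#'
#' Channel means of a recording taken with the unit kept still, y axis up.
#' By default the gravity reading on the vertical accelerometer axis is part
#' of the estimate, so subtracting the biases returns zero-mean channels on
#' the same recording (and removes the static gravity component from the
#' vertical axis of a moving recording, which is what puts the
#' acceleration-norm features on a near-zero baseline between foot strikes).
#' Set `gravity_compensate = TRUE` to subtract 9.81 m/s^2 from the vertical
#' estimate and keep gravity in the corrected signals.
#'
#' @param still tibble with columns `t, ax, ay, az, gx, gy, gz`.
#' @param min_duration minimum acceptable recording length, s.
#' @param gravity_compensate exclude gravity from the vertical-axis bias.
#' @return named list with numeric length-3 elements `acc` and `gyro`
#'   (x, y, z biases; m/s^2 and deg/s).
#' @export
estimate_static_bias <- function(still, min_duration = 30, gravity_compensate = FALSE) {
  check_cols(still, c("t", "ax", "ay", "az", "gx", "gy", "gz"), "still recording")
  if (diff(range(still$t)) < min_duration) {
    abort(sprintf("still recording shorter than %g s", min_duration))
  }
  ay_bias <- if (gravity_compensate) mean(still$ay) - GRAVITY else mean(still$ay)
  list(
    acc = c(mean(still$ax), ay_bias, mean(still$az)),
    gyro = c(mean(still$gx), mean(still$gy), mean(still$gz))
  )
}

#' Subtract static biases from an IMU stream
#'
#' @param imu tibble with `ax, ay, az, gx, gy, gz`.
#' @param biases output of [estimate_static_bias()].
#' @return the bias-corrected tibble.
#' @export
apply_bias <- function(imu, biases) {
  imu$ax <- imu$ax - biases$acc[1]
  imu$ay <- imu$ay - biases$acc[2]
  imu$az <- imu$az - biases$acc[3]
  imu$gx <- imu$gx - biases$gyro[1]
  imu$gy <- imu$gy - biases$gyro[2]
  imu$gz <- imu$gz - biases$gyro[3]
  imu
}

#' Detect turn events from the vertical-axis gyroscope
#'
#' The yaw rate is smoothed with a 0.5 Hz zero-lag low-pass Butterworth
#' filter; 180-degree turns then appear as prominent peaks of its absolute
#' value. Peaks below `min_rate` (deg/s) or below `min_height` times the
#' largest smoothed peak are ignored, as are peaks closer than `min_spacing`.
#'
#' @param imu bias-corrected IMU tibble (`t`, `gy` in deg/s; IMU clock).
#' @param fc smoothing cut-off, Hz.
#' @param min_spacing minimum time between events, s.
#' @param min_height relative peak threshold (fraction of the maximum).
#' @param min_rate absolute peak threshold, deg/s.
#' @return tibble `turn`, `t_star` (IMU clock, s); zero rows when no turn.
#' @export
detect_turns_imu <- function(imu, fc = 0.5, min_spacing = 1.5,
                             min_height = 0.3, min_rate = 20) {
  check_cols(imu, c("t", "gy"), "imu")
  fs <- sampling_rate(imu$t)
  smoothed <- abs(lowpass_zero_lag(imu$gy, fs, fc, order = 2))
  top <- max(smoothed)
  if (top < min_rate) {
    return(tibble(turn = integer(0), t_star = numeric(0)))
  }
  pk <- pracma::findpeaks(smoothed,
                          minpeakheight = max(min_rate, min_height * top),
                          minpeakdistance = round(min_spacing * fs))
  if (is.null(pk)) return(tibble(turn = integer(0), t_star = numeric(0)))
  idx <- sort(pk[, 2])
  tibble(turn = seq_along(idx), t_star = imu$t[idx])
}

#' Synchronize IMU and mocap event sets by cross-correlation
#'
#' Candidate event times from the two systems are turned into
#' Gaussian-smoothed impulse trains on a common grid (default 100 Hz); the
#' lag maximizing their normalized cross-correlation is the clock offset
#' (IMU clock minus mocap clock). Each mocap event is then matched to its
#' nearest offset-corrected IMU event, yielding per-event detection errors.
#'
#' @param imu_events event times on the IMU clock, s (or the tibble from
#'   [detect_turns_imu()]).
#' @param mocap_events event times on the mocap clock, s (or the tibble from
#'   [detect_turns_mocap()]).
#' @param fs_common grid rate, Hz.
#' @param max_lag search bound, s.
#' @param kernel_sd width of the Gaussian impulse kernel, s.
#' @param min_peak_cor minimum normalized peak correlation; below it the
#'   synchronization is declared failed (error).
#' @param match_tol maximum |error| for an event pair to count as matched, s.
#' @return object of class `cod_sync`: list with `lag` (s), `peak_cor`, and
#'   `matches` (tibble `mocap_t`, `imu_t`, `error`).
#' @export
synchronize_events <- function(imu_events, mocap_events, fs_common = 100,
                               max_lag = 3, kernel_sd = 0.1,
                               min_peak_cor = 0.2, match_tol = 0.5) {
  if (is.data.frame(imu_events)) imu_events <- imu_events$t_star
  if (is.data.frame(mocap_events)) mocap_events <- mocap_events$t_star
  if (length(imu_events) == 0 || length(mocap_events) == 0) {
    abort("both event sets must be non-empty")
  }
  dt <- 1 / fs_common
  lo <- min(imu_events, mocap_events) - max_lag - 4 * kernel_sd
  hi <- max(imu_events, mocap_events) + max_lag + 4 * kernel_sd
  grid <- seq(lo, hi, by = dt)
  train <- function(ev) {
    x <- numeric(length(grid))
    for (e in ev) {
      sel <- abs(grid - e) <= 4 * kernel_sd
      x[sel] <- x[sel] + exp(-(grid[sel] - e)^2 / (2 * kernel_sd^2))
    }
    x
  }
  xi <- train(imu_events)
  xm <- train(mocap_events)
  K <- round(max_lag / dt)
  n <- length(grid)
  score <- vapply(-K:K, function(k) {
    if (k >= 0) sum(xi[(1 + k):n] * xm[1:(n - k)])
    else sum(xi[1:(n + k)] * xm[(1 - k):n])
  }, numeric(1))
  norm <- sqrt(sum(xi^2) * sum(xm^2))
  peak <- which.max(score)
  peak_cor <- score[peak] / norm
  if (!is.finite(peak_cor) || peak_cor < min_peak_cor) {
    abort(sprintf("synchronization failed: peak correlation %.3f below %.3f",
                  peak_cor, min_peak_cor))
  }
  lag <- (-K:K)[peak] * dt
  shifted <- imu_events - lag
  matches <- dplyr::bind_rows(lapply(mocap_events, function(me) {
    j <- which.min(abs(shifted - me))
    err <- shifted[j] - me
    if (abs(err) > match_tol) return(NULL)
    tibble(mocap_t = me, imu_t = imu_events[j], error = err)
  }))
  structure(list(lag = lag, peak_cor = peak_cor, matches = matches),
            class = "cod_sync")
}

#' @export
print.cod_sync <- function(x, ...) {
  cat(sprintf("<cod_sync> lag = %.3f s, peak correlation = %.3f, %d matched events\n",
              x$lag, x$peak_cor, nrow(x$matches)))
  if (nrow(x$matches) > 1) {
    cat(sprintf("  event error: %.4f +/- %.4f s\n",
                mean(x$matches$error), sd(x$matches$error)))
  }
  invisible(x)
}
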