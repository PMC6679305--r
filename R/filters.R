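#' Zero-lag Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (`signal::filtfilt`), so the net phase response is zero and the effective
#' magnitude response is the squared Butterworth magnitude. This is the
#' smoothing primitive used on marker/CoM trajectories (15 Hz), on the
#' vertical-axis gyroscope for turn detection (0.5 Hz), on the raw inertial
#' channels (128 Hz) and on the barometric pressure (1 Hz, order 10).
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling frequency, Hz.
#' @param fc cut-off frequency, Hz; must be below the Nyquist frequency.
#' @param order filter order of the underlying one-pass filter.
#' @return filtered vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, 1 / 100)
#' x <- sin(2 * pi * t) + 0.2 * sin(2 * pi * 40 * t)
#' y <- lowpass_zero_lag(x, fs = 100, fc = 15, order = 2)
lowpass_zero_lag <- function(x, fs, fc, order = 2) {
  if (!is.numeric(x)) abort("`x` must be numeric")
  if (fc <= 0 || fc >= fs / 2) {
    abort(sprintf("cut-off %.3g Hz must lie in (0, Nyquist = %.3g Hz)", fc, fs / 2))
  }
  if (length(x) < 3 * (order + 1)) abort("signal too short for the requested filter order")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (important for low cut-offs on signals with a
  # large offset, e.g. barometric pressure)
  n <- length(x)
  pad <- min(n - 1, max(3 * order, round(3 * fs / fc)))
  m <- mean(x)
  xc <- x - m
  xp <- c(2 * xc[1] - xc[(pad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)] + m
}
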