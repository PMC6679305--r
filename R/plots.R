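# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline facet_wrap labs theme_minimal coord_flip
NULL

#' Plot the three sensor streams of a trial
#'
#' CoM lane position, vertical-axis gyroscope and barometric altitude on a
#' shared time axis (mocap clock for the CoM; sensor clock for the others,
#' so a clock offset is visible as a horizontal shift).
#'
#' @param object a `cod_trial`.
#' @param t_max truncate the view to the first `t_max` seconds.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cod_trial <- function(object, t_max = 20, ...) {
  d <- dplyr::bind_rows(
    tibble(t = object$mocap$t, value = object$mocap$x, stream = "CoM x [m]"),
    tibble(t = object$imu$t, value = object$imu$gy, stream = "gyro y [deg/s]"),
    tibble(t = object$baro$t, value = altitude_from_pressure(object$baro$p),
           stream = "baro altitude [m]")
  )
  d <- d[d$t <= t_max, ]
  ggplot(d, aes(x = .data$t, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~stream, ncol = 1, scales = "free_y") +
    labs(x = "time [s]", y = NULL, title = "Shuttle-run trial streams") +
    theme_minimal()
}

#' Plot a model evaluation
#'
#' Held-out predictions against reference values for regressions; feature
#' importance (when available) for boosted trees.
#'
#' @param object a `cod_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cod_eval <- function(object, ...) {
  if (!is.null(object$importance)) {
    d <- object$importance
    d$feature <- factor(d$feature, levels = rev(d$feature))
    return(
      ggplot(d, aes(x = .data$feature, y = .data$importance)) +
        geom_col() + coord_flip() +
        labs(title = sprintf("Boosted-trees importance: %s", object$response),
             x = NULL, y = "normalized split gain") +
        theme_minimal()
    )
  }
  if (object$task == "regression") {
    ggplot(object$predictions, aes(x = .data$y, y = .data$y_hat)) +
      geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      labs(x = "reference", y = "predicted",
           title = sprintf("%s by %s (R2 = %.2f)", object$response,
                           object$family, object$metrics$r2)) +
      theme_minimal()
  } else {
    ggplot(object$predictions, aes(x = .data$y, y = .data$score)) +
      geom_point(alpha = 0.4, size = 0.8,
                 position = ggplot2::position_jitter(width = 0.1)) +
      labs(x = "true side", y = "P(left)",
           title = sprintf("side by %s (accuracy = %.1f%%)", object$family,
                           object$metrics$accuracy)) +
      theme_minimal()
  }
}

#' Plot synchronization diagnostics
#'
#' Per-event detection errors after clock alignment.
#'
#' @param object a `cod_sync`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cod_sync <- function(object, ...) {
  ggplot(object$matches, aes(x = .data$mocap_t, y = .data$error)) +
    geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "mocap event time [s]", y = "IMU - mocap error [s]",
         title = sprintf("Event matching after lag %.3f s", object$lag)) +
    theme_minimal()
}
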