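# Reference (target) values from the centre-of-mass trajectory: turn events,
# external mechanical work, approach/exit speed.

#' Filter a CoM trajectory and derive its velocity
#'
#' Applies the zero-lag low-pass Butterworth filter (default 15 Hz, order 2)
#' to each coordinate and differentiates the filtered positions by central
#' differences (one-sided at the ends). Filtering precedes differentiation.
#'
#' @param mocap tibble with columns `t, x, y, z` (s, m), uniformly sampled;
#'   `x` is the running direction, `z` vertical.
#' @param fc,order filter cut-off (Hz) and order.
#' @return the input tibble with filtered coordinates plus `vx, vy, vz` and
#'   `speed` (norm of the CoM velocity), m/s.
#' @export
com_trajectory <- function(mocap, fc = 15, order = 2) {
  check_cols(mocap, c("t", "x", "y", "z"), "mocap")
  fs <- sampling_rate(mocap$t)
  out <- mocap
  for (col in c("x", "y", "z")) out[[col]] <- lowpass_zero_lag(mocap[[col]], fs, fc, order)
  out$vx <- central_diff(out$x, 1 / fs)
  out$vy <- central_diff(out$y, 1 / fs)
  out$vz <- central_diff(out$z, 1 / fs)
  out$speed <- sqrt(out$vx^2 + out$vy^2 + out$vz^2)
  out
}

central_diff <- function(x, dt) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

sampling_rate <- function(t) {
  dt <- diff(t)
  if (any(dt <= 0)) abort("time stamps must be strictly increasing")
  1 / median(dt)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# alternating local extrema of a series, plateau-safe; returns indices
local_extrema <- function(x) {
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  runs <- rle(s[nz])
  ends <- nz[cumsum(runs$lengths)]
  # a +run followed by a -run ends in a maximum (and vice versa)
  idx <- ends[-length(ends)] + 1
  idx[abs(diff(runs$values)) == 2]
}

#' Detect turn events from the CoM running-direction coordinate
#'
#' Turns of a shuttle run show up as alternating maxima and minima of the
#' CoM position along the lane. Extrema closer together than `min_spacing`
#' (default 1.5 s, rejecting step-level wiggles at the ~2 s shuttle period)
#' are pruned, keeping the more extreme one, and small-amplitude extrema
#' below `min_amplitude` times the half-range are discarded.
#'
#' @param com a [com_trajectory()] (or any tibble with `t` and `x`).
#' @param min_spacing minimum time between events, s.
#' @param min_amplitude fraction of the half-range of `x` an extremum must
#'   deviate from the midline to count as a turn.
#' @return tibble with one row per event: `turn`, `t_star`, `kind`
#'   (`"max"`/`"min"`); zero rows when no turn is present.
#' @export
detect_turns_mocap <- function(com, min_spacing = 1.5, min_amplitude = 0.25) {
  check_cols(com, c("t", "x"), "com")
  x <- com$x; t <- com$t
  idx <- local_extrema(x)
  if (length(idx) == 0) return(tibble(turn = integer(0), t_star = numeric(0), kind = character(0)))
  mid <- (max(x) + min(x)) / 2
  half_range <- (max(x) - min(x)) / 2
  dev <- abs(x[idx] - mid)
  idx <- idx[dev >= min_amplitude * half_range]
  # enforce minimum spacing, keeping the more extreme of close pairs
  idx <- idx[order(t[idx])]
  keep <- idx
  repeat {
    gaps <- diff(t[keep])
    close <- which(gaps < min_spacing)
    if (length(close) == 0) break
    i <- close[1]
    drop <- if (abs(x[keep[i]] - mid) >= abs(x[keep[i + 1]] - mid)) i + 1 else i
    keep <- keep[-drop]
  }
  # enforce max/min alternation, keeping the more extreme of adjacent repeats
  kind <- ifelse(x[keep] > mid, "max", "min")
  repeat {
    same <- which(diff(ifelse(kind == "max", 1, -1)) == 0)
    if (length(same) == 0) break
    i <- same[1]
    drop <- if (abs(x[keep[i]] - mid) >= abs(x[keep[i + 1]] - mid)) i + 1 else i
    keep <- keep[-drop]; kind <- kind[-drop]
  }
  tibble(turn = seq_along(keep), t_star = t[keep], kind = kind)
}

#' Mass-specific external mechanical energy of the CoM
#'
#' `E_ext(t) = 1/2 * ||v_CoM||^2 + g * h_CoM`, J/kg, with g = 9.81 m/s^2;
#' the velocity comes from central differences of the filtered trajectory.
#'
#' @param com a [com_trajectory()].
#' @return tibble with columns `t` and `e_ext` (J/kg).
#' @export
external_energy <- function(com) {
  check_cols(com, c("t", "speed", "z"), "com (run com_trajectory() first)")
  tibble(t = com$t, e_ext = 0.5 * com$speed^2 + GRAVITY * com$z)
}

#' Positive and negative external work over a turn window
#'
#' Sums the positive (respectively negative) sample-to-sample increments of
#' the external energy over the 2 s window centred on the event. Both are
#' returned as magnitudes (>= 0). By construction
#' `w_plus - w_minus = e_ext(end) - e_ext(start)` exactly.
#'
#' @param energy tibble from [external_energy()].
#' @param t_star event time, s.
#' @param window window length, s (default 2, centred on `t_star`).
#' @return named numeric `c(w_plus =, w_minus =)`, J/kg; `NA`s (with a
#'   warning) when the window is truncated by the recording bounds.
#' @export
turn_work <- function(energy, t_star, window = 2) {
  sel <- energy$t >= t_star - window / 2 & energy$t <= t_star + window / 2
  fs <- sampling_rate(energy$t)
  expected <- floor(window * fs)
  if (sum(sel) < expected) {
    warn(sprintf("turn at t=%.2f s: window truncated by recording bounds, dropped", t_star))
    return(c(w_plus = NA_real_, w_minus = NA_real_))
  }
  de <- diff(energy$e_ext[sel])
  c(w_plus = sum(pmax(de, 0)), w_minus = -sum(pmin(de, 0)))
}

#' Approach and exit speed of a turn
#'
#' Mean norm of the CoM velocity over the second before (`v_before`) and the
#' second after (`v_after`) the event.
#'
#' @param com a [com_trajectory()].
#' @inheritParams turn_work
#' @return named numeric `c(v_before =, v_after =)`, m/s; `NA`s when the
#'   1 s margins fall outside the recording.
#' @export
turn_speeds <- function(com, t_star, window = 2) {
  half <- window / 2
  before <- com$t >= t_star - half & com$t <= t_star
  after <- com$t >= t_star & com$t <= t_star + half
  fs <- sampling_rate(com$t)
  if (sum(before) < floor(half * fs) || sum(after) < floor(half * fs)) {
    return(c(v_before = NA_real_, v_after = NA_real_))
  }
  c(v_before = mean(com$speed[before]), v_after = mean(com$speed[after]))
}

#' Pivot side of a turn from the vertical-axis angular velocity
#'
#' Integrates the (bias-corrected) yaw rate over the turn window; a positive
#' net rotation in the sensor frame (y up) is a left turn. Events whose net
#' rotation is smaller than `threshold` degrees are flagged undetermined.
#'
#' @param t,gy time stamps (s) and vertical-axis angular velocity (deg/s).
#' @inheritParams turn_work
#' @param threshold minimum |net rotation| (deg) to call a side.
#' @return `"left"`, `"right"`, or `NA_character_` when undetermined.
#' @export
turn_side <- function(t, gy, t_star, window = 2, threshold = 90) {
  sel <- t >= t_star - window / 2 & t <= t_star + window / 2
  if (sum(sel) < 2) return(NA_character_)
  net <- pracma::trapz(t[sel], gy[sel])
  if (abs(net) < threshold) return(NA_character_)
  if (net > 0) "left" else "right"
}

#' Per-turn reference responses from a CoM trajectory
#'
#' Runs the full mocap side of the pipeline: filtering, turn detection,
#' external energy, and per-turn work and speeds. Events whose 2 s window is
#' truncated by the recording bounds are dropped with a warning.
#'
#' @param mocap raw CoM tibble (`t, x, y, z`).
#' @param events optional precomputed event table ([detect_turns_mocap()]);
#'   detected from `mocap` when `NULL`.
#' @param fc,order trajectory filter settings.
#' @param window analysis window length, s.
#' @return tibble with one row per retained turn: `turn`, `t_star`,
#'   `w_plus`, `w_minus` (J/kg), `v_before`, `v_after` (m/s).
#' @export
mocap_responses <- function(mocap, events = NULL, fc = 15, order = 2, window = 2) {
  com <- com_trajectory(mocap, fc = fc, order = order)
  if (is.null(events)) events <- detect_turns_mocap(com)
  energy <- external_energy(com)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    w <- suppressWarnings(turn_work(energy, events$t_star[i], window))
    v <- turn_speeds(com, events$t_star[i], window)
    tibble(turn = events$turn[i], t_star = events$t_star[i],
           w_plus = w[["w_plus"]], w_minus = w[["w_minus"]],
           v_before = v[["v_before"]], v_after = v[["v_after"]])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dropped <- !complete.cases(out)
  if (any(dropped)) {
    inform(sprintf("dropped %d turn(s) with truncated windows", sum(dropped)))
  }
  out[!dropped, , drop = FALSE]
}

# ---- marker-based CoM ------------------------------------------------------

#' Whole-body CoM from the 14-marker set (segmental centroid method)
#'
#' Body segments are approximated from marker pairs (head from the tragi,
#' trunk from acromia and trochanters, upper arms from acromion-olecranon,
#' forearms+hands from olecranon-styloid, thighs from trochanter-epicondyle,
#' shanks+feet from epicondyle-malleolus) and combined with Dempster mass
#' fractions, which sum to 1.
#'
#' @param markers tibble with column `t` plus, for each marker,
#'   `<marker>_x`, `<marker>_y`, `<marker>_z` columns; markers:
#'   tragus, acromion, olecranon, styloid, trochanter, epicondyle, malleolus,
#'   each with `_l`/`_r` suffix (e.g. `tragus_l_x`).
#' @return tibble `t, x, y, z` — the CoM trajectory.
#' @export
com_from_markers <- function(markers) {
  marker_names <- as.vector(outer(
    c("tragus", "acromion", "olecranon", "styloid",
      "trochanter", "epicondyle", "malleolus"),
    c("l", "r"), paste, sep = "_"
  ))
  needed <- as.vector(outer(marker_names, c("x", "y", "z"), paste, sep = "_"))
  missing <- setdiff(c("t", needed), names(markers))
  if (length(missing)) {
    abort(sprintf("missing marker column(s): %s", paste(missing, collapse = ", ")))
  }
  pt <- function(name) as.matrix(markers[, paste(name, c("x", "y", "z"), sep = "_")])
  mid <- function(a, b) (pt(a) + pt(b)) / 2
  segments <- list(
    list(f = 0.081, c = (pt("tragus_l") + pt("tragus_r")) / 2),
    list(f = 0.497, c = (pt("acromion_l") + pt("acromion_r") +
                           pt("trochanter_l") + pt("trochanter_r")) / 4),
    list(f = 0.028, c = mid("acromion_l", "olecranon_l")),
    list(f = 0.028, c = mid("acromion_r", "olecranon_r")),
    list(f = 0.022, c = mid("olecranon_l", "styloid_l")),
    list(f = 0.022, c = mid("olecranon_r", "styloid_r")),
    list(f = 0.100, c = mid("trochanter_l", "epicondyle_l")),
    list(f = 0.100, c = mid("trochanter_r", "epicondyle_r")),
    list(f = 0.061, c = mid("epicondyle_l", "malleolus_l")),
    list(f = 0.061, c = mid("epicondyle_r", "malleolus_r"))
  )
  com <- unname(Reduce(`+`, lapply(segments, function(s) s$f * s$c)))
  tibble(t = markers$t, x = com[, 1], y = com[, 2], z = com[, 3])
}
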