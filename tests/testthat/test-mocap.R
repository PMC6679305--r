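flat_com <- function(x = 0, y = 0, z = 1, dur = 10, fs = 100) {
  t <- seq(0, dur, 1 / fs)
  tibble::tibble(t = t, x = rep(x, length(t)), y = rep(y, length(t)),
                 z = rep(z, length(t)))
}

test_that("turn detection: monotone in, nothing out; triangle apexes found", {
  t <- seq(0, 60, 1 / 100)
  mono <- tibble::tibble(t = t, x = 0.5 * t)
  expect_equal(nrow(detect_turns_mocap(mono)), 0)

  # symmetric triangle wave, period 4 s: apexes every 2 s
  tri <- tibble::tibble(t = t, x = 2 * abs(2 * (t / 4 - floor(t / 4 + 0.5))))
  ev <- detect_turns_mocap(tri)
  expect_true(nrow(ev) %in% c(29, 30))
  apex <- seq(2, 58, by = 2)
  matched <- vapply(ev$t_star, function(ts) min(abs(apex - ts)), numeric(1))
  expect_lt(max(matched), 1 / 100 + 1e-9)
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
})

test_that("detected events match ground truth on a noiseless trial", {
  sim <- noiseless_sim()
  ev <- detect_turns_mocap(com_trajectory(sim$trial$mocap))
  expect_equal(nrow(ev), nrow(sim$truth))
  expect_lt(max(abs(ev$t_star - sim$truth$t_star)), 1 / 100 + 1e-9)
})

test_that("external energy: stationary and level-motion closed forms", {
  com <- com_trajectory(flat_com(z = 1))
  e <- external_energy(com)
  expect_equal(e$e_ext, rep(9.81, nrow(com)), tolerance = 1e-9)

  t <- seq(0, 10, 1 / 100)
  level <- tibble::tibble(t = t, x = 2 * t, y = 0, z = 0)
  e2 <- external_energy(com_trajectory(level))
  mid <- 100:900
  expect_equal(e2$e_ext[mid], rep(2.0, length(mid)), tolerance = 1e-6)
})

test_that("energy series matches the analytic profile away from edges", {
  # raised-cosine speed reversal plus a vertical dip, built independently
  fs <- 100; v <- 3; Tt <- 1; d <- 0.4
  t <- seq(0, 12, 1 / fs)
  t0 <- 5.5  # turn start; event at t0 + Tt/2
  vx <- ifelse(t < t0, v, ifelse(t < t0 + Tt, v * cos(pi * (t - t0) / Tt), -v))
  x <- cumsum(vx) / fs
  ts <- t0 + Tt / 2
  z <- 1 - ifelse(abs(t - ts) <= 1, d * (1 + cos(pi * (t - ts))) / 2, 0)
  vz <- ifelse(abs(t - ts) <= 1, d * pi / 2 * sin(pi * (t - ts)), 0)
  com <- com_trajectory(tibble::tibble(t = t, x = x, y = 0, z = z))
  e <- external_energy(com)
  e_true <- 0.5 * (vx^2 + vz^2) + 9.81 * z
  mid <- which(t > 1 & t < 11)
  expect_lt(max(abs(e$e_ext[mid] - e_true[mid]) / e_true[mid]), 0.01)
})

test_that("turn work: zero for cruise, 4.5 J/kg for a 3 -> 0 m/s brake", {
  t <- seq(0, 10, 1 / 100)
  cruise <- com_trajectory(tibble::tibble(t = t, x = 2.5 * t, y = 0, z = 0))
  w0 <- turn_work(external_energy(cruise), t_star = 5)
  expect_equal(unname(w0), c(0, 0), tolerance = 1e-6)

  # speed falls linearly 3 -> 0 over [4.25, 5.75], then holds
  vx <- pmin(3, pmax(0, 3 - 2 * (t - 4.25)))
  brake <- com_trajectory(tibble::tibble(t = t, x = cumsum(vx) / 100, y = 0, z = 0))
  w <- turn_work(external_energy(brake), t_star = 5)
  expect_equal(w[["w_minus"]], 4.5, tolerance = 0.01)
  expect_lt(w[["w_plus"]], 0.02)
})

test_that("work increments telescope exactly over any window", {
  sim <- noiseless_sim()
  com <- com_trajectory(sim$trial$mocap)
  energy <- external_energy(com)
  for (ts in sim$truth$t_star[2:5]) {
    sel <- energy$t >= ts - 1 & energy$t <= ts + 1
    w <- turn_work(energy, ts)
    gap <- energy$e_ext[max(which(sel))] - energy$e_ext[min(which(sel))]
    expect_equal(w[["w_plus"]] - w[["w_minus"]], gap, tolerance = 1e-10)
  }
})

test_that("time reversal swaps positive/negative work and the two speeds", {
  sim <- noiseless_sim()
  mocap <- sim$trial$mocap
  rev_mocap <- tibble::tibble(t = mocap$t, x = rev(mocap$x),
                              y = rev(mocap$y), z = rev(mocap$z))
  ts <- sim$truth$t_star[4]
  ts_rev <- max(mocap$t) - ts
  com <- com_trajectory(mocap); com_r <- com_trajectory(rev_mocap)
  w <- turn_work(external_energy(com), ts)
  w_r <- turn_work(external_energy(com_r), ts_rev)
  expect_equal(w[["w_plus"]], w_r[["w_minus"]], tolerance = 1e-6)
  expect_equal(w[["w_minus"]], w_r[["w_plus"]], tolerance = 1e-6)
  v <- turn_speeds(com, ts); v_r <- turn_speeds(com_r, ts_rev)
  expect_equal(v[["v_before"]], v_r[["v_after"]], tolerance = 1e-6)
  expect_equal(v[["v_after"]], v_r[["v_before"]], tolerance = 1e-6)
})

test_that("kinetic work scales quadratically with speed in level motion", {
  t <- seq(0, 10, 1 / 100)
  make <- function(k) {
    vx <- k * pmin(3, pmax(1, 3 - 2 * (t - 4)))  # 3k -> k m/s brake
    com_trajectory(tibble::tibble(t = t, x = cumsum(vx) / 100, y = 0, z = 0))
  }
  w1 <- turn_work(external_energy(make(1)), 5)
  w2 <- turn_work(external_energy(make(2)), 5)
  expect_equal(w2[["w_minus"]] / w1[["w_minus"]], 4, tolerance = 0.01)
})

test_that("turn speeds: stationary gives zero; margins enforced", {
  com <- com_trajectory(flat_com())
  v <- turn_speeds(com, 5)
  expect_equal(unname(v), c(0, 0), tolerance = 1e-9)
  expect_true(all(is.na(turn_speeds(com, 0.2))))
})

test_that("responses recover ground truth on a noiseless trial", {
  sim <- noiseless_sim()
  p <- noiseless_processed()
  m <- merge(as.data.frame(p$turns), as.data.frame(sim$truth), by = "turn")
  expect_equal(nrow(m), nrow(sim$truth))
  expect_lt(max(abs(m$t_star.x - m$t_star.y)), 1 / 100 + 1e-9)
  expect_lt(max(abs(m$v_before.x / m$v_before.y - 1)), 0.01)
  expect_lt(max(abs(m$v_after.x / m$v_after.y - 1)), 0.01)
  expect_lt(max(abs(m$w_plus.x / m$w_plus.y - 1)), 0.02)
  expect_lt(max(abs(m$w_minus.x / m$w_minus.y - 1)), 0.02)
  expect_identical(m$side.x, m$side.y)
})

test_that("marker-set CoM equals the weighted-centroid oracle", {
  markers <- c("tragus", "acromion", "olecranon", "styloid",
               "trochanter", "epicondyle", "malleolus")
  cols <- as.vector(outer(as.vector(outer(markers, c("l", "r"), paste, sep = "_")),
                          c("x", "y", "z"), paste, sep = "_"))
  # all markers coincident: CoM equals the point
  one <- as.data.frame(as.list(setNames(rep(2.5, length(cols)), cols)))
  one$t <- 0
  com <- com_from_markers(tibble::as_tibble(one))
  expect_equal(c(com$x, com$y, com$z), c(2.5, 2.5, 2.5), tolerance = 1e-12)

  # random cloud vs an independently coded weighted mean
  set.seed(7)
  cloud <- as.data.frame(matrix(rnorm(3 * 42), nrow = 3))
  names(cloud) <- cols
  cloud$t <- 0:2
  com2 <- com_from_markers(tibble::as_tibble(cloud))
  g <- function(m, a) as.matrix(cloud[, paste(m, a, sep = "_")])
  seg <- function(m1, m2) (g(m1, c("x", "y", "z")) + g(m2, c("x", "y", "z"))) / 2
  oracle <- 0.081 * seg("tragus_l", "tragus_r") +
    0.497 * (g("acromion_l", c("x", "y", "z")) + g("acromion_r", c("x", "y", "z")) +
               g("trochanter_l", c("x", "y", "z")) + g("trochanter_r", c("x", "y", "z"))) / 4 +
    0.028 * (seg("acromion_l", "olecranon_l") + seg("acromion_r", "olecranon_r")) +
    0.022 * (seg("olecranon_l", "styloid_l") + seg("olecranon_r", "styloid_r")) +
    0.100 * (seg("trochanter_l", "epicondyle_l") + seg("trochanter_r", "epicondyle_r")) +
    0.061 * (seg("epicondyle_l", "malleolus_l") + seg("epicondyle_r", "malleolus_r"))
  expect_equal(cbind(com2$x, com2$y, com2$z), unname(oracle), tolerance = 1e-12)

  # a missing marker is reported by name
  expect_error(com_from_markers(tibble::as_tibble(cloud)[, -1]),
               "tragus_l_x")
})

test_that("bilaterally symmetric posture puts the CoM on the midline", {
  markers <- c("tragus", "acromion", "olecranon", "styloid",
               "trochanter", "epicondyle", "malleolus")
  df <- list(t = 0)
  for (i in seq_along(markers)) {
    for (s in c("l", "r")) {
      df[[paste(markers[i], s, "x", sep = "_")]] <- i
      df[[paste(markers[i], s, "y", sep = "_")]] <- if (s == "l") 0.2 else -0.2
      df[[paste(markers[i], s, "z", sep = "_")]] <- 1.5 - 0.1 * i
    }
  }
  com <- com_from_markers(tibble::as_tibble(df))
  expect_equal(com$y, 0, tolerance = 1e-12)
})
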