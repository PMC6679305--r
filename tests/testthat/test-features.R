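test_that("player load: constants, unit steps and a brute-force oracle", {
  n <- 8
  const <- data.frame(ax = rep(2, n), ay = rep(-1, n), az = rep(0.5, n))
  expect_equal(player_load(const), 0)

  step <- data.frame(ax = c(0, 0, 1, 1), ay = 0, az = 0)
  expect_equal(player_load(step), 1)

  w <- withr::with_seed(3, data.frame(ax = rnorm(6), ay = rnorm(6), az = rnorm(6)))
  oracle <- 0
  for (i in 1:5) {
    oracle <- oracle + sqrt((w$ax[i + 1] - w$ax[i])^2 +
                              (w$ay[i + 1] - w$ay[i])^2 +
                              (w$az[i + 1] - w$az[i])^2)
  }
  expect_equal(player_load(w), oracle, tolerance = 1e-12)
  expect_error(player_load(w, expected_n = 1024), "expected 1024")
})

test_that("signed integrals split the trapezoid by sign", {
  dt <- 1 / 512
  pos <- abs(withr::with_seed(1, rnorm(50))) + 0.1
  si <- signed_integrals(pos, dt)
  expect_equal(si[["positive"]], pracma::trapz(pos) * dt, tolerance = 1e-12)
  expect_equal(si[["negative"]], 0)

  odd <- c(-3, -1, 0, 1, 3)
  so <- signed_integrals(odd, dt)
  expect_equal(so[["positive"]], -so[["negative"]], tolerance = 1e-12)

  x <- withr::with_seed(2, rnorm(100))
  s <- signed_integrals(x, dt)
  # independent oracle: manual trapezoid on the clipped series
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) * dt
  expect_equal(s[["positive"]], trap(pmax(x, 0)), tolerance = 1e-12)
  expect_equal(s[["negative"]], trap(pmin(x, 0)), tolerance = 1e-12)
})

test_that("moment statistics are the population moments", {
  sym <- rep(c(1, 3), 10)
  m <- moment_stats(sym)
  expect_equal(m[["skewness"]], 0, tolerance = 1e-12)
  expect_equal(m[["kurtosis"]], 1, tolerance = 1e-12)  # two-point floor

  g <- withr::with_seed(9, rnorm(2e5))
  expect_equal(moment_stats(g)[["kurtosis"]], 3, tolerance = 0.05)

  x <- c(0.3, -1.2, 2.2, 0.7, -0.4)
  mm <- moment_stats(x)
  mu <- sum(x) / 5
  s2 <- sum((x - mu)^2) / 5
  expect_equal(mm[["rms"]], sqrt(sum(x^2) / 5), tolerance = 1e-12)
  expect_equal(mm[["skewness"]], sum((x - mu)^3) / 5 / s2^1.5, tolerance = 1e-12)
  expect_equal(mm[["kurtosis"]], sum((x - mu)^4) / 5 / s2^2, tolerance = 1e-12)

  expect_error(moment_stats(rep(1, 10)), "constant")
})

test_that("baro deltas: flat altitude gives zeros, margins give NA", {
  alt <- tibble::tibble(t = seq(0, 20, 1 / 64), h = 120)
  expect_equal(unname(baro_deltas(alt, 10)), c(0, 0))
  expect_true(all(is.na(baro_deltas(alt, 0.5))))
  expect_true(all(is.na(baro_deltas(alt, 19.7))))
})

test_that("a generated dip appears as a -d/+d altitude delta pair", {
  sim <- noiseless_sim()
  alt <- baro_altitude(sim$trial$baro)
  cfg <- noiseless_config()
  for (ts in sim$truth$t_star[3:5]) {
    bd <- baro_deltas(alt, ts)
    expect_equal(bd[["delta_before"]], -cfg$vertical_dip_depth, tolerance = 0.12)
    expect_equal(bd[["delta_after"]], cfg$vertical_dip_depth, tolerance = 0.12)
  }
})

test_that("extract_features equals the composition of its parts", {
  sim <- noiseless_sim()
  imu <- prepare_imu_stream(sim$trial$imu)
  alt <- baro_altitude(sim$trial$baro)
  ts <- sim$truth$t_star[4]
  fv <- extract_features(imu, alt, ts)

  fs <- 512
  start <- which(imu$t >= ts - 1)[1]
  w <- imu[start:(start + 2 * fs - 1), ]
  expect_equal(fv$F1, player_load(w[, c("ax", "ay", "az")] / 9.81), tolerance = 1e-12)
  expect_equal(fv$F2, signed_integrals(w$ax, 1 / fs)[["positive"]], tolerance = 1e-12)
  expect_equal(fv$F7, signed_integrals(w$az, 1 / fs)[["negative"]], tolerance = 1e-12)
  ms <- moment_stats(sqrt(w$ax^2 + w$ay^2 + w$az^2))
  expect_equal(c(fv$F8, fv$F9, fv$F10), unname(ms), tolerance = 1e-12)
  expect_equal(fv$F12, pracma::trapz(w$gy) / fs * pi / 180, tolerance = 1e-12)
  bd <- baro_deltas(alt, ts)
  expect_equal(c(fv$F17, fv$F18), unname(bd), tolerance = 1e-12)
})

test_that("feature invariants hold on a processed noisy cohort", {
  d <- small_processed()$turns
  f <- d[, grep("^F[0-9]+$", names(d))]
  expect_true(all(is.finite(as.matrix(f))))
  expect_true(all(f$F1 >= 0))
  expect_true(all(f$F2 >= 0 & f$F3 >= 0 & f$F4 >= 0))
  expect_true(all(f$F5 <= 0 & f$F6 <= 0 & f$F7 <= 0))
  expect_true(all(f$F8 >= 0 & f$F14 >= 0))
  expect_true(all(f$F10 >= 1 & f$F16 >= 1))  # kurtosis lower bound
  # net yaw of a 180-degree turn is about +/- pi radians
  expect_true(all(abs(abs(f$F12) - pi) < 0.5))
})

test_that("feature means stay within the reference cohort ranges", {
  d <- small_processed()$turns
  f <- d[, grep("^F[0-9]+$", names(d))]
  in_range <- function(x, lo, hi) mean(x) >= lo & mean(x) <= hi
  # features whose units are directly comparable to the reference table
  expect_true(in_range(f$F1, 67.3, 407.4))
  expect_true(in_range(f$F8, 1.19, 21.04))
  expect_true(in_range(f$F9, 2.08, 9.00))
  expect_true(in_range(f$F10, 7.6, 98.4))
  expect_true(in_range(f$F15, 0.41, 9.31))
  expect_true(in_range(f$F16, 2.41, 104.0))
  expect_true(in_range(f$F17, -1.08, 0.36))
  expect_true(in_range(f$F18, -0.35, 1.12))
  # SI-unit integrals: magnitudes bounded by 10x the reference table span
  expect_true(all(abs(colMeans(f[, c("F2", "F3", "F4")])) < 10 * 846))
  expect_true(all(abs(colMeans(f[, c("F11", "F12", "F13")])) < 10 * 8.6e4))
})

test_that("mirroring a trial flips yaw/roll features and the lateral axis", {
  sim <- noiseless_sim()
  imu_a <- prepare_imu_stream(sim$trial$imu)
  imu_b <- prepare_imu_stream(mirror_trial(sim$trial)$imu)
  alt <- baro_altitude(sim$trial$baro)
  ts <- sim$truth$t_star[4]
  a <- extract_features(imu_a, alt, ts)
  b <- extract_features(imu_b, alt, ts)
  expect_equal(b$F11, -a$F11, tolerance = 1e-9)  # roll integral flips
  expect_equal(b$F12, -a$F12, tolerance = 1e-9)  # yaw integral flips
  expect_equal(b$F13, a$F13, tolerance = 1e-9)   # pitch integral unchanged
  expect_equal(b$F4, -a$F7, tolerance = 1e-9)    # lateral accel sign swap
  expect_equal(b$F7, -a$F4, tolerance = 1e-9)
  for (col in c("F1", "F2", "F3", "F5", "F6", "F8", "F9", "F10",
                "F14", "F15", "F16", "F17", "F18")) {
    expect_equal(b[[col]], a[[col]], tolerance = 1e-9)
  }
})
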