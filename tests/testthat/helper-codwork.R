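# Shared fixtures, built lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# a fully deterministic trial: no noise, no bias, no drift, no jitter,
# no clock offset — every stage should recover ground truth exactly
noiseless_config <- function(n_turns = 10, seed = 8, ...) {
  sim_config(
    n_turns = n_turns, seed = seed,
    acc_noise_sd = 0, gyro_noise_sd = 0, baro_noise_sd = 0,
    acc_bias = c(0, 0, 0), gyro_bias = c(0, 0, 0), gyro_drift_rate = 0,
    speed_jitter_turn = 0, dip_jitter = 0, clock_offset = 0, ...
  )
}

noiseless_sim <- function() cached("noiseless_sim", function() {
  simulate_trial(noiseless_config())
})

noiseless_processed <- function() cached("noiseless_processed", function() {
  suppressMessages(process_trial(noiseless_sim()$trial))
})

# small noisy cohort under default calibration (used by several suites)
small_cohort <- function() cached("small_cohort", function() {
  simulate_cohort(sim_config(n_turns = 24, seed = 5), 4)
})

small_processed <- function() cached("small_processed", function() {
  suppressMessages(process_cohort(small_cohort()))
})

# full-scale calibrated cohort for the acceptance checks (13 x 72 turns)
acceptance_cohort <- function() cached("acceptance_cohort", function() {
  simulate_cohort(sim_config(seed = 42), 13)
})

acceptance_processed <- function() cached("acceptance_processed", function() {
  suppressMessages(process_cohort(acceptance_cohort()))
})

acceptance_screened <- function() cached("acceptance_screened", function() {
  remove_outliers(acceptance_processed()$turns,
                  cols = c("w_plus", "w_minus", "v_before", "v_after",
                           paste0("F", 1:18)))
})

response_cols <- c("w_plus", "w_minus", "v_before", "v_after")
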