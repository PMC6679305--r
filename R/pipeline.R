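# End-to-end orchestration: trial -> synchronized per-turn responses and
# features -> model evaluation report.

#' Process one trial into per-turn responses and features
#'
#' Runs both sides of the pipeline and joins them: (1) mocap: filter the CoM
#' trajectory, detect turn events, compute external work and speeds; (2)
#' IMU: bias-correct, detect turns on the smoothed yaw rate, synchronize the
#' two clocks by impulse-train cross-correlation, pre-filter, and extract
#' the 18 features over each synchronized 2 s window; the pivot side comes
#' from the sign of the net yaw rotation. Turns whose window is truncated on
#' either stream are dropped and counted.
#'
#' @param trial a `cod_trial` (see [simulate_trial()] or [read_trial()]).
#' @param biases static sensor biases ([estimate_static_bias()]); `NULL`
#'   means no correction.
#' @param still optional still recording used to estimate `biases` when they
#'   are not supplied.
#' @param window analysis window, s.
#' @return object of class `cod_processed`: list with `turns` (tibble:
#'   `turn`, `t_star`, `side`, `w_plus`, `w_minus`, `v_before`, `v_after`,
#'   `F1...F18`), `sync` (the [synchronize_events()] result) and `counts`.
#' @export
process_trial <- function(trial, biases = NULL, still = NULL, window = 2) {
  stopifnot(inherits(trial, "cod_trial"))
  if (is.null(biases) && !is.null(still)) {
    biases <- estimate_static_bias(still, min_duration = 0)
  }
  com <- com_trajectory(trial$mocap)
  events_m <- detect_turns_mocap(com)
  if (nrow(events_m) == 0) abort("no turn events found in the mocap stream")
  responses <- suppressMessages(mocap_responses(trial$mocap, events = events_m))

  imu_bc <- if (is.null(biases)) trial$imu else apply_bias(trial$imu, biases)
  events_i <- detect_turns_imu(imu_bc)
  if (nrow(events_i) == 0) abort("no turn events found in the IMU stream")
  sync <- synchronize_events(events_i$t_star, events_m$t_star)

  imu_prep <- prepare_imu_stream(trial$imu, biases)
  altitude <- baro_altitude(trial$baro)

  rows <- lapply(seq_len(nrow(responses)), function(i) {
    t_imu <- responses$t_star[i] + sync$lag
    fv <- extract_features(imu_prep, altitude, t_imu, window = window)
    if (is.null(fv)) return(NULL)
    side <- turn_side(imu_prep$t, imu_prep$gy, t_imu, window = window)
    if (is.na(side)) return(NULL)
    dplyr::bind_cols(responses[i, ], tibble(side = side), fv)
  })
  turns <- dplyr::bind_rows(rows)
  counts <- list(
    mocap_events = nrow(events_m), imu_events = nrow(events_i),
    matched_events = nrow(sync$matches),
    responses = nrow(responses), retained = nrow(turns)
  )
  inform(sprintf(
    "processed trial: %d mocap / %d IMU events, lag %.3f s, %d turns retained",
    counts$mocap_events, counts$imu_events, sync$lag, counts$retained))
  structure(list(turns = turns, sync = sync, counts = counts),
            class = "cod_processed")
}

#' Process a simulated cohort
#'
#' Applies [process_trial()] to every subject of a [simulate_cohort()]
#' table. Static biases are estimated per subject from a simulated still
#' recording of `still_duration` seconds generated with the subject's own
#' sensor error model.
#'
#' @param cohort tibble from [simulate_cohort()].
#' @param still_duration length of the per-subject still recording, s.
#' @param window analysis window, s.
#' @return list of class `cod_processed_cohort` with `turns` (tibble with a
#'   `subject` column) and `syncs` (per-subject sync results).
#' @export
process_cohort <- function(cohort, still_duration = 60, window = 2) {
  processed <- lapply(seq_len(nrow(cohort)), function(i) {
    still <- simulate_still(cohort$config[[i]], duration = still_duration)
    suppressMessages(process_trial(cohort$trial[[i]], still = still, window = window))
  })
  turns <- dplyr::bind_rows(lapply(seq_along(processed), function(i) {
    dplyr::bind_cols(tibble(subject = cohort$subject[i]), processed[[i]]$turns)
  }))
  inform(sprintf("processed %d subjects, %d turns retained",
                 nrow(cohort), nrow(turns)))
  structure(list(turns = turns, syncs = lapply(processed, `[[`, "sync")),
            class = "cod_processed_cohort")
}

#' Train and evaluate the model suite on a turn table
#'
#' Fits the requested regression families to each continuous response and
#' the requested classifiers to the pivot side, all under the seeded
#' cross-validation scheme of [crossval_regress()] / [crossval_classify()].
#'
#' @param turns turn table (e.g. `process_cohort(...)$turns`, ideally after
#'   [remove_outliers()]).
#' @param responses continuous responses to regress.
#' @param regression_families,classification_families model families.
#' @param k folds.
#' @param seed master seed; each (response, family) pair gets a
#'   deterministic sub-seed.
#' @return object of class `cod_report`: list of `cod_eval` objects;
#'   `tidy()` gives the response-by-family metric table.
#' @export
train_models <- function(turns,
                         responses = c("w_plus", "w_minus", "v_before", "v_after"),
                         regression_families = c("multilinear", "svr", "boosted_trees", "ann"),
                         classification_families = c("lda", "svm", "boosted_trees", "ann"),
                         k = 10, seed = 1L) {
  evals <- list()
  i <- 0L
  for (resp in responses) {
    for (fam in regression_families) {
      i <- i + 1L
      spec <- model_spec(fam, seed = seed + i)
      evals[[paste(resp, fam, sep = ".")]] <- crossval_regress(turns, resp, spec, k = k)
    }
  }
  for (fam in classification_families) {
    i <- i + 1L
    spec <- model_spec(fam, seed = seed + i)
    evals[[paste("side", fam, sep = ".")]] <- crossval_classify(turns, "side", spec, k = k)
  }
  structure(list(evals = evals, seed = seed, k = k, n = nrow(turns)),
            class = "cod_report")
}

#' @export
print.cod_report <- function(x, ...) {
  cat(sprintf("<cod_report> %d models on %d turns (k = %d, seed = %d)\n",
              length(x$evals), x$n, x$k, x$seed))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy a model report into the response-by-family metric table
#'
#' @param x a `cod_report`.
#' @param ... unused.
#' @return tibble with one row per (response, family): R^2/RMSE/MAE for
#'   regressions, accuracy/sensitivity/specificity/AUC for classifiers.
#' @export
tidy.cod_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$evals, tidy))
}

#' @rdname tidy.cod_report
#' @export
glance.cod_report <- function(x, ...) {
  tibble(models = length(x$evals), n = x$n, k = x$k, seed = x$seed)
}
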