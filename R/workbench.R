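# Shell-level entry points: simulate a cohort to disk, process trial
# directories, train the model suite and write a report. A thin CLI over
# these functions lives at inst/cli/codwork.R.

subject_dirs <- function(dir) {
  sort(list.dirs(dir, recursive = FALSE)[grepl("subj[0-9]+$", list.dirs(dir, recursive = FALSE))])
}

#' Simulate a cohort and write it to disk
#'
#' Creates one `subjNN/` directory per subject containing the trial CSV/JSON
#' layout, the ground truth and a still recording for bias estimation.
#'
#' @param config cohort-level [sim_config()].
#' @param n_subjects cohort size.
#' @param out_dir output directory.
#' @param still_duration still-recording length, s.
#' @return the written subject directories, invisibly.
#' @export
run_simulate <- function(config = sim_config(), n_subjects = 13, out_dir,
                         still_duration = 60) {
  cohort <- simulate_cohort(config, n_subjects)
  dirs <- character(n_subjects)
  for (i in seq_len(n_subjects)) {
    d <- file.path(out_dir, sprintf("subj%02d", i))
    still <- simulate_still(cohort$config[[i]], duration = still_duration)
    write_trial(cohort$trial[[i]], d, truth = cohort$truth[[i]], still = still)
    dirs[i] <- d
  }
  inform(sprintf("wrote %d subject directories under %s", n_subjects, out_dir))
  invisible(dirs)
}

#' Process every subject directory under a root
#'
#' Reads each `subjNN/` trial, estimates biases from its still recording
#' when present, runs [process_trial()] and writes `responses.csv`,
#' `features.csv` and `sync.json` next to the inputs, plus a pooled
#' `turns.csv` at the root.
#'
#' @param in_dir root directory written by [run_simulate()].
#' @return the pooled turn table, invisibly.
#' @export
run_process <- function(in_dir) {
  dirs <- subject_dirs(in_dir)
  if (length(dirs) == 0) abort(sprintf("no subject directories under %s", in_dir))
  all_turns <- list()
  for (i in seq_along(dirs)) {
    tr <- read_trial(dirs[i])
    processed <- process_trial(tr$trial, still = tr$still)
    write_processed(processed, dirs[i], tr$trial$meta)
    all_turns[[i]] <- dplyr::bind_cols(tibble(subject = i), processed$turns)
  }
  turns <- dplyr::bind_rows(all_turns)
  meta <- read_trial(dirs[1])$trial$meta
  write_csv_meta(turns, file.path(in_dir, "turns.csv"), meta)
  inform(sprintf("pooled %d turns into %s", nrow(turns), file.path(in_dir, "turns.csv")))
  invisible(turns)
}

#' Train the model suite on a processed cohort directory
#'
#' Reads the pooled `turns.csv`, applies the 3-SD outlier screen, fits the
#' requested families and writes `report.json` (all metrics, hyperparameters
#' and seeds) and `importance.csv` (boosted-trees feature importance).
#'
#' @param in_dir root directory containing `turns.csv` ([run_process()]).
#' @param out_dir where to write the report (defaults to `in_dir`).
#' @param seed master seed for fold assignment and stochastic fits.
#' @inheritParams train_models
#' @return the fitted `cod_report`, invisibly.
#' @export
run_train <- function(in_dir, out_dir = in_dir,
                      responses = c("w_plus", "w_minus", "v_before", "v_after"),
                      regression_families = c("multilinear", "svr", "boosted_trees", "ann"),
                      classification_families = c("lda", "svm", "boosted_trees", "ann"),
                      k = 10, seed = 1L) {
  path <- file.path(in_dir, "turns.csv")
  if (!file.exists(path)) abort(sprintf("%s not found; run the process step first", path))
  turns <- read_csv_meta(path)
  screened <- remove_outliers(turns, cols = c(responses, feature_cols(turns)))
  inform(sprintf("outlier screen removed %d of %d turns",
                 attr(screened, "n_removed"), nrow(turns)))
  report <- train_models(screened, responses = responses,
                         regression_families = regression_families,
                         classification_families = classification_families,
                         k = k, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = seed, k = k, n = nrow(screened),
         n_outliers_removed = attr(screened, "n_removed"),
         metrics = tidy(report)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  imp <- dplyr::bind_rows(lapply(names(report$evals), function(nm) {
    ev <- report$evals[[nm]]
    if (is.null(ev$importance)) return(NULL)
    dplyr::bind_cols(tibble(model = nm), ev$importance)
  }))
  if (nrow(imp) > 0) {
    readr::write_csv(imp, file.path(out_dir, "importance.csv"))
  }
  invisible(report)
}
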