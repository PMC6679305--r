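# Plain-text trial layout: mocap.csv (t,x,y,z), imu.csv (t,ax..gz),
# baro.csv (t,p), still.csv, trial.json metadata, groundtruth.csv. Every
# file starts with a '#' metadata line carrying the config hash and seed.

meta_header <- function(meta) {
  sprintf("# codwork config=%s seed=%s", meta$config_hash, meta$seed)
}

write_csv_meta <- function(df, path, meta) {
  writeLines(meta_header(meta), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

read_csv_meta <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Write a trial (and optional ground truth) to a directory
#'
#' @param trial a `cod_trial`.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth tibble from [simulate_trial()].
#' @param still optional still recording ([simulate_still()]).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir, truth = NULL, still = NULL) {
  stopifnot(inherits(trial, "cod_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- trial$meta
  write_csv_meta(trial$mocap, file.path(dir, "mocap.csv"), meta)
  write_csv_meta(trial$imu, file.path(dir, "imu.csv"), meta)
  write_csv_meta(trial$baro, file.path(dir, "baro.csv"), meta)
  if (!is.null(still)) write_csv_meta(still, file.path(dir, "still.csv"), meta)
  if (!is.null(truth)) {
    gt <- truth
    gt$clock_offset <- attr(truth, "clock_offset")
    write_csv_meta(gt, file.path(dir, "groundtruth.csv"), meta)
  }
  jsonlite::write_json(meta, file.path(dir, "trial.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trial directory written by [write_trial()]
#'
#' @param dir trial directory.
#' @return list with `trial` (class `cod_trial`), and, when present,
#'   `truth` and `still`.
#' @export
read_trial <- function(dir) {
  need <- file.path(dir, c("mocap.csv", "imu.csv", "baro.csv", "trial.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort(sprintf("not a trial directory, missing: %s",
                  paste(basename(missing), collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(dir, "trial.json"), simplifyVector = TRUE)
  trial <- structure(
    list(mocap = read_csv_meta(file.path(dir, "mocap.csv")),
         imu = read_csv_meta(file.path(dir, "imu.csv")),
         baro = read_csv_meta(file.path(dir, "baro.csv")),
         meta = meta),
    class = "cod_trial"
  )
  out <- list(trial = trial)
  gt_path <- file.path(dir, "groundtruth.csv")
  if (file.exists(gt_path)) {
    gt <- read_csv_meta(gt_path)
    offset <- gt$clock_offset[1]
    gt$clock_offset <- NULL
    attr(gt, "clock_offset") <- offset
    out$truth <- gt
  }
  still_path <- file.path(dir, "still.csv")
  if (file.exists(still_path)) out$still <- read_csv_meta(still_path)
  out
}

#' Write processed per-turn tables
#'
#' Writes `responses.csv` (turn_id, t_star, side, w_plus, w_minus, v_before,
#' v_after), `features.csv` (turn_id, F1...F18) and `sync.json` (lag, peak
#' correlation, per-event errors).
#'
#' @param processed a `cod_processed` ([process_trial()]).
#' @param dir output directory.
#' @param meta metadata list with `config_hash` and `seed`.
#' @return `dir`, invisibly.
#' @export
write_processed <- function(processed, dir, meta) {
  stopifnot(inherits(processed, "cod_processed"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  turns <- processed$turns
  resp <- turns[, c("turn", "t_star", "side", "w_plus", "w_minus", "v_before", "v_after")]
  names(resp)[1] <- "turn_id"
  feat <- dplyr::bind_cols(tibble(turn_id = turns$turn),
                           turns[, grep("^F[0-9]+$", names(turns))])
  write_csv_meta(resp, file.path(dir, "responses.csv"), meta)
  write_csv_meta(feat, file.path(dir, "features.csv"), meta)
  jsonlite::write_json(
    list(config = meta$config_hash, seed = meta$seed,
         lag = processed$sync$lag, peak_cor = processed$sync$peak_cor,
         event_errors = processed$sync$matches$error,
         counts = processed$counts),
    file.path(dir, "sync.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
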