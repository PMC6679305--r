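# Dataset screening before model fitting: 3-SD outlier removal and the
# coefficient of variation summary.

#' Remove outlying turns (mean +/- 3 SD rule)
#'
#' A turn (row) is removed when any screened column lies outside its column
#' mean +/- 3 standard deviations. Means and SDs are computed once on the
#' full dataset; the rule is not iterated. By default every numeric column
#' (responses and features alike) is screened.
#'
#' @param data tibble with one row per turn.
#' @param cols columns to screen; defaults to all numeric columns.
#' @param n_sd the cut, in standard deviations.
#' @return the filtered tibble, with attribute `n_removed`.
#' @export
#' @examples
#' d <- tibble::tibble(a = c(rnorm(50), 10))
#' nrow(remove_outliers(d))
remove_outliers <- function(data, cols = NULL, n_sd = 3) {
  if (nrow(data) < 2) abort("need at least 2 rows to screen for outliers")
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  keep <- rep(TRUE, nrow(data))
  for (col in cols) {
    x <- data[[col]]
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s == 0) next
    keep <- keep & x >= m - n_sd * s & x <= m + n_sd * s
  }
  out <- data[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Coefficient of variation
#'
#' `CV = SD / |mean|`. Returns `NA` (not applicable) when the mean is zero
#' or when the CV exceeds `max_cv` — the convention used for bimodal
#' variables such as the signed gyroscope integrals, whose mean sits near
#' zero between two well-separated modes.
#'
#' @param x numeric vector.
#' @param max_cv applicability bound (default 50).
#' @return scalar CV, or `NA_real_` when not applicable.
#' @export
#' @examples
#' coef_variation(c(6, 8, 10))
coef_variation <- function(x, max_cv = 50) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  cv <- sd(x) / abs(m)
  if (!is.finite(cv) || cv > max_cv) return(NA_real_)
  cv
}

#' Per-variable summary table (mean, SD, CV, range)
#'
#' @param data tibble of turns.
#' @param cols columns to summarise; defaults to all numeric columns.
#' @return tibble `variable, mean, sd, cv, min, max`.
#' @export
cv_table <- function(data, cols = NULL) {
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  dplyr::bind_rows(lapply(cols, function(col) {
    x <- data[[col]]
    tibble(variable = col, mean = mean(x), sd = sd(x),
           cv = coef_variation(x), min = min(x), max = max(x))
  }))
}
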