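#' Read a patient cohort CSV
#'
#' Accepts either raw ACE-R columns (named as [acer_domains()]), normalised
#' ones (suffix `_norm`), or both; raw-only files are normalised on load
#' using `schema`. Level columns, when present, may use the published `GW`
#' header for visual processing; it is mapped to `gv`. Scores outside their
#' allowed range are rejected with the offending row and column named.
#'
#' @param path CSV file path.
#' @param schema An [acer_schema()].
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path, schema = acer_schema()) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "chclevels_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(data) <- ifelse(
    tolower(names(data)) %in% c(chc_domains(), "gw"),
    normalize_chc_alias(names(data)), names(data)
  )
  has_raw <- all(acer_domains() %in% names(data))
  has_norm <- all(paste0(acer_domains(), "_norm") %in% names(data))
  if (!has_raw && !has_norm) {
    abort(
      "Cohort CSV must contain the five ACE-R columns (raw or *_norm).",
      class = "chclevels_validation_error"
    )
  }
  if (has_raw && !has_norm) {
    data <- acer_normalize(data, schema)
  }
  invisible(acer_profile_matrix(data))
  if (has_raw) {
    for (d in acer_domains()) {
      bad <- which(data[[d]] < 0 | data[[d]] > schema[[d]])
      if (length(bad) > 0) {
        abort(
          sprintf("Raw score out of range in column '%s', row %d.", d, bad[1]),
          class = "chclevels_validation_error"
        )
      }
    }
  }
  if (all(chc_domains() %in% names(data))) invisible(level_matrix(data))
  data
}

#' Read a level CSV
#'
#' A level file holds `id` plus the nine CHC level columns (the `GW` alias
#' is accepted for `gv`).
#'
#' @param path CSV file path.
#' @return A tibble with validated integer levels.
#' @export
read_levels_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "chclevels_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(data) <- normalize_chc_alias(names(data))
  invisible(level_matrix(data))
  data
}

#' Write comparison reports
#'
#' Writes deterministic report files into `dir`: `level_errors.csv`
#' (positive-error percentages formatted to two decimals, e.g. `1.42%`),
#' `stat_report.csv` (p-values to five decimals), and, when a
#' [bonferroni_pairwise()] result is supplied, `bonferroni.txt` with the
#' grouping report.
#'
#' @param comparison A [compare_levels()] result.
#' @param dir Output directory (created if absent).
#' @param pairwise Optional `chc_pairwise` object.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(comparison, dir, pairwise = NULL) {
  stopifnot(inherits(comparison, "chc_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  err <- as_tibble(comparison$error_table)
  err$pct_gt0 <- sprintf("%.2f%%", 100 * err$n_gt0 / err$total)
  err_path <- file.path(dir, "level_errors.csv")
  readr::write_csv(err, err_path)
  stat <- comparison$stat_report
  stat <- dplyr::mutate(stat, dplyr::across(
    c("expert_mean", "predicted_mean", "difference"), ~ round(.x, 5)
  ))
  stat$p_anova <- sprintf("%.5f", stat$p_anova)
  stat$p_kw <- sprintf("%.5f", stat$p_kw)
  stat_path <- file.path(dir, "stat_report.csv")
  readr::write_csv(stat, stat_path)
  paths <- c(err_path, stat_path)
  if (!is.null(pairwise)) {
    bon_path <- file.path(dir, "bonferroni.txt")
    writeLines(utils::capture.output(print(pairwise)), bon_path)
    paths <- c(paths, bon_path)
  }
  invisible(paths)
}

#' Write a cohort or level tibble as CSV
#'
#' Plain UTF-8 CSV with dot decimal separator; a thin wrapper kept for a
#' stable on-disk interface.
#'
#' @param data A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
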