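# Results-file formats: the per-sphere results CSV (scan identifier, initial
# radius and center, final radius and center, all mm), the per-series wear
# report CSV, and a JSON summary. Lengths are written with 3 decimals (the
# design precision of the displacement table); full precision is retained
# in memory.

results_columns <- c("scan_id", "surface",
                     "initial_radius", "initial_x", "initial_y", "initial_z",
                     "final_radius", "final_x", "final_y", "final_z")

round3 <- function(df, skip = c("scan_id", "surface")) {
  for (col in setdiff(names(df), skip)) {
    if (is.numeric(df[[col]])) df[[col]] <- round(df[[col]], 3)
  }
  df
}

#' Write the sphere-fit results CSV
#'
#' Column order: scan identifier, initial radius, initial center x, y, z,
#' final radius, final center x, y, z (all mm), plus a `surface` tag
#' distinguishing cup from head rows.
#'
#' @param results Results tibble from [measurement_results()] /
#'   [run_phantom_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  if (!all(results_columns %in% names(results))) {
    stop_hipwear(sprintf("results table must have columns %s",
                         paste(results_columns, collapse = ", ")),
                 "hipwear_validation_error")
  }
  readr::write_csv(round3(results[, results_columns]), path)
  invisible(path)
}

#' Read a sphere-fit results CSV
#'
#' @param path CSV path.
#' @return Results tibble.
#' @export
read_results_csv <- function(path) {
  res <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(results_columns %in% names(res))) {
    stop_hipwear("file is not a hipwear results CSV", "hipwear_format_error")
  }
  res[, results_columns]
}

#' Write / read a wear report CSV
#'
#' Per-scan measured, expected and difference separations in mm.
#'
#' @param wear A `wear_records` tibble.
#' @param path CSV path.
#' @return `path` (write) or a `wear_records` tibble (read).
#' @export
write_wear_report <- function(wear, path) {
  readr::write_csv(round3(wear, skip = "scan_id"), path)
  invisible(path)
}

#' @rdname write_wear_report
#' @export
read_wear_report <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("scan_id", "measured_separation", "expected_separation")
  if (!all(needed %in% names(w))) {
    stop_hipwear("file is not a hipwear wear report CSV",
                 "hipwear_format_error")
  }
  wear_records(w$scan_id, w$measured_separation, w$expected_separation)
}

#' Summarise a wear study as a JSON-ready list (and optionally write it)
#'
#' Combines the 45-degree regression, summary statistics of the
#' measured-minus-expected differences, and per-surface diameter summaries.
#'
#' @param study A `wear_study` from [run_phantom_study()], or a
#'   `wear_records` tibble.
#' @param path Optional JSON output path.
#' @return The summary list, invisibly if `path` is given.
#' @export
wear_summary <- function(study, path = NULL) {
  wear <- if (inherits(study, "wear_study")) study$wear else study
  reg <- wear_regression(wear)
  out <- list(
    n_scans = nrow(wear),
    max_abs_difference_mm = max(abs(wear$difference)),
    difference_stats = as.list(summary_stats(wear$difference)),
    regression = as.list(glance(reg)))
  if (inherits(study, "wear_study")) {
    out$diameters <- lapply(split(study$diameters$diameter,
                                  study$diameters$surface),
                            function(d) as.list(summary_stats(d)))
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
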