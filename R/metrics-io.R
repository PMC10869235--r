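#' Write a per-object metrics table to CSV
#'
#' Metric columns carry their unit as a suffix in the header
#' (`volume_um3`, `surface_area_um2`, `perimeter_um`); dimensionless metrics
#' (`sphericity`, `mci`) have none. Values are written with full precision
#' and a locale-independent decimal point.
#'
#' @param table Tibble keyed by (`source_id`, `object_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  validate_metrics_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_metrics_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_metrics_table(tbl)
  tbl
}

validate_metrics_table <- function(table) {
  if (!is.data.frame(table)) abort("metrics table must be a data frame.")
  keys <- intersect(c("source_id", "object_id"), names(table))
  if (length(keys) == 2L && nrow(table) > 0) {
    if (anyDuplicated(table[, keys])) {
      abort("duplicate (source_id, object_id) keys in metrics table.",
            class = "mitomorph_validation_error")
    }
  }
  num <- vapply(table, is.numeric, TRUE)
  if (nrow(table) > 0 && any(!vapply(table[num], function(x) all(is.finite(x) | is.na(x)), TRUE))) {
    abort("non-finite values in metrics table.", class = "mitomorph_validation_error")
  }
  invisible(table)
}
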