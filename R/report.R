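# Report writers: per-patient metrics CSV, 19-row segment CSV, cohort tables.
# All geometry is reported in mm / mL world units; column order is fixed.

PATIENT_METRIC_COLS <- c(
  "infat_ml", "dense_ml", "admix_ml",
  "infat_hu", "dense_hu", "admix_hu",
  "la_vol_ml", "wall_vol_ml",
  "infat_lavol_au", "dense_lavol_au", "admix_lavol_au",
  "infat_wallvol_au", "dense_wallvol_au", "admix_wallvol_au")

#' Write the per-patient metrics report
#'
#' One CSV row with the fixed Table-3-style column order. Empty-class volumes
#' are written as 0 (never NaN); empty-class mean HU is left blank (missing).
#'
#' @param metrics a `wall_fat_metrics` row from [compute_metrics()].
#' @param path output CSV path.
#' @param patient_id optional leading id column.
#' @return `path`, invisibly.
#' @export
write_patient_report <- function(metrics, path, patient_id = NULL) {
  df <- as.data.frame(metrics)[PATIENT_METRIC_COLS]
  if (!is.null(patient_id)) df <- cbind(patient_id = patient_id, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-segment regional report (19 rows)
#' @param regional data.frame from [regional_distribution()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_report <- function(regional, path) {
  stopifnot(nrow(regional) == 19L)
  write.csv(regional, path, row.names = FALSE)
  invisible(path)
}

#' Write cohort comparison reports
#'
#' Emits the summary (group columns + p-value), pairwise and ANCOVA CSVs.
#'
#' @param comparison a `group_comparison` from [compare_groups()].
#' @param dir output directory.
#' @return named list of paths, invisibly.
#' @export
write_cohort_report <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(summary = file.path(dir, "cohort_summary.csv"),
                pairwise = file.path(dir, "cohort_pairwise.csv"),
                ancova = file.path(dir, "cohort_ancova.csv"))
  write.csv(comparison$summary, paths$summary, row.names = FALSE)
  write.csv(comparison$pairwise, paths$pairwise, row.names = FALSE)
  if (!is.null(comparison$ancova))
    write.csv(comparison$ancova, paths$ancova, row.names = FALSE)
  invisible(paths)
}
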