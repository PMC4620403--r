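# Result reports: a CSV pair (per-scar rows + patient summary row) and a
# JSON twin that round-trips the full study_metrics structure.

#' Write a study report (CSV pair + JSON twin)
#'
#' Writes `<path>_scars.csv` (one row per scar segment), `<path>_summary.csv`
#' (one patient summary row) and `<path>.json` (the full metrics object,
#' re-readable with [read_report()]).
#'
#' @param metrics a `study_metrics` (see [summarize_study()]).
#' @param path output path prefix (directories are created as needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_report <- function(metrics, path) {
  stopifnot(inherits(metrics, "study_metrics"))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  scars <- metrics$per_scar
  scar_cols <- c("patient_id", "slice_index", "scar_id", "n_pixels",
                 "delta_phi_deg", "lambda_min", "lambda_max", "delta_lambda",
                 "adherent", "segments_hit")
  if (nrow(scars)) {
    scars$patient_id <- metrics$patient_id
    scars <- scars[, scar_cols]
  } else {
    scars <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(scar_cols))), scar_cols
    )
  }
  summary <- data.frame(
    patient_id = metrics$patient_id,
    scar_size_pct_lv = metrics$scar_size_pct_lv,
    mean_delta_phi_deg = metrics$mean_delta_phi_deg,
    extent_pct_circumference = metrics$extent_pct_circumference,
    mean_delta_lambda = metrics$mean_delta_lambda,
    scarring_pct = metrics$scarring_pct
  )

  paths <- c(
    scars = paste0(path, "_scars.csv"),
    summary = paste0(path, "_summary.csv"),
    json = paste0(path, ".json")
  )
  utils::write.csv(scars, paths[["scars"]], row.names = FALSE)
  utils::write.csv(summary, paths[["summary"]], row.names = FALSE)

  payload <- unclass(metrics)
  payload$per_segment_degrees <- as.list(metrics$per_segment_degrees)
  jsonlite::write_json(payload, paths[["json"]],
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(paths)
}

#' Read a JSON study report back into a `study_metrics`
#'
#' @param path the `<prefix>.json` written by [write_report()].
#' @return a `study_metrics` object.
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  doc$per_segment_degrees <- unlist(doc$per_segment_degrees)
  doc$per_scar <- as.data.frame(doc$per_scar)
  doc$region_assignment <- as.data.frame(doc$region_assignment)
  if (!is.null(doc$ira_label) && length(doc$ira_label) == 0) doc$ira_label <- NULL
  structure(doc, class = "study_metrics")
}
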