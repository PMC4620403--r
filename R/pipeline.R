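# End-to-end pipeline and run configuration: read -> polar maps -> 3D max
# SI -> FWHM -> connected scar segments -> adherence filter -> metrics ->
# AHA allocation -> report.

#' Analysis run configuration
#'
#' @param angular_bin_deg angular bin width for the lambda normalization
#'   (degrees; default 10, wide enough that each bin samples the full wall
#'   at typical endocardial radii -- see [pixel_radial_position()]).
#' @param coverage_bin_deg bin width for the 360-degree slice-inclusion
#'   check (default 10).
#' @param connectivity scar component connectivity, 4 or 8 (default 8).
#' @param adherence_tolerance endocardial-adherence tolerance on
#'   `lambda_min`, or `NULL` for the adaptive one-radial-layer default (see
#'   [filter_endocardial_adherent()]).
#' @param assume_scar logical attestation that an operator visually
#'   confirmed a scar exists in the study. Without it, [analyze_study()]
#'   warns: the FWHM criterion applied to a scar-free study labels the
#'   brightest normal pixels as scar.
#' @param apical_anchor_deg phase of the AHA segment 14/15 border
#'   (default 345; see [aha_segment_table()]).
#' @return object of class `run_config`.
#' @export
run_config <- function(angular_bin_deg = 10,
                       coverage_bin_deg = 10,
                       connectivity = 8,
                       adherence_tolerance = NULL,
                       assume_scar = FALSE,
                       apical_anchor_deg = 345) {
  cfg <- structure(
    list(
      angular_bin_deg = angular_bin_deg,
      coverage_bin_deg = coverage_bin_deg,
      connectivity = connectivity,
      adherence_tolerance = adherence_tolerance,
      assume_scar = isTRUE(assume_scar),
      apical_anchor_deg = apical_anchor_deg
    ),
    class = "run_config"
  )
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$angular_bin_deg), cfg$angular_bin_deg > 0, cfg$angular_bin_deg <= 360,
    is.numeric(cfg$coverage_bin_deg), cfg$coverage_bin_deg > 0, cfg$coverage_bin_deg <= 360,
    cfg$connectivity %in% c(4, 8),
    is.null(cfg$adherence_tolerance) ||
      (is.numeric(cfg$adherence_tolerance) && cfg$adherence_tolerance >= 0 &&
         cfg$adherence_tolerance <= 1),
    is.numeric(cfg$apical_anchor_deg)
  )
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `overrides` (e.g. parsed
#' command-line flags) take precedence over file values.
#'
#' @param path YAML file, or `NULL` for defaults.
#' @param overrides named list of values overriding the file.
#' @return a `run_config`.
#' @export
read_config_yaml <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(run_config, vals)
}

#' Run the full scar analysis on a study
#'
#' Executes the automatic pipeline on an annotated study: myocardial
#' rasterization, polar maps (heart axis carried over to slices lacking a
#' junction point, nearest already-processed slice first, looking forward
#' when the first slices lack one), 3D max SI, FWHM thresholding, connected
#' scar segments, endocardial-adherence filtering, metrics and AHA
#' allocation.
#'
#' @param study a [patient_study()].
#' @param config a [run_config()].
#' @return list with `metrics` (a `study_metrics`), `segments` (retained),
#'   `all_segments` (flagged, including mid-wall), `polar_maps`, `masks`,
#'   `scar_masks` and `max_si`.
#' @export
analyze_study <- function(study, config = run_config()) {
  if (!config$assume_scar) {
    warning(paste(
      "assume_scar is FALSE: the FWHM criterion presumes a visually",
      "confirmed scar; on a scar-free study it labels normal bright",
      "pixels as scar"
    ), call. = FALSE)
  }
  masks <- lapply(study$slices, rasterize_myocardium)

  # heart axes: junction slices first, then carry the nearest known angle
  n <- length(study$slices)
  axes <- vector("list", n)
  has_junction <- vapply(study$slices, function(s) !is.null(s$junction), logical(1))
  for (i in seq_len(n)) {
    if (has_junction[i]) {
      axes[[i]] <- compute_heart_axis(compute_centroid(masks[[i]]),
                                      study$slices[[i]]$junction)
    }
  }
  for (i in seq_len(n)) {
    if (!has_junction[i]) {
      candidates <- which(has_junction)
      prev <- candidates[candidates < i]
      nearest <- if (length(prev)) max(prev) else min(candidates[candidates > i])
      axes[[i]] <- compute_heart_axis(compute_centroid(masks[[i]]),
                                      previous_axis = axes[[nearest]])
    }
  }

  polar_maps <- vector("list", n)
  for (i in seq_len(n)) {
    polar_maps[[i]] <- build_polar_map_from_mask(
      masks[[i]], axes[[i]], config$angular_bin_deg
    )
  }
  names(polar_maps) <- as.character(
    vapply(study$slices, `[[`, integer(1), "slice_index")
  )

  max_si <- compute_3dmax_si(study, masks)
  scar_masks <- threshold_fwhm(study, max_si, masks)

  all_segments <- list()
  for (i in seq_len(n)) {
    segs <- extract_scar_segments(
      scar_masks[[i]], polar_maps[[i]],
      slice_index = study$slices[[i]]$slice_index,
      connectivity = config$connectivity
    )
    all_segments <- c(all_segments, segs)
  }
  retained <- filter_endocardial_adherent(all_segments, config$adherence_tolerance)

  metrics <- summarize_study(
    study, retained, polar_maps, masks,
    aha_table = aha_segment_table(config$apical_anchor_deg)
  )
  list(
    metrics = metrics,
    segments = retained,
    all_segments = attr(retained, "all"),
    polar_maps = polar_maps,
    masks = masks,
    scar_masks = scar_masks,
    max_si = max_si
  )
}

#' Analyze a study from files and write its report
#'
#' Thin file-level wrapper: [read_study()] then [analyze_study()] then
#' [write_report()].
#'
#' @param image_source,annotation_source see [read_study()].
#' @param out_prefix report path prefix (see [write_report()]).
#' @param config a [run_config()].
#' @param patient_id,ira_label forwarded to [read_study()].
#' @return the analysis list from [analyze_study()], invisibly, with the
#'   written report paths attached as `report_paths`.
#' @export
analyze <- function(image_source, annotation_source, out_prefix,
                    config = run_config(), patient_id = "patient",
                    ira_label = NULL) {
  study <- read_study(image_source, annotation_source,
                      patient_id = patient_id, ira_label = ira_label,
                      config = config)
  res <- analyze_study(study, config)
  res$report_paths <- write_report(res$metrics, out_prefix)
  invisible(res)
}

#' Cohort aggregation of per-patient reports by infarct-related artery
#'
#' @param manifest data.frame with columns `patient_id`, `ira_label`, or a
#'   path to such a CSV.
#' @param reports named list of `study_metrics` (names = patient ids), or a
#'   character vector of report JSON paths (read with [read_report()]).
#' @return the per-segment percentage table from [aggregate_by_ira()].
#' @export
cohort_table <- function(manifest, reports) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("patient_id", "ira_label") %in% names(manifest)))
  if (is.character(reports)) {
    reports <- lapply(reports, read_report)
    names(reports) <- vapply(reports, `[[`, character(1), "patient_id")
  }
  missing <- setdiff(manifest$patient_id, names(reports))
  if (length(missing)) {
    stop(sprintf("no report for patient(s): %s", paste(missing, collapse = ", ")))
  }
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    deg <- reports[[manifest$patient_id[i]]]$per_segment_degrees
    rows[[i]] <- data.frame(
      patient_id = manifest$patient_id[i],
      ira_label = manifest$ira_label[i],
      segment_id = as.integer(names(deg)),
      degrees = as.numeric(deg)
    )
  }
  aggregate_by_ira(do.call(rbind, rows))
}
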