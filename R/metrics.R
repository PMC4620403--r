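# Scar quantification: smallest enclosing angular sector (endocardial
# extent, delta-phi), transmurality (delta-lambda), scar size as % of the
# analyzed LV myocardium, endocardial extent as % of the LV circumference,
# and the scarring fraction (scar area over the full-wall sectors spanned
# by the scars).

#' Smallest angular sector covering a set of phases
#'
#' The minimal sector is found via the largest gap between consecutive
#' sorted phases (wrapping through 0): the sector spans `360 - max gap` and
#' starts at the phase that follows the gap. Exact ties are broken toward
#' the smallest starting phase. A single distinct phase gives span 0.
#'
#' @param phases_deg numeric vector of angles in degrees.
#' @return list with `start` (degrees in `[0, 360)`) and `span` (degrees).
#' @export
smallest_sector <- function(phases_deg) {
  if (length(phases_deg) == 0L) stop("no phases supplied")
  u <- sort(deg_mod(phases_deg))
  n <- length(u)
  if (u[n] - u[1] == 0) return(list(start = u[1], span = 0))
  gaps <- c(diff(u), u[1] + 360 - u[n])
  gmax <- max(gaps)
  at <- which(gaps == gmax)
  starts <- ifelse(at == n, u[1], u[pmin(at + 1L, n)])
  list(start = min(starts), span = 360 - gmax)
}

#' Endocardial extent of infarction (delta-phi) of one scar segment
#'
#' The angular span of the smallest sector containing all pixels of the
#' segment (wrap through 0 degrees handled).
#'
#' @param segment a `scar_segment` (uses its stored pixel phases).
#' @param polar_map optional `polar_map` to re-derive the phases from the
#'   segment's pixel coordinates instead.
#' @return degrees in `[0, 360)`.
#' @export
endocardial_extent_angle <- function(segment, polar_map = NULL) {
  phases <- if (is.null(polar_map)) {
    segment$phi_deg
  } else {
    nr <- polar_map$dim[1]
    pos <- match(
      (segment$pixels[, "col"] - 1L) * nr + segment$pixels[, "row"],
      (polar_map$pixels$col - 1L) * nr + polar_map$pixels$row
    )
    polar_map$pixels$phi_deg[pos]
  }
  smallest_sector(phases)$span
}

#' Transmurality (delta-lambda) of one scar segment
#'
#' @param segment a `scar_segment`.
#' @return `lambda_max - lambda_min`, a fraction of the wall thickness.
#' @export
transmurality <- function(segment) {
  segment$lambda_max - segment$lambda_min
}

#' Scar size as percent of analyzed LV myocardium
#'
#' @param study a [patient_study()] (or `NULL` when `masks` given).
#' @param segments retained scar segments (numerator: their pixel counts).
#' @param masks optional precomputed myocardial masks.
#' @return percent in `[0, 100]`.
#' @export
scar_size_pct_lv <- function(study, segments, masks = NULL) {
  if (is.null(masks)) masks <- lapply(study$slices, rasterize_myocardium)
  total <- sum(vapply(masks, sum, numeric(1)))
  if (total == 0) stop("no myocardial pixels: scar size undefined")
  100 * sum(vapply(segments, `[[`, numeric(1), "n_pixels")) / total
}

#' Endocardial extent of infarction as percent of LV circumference
#'
#' The sum of all per-scar angular extents divided by 360 degrees times the
#' number of slices with at least one retained scar.
#'
#' @param segments retained scar segments.
#' @param n_slices_with_scar override for the denominator; by default the
#'   number of distinct slice indices among `segments`.
#' @return percent (0 when there are no scars).
#' @export
extent_pct_circumference <- function(segments, n_slices_with_scar = NULL) {
  if (length(segments) == 0L) return(0)
  if (is.null(n_slices_with_scar)) {
    n_slices_with_scar <- length(unique(vapply(segments, `[[`, integer(1), "slice_index")))
  }
  100 * sum(vapply(segments, `[[`, numeric(1), "delta_phi_deg")) /
    (360 * n_slices_with_scar)
}

# Myocardial pixel count of the full-wall sector spanned by a segment.
sector_pixel_count <- function(segment, polar_map, eps = 1e-9) {
  off <- deg_mod(polar_map$pixels$phi_deg - segment$sector_start_deg)
  sum(off <= segment$delta_phi_deg + eps)
}

#' Scarring fraction: scar area over the sectors surrounding the scars
#'
#' Sum of scar pixel counts divided by the summed pixel counts of the
#' full-wall myocardial sectors spanned by each scar's smallest enclosing
#' sector on its own slice. A fully transmural scar exactly filling its
#' sector gives 1.
#'
#' @param segments retained scar segments.
#' @param polar_maps named list of `polar_map`s, keyed by slice index
#'   (`as.character(slice_index)`).
#' @return ratio in `[0, 1]` (0 when there are no scars).
#' @export
scarring_pct <- function(segments, polar_maps) {
  if (length(segments) == 0L) return(0)
  sector_px <- vapply(segments, function(s) {
    pm <- polar_maps[[as.character(s$slice_index)]]
    if (is.null(pm)) stop(sprintf("no polar map for slice %d", s$slice_index))
    sector_pixel_count(s, pm)
  }, numeric(1))
  if (any(sector_px == 0)) stop("empty myocardial sector")
  sum(vapply(segments, `[[`, numeric(1), "n_pixels")) / sum(sector_px)
}

#' Patient-level summary metrics
#'
#' Aggregates retained (endocardium-adherent) scar segments into the
#' study summary: scar size as %LV, mean scar pixel count, mean angular
#' extent, endocardial extent as % of LV circumference, mean transmurality,
#' scarring fraction, and the per-AHA-segment angular sums used for
#' localization.
#'
#' @param study a [patient_study()].
#' @param segments retained scar segments (list; may carry attribute
#'   `"all"` with the unfiltered flagged segments, included in `per_scar`).
#' @param polar_maps named list of `polar_map`s keyed by slice index.
#' @param masks optional precomputed myocardial masks.
#' @param aha_table segment-boundary table (see [aha_segment_table()]).
#' @return object of class `study_metrics`.
#' @export
summarize_study <- function(study, segments, polar_maps, masks = NULL,
                            aha_table = aha_segment_table()) {
  if (is.null(masks)) masks <- lapply(study$slices, rasterize_myocardium)
  all_segments <- attr(segments, "all")
  if (is.null(all_segments)) all_segments <- segments

  slice_ids <- vapply(study$slices, `[[`, integer(1), "slice_index")
  regions <- assign_slices_to_regions(length(slice_ids))
  region_of <- stats::setNames(regions, as.character(slice_ids))

  seg_deg <- stats::setNames(numeric(16), as.character(1:16))
  rows <- list()
  for (s in all_segments) {
    region <- region_of[[as.character(s$slice_index)]]
    hit <- if (isTRUE(s$adherent)) {
      split_sector_span(s$sector_start_deg, s$delta_phi_deg, region, aha_table)
    } else {
      stats::setNames(numeric(0), character(0))
    }
    if (length(hit)) seg_deg[names(hit)] <- seg_deg[names(hit)] + hit
    rows[[length(rows) + 1L]] <- data.frame(
      slice_index = s$slice_index,
      n_pixels = s$n_pixels,
      delta_phi_deg = s$delta_phi_deg,
      sector_start_deg = s$sector_start_deg,
      lambda_min = s$lambda_min,
      lambda_max = s$lambda_max,
      delta_lambda = s$delta_lambda,
      adherent = isTRUE(s$adherent),
      region = region,
      segments_hit = paste(
        sprintf("%s:%s", names(hit), signif(hit, 8)), collapse = ";"
      )
    )
  }
  per_scar <- if (length(rows)) do.call(rbind, rows) else data.frame(
    slice_index = integer(0), n_pixels = integer(0), delta_phi_deg = numeric(0),
    sector_start_deg = numeric(0), lambda_min = numeric(0), lambda_max = numeric(0),
    delta_lambda = numeric(0), adherent = logical(0), region = character(0),
    segments_hit = character(0)
  )
  if (nrow(per_scar)) per_scar$scar_id <- seq_len(nrow(per_scar))

  n_scars <- length(segments)
  structure(
    list(
      patient_id = study$patient_id,
      ira_label = study$ira_label,
      n_slices_analyzed = length(study$slices),
      n_slices_with_scar = if (n_scars) {
        length(unique(vapply(segments, `[[`, integer(1), "slice_index")))
      } else 0L,
      n_myocardial_pixels = sum(vapply(masks, sum, numeric(1))),
      n_scar_pixels = sum(vapply(segments, `[[`, numeric(1), "n_pixels")),
      scar_size_pct_lv = scar_size_pct_lv(study, segments, masks),
      mean_scar_pixels = if (n_scars) {
        mean(vapply(segments, `[[`, numeric(1), "n_pixels"))
      } else 0,
      mean_delta_phi_deg = if (n_scars) {
        mean(vapply(segments, `[[`, numeric(1), "delta_phi_deg"))
      } else 0,
      extent_pct_circumference = extent_pct_circumference(segments),
      mean_delta_lambda = if (n_scars) {
        mean(vapply(segments, `[[`, numeric(1), "delta_lambda"))
      } else 0,
      scarring_pct = scarring_pct(segments, polar_maps),
      per_scar = per_scar,
      per_segment_degrees = seg_deg,
      region_assignment = data.frame(slice_index = slice_ids, region = regions)
    ),
    class = "study_metrics"
  )
}

#' @export
print.study_metrics <- function(x, ...) {
  cat(sprintf("<study_metrics '%s'>\n", x$patient_id))
  cat(sprintf("  slices analyzed: %d (%d with scar)\n",
              x$n_slices_analyzed, x$n_slices_with_scar))
  cat(sprintf("  scar size: %.2f %%LV (%d of %d myocardial px)\n",
              x$scar_size_pct_lv, x$n_scar_pixels, x$n_myocardial_pixels))
  cat(sprintf("  mean delta-phi: %.1f deg; endocardial extent: %.2f %% of circumference\n",
              x$mean_delta_phi_deg, x$extent_pct_circumference))
  cat(sprintf("  mean transmurality: %.3f; scarring fraction: %.3f\n",
              x$mean_delta_lambda, x$scarring_pct))
  invisible(x)
}
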