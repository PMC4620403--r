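# The AHA 17-segment model, restricted to the 16 in-plane segments the
# automatic analysis covers: slice-to-region assignment, angular segment
# boundaries per region, per-pixel segment allocation, splitting a scar
# sector across segment boundaries, and per-IRA cohort aggregation.
#
# Angles are phases relative to the heart axis (0 at the RV-LV junction,
# counterclockwise). Intervals are half-open [start, end): the start is
# inclusive, so boundary pixels resolve deterministically.

#' Angular boundary table of the 16 in-plane AHA segments
#'
#' Basal and mid regions have six 60-degree segments; the apical region has
#' four 90-degree segments whose 14/15 border sits 15 degrees clockwise of
#' the heart axis (at 345 degrees). Intervals crossing 0 are stored as two
#' rows with the same segment id. The apical anchor is configurable because
#' only the 14/15 border is pinned by the model; the other apical
#' boundaries follow as contiguous 90-degree blocks.
#'
#' @param apical_anchor_deg phase of the segment 14/15 border (default 345).
#' @return data.frame with columns `region`, `segment_id`, `start_deg`,
#'   `end_deg`; per region the half-open intervals partition `[0, 360)`.
#' @export
aha_segment_table <- function(apical_anchor_deg = 345) {
  sixty <- function(region, ids) {
    data.frame(
      region = region, segment_id = ids,
      start_deg = seq(0, 300, by = 60), end_deg = seq(60, 360, by = 60)
    )
  }
  basal <- sixty("basal", c(4L, 5L, 6L, 1L, 2L, 3L))
  mid <- sixty("mid", c(10L, 11L, 12L, 7L, 8L, 9L))
  # four contiguous 90-degree apical blocks, CCW from the 14/15 border
  edges <- deg_mod(apical_anchor_deg + c(0, 90, 180, 270))
  ids <- c(15L, 16L, 13L, 14L)
  rows <- list()
  for (i in seq_along(ids)) {
    a <- edges[i]
    b <- deg_mod(edges[i] + 90)
    if (a < b) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = "apical", segment_id = ids[i], start_deg = a, end_deg = b
      )
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        region = "apical", segment_id = ids[i],
        start_deg = c(a, 0), end_deg = c(360, b)
      )
    }
  }
  tab <- rbind(basal, mid, do.call(rbind, rows))
  tab <- tab[tab$end_deg > tab$start_deg, ]
  rownames(tab) <- NULL
  tab
}

#' Assign ordered slices to the basal/mid/apical thirds
#'
#' The LV is divided into equal thirds along the long axis. With `n` not a
#' multiple of 3, the first extra slice goes to the mid region and the
#' second to the basal region (so 6 slices give 2/2/2, 7 give 2/3/2 and 8
#' give 2/3/3, and likewise 10 -> 3/4/3, 11 -> 3/4/4). Slices are ordered
#' apex to base, so the apical block comes first.
#'
#' @param n_slices number of analyzed slices (>= 3).
#' @return character vector of length `n_slices` with values `"apical"`,
#'   `"mid"`, `"basal"` in that block order.
#' @export
assign_slices_to_regions <- function(n_slices) {
  if (n_slices < 3L) stop("region assignment requires at least 3 slices")
  base <- n_slices %/% 3L
  rem <- n_slices %% 3L
  rep(c("apical", "mid", "basal"),
      times = c(base, base + (rem >= 1L), base + (rem == 2L)))
}

#' Segment boundaries of one region
#'
#' @param region `"basal"`, `"mid"` or `"apical"`.
#' @param table boundary table (default [aha_segment_table()]).
#' @return the rows of `table` for that region.
#' @export
segment_boundaries <- function(region, table = aha_segment_table()) {
  region <- match.arg(region, c("basal", "mid", "apical"))
  out <- table[table$region == region, ]
  rownames(out) <- NULL
  out
}

#' Allocate a phase to its AHA segment
#'
#' @param phi phase(s) in degrees, wrapped into `[0, 360)`.
#' @param region `"basal"`, `"mid"` or `"apical"`.
#' @param table boundary table (default [aha_segment_table()]).
#' @return integer segment id(s) in 1..16.
#' @export
assign_pixel_to_segment <- function(phi, region, table = aha_segment_table()) {
  tab <- segment_boundaries(region, table)
  phi <- deg_mod(phi)
  out <- rep(NA_integer_, length(phi))
  for (i in seq_len(nrow(tab))) {
    hit <- phi >= tab$start_deg[i] & phi < tab$end_deg[i]
    out[hit] <- tab$segment_id[i]
  }
  out
}

# Split a sector given as (start, span) across the region's segments.
split_sector_span <- function(start, span, region, table = aha_segment_table()) {
  tab <- segment_boundaries(region, table)
  if (span <= 0) return(stats::setNames(numeric(0), character(0)))
  if (span > 360) stop("sector span exceeds 360 degrees")
  s <- deg_mod(start)
  e <- s + span
  acc <- stats::setNames(numeric(0), character(0))
  for (i in seq_len(nrow(tab))) {
    ov <- 0
    for (k in c(0, 360)) {
      ov <- ov + max(0, min(e, tab$end_deg[i] + k) - max(s, tab$start_deg[i] + k))
    }
    if (ov > 0) {
      id <- as.character(tab$segment_id[i])
      acc[id] <- if (id %in% names(acc)) acc[[id]] + ov else ov
    }
  }
  acc[order(as.integer(names(acc)))]
}

#' Split a scar sector across AHA segment boundaries
#'
#' The sector runs counterclockwise from `sector_start` to `sector_end`
#' (wrapping through 0 when needed); each intersected segment receives the
#' angular length of the overlap, and the contributions sum to the sector
#' span. A degenerate sector (equal start and end) yields an empty result.
#'
#' @param sector_start,sector_end degrees.
#' @param region `"basal"`, `"mid"` or `"apical"`.
#' @param table boundary table (default [aha_segment_table()]).
#' @return named numeric vector: degrees per intersected segment id.
#' @export
split_sector_across_segments <- function(sector_start, sector_end, region,
                                         table = aha_segment_table()) {
  span <- deg_mod(sector_end - sector_start)
  split_sector_span(sector_start, span, region, table)
}

#' Per-IRA aggregation of segmental scar involvement
#'
#' For every AHA segment, the percentage of the cohort's total angular scar
#' involvement in that segment contributed by patients with each
#' infarct-related artery. Percentages per segment sum to 100 whenever the
#' segment has any involvement; segments with none are flagged and their
#' percentages left `NA`.
#'
#' @param cohort long-format data.frame with columns `patient_id`,
#'   `ira_label` (`LAD`/`RCA`/`LCX`), `segment_id`, `degrees` (>= 0).
#' @return data.frame with one row per segment 1..16: `segment_id`, one
#'   percentage column per artery, `total_degrees`, `has_scar`.
#' @export
aggregate_by_ira <- function(cohort) {
  stopifnot(all(c("patient_id", "ira_label", "segment_id", "degrees") %in% names(cohort)))
  if (any(cohort$degrees < 0)) stop("degree sums must be non-negative")
  arteries <- c("LAD", "RCA", "LCX")
  bad <- setdiff(unique(cohort$ira_label), arteries)
  if (length(bad)) stop(sprintf("unknown IRA label(s): %s", paste(bad, collapse = ", ")))
  out <- data.frame(segment_id = 1:16)
  sums <- matrix(0, nrow = 16, ncol = length(arteries),
                 dimnames = list(NULL, arteries))
  for (a in arteries) {
    sub <- cohort[cohort$ira_label == a, ]
    if (nrow(sub)) {
      agg <- tapply(sub$degrees, sub$segment_id, sum)
      sums[as.integer(names(agg)), a] <- agg
    }
  }
  total <- rowSums(sums)
  for (a in arteries) {
    out[[a]] <- ifelse(total > 0, 100 * sums[, a] / total, NA_real_)
  }
  out$total_degrees <- total
  out$has_scar <- total > 0
  out
}

#' Visual rule for apical-cap (segment 17) scar
#'
#' Segment 17 is not part of the automatic in-plane analysis; it is judged
#' visually on long-axis views, scar being present when enhancement covers
#' more than half (> 180 degrees) of the segment's circumferential extent.
#' This helper encodes that predicate for a user-supplied measurement.
#'
#' @param circumferential_extent_deg visually measured enhancement extent.
#' @return logical.
#' @export
segment17_visual_scar <- function(circumferential_extent_deg) {
  circumferential_extent_deg > 180
}
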