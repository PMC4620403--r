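# FWHM scar segmentation: study-wide maximum signal intensity (3D max SI),
# half-max thresholding inside the myocardial mask, connected-component
# extraction of scar segments, and the endocardial-adherence filter.

#' Study-wide maximum myocardial signal intensity (3D max SI)
#'
#' The maximum SI over the union of the myocardial pixels of all retained
#' slices. This value anchors the FWHM criterion; the method presumes an
#' operator has visually confirmed that a scar exists somewhere in the
#' study (see `assume_scar` in [run_config()]).
#'
#' @param study a [patient_study()].
#' @param masks optional list of precomputed myocardial masks (same order
#'   as `study$slices`).
#' @return the maximum myocardial SI (positive scalar).
#' @export
compute_3dmax_si <- function(study, masks = NULL) {
  if (length(study$slices) == 0L) stop("empty study")
  if (is.null(masks)) masks <- lapply(study$slices, rasterize_myocardium)
  vals <- unlist(Map(function(s, m) s$si[m], study$slices, masks))
  if (length(vals) == 0L) stop("no myocardial pixels in study")
  max(vals)
}

#' FWHM scar thresholding
#'
#' A myocardial pixel is labelled scar when its SI is at least half the
#' study-wide maximum (inclusive: SI exactly equal to 0.5 * max is scar).
#' The criterion is relative, so rescaling all intensities by a positive
#' constant leaves the mask unchanged.
#'
#' @param study a [patient_study()].
#' @param max_si the 3D max SI (see [compute_3dmax_si()]).
#' @param masks optional precomputed myocardial masks.
#' @return list of logical scar masks, one per slice.
#' @export
threshold_fwhm <- function(study, max_si, masks = NULL) {
  if (!is.numeric(max_si) || max_si <= 0) stop("max_si must be positive")
  if (is.null(masks)) masks <- lapply(study$slices, rasterize_myocardium)
  Map(function(s, m) m & (s$si >= 0.5 * max_si), study$slices, masks)
}

#' Label connected components of a binary mask
#'
#' Components are computed on the pixel-adjacency graph (via
#' \pkg{igraph}); connectivity 8 joins pixels sharing an edge or a corner,
#' connectivity 4 only those sharing an edge.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix: 0 for background, 1..k component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    nb <- mask[j]
    edges <- c(edges, rbind(vid[idx[ok]][nb], vid[j][nb]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Extract connected scar segments from a slice's scar mask
#'
#' A scar segment is a connected group of at least `min_pixels` scar
#' pixels (default 2: an isolated bright pixel is treated as a possible
#' artifact and discarded). Each segment carries its per-pixel phases and
#' radial positions from the polar map, its lambda statistics, and its
#' smallest enclosing angular sector.
#'
#' @param scar_mask logical scar mask of one slice.
#' @param polar_map the slice's [build_polar_map()] result (every scar
#'   pixel must be a myocardial pixel of this map).
#' @param slice_index integer identifier stored on the segments.
#' @param connectivity 4 or 8 (default 8).
#' @param min_pixels minimum component size retained (default 2).
#' @return list of `scar_segment` objects (possibly empty).
#' @export
extract_scar_segments <- function(scar_mask, polar_map, slice_index = 0L,
                                  connectivity = 8, min_pixels = 2L) {
  lab <- label_components(scar_mask, connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  nr <- nrow(scar_mask)
  map_key <- (polar_map$pixels$col - 1L) * nr + polar_map$pixels$row
  out <- list()
  for (comp in seq_len(k)) {
    idx <- which(lab == comp)
    if (length(idx) < min_pixels) next
    pos <- match(idx, map_key)
    if (anyNA(pos)) stop("scar mask contains pixels outside the myocardial polar map")
    px <- polar_map$pixels[pos, , drop = FALSE]
    sector <- smallest_sector(px$phi_deg)
    lam_min_i <- which.min(px$lam)
    seg <- structure(
      list(
        slice_index = as.integer(slice_index),
        pixels = cbind(row = px$row, col = px$col),
        n_pixels = nrow(px),
        phi_deg = px$phi_deg,
        lam = px$lam,
        lambda_min = min(px$lam),
        lambda_max = max(px$lam),
        delta_lambda = max(px$lam) - min(px$lam),
        delta_phi_deg = sector$span,
        sector_start_deg = sector$start,
        # wall thickness (px) of the bin where lambda_min is attained;
        # drives the default adherence tolerance (innermost radial layer)
        min_bin_thickness = px$bin_thickness[lam_min_i],
        adherent = NA
      ),
      class = "scar_segment"
    )
    out[[length(out) + 1L]] <- seg
  }
  out
}

#' @export
print.scar_segment <- function(x, ...) {
  cat(sprintf(
    "<scar_segment> slice %d, %d px, dphi %.1f deg, lambda [%.3f, %.3f]%s\n",
    x$slice_index, x$n_pixels, x$delta_phi_deg, x$lambda_min, x$lambda_max,
    if (is.na(x$adherent)) "" else if (x$adherent) ", endocardium-adherent" else ", mid-wall"
  ))
  invisible(x)
}

#' Endocardial-adherence filter
#'
#' Scars touching the endocardial border (minimum lambda of 0, up to a
#' tolerance) are the ischemic-pattern scars the method localizes; mid-wall
#' enhancement is excluded. With `tolerance = NULL` the tolerance adapts to
#' rasterization: a segment counts as adherent when its minimum lambda lies
#' within the innermost discrete radial layer of its angular bin, i.e.
#' `lambda_min <= 1 / wall thickness in pixels`.
#'
#' @param segments list of `scar_segment`.
#' @param tolerance numeric adherence tolerance on `lambda_min`, or `NULL`
#'   for the per-segment one-radial-layer default.
#' @return the adherent segments, each with the `adherent` flag set; the
#'   full flagged list is attached as attribute `"all"`.
#' @export
filter_endocardial_adherent <- function(segments, tolerance = NULL) {
  flagged <- lapply(segments, function(s) {
    tol <- if (is.null(tolerance)) {
      if (s$min_bin_thickness >= 1) 1 / s$min_bin_thickness else 0
    } else {
      tolerance
    }
    s$adherent <- s$lambda_min <= tol
    s
  })
  kept <- flagged[vapply(flagged, `[[`, logical(1), "adherent")]
  attr(kept, "all") <- flagged
  kept
}
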