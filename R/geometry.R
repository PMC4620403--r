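# Polar parameterization of the myocardium: centroid, heart axis, per-pixel
# angular phase phi and normalized radial wall position lambda.

#' Centroid of a binary myocardial mask
#'
#' Arithmetic mean of the (row, col) coordinates of all mask pixels,
#' real-valued (not snapped to the pixel grid).
#'
#' @param mask logical matrix, `TRUE` on myocardium.
#' @return numeric `(row, col)` centroid.
#' @export
compute_centroid <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0L) stop("empty myocardial mask: centroid undefined")
  c(row = mean(pix[, 1]), col = mean(pix[, 2]))
}

#' Heart axis of a slice
#'
#' The heart axis is the line from the myocardial centroid toward the
#' manually marked RV-LV junction point; it defines the zero direction of
#' the angular phase. When the junction is not visible on a slice, the
#' reference *angle* is carried over from another slice's axis (the
#' centroid always comes from the current slice, because centroids shift
#' between slices while the axis direction is the invariant the method
#' needs).
#'
#' @param centroid numeric `(row, col)` myocardial centroid of this slice.
#' @param junction optional `(row, col)` RV-LV junction point.
#' @param previous_axis optional `heart_axis` to copy the reference angle
#'   from when `junction` is absent.
#' @return an object of class `heart_axis` with fields `centroid` and
#'   `reference_angle_deg`.
#' @export
compute_heart_axis <- function(centroid, junction = NULL, previous_axis = NULL) {
  if (!is.null(junction)) {
    if (sqrt(sum((junction - centroid)^2)) < 1e-9) {
      stop("junction point coincides with centroid: heart axis undefined")
    }
    ref <- direction_deg(centroid, junction)
  } else if (!is.null(previous_axis)) {
    ref <- previous_axis$reference_angle_deg
  } else {
    stop("heart axis requires a junction point or a previous slice's axis")
  }
  structure(
    list(centroid = as.numeric(centroid), reference_angle_deg = unname(ref)),
    class = "heart_axis"
  )
}

#' @export
print.heart_axis <- function(x, ...) {
  cat(sprintf(
    "<heart_axis> centroid (%.2f, %.2f), reference angle %.2f deg\n",
    x$centroid[1], x$centroid[2], x$reference_angle_deg
  ))
  invisible(x)
}

#' Angular phase of pixels relative to the heart axis
#'
#' Counterclockwise (screen convention, see [direction_deg()]) angle from
#' the heart-axis direction to the centroid-to-pixel direction, wrapped to
#' `[0, 360)`.
#'
#' @param pixel `(row, col)` coordinate or an n x 2 matrix of coordinates.
#' @param axis a `heart_axis`.
#' @return phase(s) in degrees in `[0, 360)`.
#' @export
pixel_phase <- function(pixel, axis) {
  deg_mod(direction_deg(axis$centroid, pixel) - axis$reference_angle_deg)
}

#' Normalized radial wall position of one myocardial pixel
#'
#' Within the angular bin containing the pixel's phase, the minimum and
#' maximum centroid distances over myocardial pixels define the local
#' endocardial (lambda = 0) and epicardial (lambda = 1) radii; the pixel's
#' lambda interpolates linearly between them. Degenerate bins (a single
#' radius) give lambda = 0.
#'
#' @param pixel `(row, col)` coordinate, must lie in `mask`.
#' @param mask logical myocardial mask.
#' @param axis a `heart_axis`.
#' @param angular_bin_deg bin width in degrees (default 10). The bin must be
#'   wide enough that its arc at the endocardial radius spans about two
#'   pixels (`bin >= 2 * 180 / (pi * r_endo)`), otherwise the per-bin
#'   min/max radii under-sample the wall and lambda is biased.
#' @return lambda in `[0, 1]`.
#' @export
pixel_radial_position <- function(pixel, mask, axis, angular_bin_deg = 10) {
  if (!isTRUE(mask[pixel[1], pixel[2]])) {
    stop("pixel is outside the myocardial mask")
  }
  pm <- build_polar_map_from_mask(mask, axis, angular_bin_deg)
  i <- match(
    (pixel[2] - 1) * nrow(mask) + pixel[1],
    (pm$pixels$col - 1) * nrow(mask) + pm$pixels$row
  )
  pm$pixels$lam[i]
}

# Core polar-map construction over a mask and a given axis.
build_polar_map_from_mask <- function(mask, axis, angular_bin_deg = 10) {
  stopifnot(angular_bin_deg > 0, angular_bin_deg <= 360)
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0L) stop("empty myocardial mask")
  dr <- pix[, 1] - axis$centroid[1]
  dc <- pix[, 2] - axis$centroid[2]
  r <- sqrt(dr^2 + dc^2)
  if (any(r < 1e-9)) stop("a myocardial pixel coincides with the centroid")
  phi <- pixel_phase(pix, axis)
  n_bins <- as.integer(ceiling(360 / angular_bin_deg))
  bin <- pmin(floor(phi / angular_bin_deg), n_bins - 1L) + 1L
  r_min <- stats::ave(r, bin, FUN = min)
  r_max <- stats::ave(r, bin, FUN = max)
  thick <- r_max - r_min
  lam <- ifelse(thick > 0, (r - r_min) / thick, 0)
  structure(
    list(
      pixels = data.frame(
        row = unname(pix[, 1]), col = unname(pix[, 2]),
        r = r, phi_deg = phi, lam = lam,
        bin = bin, bin_thickness = thick
      ),
      heart_axis = axis,
      angular_bin_deg = angular_bin_deg,
      dim = dim(mask)
    ),
    class = "polar_map"
  )
}

#' Polar map of one annotated slice
#'
#' Computes phi and lambda for every myocardial pixel of the slice. The
#' heart axis is derived from the slice's junction point unless an `axis`
#' (e.g. carried over from a neighbouring slice) is supplied.
#'
#' @param slice an [annotated_slice()].
#' @param angular_bin_deg angular bin width for the lambda normalization.
#' @param axis optional precomputed `heart_axis`.
#' @param mask optional precomputed myocardial mask (recomputed otherwise).
#' @return an object of class `polar_map`: a per-pixel table (`row`, `col`,
#'   `r`, `phi_deg`, `lam`, `bin`, `bin_thickness`) plus the axis and the
#'   bin width.
#' @export
build_polar_map <- function(slice, angular_bin_deg = 10, axis = NULL, mask = NULL) {
  if (is.null(mask)) mask <- rasterize_myocardium(slice)
  if (is.null(axis)) {
    if (is.null(slice$junction)) {
      stop("slice has no junction point; supply `axis` from a neighbouring slice")
    }
    axis <- compute_heart_axis(compute_centroid(mask), slice$junction)
  } else {
    # re-anchor the carried-over angle on this slice's own centroid
    axis <- compute_heart_axis(compute_centroid(mask), previous_axis = axis)
  }
  build_polar_map_from_mask(mask, axis, angular_bin_deg)
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf(
    "<polar_map> %d myocardial pixels, %g deg bins, reference angle %.2f deg\n",
    nrow(x$pixels), x$angular_bin_deg, x$heart_axis$reference_angle_deg
  ))
  invisible(x)
}

# TRUE when the mask has myocardium in every angular coverage bin
# (the 360-degree slice-inclusion rule).
has_full_angular_coverage <- function(mask, coverage_bin_deg = 10) {
  cen <- compute_centroid(mask)
  pix <- which(mask, arr.ind = TRUE)
  ang <- direction_deg(cen, pix)
  n_bins <- as.integer(ceiling(360 / coverage_bin_deg))
  bins <- pmin(floor(ang / coverage_bin_deg), n_bins - 1L)
  length(unique(bins)) == n_bins
}
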