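# Reading annotated studies (image stacks + contour/junction sidecar JSON),
# rasterizing contours into myocardial masks, and writing result reports.
#
# Pixel coordinates are (row, col); internally 1-based (R matrices), while
# the JSON sidecar on disk uses the 0-based convention of the interchange
# schema. Pixel membership is decided by pixel-center-in-polygon.

#' One annotated short-axis slice
#'
#' @param si numeric matrix of non-negative signal intensities.
#' @param endo endocardial contour: n x 2 matrix of `(row, col)` vertices
#'   (1-based pixel units, >= 3 vertices, simple closed polygon).
#' @param epi epicardial contour, same format; must enclose `endo`.
#' @param junction optional `(row, col)` RV-LV junction point.
#' @param slice_index integer slice identifier, 0-based, ascending
#'   apex-to-base.
#' @param pixel_spacing_mm length-2 positive `(row, col)` spacing in mm.
#' @param validate check the contour invariants (default `TRUE`).
#' @return an object of class `annotated_slice`.
#' @export
annotated_slice <- function(si, endo, epi, junction = NULL, slice_index = 0L,
                            pixel_spacing_mm = c(1, 1), validate = TRUE) {
  si <- as.matrix(si)
  endo <- open_polygon(endo)
  epi <- open_polygon(epi)
  s <- structure(
    list(
      slice_index = as.integer(slice_index),
      si = si, endo = endo, epi = epi,
      junction = if (!is.null(junction)) as.numeric(junction),
      pixel_spacing_mm = as.numeric(pixel_spacing_mm)
    ),
    class = "annotated_slice"
  )
  if (validate) validate_annotated_slice(s)
  s
}

validate_annotated_slice <- function(s) {
  if (any(s$si < 0)) stop("signal intensities must be non-negative")
  if (any(s$pixel_spacing_mm <= 0)) stop("pixel spacing must be positive")
  for (nm in c("endo", "epi")) {
    p <- s[[nm]]
    if (nrow(p) < 3L) stop(sprintf("%s contour needs >= 3 vertices", nm))
    if (!is_simple_polygon(p)) {
      stop(sprintf("%s contour is self-intersecting (slice %d)", nm, s$slice_index))
    }
  }
  if (!all(points_in_polygon(s$endo, s$epi))) {
    stop(sprintf(
      "endocardial contour is not inside the epicardial contour (slice %d)",
      s$slice_index
    ))
  }
  invisible(s)
}

#' @export
print.annotated_slice <- function(x, ...) {
  cat(sprintf(
    "<annotated_slice %d> %dx%d image, endo %d / epi %d vertices, junction %s\n",
    x$slice_index, nrow(x$si), ncol(x$si), nrow(x$endo), nrow(x$epi),
    if (is.null(x$junction)) "absent" else sprintf("(%g, %g)", x$junction[1], x$junction[2])
  ))
  invisible(x)
}

#' A patient study: ordered annotated slices
#'
#' @param slices list of [annotated_slice()], ordered apex-to-base.
#' @param patient_id character identifier.
#' @param ira_label optional infarct-related artery: `"LAD"`, `"RCA"` or
#'   `"LCX"`.
#' @return object of class `patient_study`.
#' @export
patient_study <- function(slices, patient_id = "patient", ira_label = NULL) {
  ord <- order(vapply(slices, function(s) s$slice_index, integer(1)))
  slices <- slices[ord]
  if (!is.null(ira_label)) ira_label <- match.arg(ira_label, c("LAD", "RCA", "LCX"))
  if (!any(vapply(slices, function(s) !is.null(s$junction), logical(1)))) {
    stop("no slice carries a junction point: heart axis undefined for the study")
  }
  structure(
    list(patient_id = patient_id, ira_label = ira_label, slices = slices),
    class = "patient_study"
  )
}

#' @export
print.patient_study <- function(x, ...) {
  cat(sprintf(
    "<patient_study '%s'> %d slices%s\n", x$patient_id, length(x$slices),
    if (is.null(x$ira_label)) "" else paste0(", IRA ", x$ira_label)
  ))
  invisible(x)
}

#' Read a contour annotation sidecar file
#'
#' Schema (0-based `[row, col]` coordinates on disk):
#' `{"slices":[{"slice_index":int,"endo":[[r,c],...],"epi":[[r,c],...],`
#' `"junction":[r,c]|null}]}`.
#'
#' @param path JSON file.
#' @return list with one element per slice: `slice_index`, `endo`, `epi`
#'   (1-based matrices), `junction` (1-based or `NULL`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$slices)) stop("annotation file has no 'slices' field")
  as_coord_matrix <- function(x) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
  lapply(doc$slices, function(sl) {
    list(
      slice_index = as.integer(sl$slice_index),
      endo = as_coord_matrix(sl$endo) + 1,
      epi = as_coord_matrix(sl$epi) + 1,
      junction = if (!is.null(sl$junction)) as.numeric(sl$junction) + 1
    )
  })
}

#' Write a contour annotation sidecar file
#'
#' Inverse of [read_annotations()]; converts the internal 1-based
#' coordinates back to the 0-based on-disk schema.
#'
#' @param slices list of [annotated_slice()] (or bare lists with
#'   `slice_index`, `endo`, `epi`, `junction`).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(slices, path) {
  doc <- list(slices = lapply(slices, function(s) {
    list(
      slice_index = s$slice_index,
      endo = unname(s$endo - 1),
      epi = unname(s$epi - 1),
      junction = if (!is.null(s$junction)) unname(s$junction - 1)
    )
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an annotated patient study
#'
#' `image_source` is either a directory containing a DICOM series (one file
#' per slice, matched to annotations via sorted InstanceNumber) or a list of
#' signal-intensity matrices (matched to annotations by position after
#' sorting annotations by `slice_index`). Slices whose myocardium does not
#' cover all 360 degrees are dropped with a warning, mirroring the
#' slice-inclusion rule for the complex myocardium/connective-tissue mix at
#' the base of the heart.
#'
#' @param image_source DICOM directory path or list of matrices.
#' @param annotation_source path to the annotation JSON (or a pre-parsed
#'   list as returned by [read_annotations()]).
#' @param patient_id,ira_label passed to [patient_study()].
#' @param config a [run_config()] (uses `coverage_bin_deg`).
#' @return a `patient_study`, slices sorted apex-to-base.
#' @export
read_study <- function(image_source, annotation_source,
                       patient_id = "patient", ira_label = NULL,
                       config = run_config()) {
  ann <- if (is.character(annotation_source)) {
    read_annotations(annotation_source)
  } else {
    annotation_source
  }
  ann <- ann[order(vapply(ann, function(a) a$slice_index, integer(1)))]

  if (is.character(image_source)) {
    series <- read_dicom_series(image_source)
    images <- lapply(series, `[[`, "si")
    spacings <- lapply(series, `[[`, "pixel_spacing_mm")
  } else if (is.list(image_source)) {
    images <- lapply(image_source, as.matrix)
    spacings <- rep(list(c(1, 1)), length(images))
  } else {
    stop("image_source must be a DICOM directory or a list of matrices")
  }

  if (length(ann) > length(images)) {
    extra <- vapply(ann, function(a) a$slice_index, integer(1))
    stop(sprintf(
      "annotation without image: %d annotations but %d images (slice indices %s)",
      length(ann), length(images), paste(extra, collapse = ", ")
    ))
  }
  if (length(images) > length(ann)) {
    stop(sprintf(
      "missing annotation for %d of %d image slices",
      length(images) - length(ann), length(images)
    ))
  }

  slices <- vector("list", length(ann))
  for (i in seq_along(ann)) {
    slices[[i]] <- annotated_slice(
      si = images[[i]],
      endo = ann[[i]]$endo, epi = ann[[i]]$epi,
      junction = ann[[i]]$junction,
      slice_index = ann[[i]]$slice_index,
      pixel_spacing_mm = spacings[[i]]
    )
  }

  keep <- vapply(slices, function(s) {
    mask <- rasterize_myocardium(s)
    ok <- has_full_angular_coverage(mask, config$coverage_bin_deg)
    if (!ok) {
      warning(sprintf(
        "slice %d dropped: myocardium does not cover all 360 degrees",
        s$slice_index
      ), call. = FALSE)
    }
    ok
  }, logical(1))

  if (!any(keep)) stop("no slice passes the 360-degree myocardium check")
  patient_study(slices[keep], patient_id = patient_id, ira_label = ira_label)
}

#' Rasterize the myocardial annulus of a slice
#'
#' A pixel belongs to the myocardium when its center lies inside the
#' epicardial contour and outside the endocardial contour.
#'
#' @param slice an [annotated_slice()].
#' @return logical matrix with the dimensions of `slice$si`.
#' @export
rasterize_myocardium <- function(slice) {
  d <- dim(slice$si)
  rmin <- max(1L, floor(min(slice$epi[, 1])))
  rmax <- min(d[1], ceiling(max(slice$epi[, 1])))
  cmin <- max(1L, floor(min(slice$epi[, 2])))
  cmax <- min(d[2], ceiling(max(slice$epi[, 2])))
  if (rmin > rmax || cmin > cmax) stop("epicardial contour outside the image")
  pts <- as.matrix(expand.grid(row = rmin:rmax, col = cmin:cmax))
  inside <- points_in_polygon(pts, slice$epi) & !points_in_polygon(pts, slice$endo)
  mask <- matrix(FALSE, d[1], d[2])
  mask[pts[inside, , drop = FALSE]] <- TRUE
  if (!any(mask)) stop("degenerate contours: empty myocardial mask")
  mask
}
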