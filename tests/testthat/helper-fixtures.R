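# Shared fixtures: small fast phantoms and crafted contour geometries.

# Small phantom used by most unit tests (96 px images, wall 12 -> 20 px).
small_phantom_spec <- function(..., seed = 42L) {
  args <- list(...)
  defaults <- list(
    n_slices = 6L, image_size = 96L, centroid = c(48, 48),
    r_endo = 12, r_epi = 20, junction_angle_deg = 90,
    seed = seed
  )
  defaults[names(args)] <- args
  if (!"scars" %in% names(args)) {
    defaults$scars <- list(list(
      slice_indices = seq_len(min(3L, defaults$n_slices - 1L)),
      phi_start_deg = 20, phi_end_deg = 80, lambda_depth = 0.6
    ))
  }
  do.call(phantom_spec, defaults)
}

# Circle contour in (row, col), screen-CCW.
circle_poly <- function(center, radius, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] - radius * sin(th), center[2] + radius * cos(th))
}

# Point at a given screen-CCW direction and distance from an origin.
point_at <- function(origin, angle_deg, dist) {
  th <- angle_deg * pi / 180
  origin + dist * c(-sin(th), cos(th))
}

# Annulus slice whose endocardium hugs the epicardium over a sector,
# leaving an angular gap with no myocardial pixels.
gap_annulus_slice <- function(size = 96, center = c(48, 48), r_endo = 12,
                              r_epi = 20, gap = c(0, 30), slice_index = 0L,
                              n = 360L) {
  th_deg <- seq(0, 360, length.out = n + 1L)[-(n + 1L)]
  in_gap <- deg_mod(th_deg - gap[1]) <= deg_mod(gap[2] - gap[1])
  r <- ifelse(in_gap, r_epi - 0.4, r_endo)
  th <- th_deg * pi / 180
  endo <- cbind(center[1] - r * sin(th), center[2] + r * cos(th))
  epi <- circle_poly(center, r_epi, 144L)
  annotated_slice(
    si = matrix(100, size, size), endo = endo, epi = epi,
    junction = point_at(center, 90, 1.5 * r_epi),
    slice_index = slice_index, validate = FALSE
  )
}

# Plain annulus slice with constant SI.
annulus_slice <- function(size = 96, center = c(48, 48), r_endo = 12,
                          r_epi = 20, si_value = 100, junction_angle = 90,
                          slice_index = 0L, n = 144L) {
  annotated_slice(
    si = matrix(si_value, size, size),
    endo = circle_poly(center, r_endo, n),
    epi = circle_poly(center, r_epi, n),
    junction = point_at(center, junction_angle, 1.5 * r_epi),
    slice_index = slice_index
  )
}
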