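make_segment <- function(phi, lam, slice_index = 0L) {
  sector <- smallest_sector(phi)
  structure(
    list(
      slice_index = as.integer(slice_index),
      pixels = cbind(row = seq_along(phi), col = seq_along(phi)),
      n_pixels = length(phi), phi_deg = phi, lam = lam,
      lambda_min = min(lam), lambda_max = max(lam),
      delta_lambda = max(lam) - min(lam),
      delta_phi_deg = sector$span, sector_start_deg = sector$start,
      min_bin_thickness = 10, adherent = TRUE
    ),
    class = "scar_segment"
  )
}

test_that("the smallest enclosing sector handles simple, wrapped and degenerate sets", {
  expect_equal(smallest_sector(c(10, 20, 30)), list(start = 10, span = 20))
  expect_equal(smallest_sector(c(350, 5)), list(start = 350, span = 15))
  expect_equal(smallest_sector(rep(42, 4)), list(start = 42, span = 0))
  expect_error(smallest_sector(numeric(0)), "no phases")
})

test_that("the smallest sector matches the O(n^2) brute force on random sets", {
  set.seed(3)
  for (i in 1:50) {
    ph <- runif(sample(2:50, 1), 0, 360)
    got <- smallest_sector(ph)
    want <- brute_smallest_sector(ph)
    expect_equal(got$span, want$span, tolerance = 1e-9)
    expect_equal(got$start, want$start, tolerance = 1e-9)
  }
})

test_that("transmurality is the lambda range and recovers the phantom depth", {
  expect_equal(transmurality(make_segment(c(1, 2), c(0, 1))), 1)
  expect_equal(transmurality(make_segment(c(1, 2), c(0, 0.5))), 0.5)
  depth <- 0.6
  ph <- generate_phantom(small_phantom_spec(
    scars = list(list(slice_indices = 1L, phi_start_deg = 40, phi_end_deg = 130,
                      lambda_depth = depth)),
    noise_sd = 0
  ))
  res <- analyze_study(ph$study, run_config(assume_scar = TRUE))
  layer <- 1 / (20 - 12)  # one radial pixel layer of this wall
  expect_lt(abs(transmurality(res$segments[[1]]) - depth), layer)
})

test_that("scar size as %LV is the pixel ratio and recovers the phantom area", {
  segs <- list(make_segment(runif(100, 10, 50), runif(100)))
  masks <- list(matrix(TRUE, 20, 50))  # 1000 myocardial pixels
  expect_equal(scar_size_pct_lv(NULL, segs, masks = masks), 10)
  expect_equal(scar_size_pct_lv(NULL, list(), masks = masks), 0)
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  res <- analyze_study(ph$study, run_config(assume_scar = TRUE))
  expect_lt(
    abs(res$metrics$scar_size_pct_lv - 100 * ph$truth$area_fraction), 1
  )
})

test_that("endocardial extent as % of circumference divides by slices with scar", {
  one <- list(make_segment(c(0, 90), runif(2), slice_index = 0L))
  expect_equal(extent_pct_circumference(one), 25)
  two <- list(
    make_segment(c(0, 60), runif(2), slice_index = 0L),
    make_segment(c(0, 120), runif(2), slice_index = 1L)
  )
  expect_equal(extent_pct_circumference(two), 25)
  expect_equal(extent_pct_circumference(list()), 0)
  # identical 45-degree scar on 4 of 6 slices -> 12.5%
  ph <- generate_phantom(small_phantom_spec(
    scars = list(list(slice_indices = 1:4, phi_start_deg = 100,
                      phi_end_deg = 145, lambda_depth = 1)),
    noise_sd = 0
  ))
  res <- analyze_study(ph$study, run_config(assume_scar = TRUE))
  expect_equal(res$metrics$n_slices_with_scar, 4L)
  # discretization clips the measured span by up to ~a pixel's angle per end
  expect_equal(res$metrics$extent_pct_circumference, 12.5, tolerance = 0.1)
})

test_that("scarring fraction is scar area over the spanned full-wall sectors", {
  # fully transmural scar exactly filling its sector
  ph_full <- generate_phantom(small_phantom_spec(
    scars = list(list(slice_indices = 1L, phi_start_deg = 30, phi_end_deg = 120,
                      lambda_depth = 1)),
    noise_sd = 0
  ))
  res_full <- analyze_study(ph_full$study, run_config(assume_scar = TRUE))
  expect_equal(res_full$metrics$scarring_pct, 1)
  # half-depth scar: ratio equals the annular-area fraction of the inner half
  r1 <- 12; r2 <- 20; rm <- r1 + 0.5 * (r2 - r1)
  analytic <- (rm^2 - r1^2) / (r2^2 - r1^2)
  ph_half <- generate_phantom(small_phantom_spec(
    scars = list(list(slice_indices = 1L, phi_start_deg = 30, phi_end_deg = 120,
                      lambda_depth = 0.5)),
    noise_sd = 0
  ))
  res_half <- analyze_study(ph_half$study, run_config(assume_scar = TRUE))
  expect_equal(res_half$metrics$scarring_pct, analytic, tolerance = 0.05)
  expect_lt(abs(res_half$metrics$scarring_pct - 0.5), 0.12)
})

test_that("study summary averages per-scar metrics over retained segments", {
  ph <- generate_phantom(small_phantom_spec())
  res <- analyze_study(ph$study, run_config(assume_scar = TRUE))
  segs <- list(
    make_segment(c(10, 40), c(0, 0.5), slice_index = 0L),
    make_segment(c(100, 150), c(0, 0.9), slice_index = 1L)
  )
  m <- summarize_study(ph$study, segs, res$polar_maps, res$masks)
  expect_equal(m$mean_delta_phi_deg, 40)
  expect_equal(m$mean_delta_lambda, 0.7)
  single <- summarize_study(ph$study, segs[1], res$polar_maps, res$masks)
  expect_equal(single$mean_delta_phi_deg, segs[[1]]$delta_phi_deg)
  expect_equal(single$mean_delta_lambda, segs[[1]]$delta_lambda)
})

test_that("adding a scar pixel never decreases extent, transmurality or size", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:40, 1)
    phi <- runif(n, 0, 360)
    lam <- runif(n)
    span0 <- smallest_sector(phi)$span
    lam_rng0 <- max(lam) - min(lam)
    phi2 <- c(phi, runif(1, 0, 360))
    lam2 <- c(lam, runif(1))
    expect_gte(smallest_sector(phi2)$span + 1e-12, span0)
    expect_gte(max(lam2) - min(lam2), lam_rng0)
    masks <- list(matrix(TRUE, 30, 30))
    expect_gte(
      scar_size_pct_lv(NULL, list(make_segment(phi2, lam2)), masks = masks),
      scar_size_pct_lv(NULL, list(make_segment(phi, lam)), masks = masks)
    )
  }
})

test_that("randomized phantom studies satisfy all summary invariants", {
  set.seed(5)
  for (i in 1:10) {
    span <- runif(1, 20, 150)
    start <- runif(1, 0, 360)
    depth <- runif(1, 0.3, 1)
    ph <- generate_phantom(small_phantom_spec(
      scars = list(list(
        slice_indices = sort(sample(0:5, sample(2:4, 1))),
        phi_start_deg = start, phi_end_deg = start + span,
        lambda_depth = depth
      )),
      junction_angle_deg = runif(1, 0, 360),
      seed = 100 + i
    ))
    m <- analyze_study(ph$study, run_config(assume_scar = TRUE))$metrics
    expect_true(m$scar_size_pct_lv >= 0 && m$scar_size_pct_lv <= 100)
    expect_true(m$extent_pct_circumference >= 0 && m$extent_pct_circumference <= 100)
    expect_true(m$scarring_pct >= 0 && m$scarring_pct <= 1)
    expect_true(m$mean_delta_phi_deg >= 0 && m$mean_delta_phi_deg <= 360)
    expect_true(all(m$per_scar$delta_lambda >= 0 & m$per_scar$delta_lambda <= 1))
    expect_equal(sum(m$per_segment_degrees),
                 sum(m$per_scar$delta_phi_deg[m$per_scar$adherent]),
                 tolerance = 1e-9)
  }
})
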