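test_that("3D max SI is the maximum over all slices' myocardium", {
  s1 <- annulus_slice(si_value = 800, slice_index = 0L)
  s2 <- annulus_slice(si_value = 950, slice_index = 1L)
  study <- patient_study(list(s1, s2))
  expect_equal(compute_3dmax_si(study), 950)
  study_const <- patient_study(list(annulus_slice(si_value = 300)))
  expect_equal(compute_3dmax_si(study_const), 300)
  # background brighter than myocardium must not leak in
  s3 <- annulus_slice(si_value = 200)
  s3$si[1, 1] <- 4000
  expect_equal(compute_3dmax_si(patient_study(list(s3))), 200)
})

test_that("3D max SI of a noisy scar plateau obeys the order-statistic bounds", {
  sd <- 20
  ph <- generate_phantom(small_phantom_spec(si_scar = 1000, noise_sd = sd))
  mx <- compute_3dmax_si(ph$study)
  expect_gte(mx, 1000 - 3 * sd)
  expect_lte(mx, 1000 + 4 * sd)
})

test_that("the FWHM threshold is inclusive at exactly half the maximum", {
  s <- annulus_slice(si_value = 100)
  mask <- rasterize_myocardium(s)
  idx <- which(mask)[1:3]
  s$si[idx[1]] <- 1000  # the maximum
  s$si[idx[2]] <- 500   # exactly half: scar
  s$si[idx[3]] <- 499   # just below: not scar
  study <- patient_study(list(s))
  sm <- threshold_fwhm(study, compute_3dmax_si(study))[[1]]
  expect_true(sm[idx[1]])
  expect_true(sm[idx[2]])
  expect_false(sm[idx[3]])
  expect_false(any(sm[!mask]))  # scar mask is confined to the myocardium
})

test_that("rescaling all intensities leaves the FWHM scar mask unchanged", {
  ph <- generate_phantom(small_phantom_spec())
  study <- ph$study
  masks <- lapply(study$slices, rasterize_myocardium)
  sm1 <- threshold_fwhm(study, compute_3dmax_si(study, masks), masks)
  study2 <- study
  for (i in seq_along(study2$slices)) study2$slices[[i]]$si <- study2$slices[[i]]$si * 3.7
  sm2 <- threshold_fwhm(study2, compute_3dmax_si(study2, masks), masks)
  expect_identical(sm1, sm2)
})

test_that("connected components match a brute-force flood fill in both connectivities", {
  # two blobs touching only at a corner
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[2, 3] <- m[3, 3] <- TRUE
  m[4, 4] <- m[4, 5] <- m[5, 5] <- TRUE
  lab8 <- label_components(m, 8)
  lab4 <- label_components(m, 4)
  expect_equal(max(lab8), 1L)
  expect_equal(max(lab4), 2L)
  expect_identical(component_signature(lab8), component_signature(brute_label_components(m, 8)))
  expect_identical(component_signature(lab4), component_signature(brute_label_components(m, 4)))
  # randomized masks
  set.seed(11)
  for (i in 1:20) {
    rm <- matrix(runif(12 * 12) < 0.4, 12, 12)
    for (conn in c(4, 8)) {
      expect_identical(
        component_signature(label_components(rm, conn)),
        component_signature(brute_label_components(rm, conn))
      )
    }
  }
})

test_that("scar segments need at least two connected pixels and fill lambda stats", {
  s <- annulus_slice()
  mask <- rasterize_myocardium(s)
  pm <- build_polar_map(s, mask = mask)
  nr <- nrow(mask)
  # a 5-pixel blob and an isolated pixel, both inside the myocardium
  blob <- pm$pixels[order(pm$pixels$phi_deg), ][1:5, ]
  lone <- pm$pixels[which.min(abs(pm$pixels$phi_deg - 180)), ]  # far from the blob
  scar <- matrix(FALSE, nr, ncol(mask))
  scar[cbind(blob$row, blob$col)] <- TRUE
  segs <- extract_scar_segments(scar, pm, slice_index = 0L)
  expect_length(segs, sum(vapply(
    component_signature(label_components(scar, 8)), length, numeric(1)) >= 2))
  scar2 <- scar
  scar2[lone$row, lone$col] <- TRUE
  segs2 <- extract_scar_segments(scar2, pm, slice_index = 0L)
  expect_equal(length(segs2), length(segs))  # singleton discarded
  total_px <- sum(vapply(segs2, `[[`, numeric(1), "n_pixels"))
  singletons <- sum(table(label_components(scar2, 8)[scar2]) == 1)
  expect_equal(total_px + singletons, sum(scar2))
  seg <- segs2[[1]]
  expect_gte(seg$n_pixels, 2)
  expect_equal(seg$delta_lambda, seg$lambda_max - seg$lambda_min)
  expect_equal(seg$delta_phi_deg, endocardial_extent_angle(seg, pm))
})

test_that("the adherence filter keeps subendocardial and drops mid-wall scars", {
  ph <- generate_phantom(small_phantom_spec(
    scars = list(
      list(slice_indices = 1L, phi_start_deg = 20, phi_end_deg = 70,
           lambda_depth = 0.5),                        # subendocardial
      list(slice_indices = 1L, phi_start_deg = 180, phi_end_deg = 230,
           lambda_depth = 0.3, lambda_offset = 0.4)    # mid-wall
    ),
    noise_sd = 0
  ))
  res <- analyze_study(ph$study, run_config(assume_scar = TRUE))
  expect_length(res$all_segments, 2L)
  expect_length(res$segments, 1L)
  kept <- res$segments[[1]]
  expect_true(kept$adherent)
  # the kept scar is the one near phase 20-70
  expect_lt(abs(deg_mod(kept$sector_start_deg - 20)), 10)
  dropped <- Filter(function(s) !s$adherent, res$all_segments)
  expect_length(dropped, 1L)
  expect_gt(dropped[[1]]$lambda_min, 0.2)
  # an explicit generous tolerance keeps both
  both <- filter_endocardial_adherent(res$all_segments, tolerance = 1)
  expect_length(both, 2L)
  # a strict zero tolerance still keeps the truly adherent one
  strict <- filter_endocardial_adherent(res$all_segments, tolerance = 0)
  expect_lte(length(strict), 1L)
})
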