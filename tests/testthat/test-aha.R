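test_that("slice counts per region follow the enumerated rules", {
  count_regions <- function(n) table(factor(assign_slices_to_regions(n),
                                            levels = c("apical", "mid", "basal")))
  expect_equal(unname(c(count_regions(6))), c(2, 2, 2))
  expect_equal(unname(c(count_regions(7))), c(2, 3, 2))
  expect_equal(unname(c(count_regions(8))), c(2, 3, 3))
  expect_equal(unname(c(count_regions(10))), c(3, 4, 3))
  expect_equal(unname(c(count_regions(11))), c(3, 4, 4))
  # apical block first (slices ordered apex to base)
  expect_equal(assign_slices_to_regions(6)[1:2], c("apical", "apical"))
  expect_equal(assign_slices_to_regions(6)[5:6], c("basal", "basal"))
  expect_error(assign_slices_to_regions(2), "at least 3")
})

test_that("each region's segment intervals tile [0, 360) exactly", {
  tab <- aha_segment_table()
  for (region in c("basal", "mid", "apical")) {
    sub <- segment_boundaries(region, tab)
    expect_equal(sum(sub$end_deg - sub$start_deg), 360)
    n_expected <- if (region == "apical") 4L else 6L
    expect_length(unique(sub$segment_id), n_expected)
    # no overlaps: sorted intervals abut exactly
    o <- order(sub$start_deg)
    expect_equal(sub$start_deg[o][-1], sub$end_deg[o][-nrow(sub)])
    expect_equal(sub$start_deg[o][1], 0)
    expect_equal(sub$end_deg[o][nrow(sub)], 360)
  }
})

test_that("pixel-to-segment allocation follows the printed basal layout", {
  expect_equal(assign_pixel_to_segment(30, "basal"), 4L)
  expect_equal(assign_pixel_to_segment(315, "basal"), 3L)
  # half-open boundaries: start inclusive
  expect_equal(assign_pixel_to_segment(0, "basal"), 4L)
  expect_equal(assign_pixel_to_segment(60, "basal"), 5L)
  # mid segments sit at the same angles as their basal counterparts
  expect_equal(assign_pixel_to_segment(30, "mid"), 10L)
  expect_equal(assign_pixel_to_segment(315, "mid"), 9L)
  # apical 14/15 border at 345 degrees
  expect_equal(assign_pixel_to_segment(345, "apical"), 15L)
  expect_equal(assign_pixel_to_segment(344.9, "apical"), 14L)
  expect_equal(assign_pixel_to_segment(0, "apical"), 15L)
  expect_equal(assign_pixel_to_segment(80, "apical"), 16L)
})

test_that("segment allocation agrees with brute-force interval membership", {
  tab <- aha_segment_table()
  phis <- seq(0, 359.9, by = 0.1)
  for (region in c("basal", "mid", "apical")) {
    sub <- segment_boundaries(region, tab)
    got <- assign_pixel_to_segment(phis, region, tab)
    want <- vapply(phis, function(p) {
      hit <- sub$segment_id[sub$start_deg <= p & p < sub$end_deg]
      expect_length(hit, 1L)  # partition: exactly one interval contains p
      hit
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("a basal sector wrapping through zero splits as printed", {
  split <- split_sector_across_segments(315, 115, "basal")
  expect_equal(split, c(`3` = 45, `4` = 60, `5` = 55))
  expect_equal(sum(split), deg_mod(115 - 315))
  # degenerate sector
  expect_length(split_sector_across_segments(90, 90, "basal"), 0L)
})

test_that("sector splits conserve the span and match a fine-grid oracle", {
  tab <- aha_segment_table()
  set.seed(23)
  for (i in 1:200) {
    start <- runif(1, 0, 360)
    span <- runif(1, 0, 359.99)
    region <- sample(c("basal", "mid", "apical"), 1)
    split <- lgescar:::split_sector_span(start, span, region, tab)
    expect_equal(sum(split), span, tolerance = 1e-9)
    approx <- grid_split_sector(start, span, region, tab)
    for (id in union(names(split), names(approx))) {
      a <- if (id %in% names(split)) split[[id]] else 0
      b <- if (id %in% names(approx)) approx[[id]] else 0
      expect_lt(abs(a - b), 0.2)
    }
  }
})

test_that("per-IRA aggregation normalizes each segment row to 100%", {
  one <- data.frame(patient_id = "a", ira_label = "LAD",
                    segment_id = 7L, degrees = 80)
  t1 <- aggregate_by_ira(one)
  expect_equal(t1$LAD[t1$segment_id == 7], 100)
  expect_false(t1$has_scar[t1$segment_id == 8])
  expect_true(is.na(t1$LAD[t1$segment_id == 8]))

  two <- rbind(one, data.frame(patient_id = "b", ira_label = "RCA",
                               segment_id = 3L, degrees = 30))
  two <- rbind(two, data.frame(patient_id = "a", ira_label = "LAD",
                               segment_id = 3L, degrees = 30))
  t2 <- aggregate_by_ira(two)
  expect_equal(t2$LAD[t2$segment_id == 3], 50)
  expect_equal(t2$RCA[t2$segment_id == 3], 50)

  set.seed(9)
  cohort <- data.frame(
    patient_id = rep(sprintf("p%02d", 1:12), each = 4),
    ira_label = rep(sample(c("LAD", "RCA", "LCX"), 12, replace = TRUE), each = 4),
    segment_id = sample(1:16, 48, replace = TRUE),
    degrees = runif(48, 0, 120)
  )
  t3 <- aggregate_by_ira(cohort)
  rows <- t3[t3$has_scar, c("LAD", "RCA", "LCX")]
  expect_true(all(abs(rowSums(rows) - 100) < 1e-9))
  expect_error(aggregate_by_ira(transform(one, ira_label = "LMS")), "unknown IRA")
  expect_error(aggregate_by_ira(transform(one, degrees = -1)), "non-negative")
})

test_that("the apical-cap visual rule triggers above half the circumference", {
  expect_true(segment17_visual_scar(181))
  expect_false(segment17_visual_scar(180))
  expect_false(segment17_visual_scar(90))
})
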