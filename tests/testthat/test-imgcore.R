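# Per-field analysis: background removal, segmentation, ROIs, target
# measurement, responder classification, focus QC, well statistics.

test_that("background removal zeroes uniform fields and never adds signal", {
  u <- matrix(500, 80, 80)
  expect_true(all(preprocess_background(u, 15) == 0))

  set.seed(1)
  noisy <- matrix(100 + rnorm(80 * 80, 0, 10), 80, 80)
  out <- preprocess_background(noisy, 15)
  expect_true(all(out <= noisy))
  expect_true(all(out >= 0))
  expect_error(preprocess_background(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("a bright disk survives background subtraction almost intact", {
  set.seed(2)
  img <- matrix(100, 60, 60) + matrix(rnorm(3600, 0, 5), 60, 60)
  img <- draw_disk(img, 30, 30, 5, 2100)
  disk_px <- hciscreen:::disk_mask(5)
  sel <- which(outer((1:60) - 30, (1:60) - 30,
                     function(a, b) a^2 + b^2 <= 25))
  amplitude_in <- mean(img[sel]) - 100

  out <- preprocess_background(img, 12)
  expect_gt(mean(out[sel]) / amplitude_in, 0.9)

  # independent check: a brute-force local-median background behaves the same
  med <- oracle_local_median(img, 12)
  out_med <- pmax(img - med, 0)
  expect_gt(mean(out_med[sel]) / amplitude_in, 0.9)
  # and the two estimates agree on the disk pixels within 5%
  expect_lt(abs(mean(out[sel]) - mean(out_med[sel])) / mean(out_med[sel]),
            0.05)
})

test_that("segmentation returns nothing on blank fields", {
  set.seed(3)
  blank <- matrix(pmax(rnorm(200 * 200, 50, 20), 0), 200, 200)
  seg <- segment_nuclei(blank, scaled_seg())
  expect_equal(nrow(seg$objects), 0)
})

test_that("segmentation recovers non-touching nuclei exactly", {
  p <- scaled_sim_params(n_cells_mean = 50, field_height_px = 260,
                         field_width_px = 260)
  for (s in 1:4) {
    gf <- generate_field(p, seed = 20 + s)
    ch1 <- preprocess_background(gf$image$ch1, 20)
    seg <- segment_nuclei(ch1, scaled_seg())
    expect_equal(nrow(seg$objects), nrow(gf$truth$cells))
    expect_true(all(seg$objects$area_px >= 30))
  }
})

test_that("touching nuclei are split when splitting is enabled", {
  # two disks radius 6 with centers 1.2 diameters apart
  set.seed(4)
  img <- matrix(rnorm(70 * 70, 0, 100), 70, 70)
  img <- draw_disk(img, 35, 28, 6, 20000)
  img <- draw_disk(img, 35, 28 + round(1.2 * 12), 6, 20000)
  seg_on <- segment_nuclei(img, scaled_seg(split_touching = TRUE))
  expect_equal(nrow(seg_on$objects), 2)
  # clumped synthetic fields recover counts within 10%
  pc <- scaled_sim_params(n_cells_mean = 50, field_height_px = 260,
                          field_width_px = 260, clump_fraction = 0.2)
  tot_truth <- 0; tot_seg <- 0
  for (s in 1:4) {
    gf <- generate_field(pc, seed = 30 + s)
    seg <- segment_nuclei(preprocess_background(gf$image$ch1, 20),
                          scaled_seg())
    tot_truth <- tot_truth + nrow(gf$truth$cells)
    tot_seg <- tot_seg + nrow(seg$objects)
  }
  expect_lt(abs(tot_seg - tot_truth) / tot_truth, 0.10)
})

test_that("ROI dilation matches the rasterized-disk oracle", {
  nuc <- matrix(FALSE, 101, 101)
  dm <- hciscreen:::disk_mask(10)
  nuc[51 + (-10:10), 51 + (-10:10)] <- dm

  expect_identical(build_roi(nuc, 0), nuc)
  expect_error(build_roi(nuc, -2), ">= 0")

  roi <- build_roi(nuc, 8)
  expect_true(all(roi[nuc]))  # ROI contains every nucleus pixel
  expect_lt(abs(sum(roi) - oracle_disk_area(18)) / oracle_disk_area(18), 0.02)

  # clipping: a nucleus 5 px from the edge loses part of its ROI
  edge <- matrix(FALSE, 101, 101)
  edge[6, 51] <- TRUE
  expect_lt(sum(build_roi(edge, 8)), oracle_disk_area(8))
})

test_that("target measurement follows the fixed-threshold contract", {
  roi <- matrix(FALSE, 50, 50)
  roi[20:30, 20:30] <- TRUE

  m_low <- measure_target(matrix(80, 50, 50), roi, 200)
  expect_equal(m_low$target_area_px, 0)
  expect_equal(m_low$target_avg_intensity, 0)

  m_all <- measure_target(matrix(300, 50, 50), roi, 200)
  expect_equal(m_all$target_area_px, m_all$roi_area_px)
  expect_equal(m_all$target_avg_intensity, 300)

  # ring of 900 on background 100: mean and area against a brute-force mask
  ch2 <- matrix(100, 50, 50)
  ring <- draw_disk(matrix(0, 50, 50), 25, 25, 8, 1) -
    draw_disk(matrix(0, 50, 50), 25, 25, 6, 1)
  ch2[ring == 1] <- 900
  roi2 <- build_roi(draw_disk(matrix(0, 50, 50), 25, 25, 5, 1) == 1, 5)
  m <- measure_target(ch2, roi2, 500)
  expect_equal(m$target_avg_intensity, 900)
  expect_equal(m$target_area_px, sum(ring == 1 & roi2))
  expect_error(measure_target(ch2, matrix(FALSE, 50, 50), 500), "one pixel")
})

test_that("responder classification computes % cells high", {
  ms <- tibble::tibble(target_avg_intensity = c(rep(800, 3), rep(0, 7)),
                       target_area_px = c(rep(10L, 3), rep(0L, 7)))
  out <- classify_response(ms, 500)
  expect_equal(out$pct_cells_high, 30)
  expect_equal(sum(out$measurements$responder), 3)

  all0 <- classify_response(
    tibble::tibble(target_avg_intensity = rep(0, 5)), 500)
  expect_equal(all0$pct_cells_high, 0)

  some <- tibble::tibble(target_avg_intensity = c(10, 20, 30))
  expect_equal(classify_response(some, 0)$pct_cells_high, 100)
  expect_equal(classify_response(some[0, ], 500)$pct_cells_high, 0)
})

test_that("focus assessment rejects only defocused fields", {
  p <- scaled_sim_params(bound_fraction = 0.5)
  gf <- generate_field(p, seed = 41)
  same <- list(gf$image, gf$image, gf$image, gf$image)
  f_same <- assess_focus(same, cutoff_fraction = 0.5)
  expect_true(all(f_same$accepted))

  mixed <- list(gf$image, generate_field(p, seed = 42)$image,
                generate_field(p, seed = 43)$image,
                apply_defocus(gf$image, 8))
  f_mixed <- assess_focus(mixed, cutoff_fraction = 0.5)
  expect_equal(which(!f_mixed$accepted), 4L)
})

test_that("well analysis pools accepted fields only", {
  p <- scaled_sim_params(bound_fraction = 0.4)
  gw <- generate_well(p, 3, seed = 44, well_id = "D05")
  blurred <- apply_defocus(gw$fields[[1]], 8)
  fields <- c(gw$fields, list(blurred))
  cal <- scaled_calibration()
  cfg <- scaled_config(fixed_threshold = cal$fixed_threshold,
                       response_limit = cal$response_limit)
  res <- analyze_well(fields, cfg)
  expect_equal(res$features$fields_acquired, 4L)
  expect_equal(res$features$fields_accepted, 3L)
  # rejected field contributes no cells; per-field counts averaged over
  # accepted fields agree with per-field segmentation run independently
  counts <- vapply(gw$fields, function(f) {
    nrow(segment_nuclei(preprocess_background(f$ch1, 20), cfg$seg)$objects)
  }, numeric(1))
  expect_equal(res$features$nuclei_per_field_avg, mean(counts))
  expect_equal(res$features$n_cells, sum(counts))
  expect_setequal(unique(res$cells$field_index), 1:3)

  # all fields rejected -> flagged, not fabricated
  bad <- lapply(gw$fields, apply_defocus, sigma = 8)
  res_bad <- analyze_well(bad, scaled_config(
    fixed_threshold = cal$fixed_threshold,
    focus_reference = focus_score(gw$fields[[1]])
  ))
  expect_equal(res_bad$features$fields_accepted, 0L)
  expect_true(is.na(res_bad$features$pct_cells_high))
  expect_match(res_bad$features$qc_flags, "no_analyzable_fields")
})

test_that("well-level percentage recovers the planted bound fraction", {
  cal <- scaled_calibration()
  cfg <- scaled_config(fixed_threshold = cal$fixed_threshold,
                       response_limit = cal$response_limit)
  p <- scaled_sim_params(bound_fraction = 0.4)
  errs <- vapply(1:3, function(s) {
    gw <- generate_well(p, 4, seed = 60 + s)
    res <- analyze_well(gw$fields, cfg)
    abs(res$features$pct_cells_high - 100 * gw$true_bound_fraction)
  }, numeric(1))
  expect_lt(mean(errs), 5)
})
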