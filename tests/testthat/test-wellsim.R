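# Synthetic field/well/plate generator: ground-truth structure, determinism,
# signal model, defocus.

test_that("parameter validation rejects out-of-range values", {
  expect_error(sim_params(transfected_fraction = 1.2), "proportion")
  expect_error(sim_params(bound_fraction = -0.1), "proportion")
  expect_error(sim_params(noise_sd = -1), ">= 0")
  expect_error(sim_params(bit_depth = 12), "8 or 16")
  expect_error(generate_field(sim_params(field_height_px = 30,
                                         min_center_spacing_px = 200)),
               "min_center_spacing_px")
})

test_that("empty and forced-binding fields match their construction", {
  p0 <- scaled_sim_params(n_cells_mean = 0)
  gf0 <- generate_field(p0, seed = 3)
  expect_equal(nrow(gf0$truth$cells), 0)
  expect_equal(gf0$truth$true_bound_fraction, 0)
  # background + noise only: intensities near the background level
  expect_lt(abs(mean(gf0$image$ch1) - p0$background_level),
            5 * p0$noise_sd)

  p1 <- scaled_sim_params(bound_fraction = 1, n_cells_mean = 40)
  gf1 <- generate_field(p1, seed = 4)
  expect_gt(nrow(gf1$truth$cells), 0)
  expect_equal(gf1$truth$true_bound_fraction, 1.0)
})

test_that("identical params and seed give bit-identical fields", {
  p <- scaled_sim_params(bound_fraction = 0.5)
  a <- generate_field(p, seed = 7)
  b <- generate_field(p, seed = 7)
  expect_identical(a$image$ch1, b$image$ch1)
  expect_identical(a$image$ch2, b$image$ch2)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- generate_field(p, seed = 8)
  expect_false(identical(a$image$ch1, c$image$ch1))
})

test_that("bound implies transfected in every generated truth record", {
  p <- scaled_sim_params(field_height_px = 120, field_width_px = 120,
                         n_cells_mean = 15, min_center_spacing_px = 12,
                         transfected_fraction = 0.5, bound_fraction = 0.5)
  for (s in 1:25) {
    tc <- generate_field(p, seed = s)$truth$cells
    expect_true(all(tc$transfected[tc$bound]))
    expect_true(all(tc$center_r >= 1 & tc$center_r <= 120))
    expect_true(all(tc$center_c >= 1 & tc$center_c <= 120))
  }
})

test_that("realized bound fractions match binomial expectation", {
  # >= 200 fields with ~50 cells: mean realized fraction within 3 SE of f
  f <- 0.3
  p <- scaled_sim_params(field_height_px = 150, field_width_px = 150,
                         n_cells_mean = 50, nucleus_radius_px = 4,
                         nucleus_radius_sd_px = 0.5,
                         min_center_spacing_px = 10,
                         transfected_fraction = 1, bound_fraction = f)
  tallies <- vapply(1:200, function(s) {
    tc <- generate_field(p, seed = 1000 + s)$truth$cells
    c(sum(tc$bound), nrow(tc))
  }, numeric(2))
  realized <- sum(tallies[1, ]) / sum(tallies[2, ])
  se <- sqrt(f * (1 - f) / sum(tallies[2, ]))
  expect_lt(abs(realized - f), 3 * se)
})

test_that("ring pixels of bound cells carry the configured signal", {
  p <- scaled_sim_params(bound_fraction = 1, n_cells_mean = 20)
  gf <- generate_field(p, seed = 11)
  tc <- gf$truth$cells
  ring_means <- vapply(seq_len(nrow(tc)), function(i) {
    rr <- tc$radius[i] + p$membrane_offset_px
    ang <- seq(0, 2 * pi, length.out = 40)
    ri <- pmin(pmax(round(tc$center_r[i] + rr * sin(ang)), 1), 220)
    ci <- pmin(pmax(round(tc$center_c[i] + rr * cos(ang)), 1), 220)
    mean(gf$image$ch2[cbind(ri, ci)])
  }, numeric(1))
  expect_gt(mean(ring_means),
            p$background_level + p$ch2_ring_signal_mean - 3 * p$noise_sd)
})

test_that("defocus blurs conservatively and lowers the focus score", {
  p <- scaled_sim_params(bound_fraction = 0.5)
  gf <- generate_field(p, seed = 5)
  expect_identical(apply_defocus(gf$image, 0), gf$image)
  expect_error(apply_defocus(gf$image, -1), ">= 0")

  blurred <- apply_defocus(gf$image, 8)
  expect_lt(focus_score(blurred), focus_score(gf$image))

  # intensity conservation on an interior-only image (1% tolerance)
  img <- matrix(0, 120, 120)
  img <- draw_disk(img, 60, 60, 15, 4000)
  fi <- field_image(img, img, bit_depth = 16L)
  bl <- apply_defocus(fi, 3)
  expect_lt(abs(sum(bl$ch1) - sum(img)) / sum(img), 0.01)
})

test_that("generate_plate emits the configured fields with role structure", {
  spec <- plate_spec()
  layout <- build_layout(spec)
  tiny <- scaled_sim_params(field_height_px = 64, field_width_px = 64,
                            n_cells_mean = 3, nucleus_radius_px = 3,
                            nucleus_radius_sd_px = 0.3,
                            min_center_spacing_px = 10,
                            bound_fraction = 0.5)
  plate <- generate_plate(
    layout,
    list(sample = tiny, negative_control = tiny, positive_control = tiny),
    seed = 2, fields_per_well = 4
  )
  roles <- vapply(plate, `[[`, character(1), "role")
  n_fields <- vapply(plate, function(w) length(w$fields), integer(1))
  # 280 sample wells x 4 fields = 1120 sample-field images
  expect_equal(sum(n_fields[roles == "sample"]), 1120)
  expect_true(all(n_fields == 4))
  # negative controls are forced to zero bound fraction
  tbf_neg <- vapply(plate[roles == "negative_control"], `[[`, numeric(1),
                    "true_bound_fraction")
  expect_true(all(tbf_neg == 0))
  expect_error(generate_plate(layout, list(sample = tiny), seed = 2),
               "negative_control")
})

test_that("plate generation is deterministic per well", {
  spec <- plate_spec()
  layout <- dplyr::filter(build_layout(spec),
                          well_id %in% c("B03", "B04", "C03"))
  tiny <- scaled_sim_params(field_height_px = 64, field_width_px = 64,
                            n_cells_mean = 5, nucleus_radius_px = 3,
                            nucleus_radius_sd_px = 0.3,
                            min_center_spacing_px = 10,
                            bound_fraction = 0.5)
  pp <- list(sample = tiny)
  a <- generate_plate(layout, pp, seed = 9, fields_per_well = 2)
  b <- generate_plate(layout, pp, seed = 9, fields_per_well = 2)
  expect_identical(
    lapply(a, function(w) lapply(w$fields, `[[`, "ch2")),
    lapply(b, function(w) lapply(w$fields, `[[`, "ch2"))
  )
})
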