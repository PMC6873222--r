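# Plate layout, clone assignment, calibration, QC, hit calling, heatmaps.

test_that("default layout counts follow the 384-well template", {
  layout <- build_layout(plate_spec())
  expect_equal(nrow(layout), 384)
  expect_equal(sum(layout$role == "edge_excluded"), 76)  # 2*24 + 2*14
  expect_equal(sum(layout$role != "edge_excluded"), 308)
  expect_equal(sum(layout$role == "sample"), 280)
  expect_equal(sum(layout$role %in% c("negative_control", "positive_control")),
               28)
  expect_equal(layout$role[layout$well_id == "A01"], "edge_excluded")
  # controls confined to columns 2 and 13
  ctrl <- layout[layout$role != "sample" & layout$role != "edge_excluded", ]
  expect_setequal(unique(ctrl$col), c(2L, 13L))
  expect_error(plate_spec(control_columns = c(1, 13)), "interior")
})

test_that("clone assignment fills plates at 280 clones per plate", {
  ids <- sprintf("c%04d", 1:2455)
  asg <- assign_clones(ids, plate_spec())
  expect_equal(length(unique(asg$plate_id)), 9)

  expect_equal(length(unique(assign_clones(ids[1:280], plate_spec())$plate_id)), 1)
  expect_equal(length(unique(assign_clones(ids[1:281], plate_spec())$plate_id)), 2)
  expect_error(assign_clones(character(0)), "nonempty")

  # no clone outside sample wells; each clone placed exactly once
  placed <- asg[!is.na(asg$clone_id), ]
  expect_true(all(placed$role == "sample"))
  expect_setequal(placed$clone_id, ids)
  expect_equal(nrow(placed), length(ids))

  # column-major order within the sample region (column 2 is controls)
  one <- assign_clones(ids[1:16], plate_spec())
  placed1 <- one[!is.na(one$clone_id), ]
  expect_equal(placed1$well_id[match(c("c0001", "c0014", "c0015"),
                                     placed1$clone_id)],
               c("B03", "O03", "B04"))
})

test_that("plates needed equals ceiling(n / capacity) across sizes", {
  spec <- plate_spec()
  for (n in c(1, 7, 279, 280, 281, 559, 560, 561, 1200)) {
    asg <- assign_clones(sprintf("x%04d", seq_len(n)), spec)
    expect_equal(length(unique(asg$plate_id)), ceiling(n / 280))
    expect_equal(sum(!is.na(asg$clone_id)), n)
  }
})

test_that("threshold calibration matches direct computation", {
  # degenerate SD: all intensities equal
  cal0 <- calibrate_from_controls(rep(100, 60))
  expect_equal(cal0$fixed_threshold, 100)
  expect_equal(cal0$response_limit, 100)

  # seeded normal draw: threshold = sample mean + 5 * sample SD
  x <- withr::with_seed(99, rnorm(1000, 100, 10))
  cal <- calibrate_from_controls(x, k_sigma = 5)
  expect_equal(cal$fixed_threshold, mean(x) + 5 * sd(x))

  # per-cell summaries reproduce pooled pixel statistics
  px <- withr::with_seed(7, rnorm(2000, 50, 8))
  groups <- rep(1:50, each = 40)
  cells <- tibble::tibble(
    roi_mean_intensity = tapply(px, groups, mean),
    roi_sd_intensity = tapply(px, groups, sd),
    roi_area_px = rep(40L, 50)
  )
  calp <- calibrate_from_controls(cells, k_sigma = 5)
  expect_equal(calp$fixed_threshold, mean(px) + 5 * sd(px))
  expect_error(calibrate_from_controls(rep(10, 20)), ">= 50")

  td <- tidy(cal)
  expect_equal(td$estimate[td$term == "fixed_threshold"], cal$fixed_threshold)
  expect_equal(glance(cal)$n_neg_cells, 1000)
})

test_that("nuclei-count QC flags only depleted wells", {
  records <- tibble::tibble(
    plate_id = "plate01",
    well_id = sprintf("B%02d", 2:13),
    role = c("negative_control", rep("sample", 11)),
    nuclei_per_field_avg = c(rep(100, 11), 10),
    pct_cells_high = 0, qc_flags = ""
  )
  out <- qc_nuclei_counts(records, 0.5)
  expect_equal(out$well_id[out$qc_flags != ""], "B13")
  expect_match(out$qc_flags[out$well_id == "B13"], "low_cells")

  # edge wells are ignored both for the median and for flagging
  with_edge <- dplyr::bind_rows(
    records,
    tibble::tibble(plate_id = "plate01", well_id = "A01",
                   role = "edge_excluded", nuclei_per_field_avg = NA_real_,
                   pct_cells_high = NA_real_, qc_flags = NA_character_)
  )
  out2 <- qc_nuclei_counts(with_edge, 0.5)
  expect_true(is.na(out2$qc_flags[out2$well_id == "A01"]))
  expect_error(qc_nuclei_counts(records[1:5, ], 0.5), ">= 10")
})

test_that("hit calling ranks by % cells high with deterministic ties", {
  recs <- tibble::tibble(
    plate_id = c("plate01", "plate01", "plate02", "plate01", "plate01"),
    well_id = c("B03", "C03", "B03", "D03", "E03"),
    role = c("sample", "sample", "sample", "sample", "negative_control"),
    clone_id = c("a", "b", "c", "d", NA),
    pct_cells_high = c(40, 5, 40, 12, 45),
    nuclei_per_field_avg = 100,
    qc_flags = c("", "", "", "low_cells", "")
  )
  hits <- call_hits(recs, hit_threshold_pct = 10)
  # controls never ranked; flagged well excluded; tie broken by plate then well
  expect_equal(hits$rank, 1:2)
  expect_equal(hits$well_id, c("B03", "B03"))
  expect_equal(hits$plate_id, c("plate01", "plate02"))

  hits_all <- call_hits(recs, 10, exclude_flagged = FALSE)
  expect_equal(nrow(hits_all), 3)
  expect_equal(nrow(call_hits(dplyr::mutate(recs, pct_cells_high = 0), 10)), 0)
})

test_that("heatmap matrix places wells and round-trips", {
  layout <- build_layout(plate_spec())
  records <- layout |>
    dplyr::mutate(
      pct_cells_high = dplyr::if_else(role == "edge_excluded", NA_real_,
                                      dplyr::row_number() / 4),
      nuclei_per_field_avg = dplyr::if_else(role == "edge_excluded",
                                            NA_real_, 100)
    )
  m <- heatmap_matrix(records, "pct_cells_high")
  expect_equal(dim(m), c(16, 24))
  # border is NA, interior populated
  expect_true(all(is.na(m["A", ])) && all(is.na(m[, 1])))
  expect_equal(sum(!is.na(m)), 308)
  # indexing contract: cell [B][3] is well B03
  expect_equal(m["B", 3],
               records$pct_cells_high[records$well_id == "B03"])
  # round-trip: reading the matrix back at each record's position is the
  # identity on non-missing entries
  back <- m[cbind(match(records$row, LETTERS), records$col)]
  ok <- !is.na(records$pct_cells_high)
  expect_equal(back[ok], records$pct_cells_high[ok])
  expect_error(heatmap_matrix(records, "banana"))

  single <- records |>
    dplyr::mutate(pct_cells_high = dplyr::if_else(well_id == "C07",
                                                  50, NA_real_))
  m1 <- heatmap_matrix(single, "pct_cells_high")
  expect_equal(sum(!is.na(m1)), 1)
  expect_equal(m1["C", 7], 50)

  gg <- autoplot(m)
  expect_s3_class(gg, "ggplot")
})

test_that("pool annotation attaches candidates without inference", {
  hits <- tibble::tibble(rank = 1:2, plate_id = "plate01",
                         well_id = c("B03", "C03"), clone_id = c("a", "b"),
                         pct_cells_high = c(40, 30),
                         nuclei_per_field_avg = 100, qc_flags = "")
  one <- annotate_pool(hits, "CD200R")
  expect_false(any(one$needs_deconvolution))
  four <- annotate_pool(hits, c("CD200R", "LPHN1", "ZP2", "GPR64"))
  expect_true(all(four$needs_deconvolution))
  expect_equal(unique(four$pool_size), 4)
  expect_equal(unique(four$candidate_probes), "CD200R;LPHN1;ZP2;GPR64")
  empty <- annotate_pool(hits[0, ], c("A", "B"))
  expect_equal(nrow(empty), 0)
  expect_error(annotate_pool(hits, character(0)), "nonempty")
})
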