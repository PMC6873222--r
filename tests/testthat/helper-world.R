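# Shared scaled fixture world: a 220 px field standing in for the 1104 px
# default (field size is a fixture convention), with geometry chosen so that
# a cell's ROI cannot reach a neighbour's membrane ring:
#   min spacing (24) >= ROI reach (radius 6 + dilation 5)
#                       + ring extent (radius 8 + suprathreshold tail ~3).
scaled_sim_params <- function(...) {
  defaults <- list(
    field_height_px = 220, field_width_px = 220, n_cells_mean = 30,
    nucleus_radius_px = 6, nucleus_radius_sd_px = 0.8,
    min_center_spacing_px = 24, transfected_fraction = 1, bound_fraction = 0,
    ch1_signal_mean = 20000, ch1_signal_sd = 3000,
    ch2_ring_signal_mean = 15000, ch2_ring_signal_sd = 2000,
    ch2_ring_width_px = 3, membrane_offset_px = 2,
    background_level = 2000, noise_sd = 300
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

scaled_seg <- function(...) {
  defaults <- list(smooth_sigma = 1, min_area_px = 30, split_min_distance = 5)
  do.call(seg_params, utils::modifyList(defaults, list(...)))
}

scaled_config <- function(...) {
  defaults <- list(bg_kernel_half = 20, seg = scaled_seg(), dilation_px = 4)
  do.call(analysis_config, utils::modifyList(defaults, list(...)))
}

# calibrate thresholds from n_neg wells of the scaled world
scaled_calibration <- function(params = scaled_sim_params(), n_neg = 2,
                               seed = 501, config = scaled_config()) {
  cfg0 <- config
  cfg0$fixed_threshold <- 0
  cfg0$response_limit <- 0
  cells <- dplyr::bind_rows(lapply(seq_len(n_neg), function(i) {
    pn <- params
    pn$bound_fraction <- 0
    gw <- generate_well(pn, 4, seed = seed + i)
    analyze_well(gw$fields, cfg0)$cells
  }))
  calibrate_from_controls(cells)
}

# --- independent oracles -----------------------------------------------------

# rasterized disk area by brute-force enumeration
oracle_disk_area <- function(radius) {
  x <- seq(-ceiling(radius), ceiling(radius))
  sum(outer(x, x, function(a, b) a^2 + b^2 <= radius^2))
}

# brute-force local-median background estimate (window 2*half+1, edge
# replicated)
oracle_local_median <- function(img, half) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- max(1, i - half):min(nr, i + half)
      cj <- max(1, j - half):min(nc, j + half)
      out[i, j] <- median(img[ri, cj])
    }
  }
  out
}

# closed-form ordinary least squares slope
oracle_ols_slope <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# render a hard disk into a matrix (test-side image construction)
draw_disk <- function(img, cr, cc, radius, value) {
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      if ((i - cr)^2 + (j - cc)^2 <= radius^2) img[i, j] <- value
    }
  }
  img
}
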