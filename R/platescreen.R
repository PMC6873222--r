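# 384-well plate logic: layout with edge exclusion and control columns,
# clone assignment, control-based threshold calibration, nuclei-count QC,
# heatmaps and rank-ordered hit calling.

#' 384-well plate specification
#'
#' Standard 16 x 24 geometry. Wells on the plate border (rows A/P, columns
#' 1/24) are excluded from analysis because of plate edge effects; two
#' interior columns are reserved for controls, split half negative (upper
#' rows) and half positive (lower rows) within each column.
#'
#' @param n_rows,n_cols Plate geometry (default 16 x 24).
#' @param control_columns Interior columns reserved for control wells
#'   (default 2 and 13).
#' @param fields_per_well Fields of view acquired per well (default 4).
#' @return A `plate_spec` list with derived counts `n_interior` and
#'   `sample_capacity`.
#' @export
plate_spec <- function(n_rows = 16L, n_cols = 24L,
                       control_columns = c(2L, 13L),
                       fields_per_well = 4L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  control_columns <- as.integer(control_columns)
  if (any(control_columns <= 1L | control_columns >= n_cols)) {
    abort("Control columns must be interior columns (not on the excluded edge).")
  }
  if (fields_per_well < 1L) abort("`fields_per_well` must be >= 1.")
  n_interior <- (n_rows - 2L) * (n_cols - 2L)
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      control_columns = control_columns,
      fields_per_well = as.integer(fields_per_well),
      n_interior = n_interior,
      sample_capacity = n_interior - length(control_columns) * (n_rows - 2L)
    ),
    class = "plate_spec"
  )
}

well_name <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Assign a role to every well of a plate
#'
#' Border wells are `edge_excluded`; interior wells of the control columns are
#' `negative_control` (upper half of the column) or `positive_control` (lower
#' half); remaining interior wells are `sample`.
#'
#' @param spec A [plate_spec()].
#' @return Tibble with one row per well: `well_id`, `row` (letter), `col`,
#'   `role`.
#' @export
build_layout <- function(spec = plate_spec()) {
  grid <- tidyr::expand_grid(row = seq_len(spec$n_rows),
                             col = seq_len(spec$n_cols))
  interior_rows <- 2:(spec$n_rows - 1L)
  n_neg <- ceiling(length(interior_rows) / 2)
  neg_rows <- interior_rows[seq_len(n_neg)]
  dplyr::mutate(
    grid,
    well_id = well_name(.data$row, .data$col),
    role = dplyr::case_when(
      .data$row == 1L | .data$row == spec$n_rows |
        .data$col == 1L | .data$col == spec$n_cols ~ "edge_excluded",
      .data$col %in% spec$control_columns & .data$row %in% neg_rows ~
        "negative_control",
      .data$col %in% spec$control_columns ~ "positive_control",
      TRUE ~ "sample"
    ),
    row = LETTERS[.data$row]
  ) |>
    dplyr::select("well_id", "row", "col", "role")
}

#' Assign library clones to sample wells across plates
#'
#' Clones fill the sample wells of successive plates in column-major order
#' (down each non-control interior column, left to right). Edge and control
#' wells never receive a clone. The number of plates is
#' `ceiling(n_clones / sample_capacity)` (280 for the default layout).
#'
#' @param clone_ids Character vector of clone identifiers, in library order.
#' @param spec A [plate_spec()].
#' @return Tibble of well records for every well of every plate: `plate_id`,
#'   `well_id`, `row`, `col`, `role`, `clone_id` (`NA` outside occupied
#'   sample wells).
#' @export
assign_clones <- function(clone_ids, spec = plate_spec()) {
  if (length(clone_ids) == 0) abort("`clone_ids` must be nonempty.")
  layout <- build_layout(spec)
  n_plates <- ceiling(length(clone_ids) / spec$sample_capacity)
  sample_slots <- layout |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::arrange(.data$col, .data$row)  # column-major fill
  purrr::map(seq_len(n_plates), function(p) {
    first <- (p - 1L) * spec$sample_capacity + 1L
    ids <- clone_ids[first:min(length(clone_ids), p * spec$sample_capacity)]
    slots <- dplyr::mutate(
      sample_slots,
      clone_id = c(ids, rep(NA_character_, nrow(sample_slots) - length(ids)))
    )
    layout |>
      dplyr::left_join(dplyr::select(slots, "well_id", "clone_id"),
                       by = "well_id") |>
      dplyr::mutate(plate_id = sprintf("plate%02d", p), .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Calibrate the fixed threshold and response limit from control wells
#'
#' The fixed Ch2 threshold is set at `mean + k_sigma * SD` of the
#' negative-control ROI pixel-intensity distribution, recovered from per-cell
#' summaries (ROI mean, SD and area measured with a fixed threshold of 0) by
#' the law of total variance. The threshold is placed on the pixel
#' distribution, not on the distribution of per-cell means: with the default
#' rule `response_limit = fixed_threshold`, a single suprathreshold pixel
#' makes a cell a responder, so the threshold must clear single-pixel noise
#' tails for negative controls to score below 1%.
#'
#' @param neg_cells Either a tibble of per-cell measurements from
#'   negative-control wells (columns `roi_mean_intensity`,
#'   `roi_sd_intensity`, `roi_area_px`; from [analyze_well()] run with
#'   `fixed_threshold = 0`), or a plain numeric vector of intensities.
#' @param k_sigma Multiplier on the SD (default 5).
#' @param limit_rule `"fixed_threshold"` (response limit equals the fixed
#'   threshold) or `"scaled"` (`limit_scale` times it).
#' @param limit_scale Multiplier used when `limit_rule = "scaled"`.
#' @param pos_pct,neg_pct Optional vectors of per-well `% Cells High` for
#'   positive and negative control wells, used only to report the
#'   standardized separation between the two distributions.
#' @param min_cells Minimum number of negative-control cells required.
#' @return An `hci_calibration` object with `fixed_threshold`,
#'   `response_limit`, `neg_stats` and `separation`; see also
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @export
calibrate_from_controls <- function(neg_cells, k_sigma = 5,
                                    limit_rule = c("fixed_threshold", "scaled"),
                                    limit_scale = 1,
                                    pos_pct = NULL, neg_pct = NULL,
                                    min_cells = 50L) {
  limit_rule <- match.arg(limit_rule)
  if (is.numeric(neg_cells)) {
    n <- length(neg_cells)
    if (n < min_cells) {
      abort(paste0("Calibration requires >= ", min_cells,
                   " negative-control intensities; got ", n, "."))
    }
    mu <- mean(neg_cells)
    sigma <- if (n > 1) sd(neg_cells) else 0
    neg_stats <- list(pixel_mean = mu, pixel_sd = sigma, n_cells = n,
                      n_pixels = n, cell_mean_mean = mu, cell_mean_sd = sigma)
  } else {
    req <- c("roi_mean_intensity", "roi_sd_intensity", "roi_area_px")
    if (!all(req %in% names(neg_cells))) {
      abort(paste0("`neg_cells` needs columns: ", paste(req, collapse = ", "),
                   " (measure with fixed_threshold = 0)."))
    }
    if (nrow(neg_cells) < min_cells) {
      abort(paste0("Calibration requires >= ", min_cells,
                   " negative-control cells; got ", nrow(neg_cells), "."))
    }
    n_i <- neg_cells$roi_area_px
    m_i <- neg_cells$roi_mean_intensity
    s_i <- neg_cells$roi_sd_intensity
    n_tot <- sum(n_i)
    mu <- sum(n_i * m_i) / n_tot
    ss <- sum((n_i - 1) * s_i^2 + n_i * (m_i - mu)^2)
    sigma <- sqrt(ss / (n_tot - 1))
    neg_stats <- list(
      pixel_mean = mu, pixel_sd = sigma,
      n_cells = nrow(neg_cells), n_pixels = n_tot,
      cell_mean_mean = mean(m_i),
      cell_mean_sd = if (nrow(neg_cells) > 1) sd(m_i) else 0
    )
  }
  fixed_threshold <- mu + k_sigma * sigma
  response_limit <- switch(limit_rule,
    fixed_threshold = fixed_threshold,
    scaled = limit_scale * fixed_threshold
  )
  separation <- NA_real_
  if (!is.null(pos_pct) && !is.null(neg_pct) &&
      length(pos_pct) > 1 && length(neg_pct) > 1) {
    separation <- (mean(pos_pct) - mean(neg_pct)) /
      sqrt(var(pos_pct) + var(neg_pct))
  }
  structure(
    list(fixed_threshold = fixed_threshold, response_limit = response_limit,
         k_sigma = k_sigma, limit_rule = limit_rule,
         neg_stats = neg_stats, separation = separation),
    class = "hci_calibration"
  )
}

#' @export
print.hci_calibration <- function(x, ...) {
  cat(sprintf(
    paste0("<hci_calibration> fixed_threshold = %.2f, response_limit = %.2f\n",
           "  negative controls: %d cells, %d ROI pixels, ",
           "pixel mean %.2f, SD %.2f (k = %g)\n"),
    x$fixed_threshold, x$response_limit, x$neg_stats$n_cells,
    x$neg_stats$n_pixels, x$neg_stats$pixel_mean, x$neg_stats$pixel_sd,
    x$k_sigma
  ))
  if (!is.na(x$separation)) {
    cat(sprintf("  positive/negative separation: %.2f\n", x$separation))
  }
  invisible(x)
}

#' @rdname calibrate_from_controls
#' @param x An `hci_calibration` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hci_calibration <- function(x, ...) {
  tibble(
    term = c("fixed_threshold", "response_limit", "neg_pixel_mean",
             "neg_pixel_sd", "separation"),
    estimate = c(x$fixed_threshold, x$response_limit, x$neg_stats$pixel_mean,
                 x$neg_stats$pixel_sd, x$separation)
  )
}

#' @rdname calibrate_from_controls
#' @exportS3Method generics::glance
glance.hci_calibration <- function(x, ...) {
  tibble(
    fixed_threshold = x$fixed_threshold,
    response_limit = x$response_limit,
    k_sigma = x$k_sigma,
    n_neg_cells = x$neg_stats$n_cells,
    separation = x$separation
  )
}

append_flag <- function(flags, add) {
  ifelse(flags == "" | is.na(flags), add, paste(flags, add, sep = ","))
}

#' Flag wells with abnormally low nuclei counts
#'
#' Compares each analyzable well's average nuclei per field to the plate
#' median (computed over analyzable wells only) and flags wells below
#' `deviation_fraction` of it with `low_cells`, to catch cell-attachment
#' failures.
#'
#' @param records Well-record tibble with `role`, `nuclei_per_field_avg` and
#'   `qc_flags` columns.
#' @param deviation_fraction Fraction of the plate median below which a well
#'   is flagged (default 0.5).
#' @return `records` with updated `qc_flags`.
#' @export
qc_nuclei_counts <- function(records, deviation_fraction = 0.5) {
  analyzable <- records$role != "edge_excluded" &
    !is.na(records$nuclei_per_field_avg)
  if (sum(analyzable) < 10) {
    abort("Nuclei-count QC requires >= 10 analyzable wells.")
  }
  med <- median(records$nuclei_per_field_avg[analyzable])
  low <- analyzable & records$nuclei_per_field_avg < deviation_fraction * med
  records$qc_flags[low] <- append_flag(records$qc_flags[low], "low_cells")
  records
}

#' Rank-ordered hit table
#'
#' Sample wells at or above the hit threshold on `% Cells High`, sorted
#' descending with ties broken by `(plate_id, well_id)`, ranks contiguous
#' from 1. QC-flagged wells are excluded by default.
#'
#' @param records Well-record tibble with `plate_id`, `well_id`, `role`,
#'   `clone_id`, `pct_cells_high`, `nuclei_per_field_avg`, `qc_flags`.
#' @param hit_threshold_pct Minimum `% Cells High` to call a hit (default
#'   10).
#' @param exclude_flagged Drop wells carrying any QC flag.
#' @return Tibble: `rank`, `plate_id`, `well_id`, `clone_id`,
#'   `pct_cells_high`, `nuclei_per_field_avg`, `qc_flags`.
#' @export
call_hits <- function(records, hit_threshold_pct = 10,
                      exclude_flagged = TRUE) {
  hits <- records |>
    dplyr::filter(
      .data$role == "sample",
      !is.na(.data$pct_cells_high),
      .data$pct_cells_high >= hit_threshold_pct
    )
  if (exclude_flagged) {
    hits <- dplyr::filter(hits, is.na(.data$qc_flags) | .data$qc_flags == "")
  }
  hits |>
    dplyr::arrange(dplyr::desc(.data$pct_cells_high), .data$plate_id,
                   .data$well_id) |>
    dplyr::transmute(
      rank = dplyr::row_number(),
      plate_id = .data$plate_id, well_id = .data$well_id,
      clone_id = .data$clone_id,
      pct_cells_high = .data$pct_cells_high,
      nuclei_per_field_avg = .data$nuclei_per_field_avg,
      qc_flags = .data$qc_flags
    )
}

#' Well-feature matrix of one plate
#'
#' Arranges a per-well feature as a 16 x 24 matrix indexed `[A..P, 1..24]`.
#' Edge-excluded and unanalyzed wells are `NA`.
#'
#' @param records Well records of one plate (`well_id`, `row`, `col`, plus
#'   the feature column).
#' @param feature `"nuclei_per_field_avg"` or `"pct_cells_high"`.
#' @param n_rows,n_cols Plate geometry.
#' @return A `plate_heatmap` matrix (rows named A..P, columns 1..24) with
#'   attribute `feature`.
#' @export
heatmap_matrix <- function(records, feature = c("pct_cells_high",
                                                "nuclei_per_field_avg"),
                           n_rows = 16L, n_cols = 24L) {
  feature <- match.arg(feature)
  m <- matrix(NA_real_, n_rows, n_cols,
              dimnames = list(LETTERS[seq_len(n_rows)], seq_len(n_cols)))
  ri <- match(records$row, LETTERS)
  vals <- records[[feature]]
  keep <- !is.na(vals)
  m[cbind(ri[keep], records$col[keep])] <- vals[keep]
  structure(m, feature = feature, class = c("plate_heatmap", class(m)))
}

#' Plot a plate heatmap
#'
#' @param x A `plate_heatmap` matrix from [heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot object (geom_tile over the plate grid; missing wells
#'   blank).
#' @exportS3Method ggplot2::autoplot
autoplot.plate_heatmap <- function(x, ...) {
  df <- tidyr::expand_grid(row = rownames(x), col = seq_len(ncol(x))) |>
    dplyr::mutate(value = as.numeric(t(unclass(x))))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$col, y = factor(.data$row, levels = rev(rownames(x))),
    fill = .data$value
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = attr(x, "feature")) +
    ggplot2::scale_x_continuous(breaks = seq(1, ncol(x), 2),
                                expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.plate_heatmap
#' @param records Well records of one plate.
#' @param feature Feature to plot; see [heatmap_matrix()].
#' @export
plot_plate_heatmap <- function(records, feature = "pct_cells_high") {
  autoplot(heatmap_matrix(records, feature))
}

#' Annotate hits with the screen's probe pool
#'
#' When probes are screened as a pool, a hit only identifies the pool, not
#' the probe; each hit is annotated with the full candidate probe set and
#' flagged for deconvolution (retesting with individual probes) when the pool
#' holds more than one probe. No inference about which probe bound is made.
#'
#' @param hits Hit table from [call_hits()].
#' @param pool_probes Character vector of probe identifiers in the screen's
#'   pool.
#' @return `hits` with `candidate_probes` (semicolon-separated), `pool_size`
#'   and `needs_deconvolution` columns.
#' @export
annotate_pool <- function(hits, pool_probes) {
  if (length(pool_probes) == 0) abort("`pool_probes` must be nonempty.")
  dplyr::mutate(
    hits,
    candidate_probes = paste(pool_probes, collapse = ";"),
    pool_size = length(pool_probes),
    needs_deconvolution = length(pool_probes) > 1
  )
}
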