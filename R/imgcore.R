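# Per-field / per-well analysis: background removal, primary-object (nucleus)
# segmentation in Ch1, circular per-cell ROI expansion, fixed-threshold target
# measurement in Ch2, responder classification, autofocus QC, and well-level
# population statistics.

#' Segmentation parameters for primary objects
#'
#' @param smooth_sigma Gaussian smoothing (px) before thresholding.
#' @param threshold Strategy for the global intensity threshold on the
#'   smoothed, background-subtracted nuclei channel: `"robust"` (default;
#'   median + `noise_k` * MAD, a noise floor that keeps blank fields empty
#'   while catching dimly stained nuclei), `"otsu"` (bimodal histogram split,
#'   bounded below by the same noise floor; can drop dim nuclei when bright
#'   ones dominate), or a fixed numeric intensity.
#' @param noise_k MAD multiplier of the robust noise floor.
#' @param min_area_px Minimum object area; smaller components are discarded.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed.
#' @param split_min_distance Minimum separation (px) between watershed seed
#'   maxima; set near the expected nucleus radius. Seeds are local maxima of
#'   the smoothed interior-distance transform.
#' @param fill_holes Fill enclosed background holes in the nucleus mask.
#' @param exclude_border Drop objects touching the field border (off by
#'   default; border objects are retained).
#' @return A `seg_params` list.
#' @export
seg_params <- function(smooth_sigma = 2, threshold = "robust", noise_k = 6,
                       min_area_px = 50L, split_touching = TRUE,
                       split_min_distance = 6, fill_holes = TRUE,
                       exclude_border = FALSE) {
  if (is.numeric(threshold) && threshold < 0) abort("`threshold` must be >= 0.")
  if (is.character(threshold) && !threshold %in% c("robust", "otsu")) {
    abort("`threshold` must be \"robust\", \"otsu\" or a number.")
  }
  structure(
    list(smooth_sigma = smooth_sigma, threshold = threshold,
         noise_k = noise_k,
         min_area_px = as.integer(min_area_px),
         split_touching = isTRUE(split_touching),
         split_min_distance = split_min_distance,
         fill_holes = isTRUE(fill_holes),
         exclude_border = isTRUE(exclude_border)),
    class = "seg_params"
  )
}

#' Analysis configuration for a well
#'
#' Collects every tunable of the per-well analysis: background removal,
#' segmentation, the per-cell ROI dilation, the fixed Ch2 intensity threshold,
#' the cellular response limit, and autofocus rejection.
#'
#' @param bg_kernel_half Half-width (px) of the square structuring element of
#'   the grayscale-opening background estimate; must be well above the nucleus
#'   radius.
#' @param seg A [seg_params()] object.
#' @param dilation_px Radius of the circular ROI dilation beyond the nucleus
#'   mask.
#' @param fixed_threshold Ch2 intensity cutoff: only pixels at or above it
#'   enter a cell's target mask (inclusive comparison).
#' @param response_limit Per-cell cutoff on the target average intensity that
#'   classifies a cell as ligand-bound; `NULL` means equal to
#'   `fixed_threshold`.
#' @param focus_cutoff_fraction A field is rejected when its sharpness score
#'   falls below this fraction of the reference (by default the median score
#'   of the well's fields).
#' @param focus_reference Optional fixed reference score (e.g. a plate
#'   median); `NULL` uses the within-well median.
#' @param preprocess Apply background removal to both channels before any
#'   measurement.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(bg_kernel_half = 48L, seg = seg_params(),
                            dilation_px = 10L, fixed_threshold = 0,
                            response_limit = NULL,
                            focus_cutoff_fraction = 0.5,
                            focus_reference = NULL,
                            preprocess = TRUE) {
  if (dilation_px < 0) abort("`dilation_px` must be >= 0.")
  if (fixed_threshold < 0) abort("`fixed_threshold` must be >= 0.")
  if (!is.null(response_limit) && response_limit < 0) {
    abort("`response_limit` must be >= 0.")
  }
  structure(
    list(bg_kernel_half = as.integer(bg_kernel_half), seg = seg,
         dilation_px = as.integer(dilation_px),
         fixed_threshold = fixed_threshold,
         response_limit = if (is.null(response_limit)) fixed_threshold
         else response_limit,
         focus_cutoff_fraction = focus_cutoff_fraction,
         focus_reference = focus_reference,
         preprocess = isTRUE(preprocess)),
    class = "analysis_config"
  )
}

#' Remove smoothly varying background fluorescence
#'
#' Estimates the background as a grayscale opening (erosion then dilation)
#' with a large square structuring element and subtracts it, clipping
#' negatives to zero. The opening never exceeds the image, so the output never
#' exceeds the input at any pixel, and a uniform field maps to zero.
#'
#' @param raster Numeric intensity matrix.
#' @param kernel_half Half-width of the structuring element in pixels; must be
#'   much larger than the nucleus radius so objects are not absorbed into the
#'   background estimate.
#' @return Background-subtracted matrix of the same shape.
#' @export
preprocess_background <- function(raster, kernel_half = 48L) {
  if (!is.matrix(raster) || length(raster) == 0) {
    abort("`raster` must be a nonempty matrix.")
  }
  bg <- gray_opening(raster, kernel_half)
  pmax(raster - bg, 0)
}

#' Segment Hoechst-stained nuclei as primary objects
#'
#' Gaussian smoothing, global thresholding (Otsu with a robust noise floor, or
#' a fixed value), hole filling, connected-component labeling, optional
#' distance-transform watershed to split touching nuclei, and a minimum-area
#' filter. Border-touching objects are retained unless `exclude_border` is
#' set.
#'
#' @param ch1 Preprocessed nuclei-channel matrix.
#' @param params A [seg_params()] object.
#' @return A `nuclei_seg` object: list with `objects` (tibble `label`,
#'   `area_px`, `centroid_r`, `centroid_c`) and `labels` (integer matrix, 0 =
#'   background).
#' @export
segment_nuclei <- function(ch1, params = seg_params()) {
  stopifnot(is.matrix(ch1))
  sm <- gaussian_blur(ch1, params$smooth_sigma)
  if (is.character(params$threshold)) {
    floor_thr <- median(sm) + params$noise_k * stats::mad(sm)
    thr <- switch(params$threshold,
      robust = floor_thr,
      otsu = max(otsu_threshold(sm), floor_thr)
    )
  } else {
    thr <- params$threshold
  }
  mask <- sm >= thr
  if (!any(mask)) return(empty_seg(dim(ch1)))
  if (params$fill_holes) mask <- cpp_fill_holes(mask)
  labels <- cpp_label_components(mask)
  if (params$split_touching) {
    # seeds = local maxima of the smoothed interior-distance transform,
    # separated by at least split_min_distance; flood by watershed on -d
    d <- cpp_dist_transform(mask)
    ds <- gaussian_blur(d, 1)
    half <- max(2L, as.integer(floor(params$split_min_distance / 2)))
    marker_mask <- mask & (ds >= cpp_dilate_rect(ds, half) - 1e-9) & (d >= 1)
    dim(marker_mask) <- dim(mask)
    markers <- cpp_label_components(marker_mask)
    labels <- cpp_watershed(-d, markers, mask)
  }
  # minimum-area filter + optional border exclusion, then consecutive relabel
  areas <- tabulate(labels[labels > 0])
  drop <- which(areas < params$min_area_px)
  if (params$exclude_border) {
    border_labels <- unique(c(labels[1, ], labels[nrow(labels), ],
                              labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, border_labels[border_labels > 0])
  }
  if (length(drop) > 0) labels[labels %in% drop] <- 0L
  keep <- sort(unique(labels[labels > 0]))
  if (length(keep) == 0) return(empty_seg(dim(ch1)))
  relab <- integer(max(keep))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  objects <- tibble(
    label = seq_along(keep),
    area_px = as.integer(tabulate(lab, nbins = length(keep))),
    centroid_r = as.numeric(tapply(rr, lab, mean)),
    centroid_c = as.numeric(tapply(cc, lab, mean))
  )
  structure(list(objects = objects, labels = labels), class = "nuclei_seg")
}

empty_seg <- function(dm) {
  structure(
    list(
      objects = tibble(label = integer(), area_px = integer(),
                       centroid_r = numeric(), centroid_c = numeric()),
      labels = matrix(0L, dm[1], dm[2])
    ),
    class = "nuclei_seg"
  )
}

#' @export
print.nuclei_seg <- function(x, ...) {
  cat(sprintf("<nuclei_seg> %d primary objects in a %d x %d px field\n",
              nrow(x$objects), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Build the circular region of interest around one nucleus
#'
#' Morphological dilation of the nucleus mask by a rasterized disk of radius
#' `dilation_px`, clipped to the field bounds. The ROI always contains the
#' nucleus pixels.
#'
#' @param nucleus_mask Logical matrix marking one nucleus's pixels (full field
#'   shape).
#' @param dilation_px Disk radius in pixels (>= 0).
#' @return Logical matrix of the same shape marking the ROI.
#' @export
build_roi <- function(nucleus_mask, dilation_px) {
  stopifnot(is.matrix(nucleus_mask), is.logical(nucleus_mask))
  if (!is.numeric(dilation_px) || dilation_px < 0) {
    abort("`dilation_px` must be >= 0.")
  }
  if (dilation_px == 0) return(nucleus_mask)
  cpp_dilate_disk(nucleus_mask, as.integer(dilation_px))
}

# Fast path used by analyze_field: ROIs for all labels via bounding-box crops.
# Returns a list of integer linear-index vectors, one per label.
build_rois_all <- function(labels, dilation_px) {
  n <- max(labels)
  if (n == 0) return(list())
  nr <- nrow(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  r <- as.integer(dilation_px)
  purrr::map(seq_len(n), function(l) {
    sel <- lab == l
    r0 <- max(1L, min(rr[sel]) - r); r1 <- min(nr, max(rr[sel]) + r)
    c0 <- max(1L, min(cc[sel]) - r); c1 <- min(ncol(labels), max(cc[sel]) + r)
    crop <- labels[r0:r1, c0:c1] == l
    roi <- if (r > 0) cpp_dilate_disk(crop, r) else crop
    w <- which(roi)
    crr <- (w - 1L) %% nrow(roi) + r0
    ccc <- (w - 1L) %/% nrow(roi) + c0
    crr + (ccc - 1L) * nr
  })
}

#' Measure a cell's ligand-channel target signal within its ROI
#'
#' Applies the fixed Ch2 threshold inside the ROI: pixels at or above the
#' threshold form the target identification mask. The target average intensity
#' is the mean over those pixels, and 0 by convention when no pixel passes
#' (unbound cells score 0 rather than a background average).
#'
#' @param ch2 Ligand-channel matrix (preprocessed).
#' @param roi Logical matrix from [build_roi()], or an integer vector of
#'   linear pixel indices.
#' @param fixed_threshold Intensity cutoff (inclusive, >= 0).
#' @return One-row tibble: `roi_area_px`, `target_area_px`,
#'   `target_avg_intensity`, `roi_mean_intensity`, `roi_sd_intensity`.
#' @export
measure_target <- function(ch2, roi, fixed_threshold) {
  if (is.matrix(roi)) roi <- which(roi)
  if (length(roi) == 0) abort("`roi` must contain at least one pixel.")
  if (!is.numeric(fixed_threshold) || fixed_threshold < 0) {
    abort("`fixed_threshold` must be >= 0.")
  }
  v <- ch2[roi]
  tv <- v[v >= fixed_threshold]
  tibble(
    roi_area_px = length(v),
    target_area_px = length(tv),
    target_avg_intensity = if (length(tv) > 0) mean(tv) else 0,
    roi_mean_intensity = mean(v),
    roi_sd_intensity = if (length(v) > 1) sd(v) else 0
  )
}

#' Classify responding cells and compute % Cells High
#'
#' A cell responds when its target average intensity is at or above the
#' response limit (inclusive). `% Cells High` is the percentage of responders
#' among all measured cells; an empty population scores 0.
#'
#' @param measurements Tibble with a `target_avg_intensity` column (from
#'   [measure_target()]).
#' @param response_limit Intensity cutoff (>= 0).
#' @return List with `measurements` (input plus logical `responder`) and
#'   `pct_cells_high` (0-100).
#' @export
classify_response <- function(measurements, response_limit) {
  if (!is.numeric(response_limit) || response_limit < 0) {
    abort("`response_limit` must be >= 0.")
  }
  measurements <- dplyr::mutate(
    measurements,
    responder = .data$target_avg_intensity >= response_limit
  )
  pct <- if (nrow(measurements) > 0) 100 * mean(measurements$responder) else 0
  list(measurements = measurements, pct_cells_high = pct)
}

#' Sharpness score of one field
#'
#' Variance of the 4-neighbour Laplacian of the nuclei channel; defocused
#' fields lose high-frequency content and score lower.
#'
#' @param field A [field_image].
#' @return A nonnegative number.
#' @export
focus_score <- function(field) {
  stopifnot(inherits(field, "field_image"))
  laplacian_variance(field$ch1)
}

#' Assess autofocus quality across a well's fields
#'
#' Scores each field's sharpness and rejects fields whose score falls below
#' `cutoff_fraction` times the reference score (by default the median score of
#' the supplied fields, so a well of uniformly sharp fields accepts all of
#' them).
#'
#' @param fields List of [field_image]s.
#' @param cutoff_fraction Relative cutoff (default 0.5).
#' @param reference Optional fixed reference score; `NULL` = median of
#'   `fields`' scores.
#' @return Tibble: `field_index`, `score`, `accepted`.
#' @export
assess_focus <- function(fields, cutoff_fraction = 0.5, reference = NULL) {
  scores <- purrr::map_dbl(fields, focus_score)
  ref <- if (is.null(reference)) median(scores) else reference
  tibble(
    field_index = purrr::map_int(seq_along(fields), function(i) {
      fi <- fields[[i]]$field_index
      if (is.na(fi)) i else fi
    }),
    score = scores,
    accepted = scores >= cutoff_fraction * ref
  )
}

# analyze one accepted field: preprocess, segment, measure each cell
analyze_field <- function(field, config) {
  ch1 <- field$ch1
  ch2 <- field$ch2
  if (config$preprocess) {
    ch1 <- preprocess_background(ch1, config$bg_kernel_half)
    ch2 <- preprocess_background(ch2, config$bg_kernel_half)
  }
  seg <- segment_nuclei(ch1, config$seg)
  if (nrow(seg$objects) == 0) {
    return(list(objects = seg$objects, cells = NULL))
  }
  rois <- build_rois_all(seg$labels, config$dilation_px)
  cells <- dplyr::bind_cols(
    seg$objects,
    dplyr::bind_rows(purrr::map(rois, function(roi) {
      measure_target(ch2, roi, config$fixed_threshold)
    }))
  )
  list(objects = seg$objects, cells = cells)
}

#' Analyze all fields of one well
#'
#' Rejects out-of-focus fields, segments and measures every accepted field,
#' pools cell measurements across accepted fields, and computes the well's
#' population statistics: the average number of nuclei per accepted field and
#' the percentage of cells classified as ligand-bound. Rejected fields
#' contribute nothing to any statistic. If every field is rejected the well is
#' flagged `no_analyzable_fields` with null-marked features; a well with
#' accepted fields but no cells is flagged `no_cells` and scores 0.
#'
#' @param fields List of [field_image]s (>= 1).
#' @param config An [analysis_config()].
#' @return List with `features` (one-row tibble: `well_id`,
#'   `fields_acquired`, `fields_accepted`, `nuclei_per_field_avg`, `n_cells`,
#'   `pct_cells_high`, `qc_flags`), `cells` (per-cell tibble pooled over
#'   accepted fields, with `field_index` and `responder`), and `focus` (the
#'   [assess_focus()] table).
#' @export
analyze_well <- function(fields, config = analysis_config()) {
  if (length(fields) < 1) abort("`fields` must contain at least one field.")
  well_id <- fields[[1]]$well_id
  focus <- assess_focus(fields, config$focus_cutoff_fraction,
                        config$focus_reference)
  acc <- which(focus$accepted)
  if (length(acc) == 0) {
    return(list(
      features = tibble(
        well_id = well_id, fields_acquired = length(fields),
        fields_accepted = 0L, nuclei_per_field_avg = NA_real_,
        n_cells = NA_integer_, pct_cells_high = NA_real_,
        qc_flags = "no_analyzable_fields"
      ),
      cells = empty_cells(), focus = focus
    ))
  }
  per_field <- purrr::map(acc, function(i) {
    res <- analyze_field(fields[[i]], config)
    if (!is.null(res$cells)) {
      res$cells <- dplyr::mutate(res$cells,
                                 field_index = focus$field_index[i],
                                 .before = 1)
    }
    res
  })
  nuclei_counts <- purrr::map_int(per_field, ~ nrow(.x$objects))
  cells <- dplyr::bind_rows(purrr::compact(purrr::map(per_field, "cells")))
  n_cells <- nrow(cells)
  if (n_cells > 0) {
    cls <- classify_response(cells, config$response_limit)
    pct <- cls$pct_cells_high
    tibble_cells <- dplyr::mutate(cls$measurements, well_id = well_id,
                                  .before = 1)
  } else {
    pct <- 0
    tibble_cells <- empty_cells()
  }
  list(
    features = tibble(
      well_id = well_id,
      fields_acquired = length(fields),
      fields_accepted = length(acc),
      nuclei_per_field_avg = mean(nuclei_counts),
      n_cells = n_cells,
      pct_cells_high = pct,
      qc_flags = if (n_cells == 0) "no_cells" else ""
    ),
    cells = tibble_cells,
    focus = focus
  )
}

empty_cells <- function() {
  tibble(
    well_id = character(), field_index = integer(), label = integer(),
    area_px = integer(), centroid_r = numeric(), centroid_c = numeric(),
    roi_area_px = integer(), target_area_px = integer(),
    target_avg_intensity = numeric(), roi_mean_intensity = numeric(),
    roi_sd_intensity = numeric(), responder = logical()
  )
}
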