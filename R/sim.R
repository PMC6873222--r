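# Synthetic two-channel field/well/plate generator with per-cell ground truth.
# Channel 1 carries Hoechst-like nuclei (soft-edged disks); channel 2 carries
# an Alexa488-like membrane ring around each cell that is transfected AND
# bound by the probe. Every draw is seeded, so identical (params, seed) give
# bit-identical images and truth.

#' Simulation parameters for a synthetic imaging field
#'
#' Describes one field of view of a well: geometry, expected cell density and
#' nucleus size, the transfected / ligand-bound subpopulation structure, the
#' two channels' signal amplitudes, background and noise, and optional defocus
#' blur. Defaults approximate a 20x field of adherent HEK293 cells at the
#' screen's working confluency on a 16-bit camera.
#'
#' @param field_height_px,field_width_px Field dimensions in pixels.
#' @param bit_depth 8 or 16; intensities are clipped to `2^bit_depth - 1`.
#' @param n_cells_mean Expected number of cells per field (Poisson draw).
#' @param nucleus_radius_px,nucleus_radius_sd_px Mean and SD of the nucleus
#'   radius in pixels.
#' @param min_center_spacing_px Minimum distance between nucleus centers
#'   (rejection sampling); relaxed for the clumped subpopulation.
#' @param clump_fraction Fraction of cells placed touching an existing cell to
#'   stress segmentation (0 disables clumping).
#' @param transfected_fraction Fraction of cells expressing the receptor.
#' @param bound_fraction Fraction of *transfected* cells displaying ligand
#'   signal; non-transfected cells never do.
#' @param ch1_signal_mean,ch1_signal_sd Nucleus amplitude above background.
#' @param ch2_ring_signal_mean,ch2_ring_signal_sd Peak membrane-ring amplitude
#'   above background.
#' @param ch2_ring_width_px Full width of the ring's radial Gaussian profile.
#' @param membrane_offset_px Ring radius beyond the nucleus radius.
#' @param background_level Additive background per channel (scalar, both
#'   channels).
#' @param noise_sd Per-pixel additive Gaussian noise SD (both channels).
#' @param defocus_sigma_px Gaussian blur applied to the noiseless signal
#'   before noise is added; 0 = in focus.
#' @param seed Default seed used by [generate_field()] when none is given.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(field_height_px = 1104L,
                       field_width_px = 1104L,
                       bit_depth = 16L,
                       n_cells_mean = 200,
                       nucleus_radius_px = 16,
                       nucleus_radius_sd_px = 2,
                       min_center_spacing_px = 40,
                       clump_fraction = 0,
                       transfected_fraction = 0.5,
                       bound_fraction = 1,
                       ch1_signal_mean = 20000,
                       ch1_signal_sd = 3000,
                       ch2_ring_signal_mean = 15000,
                       ch2_ring_signal_sd = 2000,
                       ch2_ring_width_px = 4,
                       membrane_offset_px = 3,
                       background_level = 2000,
                       noise_sd = 300,
                       defocus_sigma_px = 0,
                       seed = 1L) {
  p <- list(
    field_height_px = as.integer(field_height_px),
    field_width_px = as.integer(field_width_px),
    bit_depth = as.integer(bit_depth),
    n_cells_mean = n_cells_mean,
    nucleus_radius_px = nucleus_radius_px,
    nucleus_radius_sd_px = nucleus_radius_sd_px,
    min_center_spacing_px = min_center_spacing_px,
    clump_fraction = clump_fraction,
    transfected_fraction = transfected_fraction,
    bound_fraction = bound_fraction,
    ch1_signal_mean = ch1_signal_mean,
    ch1_signal_sd = ch1_signal_sd,
    ch2_ring_signal_mean = ch2_ring_signal_mean,
    ch2_ring_signal_sd = ch2_ring_signal_sd,
    ch2_ring_width_px = ch2_ring_width_px,
    membrane_offset_px = membrane_offset_px,
    background_level = background_level,
    noise_sd = noise_sd,
    defocus_sigma_px = defocus_sigma_px,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fracs <- c("clump_fraction", "transfected_fraction", "bound_fraction")
  for (f in fracs) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      abort(paste0("`", f, "` must be a proportion in [0, 1]."))
    }
  }
  nonneg <- c(
    "n_cells_mean", "nucleus_radius_px", "nucleus_radius_sd_px",
    "min_center_spacing_px", "ch1_signal_mean", "ch1_signal_sd",
    "ch2_ring_signal_mean", "ch2_ring_signal_sd", "ch2_ring_width_px",
    "membrane_offset_px", "background_level", "noise_sd", "defocus_sigma_px"
  )
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0) {
      abort(paste0("`", f, "` must be >= 0."))
    }
  }
  if (!p$bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  if (p$field_height_px < 8L || p$field_width_px < 8L) {
    abort("Field dimensions must be at least 8 px.")
  }
  invisible(p)
}

#' Two-channel field image container
#'
#' @param ch1,ch2 Numeric matrices of identical dimensions (nuclei and ligand
#'   channels).
#' @param well_id Plate coordinate (e.g. `"B03"`), or `NA`.
#' @param field_index Field number within the well, or `NA`.
#' @param bit_depth 8 or 16.
#' @return A `field_image` object.
#' @export
field_image <- function(ch1, ch2, well_id = NA_character_,
                        field_index = NA_integer_, bit_depth = 16L) {
  stopifnot(is.matrix(ch1), is.matrix(ch2))
  if (!identical(dim(ch1), dim(ch2))) {
    abort("`ch1` and `ch2` must have identical dimensions.")
  }
  maxv <- 2^bit_depth - 1
  if (min(ch1) < 0 || min(ch2) < 0 || max(ch1) > maxv || max(ch2) > maxv) {
    abort("Channel intensities must lie in [0, 2^bit_depth - 1].")
  }
  structure(
    list(ch1 = ch1, ch2 = ch2, well_id = well_id,
         field_index = as.integer(field_index), bit_depth = as.integer(bit_depth)),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image> %d x %d px, %d-bit, well %s field %s\n",
    nrow(x$ch1), ncol(x$ch1), x$bit_depth,
    x$well_id, x$field_index
  ))
  invisible(x)
}

# soft-edged disk / annulus rendering onto an accumulator matrix, restricted
# to the bounding box of the structure
render_radial <- function(acc, cr, cc, amp, profile, reach) {
  nr <- nrow(acc); nc <- ncol(acc)
  r0 <- max(1L, floor(cr - reach)); r1 <- min(nr, ceiling(cr + reach))
  c0 <- max(1L, floor(cc - reach)); c1 <- min(nc, ceiling(cc + reach))
  if (r0 > r1 || c0 > c1) return(acc)
  dr <- (r0:r1) - cr
  dc <- (c0:c1) - cc
  d <- sqrt(outer(dr^2, dc^2, `+`))
  acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + amp * profile(d)
  acc
}

# conservative packing capacity: half the random-sequential-adsorption
# jamming density for disks of diameter `spacing` on the placeable area
packing_capacity <- function(nr, nc, margin, spacing) {
  area <- max(0, nr - 2 * margin) * max(0, nc - 2 * margin)
  if (spacing <= 0) return(.Machine$integer.max)
  # well below the ~0.55 random-sequential-adsorption jamming coverage, so
  # rejection sampling reliably terminates
  floor(0.45 * area / (pi * (spacing / 2)^2))
}

place_centers <- function(n, nr, nc, margin, spacing, clump_fraction) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1) {
    abort("Field too small for the nucleus radius margin.")
  }
  if (packing_capacity(nr, nc, margin, spacing) < 1) {
    abort(paste0(
      "Field of ", nr, " x ", nc, " px is too small for min_center_spacing_px = ",
      spacing, "; no cell can be placed."
    ))
  }
  centers <- matrix(NA_real_, nrow = n, ncol = 2)
  clumped <- runif(n) < clump_fraction
  clumped[1] <- FALSE
  placed <- 0L
  for (i in seq_len(n)) {
    anchors <- which(!clumped[seq_len(placed)])  # clumps do not chain
    if (clumped[i] && length(anchors) > 0L) {
      # attach to a regularly placed cell at touching distance (disks are
      # tangent at 2 radii; 1.7-2.1 radii gives mild overlap to contact)
      anchor <- centers[anchors[sample.int(length(anchors), 1L)], ]
      ok <- FALSE
      for (a in 1:50) {
        ang <- runif(1, 0, 2 * pi)
        dist <- runif(1, 1.7, 2.1) * margin
        cand <- anchor + dist * c(cos(ang), sin(ang))
        if (cand[1] >= 1 + margin && cand[1] <= nr - margin &&
            cand[2] >= 1 + margin && cand[2] <= nc - margin) {
          ok <- TRUE
          break
        }
      }
      if (!ok) cand <- anchor  # degenerate fallback: full overlap
    } else {
      ok <- FALSE
      for (a in 1:1000) {
        cand <- c(runif(1, 1 + margin, nr - margin),
                  runif(1, 1 + margin, nc - margin))
        if (placed == 0L) { ok <- TRUE; break }
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
          (centers[seq_len(placed), 2] - cand[2])^2
        if (min(d2) >= spacing^2) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(paste0(
          "Could not place ", n, " cells with min_center_spacing_px = ",
          spacing, " in a ", nr, " x ", nc,
          " px field; the field is too small for the requested spacing."
        ))
      }
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Draws a Poisson number of cells, places nucleus centers by rejection
#' sampling with a minimum spacing (optionally relaxed for a clumped
#' subpopulation), marks each cell transfected and, among transfected cells,
#' ligand-bound, then renders soft-edged nucleus disks into channel 1 and
#' annular membrane rings around bound cells into channel 2. Background and
#' per-pixel Gaussian noise are added to both channels and intensities are
#' clipped to the bit depth. Identical `(params, seed)` give bit-identical
#' output.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @param well_id,field_index Optional identifiers stamped on the image.
#' @return A list with elements `image` ([field_image]) and `truth` (a
#'   `field_truth` list: `cells` tibble with `center_r`, `center_c`,
#'   `radius`, `transfected`, `bound`; `params`; `true_bound_fraction`).
#' @export
generate_field <- function(params, seed = params$seed,
                           well_id = NA_character_, field_index = 1L) {
  validate_sim_params(params)
  withr::with_seed(seed, {
    nr <- params$field_height_px
    nc <- params$field_width_px
    margin <- ceiling(params$nucleus_radius_px)
    capacity <- packing_capacity(nr, nc, margin,
                                 params$min_center_spacing_px)
    if (capacity < 1 && params$n_cells_mean > 0) {
      abort(paste0(
        "Field of ", nr, " x ", nc,
        " px cannot hold any cell at min_center_spacing_px = ",
        params$min_center_spacing_px, "."
      ))
    }
    # cell density saturates at a packing limit, as in a confluent monolayer
    n <- min(rpois(1L, params$n_cells_mean), capacity)
    radii <- pmax(2, rnorm(n, params$nucleus_radius_px,
                           params$nucleus_radius_sd_px))
    centers <- place_centers(n, nr, nc, margin,
                             params$min_center_spacing_px,
                             params$clump_fraction)
    transfected <- runif(n) < params$transfected_fraction
    bound <- transfected & (runif(n) < params$bound_fraction)
    amps1 <- pmax(0, rnorm(n, params$ch1_signal_mean, params$ch1_signal_sd))
    amps2 <- pmax(0, rnorm(n, params$ch2_ring_signal_mean,
                           params$ch2_ring_signal_sd))
    s1 <- matrix(0, nr, nc)
    s2 <- matrix(0, nr, nc)
    edge <- 1.0  # px, Gaussian falloff at the nucleus rim
    ring_sd <- max(0.5, params$ch2_ring_width_px / 2)
    for (i in seq_len(n)) {
      r <- radii[i]
      s1 <- render_radial(
        s1, centers[i, 1], centers[i, 2], amps1[i],
        function(d) exp(-pmax(0, d - r)^2 / (2 * edge^2)),
        r + 3 * edge
      )
      if (bound[i]) {
        rr <- r + params$membrane_offset_px
        s2 <- render_radial(
          s2, centers[i, 1], centers[i, 2], amps2[i],
          function(d) exp(-(d - rr)^2 / (2 * ring_sd^2)),
          rr + 3 * ring_sd
        )
      }
    }
    if (params$defocus_sigma_px > 0) {
      s1 <- gaussian_blur(s1, params$defocus_sigma_px)
      s2 <- gaussian_blur(s2, params$defocus_sigma_px)
    }
    maxv <- 2^params$bit_depth - 1
    quantize <- function(s) {
      matrix(
        pmin(pmax(round(s + params$background_level +
                          rnorm(nr * nc, 0, params$noise_sd)), 0), maxv),
        nr, nc
      )
    }
    ch1 <- quantize(s1)
    ch2 <- quantize(s2)
    truth <- structure(
      list(
        cells = tibble(
          cell = seq_len(n),
          center_r = centers[, 1], center_c = centers[, 2],
          radius = radii, transfected = transfected, bound = bound
        ),
        params = params,
        true_bound_fraction = if (n > 0) mean(bound) else 0
      ),
      class = "field_truth"
    )
    list(
      image = field_image(ch1, ch2, well_id, field_index, params$bit_depth),
      truth = truth
    )
  })
}

#' Defocus a field image
#'
#' Gaussian-blurs both channels, emulating an autofocus failure. `sigma = 0`
#' returns the input unchanged.
#'
#' @param image A [field_image].
#' @param sigma Blur scale in pixels (>= 0).
#' @return A blurred `field_image`.
#' @export
apply_defocus <- function(image, sigma) {
  stopifnot(inherits(image, "field_image"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    abort("`sigma` must be a single value >= 0.")
  }
  if (sigma == 0) return(image)
  image$ch1 <- gaussian_blur(image$ch1, sigma)
  image$ch2 <- gaussian_blur(image$ch2, sigma)
  image
}

# deterministic per-well / per-field seed derivation; stays below 2^31
derive_seed <- function(seed, i, j = 0L) {
  m <- 2147483629
  as.integer((as.numeric(seed) %% m * 48271 + i * 69621 + j * 1013) %% m) + 1L
}

#' Generate all fields of one synthetic well
#'
#' @param params A [sim_params()] object for the well's population.
#' @param n_fields Number of fields of view to generate.
#' @param seed Integer seed for the well; field seeds are derived from it.
#' @param well_id Optional well identifier stamped on the images.
#' @return A list with `fields` (list of [field_image]), `truths` (list of
#'   `field_truth`) and `true_bound_fraction` pooled over all cells of the
#'   well.
#' @export
generate_well <- function(params, n_fields = 4L, seed = params$seed,
                          well_id = NA_character_) {
  if (n_fields < 1L) abort("`n_fields` must be >= 1.")
  out <- purrr::map(seq_len(n_fields), function(k) {
    generate_field(params, seed = derive_seed(seed, 0L, k),
                   well_id = well_id, field_index = k)
  })
  cells <- purrr::map_int(out, ~ nrow(.x$truth$cells))
  bound <- purrr::map_int(out, ~ sum(.x$truth$cells$bound))
  list(
    fields = purrr::map(out, "image"),
    truths = purrr::map(out, "truth"),
    true_bound_fraction = if (sum(cells) > 0) sum(bound) / sum(cells) else 0
  )
}

#' Generate a full synthetic plate
#'
#' Produces the configured number of fields for every analyzable well of the
#' layout, with parameters selected by well role. Negative-control wells are
#' forced to `bound_fraction = 0`. Generation is deterministic per well: the
#' same `(layout, params, seed)` reproduce the same plate.
#'
#' @param layout Tibble from [build_layout()] (`well_id`, `row`, `col`,
#'   `role`).
#' @param per_role_params Named list mapping each role present in the layout
#'   (other than `edge_excluded`) to a [sim_params()] object.
#' @param seed Integer seed.
#' @param fields_per_well Fields of view per well.
#' @return A list of per-well entries (`well_id`, `role`, `fields`, `truths`,
#'   `true_bound_fraction`). At default field size this is large; use small
#'   fields or [simulate_plate_images()] for full plates.
#' @export
generate_plate <- function(layout, per_role_params, seed = 1L,
                           fields_per_well = 4L) {
  wells <- dplyr::filter(layout, .data$role != "edge_excluded")
  roles <- unique(wells$role)
  missing <- setdiff(roles, names(per_role_params))
  if (length(missing) > 0) {
    abort(paste0("No sim_params supplied for role(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (fields_per_well < 1L) abort("`fields_per_well` must be >= 1.")
  purrr::map(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    p <- per_role_params[[w$role]]
    if (w$role == "negative_control") p$bound_fraction <- 0
    gw <- generate_well(p, fields_per_well,
                        seed = derive_seed(seed, match(w$well_id, layout$well_id)),
                        well_id = w$well_id)
    c(list(well_id = w$well_id, role = w$role), gw)
  })
}

#' Simulate a plate to TIFF files on disk
#'
#' Writes per-field grayscale TIFFs named
#' `<plate>_<well>_f<field>_ch<1|2>.tif`, a JSON ground-truth sidecar per
#' well, and a CSV manifest listing every image file.
#'
#' @inheritParams generate_plate
#' @param out_dir Output directory (created if absent).
#' @param plate_id Plate identifier used in file names.
#' @param wells Optional character vector restricting simulation to a subset
#'   of well ids.
#' @return The manifest tibble (`plate`, `well`, `field`, `channel`, `path`),
#'   also written to `manifest.csv` in `out_dir`.
#' @export
simulate_plate_images <- function(layout, per_role_params, out_dir,
                                  plate_id = "plate01", seed = 1L,
                                  fields_per_well = 4L, wells = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  todo <- dplyr::filter(layout, .data$role != "edge_excluded")
  if (!is.null(wells)) todo <- dplyr::filter(todo, .data$well_id %in% wells)
  roles <- unique(todo$role)
  missing <- setdiff(roles, names(per_role_params))
  if (length(missing) > 0) {
    abort(paste0("No sim_params supplied for role(s): ",
                 paste(missing, collapse = ", ")))
  }
  rows <- purrr::map(seq_len(nrow(todo)), function(i) {
    w <- todo[i, ]
    p <- per_role_params[[w$role]]
    if (w$role == "negative_control") p$bound_fraction <- 0
    gw <- generate_well(p, fields_per_well,
                        seed = derive_seed(seed, match(w$well_id, layout$well_id)),
                        well_id = w$well_id)
    truth_path <- file.path(out_dir,
                            sprintf("%s_%s_truth.json", plate_id, w$well_id))
    truth <- list(
      well_id = w$well_id, role = w$role,
      true_bound_fraction = gw$true_bound_fraction,
      fields = purrr::map(gw$truths, function(t) {
        list(n_cells = nrow(t$cells),
             cells = as.data.frame(t$cells))
      })
    )
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    purrr::map(seq_len(fields_per_well), function(k) {
      purrr::map(1:2, function(ch) {
        path <- file.path(out_dir, sprintf("%s_%s_f%d_ch%d.tif",
                                           plate_id, w$well_id, k, ch))
        img <- if (ch == 1) gw$fields[[k]]$ch1 else gw$fields[[k]]$ch2
        write_gray_tiff(img, path, bit_depth = p$bit_depth)
        tibble(plate = plate_id, well = w$well_id, field = k,
               channel = ch, path = path)
      })
    })
  })
  manifest <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
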