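# Orchestration: simulate -> analyze -> calibrate -> QC -> hit calling, from
# in-memory synthetic plates or from TIFF manifests on disk. Calibration is
# two-pass: control wells are first measured with a fixed threshold of 0 (so
# per-cell ROI pixel statistics are recoverable), thresholds are derived from
# the negative controls, then every well is analyzed under the calibrated
# configuration. Generation/loading is deterministic per well, so both passes
# see identical images.

#' Serialize / restore an analysis configuration
#'
#' JSON round-trip of an [analysis_config()] (including its nested
#' [seg_params()]), used for reproducible runs.
#'
#' @param config An [analysis_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the restored `analysis_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- unclass(config)
  x$seg <- unclass(x$seg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- do.call(seg_params, x$seg)
  x$seg <- NULL
  cfg <- do.call(analysis_config, c(x["bg_kernel_half"], list(seg = seg),
                                    x[setdiff(names(x), "bg_kernel_half")]))
  cfg
}

#' Build a field-image manifest from a directory of TIFFs
#'
#' Reconstructs the manifest from files following the simulator's naming
#' convention `<plate>_<well>_f<field>_ch<1|2>.tif`.
#'
#' @param dir Directory containing the per-field TIFFs.
#' @return Manifest tibble (`plate`, `well`, `field`, `channel`, `path`).
#' @export
manifest_from_dir <- function(dir) {
  files <- list.files(dir, pattern = "_f[0-9]+_ch[12]\\.tif$",
                      full.names = TRUE)
  if (length(files) == 0) {
    abort(paste0("No field TIFFs matching the naming convention in: ", dir))
  }
  base <- sub("\\.tif$", "", basename(files))
  parts <- regmatches(base, regexec("^(.+)_([A-P][0-9]{2})_f([0-9]+)_ch([12])$",
                                    base))
  keep <- lengths(parts) == 5
  parts <- parts[keep]
  tibble(
    plate = vapply(parts, `[[`, character(1), 2),
    well = vapply(parts, `[[`, character(1), 3),
    field = as.integer(vapply(parts, `[[`, character(1), 4)),
    channel = as.integer(vapply(parts, `[[`, character(1), 5)),
    path = files[keep]
  ) |>
    dplyr::arrange(.data$plate, .data$well, .data$field, .data$channel)
}

# read one well's fields from manifest rows; malformed/missing files degrade
# to a dropped field with a warning (mirrors autofocus rejection)
load_well_fields <- function(rows, well_id) {
  fields <- list()
  for (k in sort(unique(rows$field))) {
    fr <- rows[rows$field == k, ]
    p1 <- fr$path[fr$channel == 1]
    p2 <- fr$path[fr$channel == 2]
    if (length(p1) != 1 || length(p2) != 1) {
      warn(paste0("Well ", well_id, " field ", k,
                  ": missing channel image; field dropped."))
      next
    }
    img <- tryCatch({
      ch1 <- read_gray_tiff(p1)
      ch2 <- read_gray_tiff(p2)
      field_image(ch1, ch2, well_id, as.integer(k),
                  attr(ch1, "bit_depth"))
    }, error = function(e) {
      warn(paste0("Well ", well_id, " field ", k, ": ",
                  conditionMessage(e), "; field dropped."))
      NULL
    })
    if (!is.null(img)) fields[[length(fields) + 1L]] <- img
  }
  fields
}

null_features <- function(well_id, flag = "no_analyzable_fields") {
  tibble(
    well_id = well_id, fields_acquired = 0L, fields_accepted = 0L,
    nuclei_per_field_avg = NA_real_, n_cells = NA_integer_,
    pct_cells_high = NA_real_, qc_flags = flag
  )
}

#' Run the screening pipeline on a manifest of field images
#'
#' Loads per-field TIFFs well by well, optionally calibrates the fixed
#' threshold and response limit from the plate map's negative-control wells,
#' analyzes every well, applies nuclei-count QC, and calls rank-ordered hits.
#' Missing or malformed field images degrade to dropped fields, not aborted
#' plates. Rerunning with identical inputs yields identical outputs.
#'
#' @param manifest Data frame (or CSV path) with columns `plate`, `well`,
#'   `field`, `channel`, `path`.
#' @param platemap Data frame (or CSV path) with columns `plate`, `well`,
#'   `role` and optionally `clone_id`.
#' @param config An [analysis_config()]. When `calibrate` is `TRUE` its
#'   `fixed_threshold`/`response_limit` are replaced by calibrated values.
#' @param calibrate Calibrate thresholds from negative-control wells.
#' @param k_sigma Calibration multiplier (see [calibrate_from_controls()]).
#' @param hit_threshold_pct Hit threshold on `% Cells High`.
#' @param qc_deviation_fraction See [qc_nuclei_counts()].
#' @param out_dir Optional output directory: writes `well_features.csv`,
#'   `hit_table.csv`, `calibration.json`, `run_log.json`, heatmap PNGs per
#'   plate and feature, and (optionally) `cells.csv`.
#' @param write_cells Persist per-cell measurements (population statistics
#'   only are written by default, keeping storage small).
#' @return List: `records` (well-record tibble), `calibration`, `hits`,
#'   `cells` (per-cell tibble if `write_cells`, else `NULL`).
#' @export
run_pipeline <- function(manifest, platemap, config = analysis_config(),
                         calibrate = TRUE, k_sigma = 5,
                         hit_threshold_pct = 10,
                         qc_deviation_fraction = 0.5,
                         out_dir = NULL, write_cells = FALSE) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) abort(paste0("Manifest not found: ", manifest))
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  if (is.character(platemap)) {
    if (!file.exists(platemap)) abort(paste0("Plate map not found: ", platemap))
    platemap <- readr::read_csv(platemap, show_col_types = FALSE)
  }
  manifest <- as_tibble(manifest)
  platemap <- as_tibble(platemap)
  if (nrow(platemap) == 0) abort("Plate map is empty.")
  if (!"clone_id" %in% names(platemap)) platemap$clone_id <- NA_character_
  wells <- manifest |>
    dplyr::distinct(.data$plate, .data$well) |>
    dplyr::left_join(platemap, by = c("plate", "well"))

  analyze_one <- function(plate, well, cfg) {
    rows <- manifest[manifest$plate == plate & manifest$well == well, ]
    fields <- load_well_fields(rows, well)
    if (length(fields) == 0) {
      return(list(features = null_features(well), cells = empty_cells()))
    }
    analyze_well(fields, cfg)
  }

  calibration <- NULL
  if (calibrate) {
    cfg0 <- config
    cfg0$fixed_threshold <- 0
    cfg0$response_limit <- 0
    neg <- wells[which(wells$role == "negative_control"), ]
    neg_cells <- dplyr::bind_rows(purrr::map(seq_len(nrow(neg)), function(i) {
      analyze_one(neg$plate[i], neg$well[i], cfg0)$cells
    }))
    calibration <- calibrate_from_controls(neg_cells, k_sigma = k_sigma)
    config$fixed_threshold <- calibration$fixed_threshold
    config$response_limit <- calibration$response_limit
  }

  res <- purrr::map(seq_len(nrow(wells)), function(i) {
    analyze_one(wells$plate[i], wells$well[i], config)
  })
  features <- dplyr::bind_rows(purrr::map(res, "features")) |>
    dplyr::select(-"well_id")
  records <- dplyr::bind_cols(wells, features) |>
    dplyr::rename(plate_id = "plate", well_id = "well") |>
    dplyr::mutate(
      row = substr(.data$well_id, 1, 1),
      col = as.integer(substr(.data$well_id, 2, 3)),
      .after = "well_id"
    )
  records <- tryCatch(
    qc_nuclei_counts(records, qc_deviation_fraction),
    error = function(e) {
      warn(paste0("Nuclei-count QC skipped: ", conditionMessage(e)))
      records
    }
  )
  hits <- call_hits(records, hit_threshold_pct)
  cells <- if (write_cells) dplyr::bind_rows(purrr::map(res, "cells")) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(records, file.path(out_dir, "well_features.csv"))
    readr::write_csv(hits, file.path(out_dir, "hit_table.csv"))
    if (!is.null(cells)) readr::write_csv(cells, file.path(out_dir, "cells.csv"))
    if (!is.null(calibration)) {
      jsonlite::write_json(
        list(fixed_threshold = calibration$fixed_threshold,
             response_limit = calibration$response_limit,
             k_sigma = calibration$k_sigma,
             neg_stats = calibration$neg_stats),
        file.path(out_dir, "calibration.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    jsonlite::write_json(
      list(
        config_hash = rlang::hash(config),
        fixed_threshold = config$fixed_threshold,
        response_limit = config$response_limit,
        hit_threshold_pct = hit_threshold_pct,
        qc_deviation_fraction = qc_deviation_fraction,
        n_wells = nrow(wells), n_hits = nrow(hits)
      ),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA
    )
    for (p in unique(records$plate_id)) {
      pr <- records[records$plate_id == p, ]
      for (f in c("pct_cells_high", "nuclei_per_field_avg")) {
        ggplot2::ggsave(
          file.path(out_dir, sprintf("heatmap_%s_%s.png", p, f)),
          autoplot(heatmap_matrix(pr, f)), width = 8, height = 5, dpi = 120
        )
      }
    }
  }
  list(records = records, calibration = calibration, hits = hits,
       cells = cells)
}

#' Simulate and analyze a full synthetic one-plate screen in memory
#'
#' Generates a seeded synthetic 384-well plate (border wells excluded,
#' controls in the configured columns), plants a chosen number of
#' ligand-binding sample wells among non-binding ones, calibrates the fixed
#' threshold and response limit from the negative controls, analyzes every
#' well, applies nuclei-count QC and calls hits. Wells are generated and
#' analyzed one at a time, so memory stays flat. The same seed reproduces
#' the identical screen.
#'
#' @param spec A [plate_spec()].
#' @param base_params [sim_params()] shared by all wells; `bound_fraction`
#'   is overridden per role (0 for samples and negative controls,
#'   `pos_bound_fraction` for positive controls, `planted_bound_fraction`
#'   for planted sample wells).
#' @param n_planted Number of sample wells planted with a true binding
#'   population.
#' @param planted_bound_fraction Bound fraction of planted wells.
#' @param pos_bound_fraction Bound fraction of positive-control wells.
#' @param seed Integer master seed.
#' @param config Base [analysis_config()] (thresholds are calibrated).
#' @param k_sigma Calibration multiplier.
#' @param hit_threshold_pct Hit threshold on `% Cells High`.
#' @param qc_deviation_fraction See [qc_nuclei_counts()].
#' @return List: `records` (well records with `true_bound_fraction`),
#'   `calibration`, `hits`, `planted` (planted well ids), `layout`.
#' @export
simulate_screen <- function(spec = plate_spec(),
                            base_params = sim_params(),
                            n_planted = 3L,
                            planted_bound_fraction = 0.4,
                            pos_bound_fraction = 0.5,
                            seed = 1L,
                            config = analysis_config(),
                            k_sigma = 5,
                            hit_threshold_pct = 10,
                            qc_deviation_fraction = 0.5) {
  layout <- build_layout(spec)
  analyzable <- dplyr::filter(layout, .data$role != "edge_excluded")
  sample_wells <- analyzable$well_id[analyzable$role == "sample"]
  planted <- withr::with_seed(
    derive_seed(seed, 999983L),
    sort(sample(sample_wells, n_planted))
  )
  well_params <- function(role, well_id) {
    p <- base_params
    p$bound_fraction <- dplyr::case_when(
      role == "positive_control" ~ pos_bound_fraction,
      role == "sample" & well_id %in% planted ~ planted_bound_fraction,
      .default = 0
    )
    p
  }
  gen_well <- function(well_id, role) {
    generate_well(well_params(role, well_id), spec$fields_per_well,
                  seed = derive_seed(seed, match(well_id, layout$well_id)),
                  well_id = well_id)
  }

  # pass 1: negative controls at threshold 0 for calibration
  cfg0 <- config
  cfg0$fixed_threshold <- 0
  cfg0$response_limit <- 0
  neg <- dplyr::filter(analyzable, .data$role == "negative_control")
  neg_cells <- dplyr::bind_rows(
    purrr::map(seq_len(nrow(neg)), function(i) {
      gw <- gen_well(neg$well_id[i], "negative_control")
      analyze_well(gw$fields, cfg0)$cells
    })
  )
  calibration <- calibrate_from_controls(neg_cells, k_sigma = k_sigma)
  config$fixed_threshold <- calibration$fixed_threshold
  config$response_limit <- calibration$response_limit

  # pass 2: every analyzable well under the calibrated configuration
  res <- purrr::map(seq_len(nrow(analyzable)), function(i) {
    w <- analyzable[i, ]
    gw <- gen_well(w$well_id, w$role)
    out <- analyze_well(gw$fields, config)
    dplyr::mutate(out$features,
                  true_bound_fraction = gw$true_bound_fraction)
  })
  features <- dplyr::bind_rows(res) |> dplyr::select(-"well_id")
  records <- layout |>
    dplyr::left_join(
      dplyr::bind_cols(dplyr::select(analyzable, "well_id"), features),
      by = "well_id"
    ) |>
    dplyr::mutate(
      plate_id = "plate01",
      clone_id = NA_character_,
      .before = 1
    )
  records$qc_flags[is.na(records$qc_flags) & records$role != "edge_excluded"] <- ""
  records <- qc_nuclei_counts(records, qc_deviation_fraction)
  # report control separation on the calibrated features
  pos_pct <- records$pct_cells_high[records$role == "positive_control"]
  neg_pct <- records$pct_cells_high[records$role == "negative_control"]
  if (length(pos_pct) > 1 && length(neg_pct) > 1 &&
      var(pos_pct) + var(neg_pct) > 0) {
    calibration$separation <- (mean(pos_pct) - mean(neg_pct)) /
      sqrt(var(pos_pct) + var(neg_pct))
  }
  hits <- call_hits(records, hit_threshold_pct)
  list(records = records, calibration = calibration, hits = hits,
       planted = planted, layout = layout)
}
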