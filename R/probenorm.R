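# Beta-lactamase activity normalization: probes carry a beta-lactamase tag,
# so the nitrocefin hydrolysis rate (absorbance at 485 nm vs time) is a
# concentration proxy. Equalizing rates by dilution equalizes probe amounts
# before screening.

#' Nitrocefin hydrolysis rate of one activity series
#'
#' Ordinary least-squares slope of absorbance (485 nm) against time over the
#' chosen window. A constant series has rate 0.
#'
#' @param series Data frame with numeric columns `time_s` (strictly
#'   increasing, seconds) and `a485` (absorbance units, finite and >= 0).
#' @param window Optional `c(start, end)` in seconds restricting the fit to a
#'   linear portion; default uses the full series.
#' @return Rate in AU/s (slope).
#' @export
hydrolysis_rate <- function(series, window = NULL) {
  if (!all(c("time_s", "a485") %in% names(series))) {
    abort("`series` needs columns `time_s` and `a485`.")
  }
  t <- series$time_s
  y <- series$a485
  if (any(!is.finite(t)) || any(!is.finite(y)) || any(y < 0)) {
    abort("Readings must be finite and >= 0.")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing.")
  }
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 3) abort("Need at least 3 points in the fit window.")
  unname(coef(lm(y ~ t))[2])
}

#' Hydrolysis rates for a table of probes
#'
#' @param activity Data frame with columns `probe_id`, `time_s`, `a485` (and
#'   optionally `dilution`, ignored here).
#' @param window Optional fit window passed to [hydrolysis_rate()].
#' @return Tibble: `probe_id`, `rate`.
#' @export
hydrolysis_rates <- function(activity, window = NULL) {
  activity |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      rate = hydrolysis_rate(dplyr::pick("time_s", "a485"), window),
      .groups = "drop"
    )
}

#' Dilution plan equalizing probe activities
#'
#' Expresses each probe's activity relative to a reference (the slowest probe
#' by default, so normalization is dilute-only) and prescribes the fold
#' dilution that equalizes activities. Probes below the reference are not
#' concentrated: they get factor 1 and a `below_reference` flag.
#'
#' @param rates Tibble with `probe_id` and `rate` (all rates > 0), e.g. from
#'   [hydrolysis_rates()].
#' @param reference `"min"` (slowest probe) or a probe id.
#' @return Tibble: `probe_id`, `rate`, `relative_activity`,
#'   `dilution_factor`, `below_reference`.
#' @export
normalize_probes <- function(rates, reference = "min") {
  if (nrow(rates) == 0) abort("`rates` must be nonempty.")
  if (any(!is.finite(rates$rate)) || any(rates$rate <= 0)) {
    abort("All rates must be positive.")
  }
  ref_rate <- if (identical(reference, "min")) {
    min(rates$rate)
  } else {
    if (!reference %in% rates$probe_id) {
      abort(paste0("Reference probe not found: ", reference))
    }
    rates$rate[match(reference, rates$probe_id)]
  }
  dplyr::mutate(
    rates,
    relative_activity = .data$rate / ref_rate,
    dilution_factor = pmax(1, .data$relative_activity),
    below_reference = .data$relative_activity < 1
  )
}

#' Two-fold serial dilution series
#'
#' The fold factors of a serial dilution down the plate, e.g. the default
#' 7-step two-fold series 2, 4, 8, 16, 32, 64, 128 (1:2 to 1:128).
#'
#' @param fold Fold factor per step (default 2).
#' @param n_steps Number of steps (default 7).
#' @return Numeric vector of cumulative fold factors.
#' @export
dilution_series <- function(fold = 2, n_steps = 7L) {
  if (fold <= 1) abort("`fold` must be > 1.")
  if (n_steps < 1) abort("`n_steps` must be >= 1.")
  fold^seq_len(n_steps)
}
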