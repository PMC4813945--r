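GAS_CHANNELS <- c("TGS2620", "TGS2602", "TGS2201A", "TGS2201B")
AUX_CHANNELS <- c("temp_C", "rh_pct")

#' Sensor response curves
#'
#' A response curve holds the per-channel time series of one sampling
#' experiment on a uniform 1 Hz grid, together with the phase boundaries
#' of the protocol: clean-air baseline, gas exposure, clean-air recovery.
#' It is a tibble with a `time_s` column plus one numeric column per
#' channel, and attributes `baseline_end`, `exposure_end`, `recovery_end`
#' (seconds).
#'
#' @param values data frame with a `time_s` column (seconds, strictly
#'   increasing, uniform grid) and one numeric column per channel.
#' @param baseline_end,exposure_end,recovery_end phase boundaries in
#'   seconds; must satisfy `0 < baseline_end < exposure_end <=
#'   recovery_end <= max(time_s)`.
#' @return a `response_curve` tibble.
#' @export
response_curve <- function(values, baseline_end = 120, exposure_end = 360,
                           recovery_end = 900) {
  if (!"time_s" %in% names(values)) abort("curve needs a `time_s` column")
  t <- values$time_s
  dt <- diff(t)
  if (length(t) < 2 || any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
    abort("`time_s` must be strictly increasing on a uniform grid")
  }
  if (!(baseline_end > 0 && baseline_end < exposure_end &&
        exposure_end <= recovery_end && recovery_end <= max(t))) {
    abort("phase marks must satisfy 0 < baseline_end < exposure_end <= recovery_end <= max(time_s)")
  }
  out <- tibble::as_tibble(values)
  attr(out, "baseline_end") <- baseline_end
  attr(out, "exposure_end") <- exposure_end
  attr(out, "recovery_end") <- recovery_end
  class(out) <- c("response_curve", class(out))
  out
}

curve_phases <- function(curve) {
  list(baseline_end = attr(curve, "baseline_end"),
       exposure_end = attr(curve, "exposure_end"),
       recovery_end = attr(curve, "recovery_end"))
}

curve_channels <- function(curve) setdiff(names(curve), "time_s")

#' Read a response curve from CSV
#'
#' Expects header `time_s,<channel columns...>`, e.g.
#' `time_s,TGS2620,TGS2602,TGS2201A,TGS2201B[,temp_C,rh_pct]`.
#'
#' @param path CSV path.
#' @inheritParams response_curve
#' @return a `response_curve` tibble.
#' @export
read_response_curve <- function(path, baseline_end = 120,
                                exposure_end = 360, recovery_end = 900) {
  d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                       progress = FALSE, show_col_types = FALSE)
  response_curve(d, baseline_end, exposure_end, recovery_end)
}

#' Steady-state maximum feature
#'
#' Extracts, per channel, the maximum recorded response within a window.
#' The default window is the gas-exposure phase
#' `[baseline_end, exposure_end]`, where metal-oxide sensor responses
#' plateau; that plateau maximum is the per-sensor feature used
#' throughout the package. No baseline correction is applied unless
#' `subtract_baseline = TRUE`, which subtracts each channel's mean over
#' the baseline phase.
#'
#' @param curve a [response_curve()].
#' @param window optional `c(start, end)` in seconds, overriding the
#'   default exposure-phase window; must contain at least one grid point.
#' @param subtract_baseline subtract the baseline-phase mean per channel
#'   (default `FALSE`).
#' @return named numeric vector, one value per channel in curve order.
#' @export
extract_steady_state_max <- function(curve, window = NULL,
                                     subtract_baseline = FALSE) {
  ph <- curve_phases(curve)
  if (is.null(window)) window <- c(ph$baseline_end, ph$exposure_end)
  if (window[1] < min(curve$time_s) || window[2] > max(curve$time_s)) {
    abort("window lies outside the recorded times")
  }
  in_win <- curve$time_s >= window[1] & curve$time_s <= window[2]
  if (!any(in_win)) abort("window contains no grid points")
  chans <- curve_channels(curve)
  out <- vapply(chans, function(ch) {
    v <- curve[[ch]][in_win]
    if (any(is.na(v))) abort(sprintf("NaN/NA in window on channel %s", ch))
    max(v)
  }, numeric(1))
  if (subtract_baseline) {
    base <- curve$time_s <= ph$baseline_end
    out <- out - vapply(chans, function(ch) mean(curve[[ch]][base]), numeric(1))
  }
  out
}

#' Convert a response curve to a feature-table row
#'
#' Extracts the steady-state maximum of the four gas-sensor channels
#' (`TGS2620`, `TGS2602`, `TGS2201A`, `TGS2201B`, in that fixed order)
#' into a one-row feature table. Auxiliary temperature/humidity channels,
#' if present, are dropped with a message; a missing gas channel is an
#' error.
#'
#' @param curve a [response_curve()].
#' @param sample_id sample identifier.
#' @param label optional class label.
#' @param concentration optional concentration (ppm).
#' @inheritParams extract_steady_state_max
#' @return one-row feature table tibble with 4 feature columns.
#' @export
curves_to_sample <- function(curve, sample_id, label = NA_character_,
                             concentration = NA_real_, window = NULL,
                             subtract_baseline = FALSE) {
  chans <- curve_channels(curve)
  missing <- setdiff(GAS_CHANNELS, chans)
  if (length(missing) > 0) {
    abort(sprintf("curve is missing gas channel(s): %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(chans, GAS_CHANNELS)
  if (length(extra) > 0) {
    inform(sprintf("dropping non-gas channel(s): %s",
                   paste(extra, collapse = ", ")))
  }
  feats <- extract_steady_state_max(curve, window, subtract_baseline)[GAS_CHANNELS]
  dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(sample_id)),
    tibble::as_tibble(as.list(feats)),
    tibble::tibble(label = as.character(label),
                   concentration = as.numeric(concentration))
  )
}
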