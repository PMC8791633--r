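#' Analysis configuration
#'
#' Bundles every analysis constant used across the opto-tagging and spatial
#' pipelines. Defaults are the canonical values for juxtacellular CA1
#' recordings on the O-shaped maze: 2.5 cm spatial pixels smoothed with a
#' Gaussian kernel of one pixel SD, a 20 ms pixel-occupancy display mask, a
#' 1 cm/s movement threshold, a 20 ms post-pulse latency window binned at
#' 0.1 ms, a 4 ms mean-latency criterion for direct light activation, pulse
#' inclusion restricted to interpulse intervals of at least 200 ms and powers
#' of at most 5 mW (40 Hz trains excluded), a 6 ms burst interspike-interval
#' threshold, and spatial inclusion requiring more than 50 movement spikes
#' and at least 3 laps.
#'
#' @param pixel_size_cm Spatial pixel edge length (cm).
#' @param kernel_sigma_px Gaussian smoothing SD, in pixels.
#' @param occupancy_mask_s Minimum pixel occupancy (s) for a rate estimate.
#' @param speed_threshold_cm_s Movement threshold (cm/s); slower samples and
#'   the spikes coincident with them are excluded from spatial analysis.
#' @param latency_window_ms Post-pulse window for evoked spikes (ms).
#' @param psth_bin_ms PSTH bin width (ms).
#' @param direct_latency_threshold_ms Mean first-spike latency below which a
#'   reliably responsive cell counts as directly light-activated (ms).
#' @param min_interpulse_ms Minimum onset-to-onset interpulse interval (ms)
#'   for a pulse to enter latency analysis.
#' @param max_power_mW Maximum pulse power (mW) included in analysis.
#' @param exclude_train_hz Train frequencies (Hz) excluded outright.
#' @param burst_isi_ms Interspike interval (ms) at or below which an interval
#'   counts toward the burst index.
#' @param min_spikes Movement-filtered spike count must exceed this for
#'   spatial inclusion (also the floor for burst-index analysis).
#' @param min_laps Minimum lap count for spatial inclusion.
#' @param response_probability_min Minimum fraction of pulses with an evoked
#'   spike for a cell to count as light-responsive.
#' @param speed_smooth_s Boxcar window (s) applied to the speed trace.
#' @param linear_bin_cm Arc-length bin width (cm) of linearized rate maps.
#' @param rng_seed Optional integer seed recorded with pipeline output.
#'
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$direct_latency_threshold_ms
#' @export
analysis_config <- function(pixel_size_cm = 2.5,
                            kernel_sigma_px = 1,
                            occupancy_mask_s = 0.020,
                            speed_threshold_cm_s = 1,
                            latency_window_ms = 20,
                            psth_bin_ms = 0.1,
                            direct_latency_threshold_ms = 4,
                            min_interpulse_ms = 200,
                            max_power_mW = 5,
                            exclude_train_hz = 40,
                            burst_isi_ms = 6,
                            min_spikes = 50,
                            min_laps = 3,
                            response_probability_min = 0.5,
                            speed_smooth_s = 0.25,
                            linear_bin_cm = 2.5,
                            rng_seed = NULL) {
  cfg <- list(
    pixel_size_cm = pixel_size_cm,
    kernel_sigma_px = kernel_sigma_px,
    occupancy_mask_s = occupancy_mask_s,
    speed_threshold_cm_s = speed_threshold_cm_s,
    latency_window_ms = latency_window_ms,
    psth_bin_ms = psth_bin_ms,
    direct_latency_threshold_ms = direct_latency_threshold_ms,
    min_interpulse_ms = min_interpulse_ms,
    max_power_mW = max_power_mW,
    exclude_train_hz = exclude_train_hz,
    burst_isi_ms = burst_isi_ms,
    min_spikes = min_spikes,
    min_laps = min_laps,
    response_probability_min = response_probability_min,
    speed_smooth_s = speed_smooth_s,
    linear_bin_cm = linear_bin_cm,
    rng_seed = rng_seed
  )
  numeric_fields <- setdiff(names(cfg), c("rng_seed", "exclude_train_hz"))
  for (f in numeric_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("analysis_config: '", f, "' must be a positive finite scalar",
           call. = FALSE)
  }
  if (cfg$response_probability_min > 1)
    stop("analysis_config: 'response_probability_min' must be <= 1",
         call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-28s %s\n", f,
                if (is.null(v)) "<unset>" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Read or write an analysis configuration file
#'
#' The on-disk format is a flat YAML mapping whose keys mirror the
#' [analysis_config()] argument names exactly; unset optional fields are
#' omitted.
#'
#' @param path File path.
#' @return `read_config()` returns an `analysis_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("read_config: unknown field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config An `analysis_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(unclass(out), path)
  invisible(path)
}
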