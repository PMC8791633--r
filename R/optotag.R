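#' Select pulses eligible for latency analysis
#'
#' Keeps pulses whose onset-to-onset interval from the preceding pulse is at
#' least `min_interpulse_ms` (the first pulse is always eligible on that
#' criterion), whose power does not exceed `max_power_mW`, and whose train
#' frequency is not excluded outright (40 Hz trains are dropped by default
#' because of their high spiking-failure probability). Order is preserved;
#' an empty result is allowed.
#'
#' @param pulses A [light_pulse_train()].
#' @param min_interpulse_ms Minimum preceding interval (ms).
#' @param max_power_mW Maximum included power (mW).
#' @param exclude_train_hz Numeric vector of excluded train frequencies.
#' @return A filtered [light_pulse_train()].
#' @examples
#' lp <- light_pulse_train(c(0, 0.1, 0.4), 1, 1, 1)
#' length(filter_pulses(lp)$onsets)  # pulses 1 and 3 survive
#' @export
filter_pulses <- function(pulses, min_interpulse_ms = 200, max_power_mW = 5,
                          exclude_train_hz = 40) {
  stopifnot(inherits(pulses, "light_pulse_train"))
  n <- length(pulses$onsets)
  if (n == 0) return(pulses)
  gap_ok <- c(TRUE, diff(pulses$onsets) * 1000 >= min_interpulse_ms)
  keep <- gap_ok & pulses$power_mW <= max_power_mW &
    !(pulses$train_hz %in% exclude_train_hz)
  light_pulse_train(pulses$onsets[keep], pulses$duration_ms[keep],
                    pulses$power_mW[keep], pulses$train_hz[keep])
}

#' Peristimulus time histogram
#'
#' Spike counts in fine bins aligned to pulse onsets, aggregated over all
#' pulses. Bins are half-open `[k*bin, (k+1)*bin)` ms relative to onset;
#' spikes before onset or at/after the window end are excluded.
#'
#' @param spikes A [spike_train()].
#' @param pulses A non-empty [light_pulse_train()] (already filtered).
#' @param window_ms Window length (ms).
#' @param bin_ms Bin width (ms); must divide the window.
#' @return An object of class `psth`: list with `bin_edges_ms` (length
#'   `n_bins + 1`), `counts`, `n_pulses`.
#' @export
compute_psth <- function(spikes, pulses, window_ms = 20, bin_ms = 0.1) {
  stopifnot(inherits(spikes, "spike_train"),
            inherits(pulses, "light_pulse_train"))
  if (length(pulses$onsets) == 0)
    stop("compute_psth: empty pulse train", call. = FALSE)
  n_bins <- window_ms / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("compute_psth: bin_ms must divide window_ms", call. = FALSE)
  n_bins <- as.integer(round(n_bins))
  counts <- integer(n_bins)
  for (onset in pulses$onsets) {
    rel <- (spikes$times - onset) * 1000
    rel <- rel[rel >= 0 & rel < window_ms]
    if (length(rel) > 0) {
      b <- floor(rel / bin_ms) + 1L
      b[b > n_bins] <- n_bins  # guard against floating round-up at the edge
      counts <- counts + tabulate(b, nbins = n_bins)
    }
  }
  structure(list(bin_edges_ms = seq(0, window_ms, by = bin_ms),
                 counts = counts, n_pulses = length(pulses$onsets)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %.2g ms over %d pulses, %d spikes\n",
              length(x$counts), diff(x$bin_edges_ms[1:2]), x$n_pulses,
              sum(x$counts)))
  invisible(x)
}

#' Per-trial first-spike latencies
#'
#' For each pulse, the latency of the first spike falling in
#' `(onset, onset + window]`; trials with no such spike are failures (`NA`).
#' A spike exactly at onset does not count (latency must be positive); a
#' spike exactly at the window edge does. Pulses must be pre-filtered so
#' their windows do not overlap, which also guarantees a spike can belong
#' to at most one trial.
#'
#' @param spikes A [spike_train()].
#' @param pulses A filtered [light_pulse_train()].
#' @param window_ms Latency window (ms).
#' @return An object of class `trial_latencies`: list with `latency_ms`
#'   (NA = failure) and `window_ms`.
#' @export
first_spike_latencies <- function(spikes, pulses, window_ms = 20) {
  stopifnot(inherits(spikes, "spike_train"),
            inherits(pulses, "light_pulse_train"))
  on <- pulses$onsets
  if (length(on) > 1 && any(diff(on) * 1000 < window_ms))
    stop("first_spike_latencies: pulse windows overlap; filter pulses first",
         call. = FALSE)
  lat <- vapply(on, function(onset) {
    rel <- (spikes$times - onset) * 1000
    # the window edge is inclusive; tolerance absorbs float representation
    hit <- rel[rel > 0 & rel <= window_ms + 1e-9]
    if (length(hit) == 0) NA_real_ else hit[1]
  }, numeric(1))
  structure(list(latency_ms = lat, window_ms = window_ms),
            class = "trial_latencies")
}

#' Summarize trial latencies
#'
#' Mean and SD of the non-failure latencies, and the response probability
#' (fraction of trials with an evoked spike). With zero successful trials
#' the mean and SD are `NA` and the probability 0.
#'
#' @param trials A `trial_latencies` object from [first_spike_latencies()].
#' @return An object of class `latency_summary`: list with `mean_ms`,
#'   `sd_ms`, `response_probability`, `n_trials`, `n_responses`.
#' @export
summarize_latency <- function(trials) {
  stopifnot(inherits(trials, "trial_latencies"))
  lat <- trials$latency_ms
  if (length(lat) < 1)
    stop("summarize_latency: need at least one trial", call. = FALSE)
  ok <- !is.na(lat)
  structure(list(
    mean_ms = if (any(ok)) mean(lat[ok]) else NA_real_,
    sd_ms = if (sum(ok) > 1) stats::sd(lat[ok]) else
      if (sum(ok) == 1) 0 else NA_real_,
    response_probability = mean(ok),
    n_trials = length(lat), n_responses = sum(ok)),
    class = "latency_summary")
}

#' @export
print.latency_summary <- function(x, ...) {
  cat(sprintf(
    "Latency: %.2f +/- %.2f ms, response probability %.2f (%d/%d trials)\n",
    x$mean_ms, x$sd_ms, x$response_probability, x$n_responses, x$n_trials))
  invisible(x)
}

#' Mean number of evoked spikes per pulse
#'
#' Average, over pulses, of the spike count in `(onset, onset + window]`.
#'
#' @inheritParams first_spike_latencies
#' @return Mean spikes per pulse (numeric scalar).
#' @export
evoked_spikes_per_pulse <- function(spikes, pulses, window_ms = 20) {
  stopifnot(inherits(spikes, "spike_train"),
            inherits(pulses, "light_pulse_train"))
  if (length(pulses$onsets) == 0)
    stop("evoked_spikes_per_pulse: empty pulse train", call. = FALSE)
  counts <- vapply(pulses$onsets, function(onset) {
    rel <- (spikes$times - onset) * 1000
    sum(rel > 0 & rel <= window_ms + 1e-9)
  }, numeric(1))
  mean(counts)
}

#' Classify a cell's light response
#'
#' Latency-based opto-tag classification: a cell is *direct* (putative
#' opsin-expressing) if its mean first-spike latency is below the direct
#' threshold and spikes are reliably evoked (response probability at or
#' above the configured minimum); *nonresponsive* if the response
#' probability is below that minimum; *indirect* (synaptically driven)
#' otherwise.
#'
#' @param summary A `latency_summary` from [summarize_latency()].
#' @param config An [analysis_config()].
#' @return An object of class `opto_class`: list with `label` (one of
#'   `"direct"`, `"indirect"`, `"nonresponsive"`) and `evidence` (the
#'   summary).
#' @examples
#' tl <- structure(list(latency_ms = c(2.1, 2.2, 2.0), window_ms = 20),
#'                 class = "trial_latencies")
#' classify_optotag(summarize_latency(tl), analysis_config())$label
#' @export
classify_optotag <- function(summary, config = analysis_config()) {
  stopifnot(inherits(summary, "latency_summary"),
            inherits(config, "analysis_config"))
  label <- if (summary$response_probability < config$response_probability_min)
    "nonresponsive"
  else if (!is.na(summary$mean_ms) &&
           summary$mean_ms < config$direct_latency_threshold_ms)
    "direct"
  else
    "indirect"
  structure(list(label = label, evidence = summary), class = "opto_class")
}

#' @export
print.opto_class <- function(x, ...) {
  cat(sprintf("Opto class: %s (mean %.2f ms, p %.2f)\n", x$label,
              x$evidence$mean_ms, x$evidence$response_probability))
  invisible(x)
}

#' Export a PSTH as a two-column data frame
#'
#' @param psth A `psth` object.
#' @return Data frame with `bin_start_ms` and `count`.
#' @export
psth_as_data_frame <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  data.frame(bin_start_ms = psth$bin_edges_ms[-length(psth$bin_edges_ms)],
             count = psth$counts)
}
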