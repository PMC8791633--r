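#' Mean firing rate
#'
#' Spike count divided by recording-span duration.
#'
#' @param spikes A [spike_train()].
#' @return Rate (Hz).
#' @export
mean_firing_rate <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  dur <- diff(spikes$recording_span)
  if (dur <= 0)
    stop("mean_firing_rate: zero-duration recording", call. = FALSE)
  length(spikes$times) / dur
}

#' Burst index
#'
#' Fraction of spiking attributable to complex-spike bursts: the number of
#' interspike intervals at or below `isi_threshold_ms`, divided by the
#' total spike count. Trains with fewer than two spikes return 0. The
#' "sum of spikes with a short ISI" admits several counting conventions
#' (spikes preceded by, followed by, or participating in a short interval);
#' the interval-count convention used here is selectable against the
#' `"participating"` alternative, which counts every spike belonging to at
#' least one short interval.
#'
#' @param spikes A [spike_train()].
#' @param isi_threshold_ms Interval threshold (ms).
#' @param convention `"intervals"` (default) or `"participating"`.
#' @return Burst index in `[0, 1]` (`"intervals"`) or `[0, 1]`
#'   (`"participating"`).
#' @examples
#' st <- spike_train(c(0, 0.005, 0.1, 0.104, 0.2), c(0, 1))
#' burst_index(st)  # 2 short intervals / 5 spikes = 0.4
#' @export
burst_index <- function(spikes, isi_threshold_ms = 6,
                        convention = c("intervals", "participating")) {
  stopifnot(inherits(spikes, "spike_train"))
  convention <- match.arg(convention)
  n <- length(spikes$times)
  if (n < 2) return(0)
  short <- diff(spikes$times) * 1000 <= isi_threshold_ms
  if (convention == "intervals") {
    sum(short) / n
  } else {
    member <- c(short, FALSE) | c(FALSE, short)
    sum(member) / n
  }
}

#' Electrophysiological cell typing
#'
#' Interneurons are identified by high firing rate (>10 Hz during
#' exploration) or, when a waveform annotation is available, a narrow spike
#' (peak-to-trough < 0.4 ms); all other cells are classified pyramidal.
#'
#' @param rate_hz Mean firing rate (Hz).
#' @param waveform_peak_to_trough_ms Optional spike width (ms); `NA` if
#'   unavailable.
#' @param rate_threshold_hz,waveform_threshold_ms Classification cut-offs.
#' @return `"pyramidal"` or `"interneuron"`.
#' @export
classify_cell_type <- function(rate_hz, waveform_peak_to_trough_ms = NA,
                               rate_threshold_hz = 10,
                               waveform_threshold_ms = 0.4) {
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L)
  narrow <- !is.na(waveform_peak_to_trough_ms) &&
    waveform_peak_to_trough_ms < waveform_threshold_ms
  if (rate_hz > rate_threshold_hz || narrow) "interneuron" else "pyramidal"
}

#' Spatial-analysis inclusion
#'
#' A recording enters the spatial group comparison only if it has more than
#' `min_spikes` movement-filtered spikes and at least `min_laps` laps.
#'
#' @param n_spikes_included Movement-filtered spike count.
#' @param n_laps Lap count.
#' @param config An [analysis_config()].
#' @return Logical flag.
#' @export
spatial_inclusion <- function(n_spikes_included, n_laps,
                              config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  isTRUE(n_spikes_included > config$min_spikes) &&
    isTRUE(n_laps >= config$min_laps)
}

#' Final molecular-class label
#'
#' Combines the opto-tag class with any histology annotation: direct
#' light activation implies Calb1-positive; nonresponsive cells are
#' Calb1-negative; histology fills in when the opto class is missing or
#' indeterminate. Interneurons are excluded from further (spatial group)
#' analysis regardless of label. A direct responder annotated
#' histologically Calb1-negative is a conflict and is surfaced as such,
#' not silently resolved.
#'
#' @param opto An `opto_class` from [classify_optotag()], or `NULL`.
#' @param histology `"positive"`, `"negative"`, or `"unknown"`.
#' @param cell_type `"pyramidal"` or `"interneuron"`.
#' @return A list with `label` (`"Calb1_positive"`, `"Calb1_negative"`, or
#'   `"excluded"`) and `conflict` (logical).
#' @export
assign_final_label <- function(opto, histology = "unknown",
                               cell_type = "pyramidal") {
  if (is.null(opto) && histology == "unknown")
    stop("assign_final_label: need an opto class or histology", call. = FALSE)
  conflict <- FALSE
  if (cell_type == "interneuron")
    return(list(label = "excluded", conflict = FALSE))
  label <- if (!is.null(opto)) {
    if (opto$label == "direct") {
      if (histology == "negative") conflict <- TRUE
      "Calb1_positive"
    } else if (opto$label == "nonresponsive") {
      if (histology == "positive") "Calb1_positive" else "Calb1_negative"
    } else {  # indirect: synaptically driven, class from histology if any
      switch(histology, positive = "Calb1_positive",
             negative = "Calb1_negative", "excluded")
    }
  } else {
    switch(histology, positive = "Calb1_positive",
           negative = "Calb1_negative")
  }
  list(label = label, conflict = conflict)
}
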