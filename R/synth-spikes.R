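#' Place-field specification
#'
#' Generative parameters of a simulated pyramidal cell: a baseline Poisson
#' rate plus a Gaussian rate bump on the circular linearized coordinate,
#' with complex-spike bursting added by promoting single spikes to short
#' high-frequency bursts.
#'
#' @param baseline_rate_hz Spatially uniform rate (Hz).
#' @param field_center_cm Field center as arc length on the midline (cm);
#'   `NA` means "draw uniformly per cell" when used in a cohort class.
#' @param field_width_cm Gaussian SD of the field on the linearized
#'   coordinate (cm).
#' @param field_gain_hz Added rate at the field center (Hz). Weakly
#'   modulated cells use a gain at or below their baseline.
#' @param burst_probability Probability that a generated spike is promoted
#'   to a burst.
#' @param burst_size Number of spikes per burst (the promoted spike plus
#'   `burst_size - 1` trailing spikes).
#' @param burst_isi_ms Length-2 range the intra-burst interspike intervals
#'   are drawn from (ms).
#' @return An object of class `place_field_spec`.
#' @export
place_field_spec <- function(baseline_rate_hz = 0.5, field_center_cm = NA,
                             field_width_cm = 10, field_gain_hz = 6,
                             burst_probability = 0.4, burst_size = 2,
                             burst_isi_ms = c(3, 5)) {
  if (baseline_rate_hz < 0 || field_gain_hz < 0)
    stop("place_field_spec: rates must be non-negative", call. = FALSE)
  if (field_width_cm <= 0)
    stop("place_field_spec: field_width_cm must be positive", call. = FALSE)
  if (burst_probability < 0 || burst_probability > 1)
    stop("place_field_spec: burst_probability must be in [0, 1]",
         call. = FALSE)
  stopifnot(length(burst_isi_ms) == 2, burst_isi_ms[1] > 0,
            burst_isi_ms[2] >= burst_isi_ms[1], burst_size >= 2)
  structure(list(baseline_rate_hz = baseline_rate_hz,
                 field_center_cm = field_center_cm,
                 field_width_cm = field_width_cm,
                 field_gain_hz = field_gain_hz,
                 burst_probability = burst_probability,
                 burst_size = burst_size,
                 burst_isi_ms = as.numeric(burst_isi_ms)),
            class = "place_field_spec")
}

# enforce strict monotonicity and an absolute refractory period (s)
enforce_refractory <- function(times, refractory_s = 0.002) {
  times <- sort(times)
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (k in 2:length(times)) {
    if (times[k] - last >= refractory_s) {
      keep[k] <- TRUE
      last <- times[k]
    }
  }
  times[keep]
}

# promote spikes to bursts with the given probability; returns merged times
promote_bursts <- function(times, probability, size, isi_range_ms) {
  if (length(times) == 0 || probability <= 0) return(times)
  promoted <- stats::runif(length(times)) < probability
  if (!any(promoted)) return(times)
  extra <- unlist(lapply(times[promoted], function(t0) {
    isis <- stats::runif(size - 1, isi_range_ms[1], isi_range_ms[2]) / 1000
    t0 + cumsum(isis)
  }))
  sort(c(times, extra))
}

#' Simulate a place-modulated spike train
#'
#' Draws spikes from an inhomogeneous Poisson process by thinning: the
#' instantaneous rate is `baseline + gain * exp(-d(s, center)^2 / (2 w^2))`
#' where `d` is the wrapped (circular) arc-length distance of the animal's
#' linearized position `s(t)` from the field center. Spikes are then
#' promoted to bursts with the spec's burst probability, and a 2 ms
#' absolute refractory period is enforced.
#'
#' @param spec A [place_field_spec()]; `field_center_cm` must be set.
#' @param tracking A [tracking_trace()] giving the time base.
#' @param linear_pos Circular arc-length coordinate (cm) per tracking frame,
#'   aligned with `tracking$t`.
#' @param period Track perimeter (cm), the period of `linear_pos`.
#' @param seed Integer seed.
#' @return A [spike_train()] spanning the tracking interval.
#' @export
simulate_place_cell <- function(spec, tracking, linear_pos, period, seed = 1) {
  stopifnot(inherits(spec, "place_field_spec"),
            inherits(tracking, "tracking_trace"),
            length(linear_pos) == length(tracking$t), period > 0)
  if (is.na(spec$field_center_cm))
    stop("simulate_place_cell: spec$field_center_cm must be set",
         call. = FALSE)
  set.seed(seed)
  t0 <- tracking$t[1]
  t1 <- tracking$t[length(tracking$t)]
  lambda_max <- spec$baseline_rate_hz + spec$field_gain_hz
  if (lambda_max == 0)
    return(spike_train(numeric(0), recording_span = c(t0, t1)))

  n_cand <- stats::rpois(1, lambda_max * (t1 - t0))
  cand <- sort(stats::runif(n_cand, t0, t1))
  # wrapped-coordinate interpolation: interpolate the unwrapped phase
  phase <- unwrap_phase(linear_pos * 2 * pi / period)
  s_cand <- stats::approx(tracking$t, phase, xout = cand)$y *
    period / (2 * pi)
  d <- abs(s_cand - spec$field_center_cm) %% period
  d <- pmin(d, period - d)
  rate <- spec$baseline_rate_hz +
    spec$field_gain_hz * exp(-d^2 / (2 * spec$field_width_cm^2))
  keep <- stats::runif(n_cand) < rate / lambda_max
  times <- cand[keep]
  times <- promote_bursts(times, spec$burst_probability, spec$burst_size,
                          spec$burst_isi_ms)
  times <- enforce_refractory(times[times <= t1])
  spike_train(times, recording_span = c(t0, t1))
}

#' Simulate a homogeneous Poisson spike train
#'
#' Constant-rate Poisson spiking with optional burst promotion and a 2 ms
#' refractory period; used for spontaneous activity outside the tracked
#' epoch and for untracked cells.
#'
#' @param rate_hz Mean rate (Hz).
#' @param span Length-2 recording span (s).
#' @param seed Integer seed.
#' @param burst_probability,burst_size,burst_isi_ms As in
#'   [place_field_spec()].
#' @return A [spike_train()].
#' @export
simulate_homogeneous_train <- function(rate_hz, span, seed = 1,
                                       burst_probability = 0,
                                       burst_size = 2,
                                       burst_isi_ms = c(3, 5)) {
  stopifnot(rate_hz >= 0, length(span) == 2, span[2] > span[1])
  set.seed(seed)
  n <- stats::rpois(1, rate_hz * diff(span))
  times <- sort(stats::runif(n, span[1], span[2]))
  times <- promote_bursts(times, burst_probability, burst_size, burst_isi_ms)
  times <- enforce_refractory(times[times <= span[2]])
  spike_train(times, recording_span = as.numeric(span))
}

#' Light-response specification
#'
#' Generative parameters of a cell's response to blue-light pulses. Direct
#' (opsin-driven) responders spike at short latency with high reliability;
#' indirect (synaptically driven) responders at longer, more variable
#' latency with failures and, for repetitive stimulation, optional
#' facilitation (response probability grows with pulse number within a
#' train). Latencies are drawn from a normal distribution truncated below
#' at 0.5 ms.
#'
#' @param responder_class `"direct"`, `"indirect"`, or `"none"`.
#' @param latency_mean_ms,latency_sd_ms Evoked-spike latency distribution
#'   (ms). Defaults: direct 2.5 +/- 0.5, indirect 7.5 +/- 2.0.
#' @param response_probability Per-pulse probability of an evoked spike
#'   (before facilitation). Defaults: direct 0.9, indirect 0.6, none 0.
#' @param facilitation_increment Additive probability gain per successive
#'   pulse within a train, capped at 1. Must be 0 for class `"none"`.
#' @param evoked_burst_probability Probability that an evoked spike is
#'   promoted to a burst (awake 5-ms-pulse regime); 0 reproduces the
#'   single-spike anesthetized regime.
#' @param burst_isi_ms Intra-burst ISI range (ms) for promoted evoked
#'   spikes.
#' @return An object of class `opto_response_spec`.
#' @export
opto_response_spec <- function(responder_class = c("direct", "indirect",
                                                   "none"),
                               latency_mean_ms = NULL, latency_sd_ms = NULL,
                               response_probability = NULL,
                               facilitation_increment = 0,
                               evoked_burst_probability = 0,
                               burst_isi_ms = c(3, 5)) {
  responder_class <- match.arg(responder_class)
  defaults <- switch(responder_class,
    direct = list(mean = 2.5, sd = 0.5, p = 0.9),
    indirect = list(mean = 7.5, sd = 2.0, p = 0.6),
    none = list(mean = NA_real_, sd = NA_real_, p = 0))
  if (is.null(latency_mean_ms)) latency_mean_ms <- defaults$mean
  if (is.null(latency_sd_ms)) latency_sd_ms <- defaults$sd
  if (is.null(response_probability)) response_probability <- defaults$p
  if (response_probability < 0 || response_probability > 1)
    stop("opto_response_spec: response_probability must be in [0, 1]",
         call. = FALSE)
  if (responder_class == "none" && facilitation_increment != 0)
    stop("opto_response_spec: class 'none' cannot facilitate", call. = FALSE)
  if (responder_class == "indirect" && response_probability >= 1)
    stop("opto_response_spec: indirect responders must have ",
         "response_probability < 1", call. = FALSE)
  structure(list(responder_class = responder_class,
                 latency_mean_ms = latency_mean_ms,
                 latency_sd_ms = latency_sd_ms,
                 response_probability = response_probability,
                 facilitation_increment = facilitation_increment,
                 evoked_burst_probability = evoked_burst_probability,
                 burst_isi_ms = as.numeric(burst_isi_ms)),
            class = "opto_response_spec")
}

# index of each pulse within its train (gap > 1.5 periods starts a new train)
pulse_train_index <- function(pulses) {
  n <- length(pulses$onsets)
  if (n == 0) return(integer(0))
  idx <- integer(n)
  idx[1] <- 1L
  if (n > 1) {
    gaps <- diff(pulses$onsets)
    new_train <- gaps > 1.5 / pulses$train_hz[-1] |
      pulses$train_hz[-1] != pulses$train_hz[-n]
    for (k in 2:n) idx[k] <- if (new_train[k - 1]) 1L else idx[k - 1] + 1L
  }
  idx
}

#' Superimpose light-evoked spikes on a baseline train
#'
#' For each pulse, an evoked spike is generated with the spec's per-pulse
#' probability (plus facilitation for within-train pulse number) at
#' `onset + latency`, with latency drawn from the spec's truncated normal.
#' Evoked spikes are merged with the baseline train; monotonicity and a
#' 2 ms refractory period are enforced on the merged train. Class `"none"`
#' returns the baseline unchanged.
#'
#' @param spec An [opto_response_spec()].
#' @param baseline A [spike_train()]; the pulses must lie in its span.
#' @param pulses A [light_pulse_train()].
#' @param seed Integer seed.
#' @return A [spike_train()] with the same recording span as `baseline`.
#' @export
simulate_opto_response <- function(spec, baseline, pulses, seed = 1) {
  stopifnot(inherits(spec, "opto_response_spec"),
            inherits(baseline, "spike_train"),
            inherits(pulses, "light_pulse_train"))
  span <- baseline$recording_span
  n <- length(pulses$onsets)
  if (n > 0 && (pulses$onsets[1] < span[1] || pulses$onsets[n] > span[2]))
    stop("simulate_opto_response: pulses outside the baseline span",
         call. = FALSE)
  if (spec$responder_class == "none" || n == 0) return(baseline)
  set.seed(seed)
  k_in_train <- pulse_train_index(pulses)
  p_pulse <- pmin(1, spec$response_probability +
                     spec$facilitation_increment * (k_in_train - 1))
  responds <- stats::runif(n) < p_pulse
  n_resp <- sum(responds)
  if (n_resp == 0) return(baseline)
  lat <- numeric(n_resp)
  for (k in seq_len(n_resp)) {
    repeat {
      l <- stats::rnorm(1, spec$latency_mean_ms, spec$latency_sd_ms)
      if (l > 0.5) break
    }
    lat[k] <- l
  }
  evoked <- pulses$onsets[responds] + lat / 1000
  if (spec$evoked_burst_probability > 0)
    evoked <- promote_bursts(evoked, spec$evoked_burst_probability, 2,
                             spec$burst_isi_ms)
  merged <- enforce_refractory(c(baseline$times, evoked))
  merged <- merged[merged >= span[1] & merged <= span[2]]
  spike_train(merged, recording_span = span)
}
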