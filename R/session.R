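#' Spike train
#'
#' An ordered set of spike times with the recording span they were observed
#' in. Times are seconds from session start. Duplicate or non-increasing
#' timestamps are rejected: juxtacellular spikes are unambiguous single-cell
#' events and can never coincide.
#'
#' @param times Numeric vector of spike times (s), strictly increasing.
#' @param recording_span Numeric length-2 `(t0, t1)`; all times must lie
#'   within it.
#' @return An object of class `spike_train`.
#' @examples
#' st <- spike_train(c(0.5, 1.2, 3.4), recording_span = c(0, 10))
#' length(st$times)
#' @export
spike_train <- function(times, recording_span) {
  times <- as.numeric(times)
  stopifnot(length(recording_span) == 2, is.finite(recording_span))
  if (recording_span[2] <= recording_span[1])
    stop("spike_train: recording_span must have t1 > t0", call. = FALSE)
  if (anyNA(times))
    stop("spike_train: spike times must not contain NA", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike_train: spike times must be strictly increasing",
         call. = FALSE)
  if (length(times) > 0 &&
      (times[1] < recording_span[1] || times[length(times)] > recording_span[2]))
    stop("spike_train: spike times outside recording_span", call. = FALSE)
  structure(list(times = times, recording_span = as.numeric(recording_span)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- diff(x$recording_span)
  cat(sprintf("Spike train: %d spikes over %.1f s (%.2f Hz)\n",
              length(x$times), dur, length(x$times) / dur))
  invisible(x)
}

#' Head-tracking trace
#'
#' Regularly sampled two-LED head tracking. Positions are cm from the arena
#' lower-left corner; missing video samples are encoded as `NA` coordinate
#' pairs and are dropped (never interpolated) by downstream analysis.
#'
#' @param t Sample times (s), strictly increasing and regular to within 1%.
#' @param led1_xy,led2_xy Two-column matrices (or data frames) of x/y
#'   positions (cm); rows may be `NA` for dropped frames.
#' @return An object of class `tracking_trace` with fields `t`, `led1_xy`,
#'   `led2_xy`, and the frame interval `dt`.
#' @export
tracking_trace <- function(t, led1_xy, led2_xy) {
  t <- as.numeric(t)
  led1_xy <- as.matrix(led1_xy); led2_xy <- as.matrix(led2_xy)
  storage.mode(led1_xy) <- "double"; storage.mode(led2_xy) <- "double"
  if (length(t) < 2)
    stop("tracking_trace: need at least two samples", call. = FALSE)
  if (ncol(led1_xy) != 2 || ncol(led2_xy) != 2 ||
      nrow(led1_xy) != length(t) || nrow(led2_xy) != length(t))
    stop("tracking_trace: LED matrices must be n x 2, aligned with t",
         call. = FALSE)
  dts <- diff(t)
  if (any(dts <= 0))
    stop("tracking_trace: sample times must be strictly increasing",
         call. = FALSE)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 0.01 * dt))
    stop("tracking_trace: frame interval must be constant to within 1%",
         call. = FALSE)
  structure(list(t = t, led1_xy = unname(led1_xy), led2_xy = unname(led2_xy),
                 dt = dt),
            class = "tracking_trace")
}

#' @export
print.tracking_trace <- function(x, ...) {
  cat(sprintf("Tracking: %d frames at %.1f Hz (%.1f s)\n",
              length(x$t), 1 / x$dt, x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' Light-pulse train
#'
#' Photostimulation events: pulse onsets with per-pulse duration, power, and
#' the frequency label of the train each pulse belongs to.
#'
#' @param onsets Pulse onset times (s), strictly increasing.
#' @param duration_ms,power_mW,train_hz Per-pulse scalars, recycled if
#'   length one.
#' @return An object of class `light_pulse_train`.
#' @examples
#' lp <- light_pulse_train(seq(0, 9), duration_ms = 1, power_mW = 0.5,
#'                         train_hz = 1)
#' @export
light_pulse_train <- function(onsets, duration_ms, power_mW, train_hz) {
  onsets <- as.numeric(onsets)
  n <- length(onsets)
  if (n > 1 && any(diff(onsets) <= 0))
    stop("light_pulse_train: onsets must be strictly increasing",
         call. = FALSE)
  rec <- function(v, nm) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n)
      stop("light_pulse_train: '", nm, "' must have length 1 or length(onsets)",
           call. = FALSE)
    v
  }
  duration_ms <- rec(duration_ms, "duration_ms")
  power_mW <- rec(power_mW, "power_mW")
  train_hz <- rec(train_hz, "train_hz")
  if (n > 0 && any(power_mW <= 0))
    stop("light_pulse_train: power_mW must be positive", call. = FALSE)
  if (n > 0 && any(duration_ms <= 0))
    stop("light_pulse_train: duration_ms must be positive", call. = FALSE)
  structure(list(onsets = onsets, duration_ms = duration_ms,
                 power_mW = power_mW, train_hz = train_hz),
            class = "light_pulse_train")
}

#' @export
print.light_pulse_train <- function(x, ...) {
  cat(sprintf("Light pulses: %d pulses, %s ms, %s mW\n",
              length(x$onsets),
              paste(format(range(x$duration_ms)), collapse = "-"),
              paste(format(range(x$power_mW)), collapse = "-")))
  invisible(x)
}

#' @export
length.light_pulse_train <- function(x) length(x$onsets)

#' Recording session
#'
#' One juxtacellular recording: the spike train plus, when present, head
#' tracking, a light-pulse protocol, the arena geometry, and free-form
#' annotations (e.g. `histology_calb1: positive`). Tracking and pulses must
#' overlap the spike train's recording span.
#'
#' @param session_id Character scalar, unique within a cohort.
#' @param spikes A [spike_train()].
#' @param tracking A [tracking_trace()] or `NULL`.
#' @param pulses A [light_pulse_train()] or `NULL`.
#' @param arena A [maze_geometry()] or `NULL`.
#' @param annotations Named list of scalar labels.
#' @return An object of class `session_record`.
#' @export
session_record <- function(session_id, spikes, tracking = NULL, pulses = NULL,
                           arena = NULL, annotations = list()) {
  stopifnot(is.character(session_id), length(session_id) == 1L,
            inherits(spikes, "spike_train"))
  span <- spikes$recording_span
  if (!is.null(tracking)) {
    stopifnot(inherits(tracking, "tracking_trace"))
    if (tracking$t[length(tracking$t)] < span[1] || tracking$t[1] > span[2])
      stop("session_record: tracking does not overlap the recording span",
           call. = FALSE)
    if (!is.null(arena)) {
      bb <- arena$bounding_box
      xy <- rbind(tracking$led1_xy, tracking$led2_xy)
      ok <- stats::complete.cases(xy)
      if (any(xy[ok, 1] < -1e-6 | xy[ok, 1] > bb[1] + 1e-6 |
              xy[ok, 2] < -1e-6 | xy[ok, 2] > bb[2] + 1e-6))
        stop("session_record: tracking coordinates outside the arena ",
             "bounding box", call. = FALSE)
    }
  }
  if (!is.null(pulses)) {
    stopifnot(inherits(pulses, "light_pulse_train"))
    n <- length(pulses$onsets)
    if (n > 0 && (pulses$onsets[1] < span[1] || pulses$onsets[n] > span[2]))
      stop("session_record: pulses outside the recording span", call. = FALSE)
  }
  if (!is.null(arena)) stopifnot(inherits(arena, "maze_geometry"))
  if (length(annotations) > 0 &&
      (is.null(names(annotations)) || any(names(annotations) == "")))
    stop("session_record: annotations must be a named list", call. = FALSE)
  structure(list(session_id = session_id, spikes = spikes,
                 tracking = tracking, pulses = pulses, arena = arena,
                 annotations = annotations),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session '%s': %d spikes, %s tracking, %s pulses\n",
              x$session_id, length(x$spikes$times),
              if (is.null(x$tracking)) "no" else
                sprintf("%d-frame", length(x$tracking$t)),
              if (is.null(x$pulses)) "no" else
                sprintf("%d", length(x$pulses$onsets))))
  invisible(x)
}
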