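#' Cohort cell-class specification
#'
#' Defines one homogeneous group of simulated cells: its size, tuning class
#' and place-field parameters, light-response class, and cell type.
#'
#' @param name Class label (used as session-id prefix).
#' @param n Number of cells.
#' @param place A [place_field_spec()], or `NULL` for a cell simulated
#'   without tracking (spikes and pulses only).
#' @param opto An [opto_response_spec()].
#' @param tuning_class `"tuned"`, `"weak"`, or `"untracked"`.
#' @param cell_type `"pyramidal"` or `"interneuron"` ground truth.
#' @param annotations Annotations copied into each session.
#' @return An object of class `cell_class_spec`.
#' @export
cell_class_spec <- function(name, n, place = place_field_spec(),
                            opto = opto_response_spec("none"),
                            tuning_class = c("tuned", "weak", "untracked"),
                            cell_type = c("pyramidal", "interneuron"),
                            annotations = list()) {
  tuning_class <- match.arg(tuning_class)
  cell_type <- match.arg(cell_type)
  stopifnot(is.character(name), length(name) == 1L, n >= 0,
            is.null(place) || inherits(place, "place_field_spec"),
            inherits(opto, "opto_response_spec"))
  if (is.null(place) && tuning_class != "untracked")
    stop("cell_class_spec: tracked tuning classes need a place spec",
         call. = FALSE)
  if (tuning_class == "weak" && !is.null(place) &&
      place$field_gain_hz > place$baseline_rate_hz)
    stop("cell_class_spec: weakly modulated cells must have ",
         "field_gain_hz <= baseline_rate_hz", call. = FALSE)
  structure(list(name = name, n = as.integer(n), place = place, opto = opto,
                 tuning_class = tuning_class, cell_type = cell_type,
                 annotations = annotations),
            class = "cell_class_spec")
}

#' Synthetic cohort specification
#'
#' Full generative description of a synthetic study: the cell classes, the
#' maze, session timing, the photostimulation protocol appended to each
#' session, and the master seed. Identical spec + seed always reproduces an
#' identical cohort.
#'
#' @param classes List of [cell_class_spec()]s.
#' @param session_duration_s Tracked exploration length per session (s).
#' @param tracking_rate_hz Camera frame rate (Hz).
#' @param maze A [maze_geometry()].
#' @param pulse_protocol Named list: `n_pulses`, `rate_hz`, `duration_ms`,
#'   `power_mW` for the pulse train delivered after exploration; `NULL` for
#'   no photostimulation.
#' @param rng_seed Master integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(classes, session_duration_s = 600,
                        tracking_rate_hz = 25, maze = maze_geometry(),
                        pulse_protocol = list(n_pulses = 50, rate_hz = 1,
                                              duration_ms = 1,
                                              power_mW = 0.5),
                        rng_seed = 1) {
  stopifnot(is.list(classes),
            all(vapply(classes, inherits, logical(1), "cell_class_spec")),
            session_duration_s > 0, tracking_rate_hz > 0,
            inherits(maze, "maze_geometry"))
  structure(list(classes = classes,
                 session_duration_s = session_duration_s,
                 tracking_rate_hz = tracking_rate_hz, maze = maze,
                 pulse_protocol = pulse_protocol,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Default study cohort
#'
#' The cohort emulating the recorded CA1 population that enters the spatial
#' analysis: 26 strongly place-tuned, light-nonresponsive (Calb1-negative
#' -like) pyramidal cells and 12 weakly modulated, directly light-activated
#' (Calb1-positive-like) pyramidal cells, all firing below 10 Hz with a
#' burst index near 0.29, exploring the 70 x 50 cm O-maze for 10 minutes
#' before a 1 Hz / 1 ms / 0.5 mW tagging train.
#'
#' @param n_tuned,n_weak Class sizes.
#' @param rng_seed Master seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_tuned = 26, n_weak = 12, rng_seed = 1) {
  tuned <- cell_class_spec(
    "tuned", n_tuned,
    place = place_field_spec(baseline_rate_hz = 0.5, field_width_cm = 10,
                             field_gain_hz = 6, burst_probability = 0.4),
    opto = opto_response_spec("none"),
    tuning_class = "tuned", cell_type = "pyramidal")
  weak <- cell_class_spec(
    "weak", n_weak,
    place = place_field_spec(baseline_rate_hz = 1.3, field_width_cm = 15,
                             field_gain_hz = 0.8, burst_probability = 0.4),
    opto = opto_response_spec("direct"),
    tuning_class = "weak", cell_type = "pyramidal")
  cohort_spec(list(tuned, weak), rng_seed = rng_seed)
}

#' Opto-tagging benchmark cohort
#'
#' Cells simulated without tracking (spontaneous spiking plus the tagging
#' pulse train only), for benchmarking the latency classifier: direct
#' responders at 2.5 +/- 0.5 ms, indirect at 7.5 +/- 2.0 ms with failures,
#' and nonresponders.
#'
#' @param n_direct,n_indirect,n_none Class sizes.
#' @param spont_rate_hz Spontaneous rate of every cell (Hz).
#' @param rng_seed Master seed.
#' @return A [cohort_spec()].
#' @export
opto_bench_cohort_spec <- function(n_direct = 50, n_indirect = 50,
                                   n_none = 50, spont_rate_hz = 2,
                                   rng_seed = 1) {
  mk <- function(name, n, class)
    cell_class_spec(name, n, place = NULL,
                    opto = opto_response_spec(class),
                    tuning_class = "untracked", cell_type = "pyramidal",
                    annotations = list(spont_rate_hz = spont_rate_hz))
  cohort_spec(list(mk("direct", n_direct, "direct"),
                   mk("indirect", n_indirect, "indirect"),
                   mk("none", n_none, "none")),
              session_duration_s = 60, rng_seed = rng_seed)
}

#' Generate a synthetic cohort
#'
#' Produces one [session_record()] per cell, each with its own simulated
#' trajectory (for tracked classes), place-modulated spike train, and
#' light-pulse protocol appended after the exploration epoch, together with
#' a ground-truth table for recovery testing. The whole cohort is a
#' deterministic function of the spec (per-cell sub-seeds are drawn from
#' the master seed).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with `sessions`
#'   (list of session records) and `ground_truth` (data frame with columns
#'   `session_id, responder_class, tuning_class, cell_type,
#'   field_center_cm`).
#' @examples
#' co <- generate_cohort(opto_bench_cohort_spec(2, 2, 2))
#' co$ground_truth$responder_class
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(vapply(spec$classes, function(cl) cl$n, integer(1)))
  set.seed(spec$rng_seed)
  # independent sub-seeds per cell and stage
  seeds <- matrix(sample.int(2^31 - 2, max(1L, n_total) * 4L),
                  ncol = 4L)
  field_u <- stats::runif(max(1L, n_total))

  perim <- spec$maze$midline$perimeter
  pp <- spec$pulse_protocol
  sessions <- vector("list", n_total)
  gt <- vector("list", n_total)
  cell <- 0L
  for (cl in spec$classes) {
    for (j in seq_len(cl$n)) {
      cell <- cell + 1L
      sid <- sprintf("%s_%03d", cl$name, j)
      tracked <- !is.null(cl$place)

      dur <- spec$session_duration_s
      if (!is.null(pp)) {
        pulse_start <- dur + 5
        onsets <- pulse_start + (seq_len(pp$n_pulses) - 1) / pp$rate_hz
        span <- c(0, onsets[pp$n_pulses] + 1)
        pulses <- light_pulse_train(onsets, pp$duration_ms, pp$power_mW,
                                    pp$rate_hz)
      } else {
        span <- c(0, dur)
        pulses <- NULL
      }

      if (tracked) {
        place <- cl$place
        if (is.na(place$field_center_cm))
          place$field_center_cm <- field_u[cell] * perim
        tr <- simulate_trajectory(spec$maze, dur, spec$tracking_rate_hz,
                                  seed = seeds[cell, 1])
        st <- simulate_place_cell(place, tr, attr(tr, "linear_s"), perim,
                                  seed = seeds[cell, 2])
        times <- st$times
        if (!is.null(pp)) {
          post <- simulate_homogeneous_train(
            place$baseline_rate_hz, c(dur, span[2]),
            seed = seeds[cell, 3],
            burst_probability = place$burst_probability,
            burst_size = place$burst_size,
            burst_isi_ms = place$burst_isi_ms)
          times <- enforce_refractory(c(times, post$times))
        }
        base_train <- spike_train(times, recording_span = span)
        center_out <- place$field_center_cm
      } else {
        rate <- cl$annotations$spont_rate_hz
        if (is.null(rate)) rate <- 2
        base_train <- simulate_homogeneous_train(
          rate, span, seed = seeds[cell, 3], burst_probability = 0.4)
        tr <- NULL
        center_out <- NA_real_
      }

      final <- if (!is.null(pulses))
        simulate_opto_response(cl$opto, base_train, pulses,
                               seed = seeds[cell, 4])
      else base_train

      ann <- cl$annotations
      ann$spont_rate_hz <- NULL
      sessions[[cell]] <- session_record(
        session_id = sid, spikes = final, tracking = tr, pulses = pulses,
        arena = if (tracked) spec$maze else NULL, annotations = ann)
      gt[[cell]] <- data.frame(
        session_id = sid, responder_class = cl$opto$responder_class,
        tuning_class = cl$tuning_class, cell_type = cl$cell_type,
        field_center_cm = center_out, stringsAsFactors = FALSE)
    }
  }
  ground_truth <- if (n_total > 0) do.call(rbind, gt) else
    data.frame(session_id = character(0), responder_class = character(0),
               tuning_class = character(0), cell_type = character(0),
               field_center_cm = numeric(0))
  structure(list(sessions = sessions, ground_truth = ground_truth,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d sessions (%s)\n",
              length(x$sessions),
              paste(sprintf("%s: %d", names(table(x$ground_truth$tuning_class)),
                            table(x$ground_truth$tuning_class)),
                    collapse = ", ")))
  invisible(x)
}
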