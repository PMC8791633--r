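# shared per-session spatial scaffolding: positions, movement filter,
# ellipse linearization, and spike-to-frame assignment
session_spatial_frame <- function(session, config = analysis_config()) {
  stopifnot(inherits(session, "session_record"))
  if (is.null(session$tracking))
    stop("session_spatial_frame: session has no tracking", call. = FALSE)
  pos <- midpoint_position(session$tracking)
  dt <- session$tracking$dt
  speed <- compute_speed(pos, dt, config$speed_smooth_s)
  moving <- speed > config$speed_threshold_cm_s
  ellipse <- fit_ellipse(pos[, c("x", "y")])
  linear_s <- linearize(pos[, c("x", "y")], ellipse)

  spk <- session$spikes$times
  in_epoch <- spk >= pos$t[1] & spk <= pos$t[nrow(pos)]
  spike_t <- spk[in_epoch]
  idx <- findInterval(spike_t, pos$t, all.inside = TRUE)
  use_next <- (pos$t[pmin(idx + 1L, nrow(pos))] - spike_t) <
    (spike_t - pos$t[idx])
  idx <- ifelse(use_next, pmin(idx + 1L, nrow(pos)), idx)
  spike_included <- moving[idx]

  structure(
    list(positions = pos, dt = dt, speed = speed, moving = moving,
         ellipse = ellipse, perimeter = ellipse$perimeter,
         linear_s = linear_s, spike_t = spike_t, spike_idx = idx,
         spike_included = spike_included,
         spike_s = linear_s[idx],
         spike_xy = cbind(x = pos$x[idx], y = pos$y[idx])),
    class = "session_spatial_frame")
}

#' Analyze one recording session
#'
#' Runs the full per-cell analysis: mean rate and burst index, cell typing,
#' opto-tag classification from the (filtered) pulse protocol, spatial
#' metrics from the movement-filtered tracking (occupancy and rate maps,
#' spatial information, sparsity, peak rate, laps, split-half stability),
#' the inclusion flags, and the final molecular-class label.
#'
#' @param session A [session_record()].
#' @param config An [analysis_config()].
#' @return An object of class `cell_summary`: a named list with the mean
#'   rate, burst index, cell type, opto class and latency evidence, spatial
#'   metrics, inclusion flags, and final label.
#' @export
analyze_session <- function(session, config = analysis_config()) {
  stopifnot(inherits(session, "session_record"))
  out <- list(session_id = session$session_id)
  out$mean_rate_hz <- mean_firing_rate(session$spikes)
  n_spk <- length(session$spikes$times)
  out$burst_index <- if (n_spk > config$min_spikes)
    burst_index(session$spikes, config$burst_isi_ms) else NA_real_
  wf <- session$annotations$waveform_ms
  out$waveform_ms <- if (is.null(wf)) NA_real_ else as.numeric(wf)
  out$cell_type <- classify_cell_type(out$mean_rate_hz, out$waveform_ms)

  out$opto <- NULL
  if (!is.null(session$pulses)) {
    kept <- filter_pulses(session$pulses, config$min_interpulse_ms,
                          config$max_power_mW, config$exclude_train_hz)
    if (length(kept$onsets) > 0) {
      trials <- first_spike_latencies(session$spikes, kept,
                                      config$latency_window_ms)
      out$opto <- classify_optotag(summarize_latency(trials), config)
      out$evoked_per_pulse <- evoked_spikes_per_pulse(
        session$spikes, kept, config$latency_window_ms)
    }
  }

  out$spatial <- NULL
  out$included_spatial <- FALSE
  if (!is.null(session$tracking) && !is.null(session$arena)) {
    fr <- session_spatial_frame(session, config)
    mov_pos <- fr$positions[fr$moving, , drop = FALSE]
    n_inc <- sum(fr$spike_included)
    n_laps <- count_laps(fr$linear_s[fr$moving], fr$perimeter)
    sp <- list(n_spikes_included = n_inc, n_laps = n_laps)
    if (nrow(mov_pos) > 0 && n_inc > 0) {
      occ <- compute_occupancy(mov_pos, fr$dt, session$arena, config)
      rmap <- compute_ratemap(fr$spike_xy[fr$spike_included, , drop = FALSE],
                              occ)
      sp$information_bits_per_spike <- spatial_information(rmap, occ)
      sp$sparsity_index <- sparsity(rmap, occ)
      sp$peak_rate_hz <- peak_firing_rate(rmap)
      sp$stability_r <- tryCatch(split_half_stability(fr, config),
                                 error = function(e) NA_real_)
    }
    out$spatial <- sp
    out$included_spatial <- spatial_inclusion(n_inc, n_laps, config)
  }

  hist_ann <- session$annotations$histology_calb1
  if (is.null(hist_ann)) hist_ann <- "unknown"
  fl <- if (is.null(out$opto) && hist_ann == "unknown")
    list(label = "excluded", conflict = FALSE)
  else assign_final_label(out$opto, hist_ann, out$cell_type)
  out$final_label <- fl$label
  out$conflict <- fl$conflict
  structure(out, class = "cell_summary")
}

# flatten a cell_summary into one data-frame row
summary_row <- function(cs) {
  sp <- cs$spatial
  g <- function(x, f) if (is.null(x) || is.null(x[[f]])) NA_real_ else x[[f]]
  data.frame(
    session_id = cs$session_id,
    mean_rate_hz = cs$mean_rate_hz,
    burst_index = cs$burst_index,
    waveform_ms = cs$waveform_ms,
    cell_type = cs$cell_type,
    opto_class = if (is.null(cs$opto)) NA_character_ else cs$opto$label,
    mean_latency_ms = if (is.null(cs$opto)) NA_real_ else
      cs$opto$evidence$mean_ms,
    latency_sd_ms = if (is.null(cs$opto)) NA_real_ else
      cs$opto$evidence$sd_ms,
    response_probability = if (is.null(cs$opto)) NA_real_ else
      cs$opto$evidence$response_probability,
    n_spikes_included = g(sp, "n_spikes_included"),
    n_laps = g(sp, "n_laps"),
    information_bits_per_spike = g(sp, "information_bits_per_spike"),
    sparsity_index = g(sp, "sparsity_index"),
    peak_rate_hz = g(sp, "peak_rate_hz"),
    stability_r = g(sp, "stability_r"),
    included_spatial = cs$included_spatial,
    final_label = cs$final_label,
    conflict = cs$conflict,
    error = NA_character_,
    stringsAsFactors = FALSE)
}

#' Run the cohort analysis pipeline
#'
#' Analyzes every session of a cohort, assembles the per-cell summary
#' table, and computes the Calb1-positive versus Calb1-negative group
#' comparisons (spatial information, sparsity, stability over spatially
#' included pyramidal cells; mean rate and burst index over all pyramidal
#' cells). Per-session errors are recorded in the table and do not abort
#' the remaining cells. The result is deterministic given the inputs.
#'
#' @param cohort A cohort directory path, a `synthetic_cohort`, or a list
#'   of [session_record()]s.
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory; when given, `cells.csv`,
#'   `comparisons.csv`, and `run_log.txt` are written there.
#' @return An object of class `cohort_report`: `cells` (data frame),
#'   `comparisons` (data frame), `log` (character vector).
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         out_dir = NULL) {
  sessions <- if (is.character(cohort)) read_cohort(cohort)$sessions
  else if (inherits(cohort, "synthetic_cohort")) cohort$sessions
  else cohort
  stopifnot(length(sessions) > 0)

  rows <- lapply(sessions, function(s) {
    tryCatch(summary_row(analyze_session(s, config)),
             error = function(e) {
               r <- summary_row(structure(
                 list(session_id = s$session_id, mean_rate_hz = NA_real_,
                      burst_index = NA_real_, waveform_ms = NA_real_,
                      cell_type = NA_character_, opto = NULL, spatial = NULL,
                      included_spatial = FALSE, final_label = "excluded",
                      conflict = FALSE), class = "cell_summary"))
               r$error <- conditionMessage(e)
               r
             })
  })
  cells <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  pyr <- cells[!is.na(cells$cell_type) & cells$cell_type == "pyramidal", ]
  pos <- pyr[pyr$final_label == "Calb1_positive", ]
  neg <- pyr[pyr$final_label == "Calb1_negative", ]
  cmp_metric <- function(metric, only_included) {
    a <- pos; b <- neg
    if (only_included) {
      a <- a[a$included_spatial, ]; b <- b[b$included_spatial, ]
    }
    va <- a[[metric]]; vb <- b[[metric]]
    if (sum(!is.na(va)) == 0 || sum(!is.na(vb)) == 0) return(NULL)
    gc <- compare_groups(va, vb, metric = metric,
                         labels = c("Calb1_positive", "Calb1_negative"))
    data.frame(metric = metric, n_positive = gc$n[1], n_negative = gc$n[2],
               median_positive = stats::median(va, na.rm = TRUE),
               median_negative = stats::median(vb, na.rm = TRUE),
               statistic = gc$statistic, p_value = gc$p_value,
               method = gc$method, stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, c(Filter(Negate(is.null), list(
    cmp_metric("information_bits_per_spike", TRUE),
    cmp_metric("sparsity_index", TRUE),
    cmp_metric("stability_r", TRUE),
    cmp_metric("mean_rate_hz", FALSE),
    cmp_metric("burst_index", FALSE))),
    list(make.row.names = FALSE)))

  log <- c(sprintf("optoplace pipeline, %d sessions", nrow(cells)),
           sprintf("config: %s", paste(
             vapply(names(unclass(config)), function(f) {
               v <- config[[f]]
               sprintf("%s=%s", f,
                       if (is.null(v)) "unset" else
                         paste(format(v), collapse = "/"))
             }, character(1)), collapse = "; ")),
           sprintf("errors: %d", sum(!is.na(cells$error))))

  report <- structure(list(cells = cells, comparisons = comparisons,
                           log = log),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d cells (%d spatially included)\n",
              nrow(x$cells), sum(x$cells$included_spatial)))
  if (!is.null(x$comparisons) && nrow(x$comparisons) > 0) {
    cat("Group comparisons (Calb1-positive vs Calb1-negative):\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
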