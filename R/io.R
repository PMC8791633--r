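#' Read a recording session from disk
#'
#' Sessions are stored as plain delimited text plus a YAML manifest. The
#' manifest names the component tables (paths relative to the manifest),
#' the recording span, the arena geometry, and any annotations. Components
#' listed as `null` are treated as absent, never fabricated. All tables are
#' validated on read; violated invariants raise errors naming the offending
#' file.
#'
#' File formats: `spikes.csv` has column `time_s`; `tracking.csv` has
#' `time_s, led1_x_cm, led1_y_cm, led2_x_cm, led2_y_cm` (empty fields mark
#' missing samples); `pulses.csv` has `onset_s, duration_ms, power_mW,
#' train_hz`.
#'
#' @param manifest_path Path to a `session.yaml` manifest.
#' @return A validated [session_record()].
#' @seealso [write_session()] for the inverse operation.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("read_session: manifest not found: ", manifest_path, call. = FALSE)
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  need <- c("session_id", "recording_span", "files")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0)
    stop("read_session: manifest missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  read_table <- function(rel, cols) {
    path <- file.path(base, rel)
    if (!file.exists(path))
      stop("read_session: referenced file not found: ", path, call. = FALSE)
    df <- tryCatch(
      utils::read.csv(path, colClasses = "numeric"),
      error = function(e)
        stop("read_session: parse error in ", path, ": ",
             conditionMessage(e), call. = FALSE))
    if (!identical(names(df), cols))
      stop("read_session: ", path, " must have columns ",
           paste(cols, collapse = ", "), call. = FALSE)
    df
  }

  spikes_df <- read_table(man$files$spikes, "time_s")
  bad <- which(!is.finite(spikes_df$time_s))
  if (length(bad) > 0)
    stop("read_session: non-numeric spike time at row ", bad[1], " of ",
         man$files$spikes, call. = FALSE)
  spikes <- spike_train(spikes_df$time_s,
                        recording_span = as.numeric(man$recording_span))

  tracking <- NULL
  if (!is.null(man$files$tracking)) {
    td <- read_table(man$files$tracking,
                     c("time_s", "led1_x_cm", "led1_y_cm",
                       "led2_x_cm", "led2_y_cm"))
    tracking <- tracking_trace(td$time_s,
                               cbind(td$led1_x_cm, td$led1_y_cm),
                               cbind(td$led2_x_cm, td$led2_y_cm))
  }

  pulses <- NULL
  if (!is.null(man$files$pulses)) {
    pd <- read_table(man$files$pulses,
                     c("onset_s", "duration_ms", "power_mW", "train_hz"))
    pulses <- light_pulse_train(pd$onset_s, pd$duration_ms, pd$power_mW,
                                pd$train_hz)
  }

  arena <- NULL
  if (!is.null(man$arena)) {
    ar <- man$arena
    arena <- maze_geometry(bounding_box = as.numeric(ar$bounding_box),
                           path_width = as.numeric(ar$path_width),
                           center = as.numeric(ar$center),
                           semi_axes = as.numeric(ar$semi_axes))
  }

  ann <- man$annotations
  if (is.null(ann)) ann <- list()

  session_record(session_id = man$session_id, spikes = spikes,
                 tracking = tracking, pulses = pulses, arena = arena,
                 annotations = ann)
}

fmt_num <- function(x, digits) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- ""
  out
}

#' Write a recording session to disk
#'
#' Writes the session's component tables and manifest into
#' `dir/<session_id>/`. Times are stored to nanosecond and positions to
#' micrometer precision, so `read_session(write_session(s))` reproduces `s`
#' within 1e-9 s and 1e-6 cm.
#'
#' @param session A [session_record()].
#' @param dir Output directory (created if necessary).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  sdir <- file.path(dir, session$session_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(sdir))
    stop("write_session: cannot create directory ", sdir, call. = FALSE)

  write_tab <- function(df, name) {
    path <- file.path(sdir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    name
  }

  files <- list(spikes = write_tab(
    data.frame(time_s = fmt_num(session$spikes$times, 9)), "spikes.csv"))

  if (!is.null(session$tracking)) {
    tr <- session$tracking
    files$tracking <- write_tab(data.frame(
      time_s = fmt_num(tr$t, 9),
      led1_x_cm = fmt_num(tr$led1_xy[, 1], 6),
      led1_y_cm = fmt_num(tr$led1_xy[, 2], 6),
      led2_x_cm = fmt_num(tr$led2_xy[, 1], 6),
      led2_y_cm = fmt_num(tr$led2_xy[, 2], 6)), "tracking.csv")
  }
  if (!is.null(session$pulses)) {
    pu <- session$pulses
    files$pulses <- write_tab(data.frame(
      onset_s = fmt_num(pu$onsets, 9),
      duration_ms = fmt_num(pu$duration_ms, 6),
      power_mW = fmt_num(pu$power_mW, 6),
      train_hz = fmt_num(pu$train_hz, 6)), "pulses.csv")
  }

  man <- list(session_id = session$session_id,
              recording_span = as.numeric(session$spikes$recording_span),
              files = files)
  if (!is.null(session$arena)) {
    mz <- session$arena
    man$arena <- list(bounding_box = mz$bounding_box,
                      path_width = mz$path_width,
                      center = mz$midline$center,
                      semi_axes = c(mz$midline$a, mz$midline$b))
  }
  if (length(session$annotations) > 0) man$annotations <- session$annotations

  manifest_path <- file.path(sdir, "session.yaml")
  yaml::write_yaml(man, manifest_path, precision = 15)
  invisible(manifest_path)
}

#' Read or write a whole cohort
#'
#' A cohort directory holds one subdirectory per session (see
#' [write_session()]) and, for synthetic cohorts, a `ground_truth.csv` with
#' columns `session_id, responder_class, tuning_class, cell_type`.
#'
#' @param cohort A list of [session_record()]s, or a `synthetic_cohort` from
#'   [generate_cohort()].
#' @param dir Cohort directory.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a list with elements `sessions` (named list of session records) and
#'   `ground_truth` (data frame or `NULL`).
#' @export
write_cohort <- function(cohort, dir) {
  sessions <- if (inherits(cohort, "synthetic_cohort")) cohort$sessions
              else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(sessions, function(s) s$session_id, character(1))
  if (anyDuplicated(ids))
    stop("write_cohort: duplicate session_id in cohort", call. = FALSE)
  for (s in sessions) write_session(s, dir)
  if (inherits(cohort, "synthetic_cohort"))
    utils::write.csv(cohort$ground_truth,
                     file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifests <- sort(list.files(dir, pattern = "^session\\.yaml$",
                               recursive = TRUE, full.names = TRUE))
  if (length(manifests) == 0)
    stop("read_cohort: no session manifests under ", dir, call. = FALSE)
  sessions <- lapply(manifests, read_session)
  names(sessions) <- vapply(sessions, function(s) s$session_id, character(1))
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path))
    utils::read.csv(gt_path, stringsAsFactors = FALSE) else NULL
  list(sessions = sessions, ground_truth = gt)
}
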