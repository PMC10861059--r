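#' Fixation filter configuration
#'
#' Parameters of the velocity-threshold (I-VT) fixation identification chain:
#' samples whose point-to-point angular velocity is below
#' `velocity_threshold_deg_s` form fixation candidates; adjacent fixations
#' closer than `merge_max_gap_ms` in time and `merge_max_angle_deg` in space
#' are merged; fixations shorter than `min_duration_ms` are then discarded;
#' and a recording is kept for analysis only when total fixation time reaches
#' `min_trial_fixation_s`.
#'
#' The 100 ms / 75 ms / 0.5 deg / 15 s constants follow the standard I-VT
#' post-processing defaults for preferential-looking work; the velocity
#' threshold defaults to the common 30 deg/s.
#'
#' @param velocity_threshold_deg_s Velocity threshold in degrees/second.
#' @param min_duration_ms Minimum fixation duration kept, in ms.
#' @param merge_max_gap_ms Maximum inter-fixation gap merged, in ms.
#' @param merge_max_angle_deg Maximum centroid separation merged, in degrees.
#' @param min_trial_fixation_s Minimum total fixation time for inclusion, s.
#' @param merge_before_discard If `TRUE` (default) adjacent fixations are
#'   merged before short ones are discarded.
#' @return An object of class `fixation_filter_config`.
#' @export
fixation_filter_config <- function(velocity_threshold_deg_s = 30,
                                   min_duration_ms = 100,
                                   merge_max_gap_ms = 75,
                                   merge_max_angle_deg = 0.5,
                                   min_trial_fixation_s = 15,
                                   merge_before_discard = TRUE) {
  vals <- c(velocity_threshold_deg_s, min_duration_ms, merge_max_gap_ms,
            merge_max_angle_deg, min_trial_fixation_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all fixation filter thresholds must be finite and > 0")
  structure(list(velocity_threshold_deg_s = velocity_threshold_deg_s,
                 min_duration_ms = min_duration_ms,
                 merge_max_gap_ms = merge_max_gap_ms,
                 merge_max_angle_deg = merge_max_angle_deg,
                 min_trial_fixation_s = min_trial_fixation_s,
                 merge_before_discard = isTRUE(merge_before_discard)),
            class = "fixation_filter_config")
}

#' Construct a gaze recording
#'
#' A gaze recording bundles one participant's time-ordered gaze samples (in
#' stimulus coordinates, origin top-left, 0-based) with group / severity
#' metadata and, after processing, the detected fixations.
#'
#' @param participant_id Participant identifier (string).
#' @param samples `data.frame` with columns `t_ms`, `x_px`, `y_px`, `valid`.
#' @param group `"ASD"` or `"TD"`.
#' @param severity `"moderate"`, `"high"`, or `"none"`; must be `"none"` iff
#'   the participant is TD.
#' @param age_years,gender Optional demographics.
#' @param fixations Optional fixation `data.frame` (see
#'   [ivt_detect_fixations()]).
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(participant_id, samples, group = c("ASD", "TD"),
                           severity = NULL,
                           age_years = NA_real_, gender = NA_character_,
                           fixations = NULL) {
  group <- match.arg(group)
  severity <- severity %||% if (group == "TD") "none" else "moderate"
  severity <- match.arg(severity, c("none", "moderate", "high"))
  required <- c("t_ms", "x_px", "y_px", "valid")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(diff(samples$t_ms) < 0)) {
    bad <- which(diff(samples$t_ms) < 0) + 1L
    stop("timestamps are not non-decreasing at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (any(samples$t_ms < 0)) stop("t_ms must be non-negative")
  if (group == "TD" && severity != "none")
    stop("TD participants must have severity 'none'")
  if (group == "ASD" && severity == "none")
    stop("ASD participants need severity 'moderate' or 'high'")
  structure(list(participant_id = as.character(participant_id),
                 group = group, severity = severity,
                 age_years = age_years, gender = gender,
                 samples = as.data.frame(samples),
                 fixations = fixations),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  nf <- if (is.null(x$fixations)) 0L else nrow(x$fixations)
  cat(sprintf("<gaze_recording> %s [%s/%s]: %d samples (%d valid), %d fixations\n",
              x$participant_id, x$group, x$severity, nrow(x$samples),
              sum(x$samples$valid), nf))
  invisible(x)
}

#' Read a delimited gaze table
#'
#' Reads a CSV/TSV gaze file with header columns `participant_id`, `t_ms`,
#' `x_px`, `y_px`, `valid` (screen coordinates) and returns one
#' [gaze_recording()] with coordinates mapped into stimulus space through the
#' geometry's display mapping. Invalid rows are retained but flagged.
#'
#' @param path Path to the delimited file.
#' @param geometry A [screen_geometry()].
#' @param meta Optional one-row `data.frame` with `group`, `severity`,
#'   `age_years`, `gender` for the participant.
#' @param sep Field separator; guessed from the file extension by default.
#' @return A [gaze_recording()] with samples in stimulus coordinates.
#' @export
read_gaze_table <- function(path, geometry, meta = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("participant_id", "t_ms", "x_px", "y_px", "valid")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("gaze table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ids <- unique(raw$participant_id)
  if (length(ids) != 1)
    stop("expected a single participant per gaze file, found: ",
         paste(ids, collapse = ", "))
  st <- screen_to_stimulus(raw$x_px, raw$y_px, geometry)
  samples <- data.frame(t_ms = as.numeric(raw$t_ms),
                        x_px = st$x, y_px = st$y,
                        valid = as.logical(raw$valid) |
                          (is.numeric(raw$valid) & raw$valid != 0))
  args <- list(participant_id = ids, samples = samples)
  if (!is.null(meta)) {
    args$group <- as.character(meta$group)
    args$severity <- as.character(meta$severity)
    if (!is.null(meta$age_years)) args$age_years <- meta$age_years
    if (!is.null(meta$gender)) args$gender <- as.character(meta$gender)
  }
  do.call(gaze_recording, args)
}

#' Write a gaze recording to CSV in screen coordinates
#'
#' Inverse of [read_gaze_table()]: stimulus coordinates are mapped back to
#' screen coordinates so that written files round-trip through the reader.
#'
#' @param recording A [gaze_recording()].
#' @param path Output CSV path.
#' @inheritParams read_gaze_table
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(recording, path, geometry) {
  sc <- stimulus_to_screen(recording$samples$x_px, recording$samples$y_px,
                           geometry)
  out <- data.frame(participant_id = recording$participant_id,
                    t_ms = recording$samples$t_ms,
                    x_px = sc$x, y_px = sc$y,
                    valid = as.integer(recording$samples$valid))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write detected fixations as TSV
#'
#' @param recordings A list of [gaze_recording()]s with fixations populated.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fixations_tsv <- function(recordings, path) {
  rows <- lapply(recordings, function(r) {
    if (is.null(r$fixations) || !nrow(r$fixations)) return(NULL)
    cbind(participant_id = r$participant_id, r$fixations)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participant metadata table
#'
#' @param path CSV with columns `participant_id`, `group`, `severity`,
#'   `age_years`, `gender`.
#' @return A `data.frame`.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "group", "severity")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  meta
}
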