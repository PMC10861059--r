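#' Detect fixations with a velocity-threshold (I-VT) filter
#'
#' Computes the point-to-point angular velocity between consecutive valid
#' gaze samples; maximal runs of samples in which every between-sample
#' velocity stays below the configured threshold become fixation candidates
#' (runs of fewer than two samples are dropped). A run is also broken by a
#' recording gap larger than twice the nominal sample period or by dropped
#' invalid samples between the two neighbours — no gaze is fabricated across
#' dropouts. Candidate intervals are half-open `[start_ms, end_ms)` with the
#' end extended by one nominal sample period so that an n-sample fixation at
#' a regular rate spans n periods; the centroid is the mean of the member
#' samples.
#'
#' The raw candidates returned here are normally post-processed with
#' [merge_and_filter_fixations()].
#'
#' @param recording A [gaze_recording()] (or a bare sample `data.frame`).
#' @param cfg A [fixation_filter_config()].
#' @param geometry A [screen_geometry()] used for the pixel-to-angle
#'   conversion (samples are in stimulus coordinates).
#' @return A fixation `data.frame` with columns `start_ms`, `end_ms`,
#'   `duration_ms`, `cx_px`, `cy_px`, `n_samples`. Empty (zero rows) when no
#'   fixation is found or fewer than two valid samples exist.
#' @export
ivt_detect_fixations <- function(recording, cfg = fixation_filter_config(),
                                 geometry = screen_geometry()) {
  samples <- if (inherits(recording, "gaze_recording")) recording$samples
             else as.data.frame(recording)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      duration_ms = numeric(0), cx_px = numeric(0),
                      cy_px = numeric(0), n_samples = integer(0))
  v <- samples[samples$valid, , drop = FALSE]
  if (nrow(v) < 2) return(empty)

  dt <- diff(v$t_ms)
  period <- stats::median(dt)
  if (!is.finite(period) || period <= 0) return(empty)
  disp_px <- sqrt(diff(v$x_px)^2 + diff(v$y_px)^2)
  disp_deg <- stimulus_px_to_degrees(disp_px, geometry)
  vel <- disp_deg / (dt / 1000)            # deg/s, between sample pairs
  # a run breaks where the between-sample velocity reaches the threshold,
  # where a recording gap exceeds two nominal periods, or where invalid
  # samples were dropped between the two neighbours (time-reversal
  # symmetric, since all three predicates act on sample pairs)
  gap_has_invalid <- diff(which(samples$valid)) > 1
  breaks <- vel >= cfg$velocity_threshold_deg_s | dt > 2 * period |
    gap_has_invalid
  run_id <- cumsum(c(0, breaks))
  parts <- split(seq_len(nrow(v)), run_id)
  parts <- parts[vapply(parts, length, integer(1)) >= 2]
  if (!length(parts)) return(empty)
  rows <- lapply(parts, function(idx) {
    data.frame(start_ms = v$t_ms[idx[1]],
               end_ms = v$t_ms[idx[length(idx)]] + period,
               cx_px = mean(v$x_px[idx]), cy_px = mean(v$y_px[idx]),
               n_samples = length(idx))
  })
  out <- do.call(rbind, rows)
  out$duration_ms <- out$end_ms - out$start_ms
  rownames(out) <- NULL
  out[, c("start_ms", "end_ms", "duration_ms", "cx_px", "cy_px", "n_samples")]
}

#' Merge adjacent fixations, then discard short ones
#'
#' Adjacent fixation pairs are merged when the inter-fixation gap is at most
#' `merge_max_gap_ms` and the centroid separation at most
#' `merge_max_angle_deg`; merging proceeds left to right and repeats until
#' stable. After merging, fixations shorter than `min_duration_ms` are
#' discarded (the merge-before-discard order lets two short neighbouring
#' fixations survive as one). Merged centroids are duration-weighted means
#' and the merged interval spans from the first start to the last end.
#'
#' @param fixations Fixation `data.frame` as from [ivt_detect_fixations()],
#'   time-ordered.
#' @inheritParams ivt_detect_fixations
#' @return Filtered fixation `data.frame`.
#' @export
merge_and_filter_fixations <- function(fixations,
                                       cfg = fixation_filter_config(),
                                       geometry = screen_geometry()) {
  fx <- fixations
  discard_short <- function(f)
    f[f$duration_ms >= cfg$min_duration_ms, , drop = FALSE]
  if (!cfg$merge_before_discard) fx <- discard_short(fx)
  if (nrow(fx) > 1) {
    max_sep_px <- degrees_to_stimulus_px(cfg$merge_max_angle_deg, geometry)
    repeat {
      merged_any <- FALSE
      i <- 1L
      while (i < nrow(fx)) {
        gap <- fx$start_ms[i + 1] - fx$end_ms[i]
        sep <- sqrt((fx$cx_px[i + 1] - fx$cx_px[i])^2 +
                    (fx$cy_px[i + 1] - fx$cy_px[i])^2)
        if (gap <= cfg$merge_max_gap_ms && sep <= max_sep_px) {
          w <- c(fx$duration_ms[i], fx$duration_ms[i + 1])
          fx$cx_px[i] <- sum(w * fx$cx_px[i:(i + 1)]) / sum(w)
          fx$cy_px[i] <- sum(w * fx$cy_px[i:(i + 1)]) / sum(w)
          fx$end_ms[i] <- fx$end_ms[i + 1]
          fx$duration_ms[i] <- fx$end_ms[i] - fx$start_ms[i]
          fx$n_samples[i] <- fx$n_samples[i] + fx$n_samples[i + 1]
          fx <- fx[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!merged_any) break
    }
  }
  if (cfg$merge_before_discard) fx <- discard_short(fx)
  rownames(fx) <- NULL
  fx
}

#' Run the full fixation-processing chain on a recording
#'
#' Convenience wrapper: I-VT detection, merge/discard post-processing and
#' frame mapping, storing the result in the recording.
#'
#' @inheritParams ivt_detect_fixations
#' @param n_frames,duration_s Stimulus frame count and duration for frame
#'   mapping; skipped when `NULL`.
#' @return The recording with `$fixations` populated.
#' @export
process_recording <- function(recording, cfg = fixation_filter_config(),
                              geometry = screen_geometry(),
                              n_frames = NULL, duration_s = NULL) {
  fx <- ivt_detect_fixations(recording, cfg, geometry)
  fx <- merge_and_filter_fixations(fx, cfg, geometry)
  if (!is.null(n_frames) && !is.null(duration_s) && nrow(fx))
    fx <- map_fixations_to_frames(fx, n_frames, duration_s)
  recording$fixations <- fx
  recording
}

#' Decide trial inclusion from total fixation time
#'
#' A recording is included when its total fixation duration reaches the
#' configured minimum (default 15 s, i.e. roughly a quarter of a one-minute
#' stimulus).
#'
#' @inheritParams ivt_detect_fixations
#' @return `TRUE` when the recording passes the inclusion rule.
#' @export
trial_inclusion <- function(recording, cfg = fixation_filter_config()) {
  fx <- if (inherits(recording, "gaze_recording")) recording$fixations
        else recording
  if (is.null(fx)) stop("fixations are not populated")
  sum(fx$duration_ms) >= cfg$min_trial_fixation_s * 1000
}

#' Map fixations to stimulus frame indices
#'
#' Assigns to each fixation the 0-based frame indices whose display interval
#' `[i/fps, (i+1)/fps)` overlaps the fixation interval, with
#' `fps = n_frames / duration_s`. Fixations extending beyond the video are
#' clipped; a fixation entirely outside yields an empty span (frame columns
#' `NA`).
#'
#' @param fixations Fixation `data.frame`.
#' @param n_frames Total number of video frames.
#' @param duration_s Video duration in seconds.
#' @return The fixation `data.frame` with `first_frame` and `last_frame`
#'   columns added.
#' @export
map_fixations_to_frames <- function(fixations, n_frames, duration_s) {
  if (n_frames <= 0 || duration_s <= 0)
    stop("n_frames and duration_s must be > 0")
  fps <- n_frames / duration_s
  frame_ms <- 1000 / fps
  first <- floor(fixations$start_ms / frame_ms)
  last <- ceiling(fixations$end_ms / frame_ms) - 1
  first <- pmax(first, 0)
  last <- pmin(last, n_frames - 1)
  dead <- last < first | fixations$end_ms <= 0 |
    fixations$start_ms >= duration_s * 1000
  first[dead] <- NA_integer_
  last[dead] <- NA_integer_
  fixations$first_frame <- as.integer(first)
  fixations$last_frame <- as.integer(last)
  fixations
}

#' Mean distance between fixation centroids and a calibration point
#'
#' Accuracy statistic for calibration-quality checks: the mean Euclidean
#' distance (in stimulus pixels) between detected fixation centroids and a
#' known target location.
#'
#' @param fixations Fixation `data.frame` with at least one row.
#' @param point Numeric length-2 vector `c(x, y)` in stimulus coordinates.
#' @return Mean distance in pixels.
#' @export
calibration_accuracy <- function(fixations, point) {
  if (is.null(fixations) || !nrow(fixations))
    stop("calibration accuracy is undefined without fixations")
  mean(sqrt((fixations$cx_px - point[1])^2 + (fixations$cy_px - point[2])^2))
}
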