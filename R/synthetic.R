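#' Cohort specification for the gaze simulator
#'
#' Parameters of the synthetic split-screen cohort. Per-participant %Geo is
#' drawn from a normal distribution truncated to `[0, 100]` with the given
#' per-group mean/SD; the defaults reproduce the reference cohort structure
#' for preferential-looking studies of preschool ASD (ASD 49.37 (24.14) vs
#' TD 35.97 (18.58), with the ASD group split into moderate 48.21 (23.82)
#' and high 50.98 (25.00) severity strata). Gaze is simulated at the
#' fixation level: alternating fixation/saccade events sampled at 60 Hz,
#' log-normal fixation durations, isotropic within-fixation jitter.
#'
#' @param n_asd,n_td Participants per group (reference cohort: 57 ASD of
#'   which 33 moderate / 24 high, and 17 TD).
#' @param n_moderate Number of ASD participants labelled moderate; the rest
#'   are high.
#' @param geo_mean_asd,geo_sd_asd,geo_mean_td,geo_sd_td %Geo distribution
#'   per diagnostic group (percent).
#' @param geo_mean_moderate,geo_sd_moderate,geo_mean_high,geo_sd_high %Geo
#'   distribution per severity stratum (percent).
#' @param fixation_meanlog,fixation_sdlog Log-normal parameters of fixation
#'   duration in ms (defaults give median ~250 ms).
#' @param saccade_ms Mean saccade (gap) duration in ms.
#' @param sample_rate_hz Eye-tracker sampling rate.
#' @param noise_sd_deg Within-fixation jitter SD in degrees.
#' @param age_mean,age_sd Cohort age distribution in years.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 57, n_td = 17, n_moderate = 33,
                        geo_mean_asd = 49.37, geo_sd_asd = 24.14,
                        geo_mean_td = 35.97, geo_sd_td = 18.58,
                        geo_mean_moderate = 48.21, geo_sd_moderate = 23.82,
                        geo_mean_high = 50.98, geo_sd_high = 25.00,
                        fixation_meanlog = log(250), fixation_sdlog = 0.5,
                        saccade_ms = 40, sample_rate_hz = 60,
                        noise_sd_deg = 0.15, age_mean = 4.6, age_sd = 0.8,
                        seed = 1) {
  stopifnot(n_asd >= 0, n_td >= 0, n_moderate <= n_asd,
            sample_rate_hz > 0, saccade_ms > 0, noise_sd_deg >= 0)
  for (m in c(geo_mean_asd, geo_mean_td, geo_mean_moderate, geo_mean_high))
    if (m < 0 || m > 100) stop("geo means must be in [0, 100]")
  structure(as.list(environment()), class = "cohort_spec")
}

rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic split-screen stimulus
#'
#' Produces grayscale frames whose two halves carry visually distinct
#' moving patterns: a drifting grating on the geometric side and a set of
#' moving Gaussian blobs (crude figure-like motion) on the social side. The
#' geometric side alternates between left and right across scenes, and the
#' per-scene schedule is emitted as the AOI table. Deterministic given
#' `seed`.
#'
#' @param n_frames Number of frames.
#' @param shape Integer `c(height, width)`; default 72x128, a 1/10-scale
#'   16:9 frame.
#' @param duration_s Nominal playback duration in seconds.
#' @param n_scenes Number of alternating scenes.
#' @param seed Integer seed.
#' @return A list of class `synthetic_stimulus` with `frames` (list of
#'   matrices in `[0,1]`), `aoi` (`data.frame`: `scene`, `first_frame`,
#'   `last_frame`, `geo_side`), `n_frames`, `duration_s`, `shape`.
#' @export
make_stimulus <- function(n_frames = 61, shape = c(72, 128),
                          duration_s = n_frames / 24.39,
                          n_scenes = max(1, round(n_frames / 53)),
                          seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  h <- shape[1]; w <- shape[2]; half <- floor(w / 2)
  scene_of <- pmin(floor(seq(0, n_frames - 1) / (n_frames / n_scenes)),
                   n_scenes - 1)
  sides <- rep(c("left", "right"), length.out = n_scenes)
  n_blobs <- 3
  blob_xy <- cbind(stats::runif(n_blobs, 0.2, 0.8),
                   stats::runif(n_blobs, 0.2, 0.8))
  blob_ph <- stats::runif(n_blobs, 0, 2 * pi)
  xs <- seq_len(half) / half
  ys <- seq_len(h) / h
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    tt <- f / 10
    grating <- 0.5 + 0.5 * sin(outer(ys * 6, xs * 10 * pi, "+") + tt * 2)
    social <- matrix(0.1, h, half)
    for (b in seq_len(n_blobs)) {
      bx <- blob_xy[b, 1] + 0.15 * sin(tt + blob_ph[b])
      by <- blob_xy[b, 2] + 0.15 * cos(0.7 * tt + blob_ph[b])
      social <- social + 0.6 * exp(-(outer((ys - by)^2, (xs - bx)^2, "+")) /
                                     (2 * 0.03^2))
    }
    social <- pmin(social, 1)
    fr <- matrix(0, h, w)
    if (sides[scene_of[f] + 1] == "left") {
      fr[, seq_len(half)] <- grating
      fr[, (w - half + 1):w] <- social
    } else {
      fr[, seq_len(half)] <- social
      fr[, (w - half + 1):w] <- grating
    }
    frames[[f]] <- fr
  }
  scene_first <- vapply(0:(n_scenes - 1),
                        function(s) min(which(scene_of == s)) - 1L,
                        integer(1))
  scene_last <- vapply(0:(n_scenes - 1),
                       function(s) max(which(scene_of == s)) - 1L,
                       integer(1))
  structure(list(frames = frames,
                 aoi = data.frame(scene = seq_len(n_scenes) - 1L,
                                  first_frame = scene_first,
                                  last_frame = scene_last,
                                  geo_side = sides),
                 n_frames = as.integer(n_frames), duration_s = duration_s,
                 shape = c(h, w)),
            class = "synthetic_stimulus")
}

#' @export
print.synthetic_stimulus <- function(x, ...) {
  cat(sprintf("<synthetic_stimulus> %d frames %dx%d, %.1f s, %d scenes\n",
              x$n_frames, x$shape[1], x$shape[2], x$duration_s,
              nrow(x$aoi)))
  invisible(x)
}

#' Simulate one participant's gaze recording
#'
#' Draws the participant's %Geo from the group's truncated-normal
#' distribution (unless given), then generates alternating fixations and
#' saccade gaps across the stimulus duration: each fixation lands on the
#' geometric side with probability `%Geo / 100` (at a random location within
#' that half, biased away from the edges), lasts a log-normal duration, and
#' contributes 60 Hz samples with isotropic angular jitter. Saccade-gap
#' samples are emitted as invalid, so the velocity filter sees clean
#' fixation runs separated by dropouts, as in screen-based recordings where
#' between-fixation samples are unreliable.
#'
#' @param spec A [cohort_spec()].
#' @param stimulus A [make_stimulus()] object.
#' @param group `"ASD"` or `"TD"`.
#' @param participant_id Identifier string.
#' @param severity Severity stratum for ASD participants.
#' @param percent_geo Optional fixed ground-truth %Geo (otherwise drawn).
#' @param geometry A [screen_geometry()]; defaults to a geometry matched to
#'   the stimulus resolution.
#' @return A [gaze_recording()] with attribute `truth` (list with
#'   `percent_geo`, `n_fixations`).
#' @export
simulate_recording <- function(spec, stimulus, group = "ASD",
                               participant_id = "p1",
                               severity = if (group == "ASD") "moderate"
                                          else "none",
                               percent_geo = NULL, geometry = NULL) {
  h <- stimulus$shape[1]; w <- stimulus$shape[2]
  geometry <- geometry %||% stimulus_geometry(stimulus)
  if (is.null(percent_geo)) {
    percent_geo <- if (group == "TD")
      rtruncnorm01(1, spec$geo_mean_td, spec$geo_sd_td)
    else if (severity == "high")
      rtruncnorm01(1, spec$geo_mean_high, spec$geo_sd_high)
    else rtruncnorm01(1, spec$geo_mean_moderate, spec$geo_sd_moderate)
  }
  period_ms <- 1000 / spec$sample_rate_hz
  total_ms <- stimulus$duration_s * 1000
  jitter_px <- degrees_to_stimulus_px(spec$noise_sd_deg, geometry)
  fps <- stimulus$n_frames / stimulus$duration_s

  t <- 0; rows <- list(); n_fix <- 0L
  while (t < total_ms) {
    dur <- stats::rlnorm(1, spec$fixation_meanlog, spec$fixation_sdlog)
    dur <- min(dur, total_ms - t)
    frame0 <- min(floor(t * fps / 1000), stimulus$n_frames - 1)
    side <- stimulus$aoi$geo_side[stimulus$aoi$first_frame <= frame0 &
                                    stimulus$aoi$last_frame >= frame0][1]
    on_geo <- stats::runif(1) < percent_geo / 100
    on_left <- (side == "left") == on_geo
    cx <- stats::runif(1, 0.1, 0.4) * w + if (on_left) 0 else w / 2
    cy <- stats::runif(1, 0.15, 0.85) * h
    ts <- seq(t, t + dur - 1e-9, by = period_ms)
    if (length(ts) >= 2) {
      n_fix <- n_fix + 1L
      rows[[length(rows) + 1]] <- data.frame(
        t_ms = ts,
        x_px = cx + stats::rnorm(length(ts), 0, jitter_px),
        y_px = cy + stats::rnorm(length(ts), 0, jitter_px),
        valid = TRUE)
    }
    gap <- stats::rexp(1, 1 / spec$saccade_ms) + period_ms
    gap_end <- min(t + dur + gap, total_ms) - 1e-9
    gap_ts <- if (gap_end > t + dur) seq(t + dur, gap_end, by = period_ms)
              else numeric(0)
    if (length(gap_ts))
      rows[[length(rows) + 1]] <- data.frame(t_ms = gap_ts, x_px = NA_real_,
                                             y_px = NA_real_, valid = FALSE)
    t <- t + dur + gap
  }
  samples <- do.call(rbind, rows)
  samples <- samples[order(samples$t_ms), ]
  rec <- gaze_recording(participant_id, samples, group = group,
                        severity = severity,
                        age_years = stats::rnorm(1, spec$age_mean,
                                                 spec$age_sd),
                        gender = sample(c("F", "M"), 1))
  attr(rec, "truth") <- list(percent_geo = percent_geo,
                             n_fixations = n_fix)
  rec
}

#' Geometry matched to a synthetic stimulus
#'
#' A [screen_geometry()] whose stimulus dimensions equal the synthetic
#' stimulus so that angular conversions stay physically meaningful at
#' reduced resolution (the display mapping absorbs the scale change).
#'
#' @param stimulus A [make_stimulus()] object.
#' @return A [screen_geometry()].
#' @export
stimulus_geometry <- function(stimulus) {
  screen_geometry(stimulus_w_px = stimulus$shape[2],
                  stimulus_h_px = stimulus$shape[1])
}

#' Simulate a full cohort
#'
#' Generates `n_asd + n_td` recordings with group, severity and demographic
#' metadata, plus a ground-truth table. Reproducible by seed.
#'
#' @param spec A [cohort_spec()].
#' @param stimulus A [make_stimulus()] object.
#' @param geometry Optional [screen_geometry()].
#' @return A list of class `synthetic_cohort` with `recordings` (list of
#'   [gaze_recording()]s) and `truth` (`data.frame`: `participant_id`,
#'   `group`, `severity`, `percent_geo`, `n_fixations`).
#' @export
make_cohort <- function(spec, stimulus, geometry = NULL) {
  set.seed(spec$seed)
  geometry <- geometry %||% stimulus_geometry(stimulus)
  plan <- data.frame(
    group = c(rep("ASD", spec$n_asd), rep("TD", spec$n_td)),
    severity = c(rep("moderate", spec$n_moderate),
                 rep("high", spec$n_asd - spec$n_moderate),
                 rep("none", spec$n_td)))
  plan$participant_id <- sprintf("%s%03d", tolower(plan$group),
                                 seq_len(nrow(plan)))
  recordings <- vector("list", nrow(plan))
  truth <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    rec <- simulate_recording(spec, stimulus, group = plan$group[i],
                              participant_id = plan$participant_id[i],
                              severity = plan$severity[i],
                              geometry = geometry)
    recordings[[i]] <- rec
    tr <- attr(rec, "truth")
    truth[[i]] <- data.frame(participant_id = plan$participant_id[i],
                             group = plan$group[i],
                             severity = plan$severity[i],
                             percent_geo = tr$percent_geo,
                             n_fixations = tr$n_fixations)
  }
  structure(list(recordings = recordings, truth = do.call(rbind, truth),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d recordings (%s)\n",
              length(x$recordings),
              paste(names(table(x$truth$group)), table(x$truth$group),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
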