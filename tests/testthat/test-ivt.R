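test_that("I-VT segments stationary runs separated by a saccade", {
  geom <- test_geometry()
  cfg <- fixation_filter_config()
  # 200 ms at (100,100), instantaneous jump, 200 ms at (500,500)
  s <- rbind(stationary_stream(0, 200, 100, 100),
             stationary_stream(200, 200, 500, 500))
  fx <- ivt_detect_fixations(s, cfg, geom)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$cx_px, c(100, 500))
  expect_equal(fx$cy_px, c(100, 500))

  # constant position for 500 ms -> one fixation of 500 ms
  fx1 <- ivt_detect_fixations(stationary_stream(0, 500, 50, 50), cfg, geom)
  expect_equal(nrow(fx1), 1)
  expect_equal(fx1$duration_ms, 500, tolerance = 1e-6)

  # smooth drift above threshold -> no fixations
  drift_px_per_sample <- degrees_to_pixels(1, geom)  # 60 deg/s at 60 Hz
  ts <- seq(0, 500 - 1e-9, by = 1000 / 60)
  drift <- data.frame(t_ms = ts, x_px = 100 + seq_along(ts) *
                        drift_px_per_sample, y_px = 100, valid = TRUE)
  expect_equal(nrow(ivt_detect_fixations(drift, cfg, geom)), 0)
})

test_that("all-invalid or too-short streams yield an empty fixation table", {
  geom <- test_geometry()
  s <- stationary_stream(0, 200, 10, 10)
  s$valid <- FALSE
  expect_equal(nrow(ivt_detect_fixations(s, geometry = geom)), 0)
  expect_equal(nrow(ivt_detect_fixations(s[1, ], geometry = geom)), 0)
})

test_that("invalid samples break fixation runs", {
  geom <- test_geometry()
  s <- stationary_stream(0, 400, 100, 100)
  mid <- seq(10, 13)
  s$valid[mid] <- FALSE
  fx <- ivt_detect_fixations(s, geometry = geom)
  expect_equal(nrow(fx), 2)
})

test_that("merge precedes duration discard and respects both criteria", {
  geom <- test_geometry()
  cfg <- fixation_filter_config()
  px02 <- degrees_to_pixels(0.2, geom)
  px10 <- degrees_to_pixels(1.0, geom)

  # two 60 ms fixations 50 ms apart, 0.2 deg apart -> merged, kept
  fx <- rbind(small_fix(0, 60, 100, 100),
              small_fix(110, 170, 100 + px02, 100))
  out <- merge_and_filter_fixations(fx, cfg, geom)
  expect_equal(nrow(out), 1)
  expect_equal(out$duration_ms, 170)
  # duration-weighted centroid of equal-duration pair is the midpoint
  expect_equal(out$cx_px, 100 + px02 / 2)

  # single 80 ms fixation with no neighbour -> discarded
  expect_equal(nrow(merge_and_filter_fixations(small_fix(0, 80, 5, 5),
                                               cfg, geom)), 0)

  # 1.0 deg apart -> not merged, both short ones dropped
  fx2 <- rbind(small_fix(0, 60, 100, 100),
               small_fix(110, 170, 100 + px10, 100))
  expect_equal(nrow(merge_and_filter_fixations(fx2, cfg, geom)), 0)

  # gap above 75 ms -> not merged
  fx3 <- rbind(small_fix(0, 60, 100, 100),
               small_fix(140, 200, 100 + px02, 100))
  expect_equal(nrow(merge_and_filter_fixations(fx3, cfg, geom)), 0)
})

test_that("merge/filter is idempotent and never increases total duration", {
  geom <- test_geometry()
  cfg <- fixation_filter_config()
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    starts <- cumsum(runif(n, 0, 300))
    durs <- runif(n, 40, 400)
    fx <- do.call(rbind, lapply(seq_len(n), function(i)
      small_fix(starts[i], starts[i] + durs[i],
                runif(1, 0, 500), runif(1, 0, 500))))
    once <- merge_and_filter_fixations(fx, cfg, geom)
    twice <- merge_and_filter_fixations(once, cfg, geom)
    expect_equal(once, twice)
    expect_lte(sum(once$duration_ms), sum(fx$duration_ms) + 1e-9)
  }
})

test_that("time-reversed streams yield mirrored fixation intervals", {
  geom <- test_geometry()
  s <- rbind(stationary_stream(0, 300, 100, 100),
             stationary_stream(300, 200, 700, 400))
  rev_s <- data.frame(t_ms = max(s$t_ms) - rev(s$t_ms),
                      x_px = rev(s$x_px), y_px = rev(s$y_px), valid = TRUE)
  fx <- ivt_detect_fixations(s, geometry = geom)
  fx_r <- ivt_detect_fixations(rev_s, geometry = geom)
  expect_equal(nrow(fx), nrow(fx_r))
  expect_equal(sort(fx$duration_ms), sort(fx_r$duration_ms),
               tolerance = 1e-6)
  expect_setequal(round(fx$cx_px), round(fx_r$cx_px))
})

test_that("trial inclusion applies the 15 s boundary inclusively", {
  cfg <- fixation_filter_config()
  expect_false(trial_inclusion(small_fix(0, 14999, 0, 0), cfg))
  expect_true(trial_inclusion(small_fix(0, 15000, 0, 0), cfg))
  # a recording at the reference mean attention (37.13 s) is included
  expect_true(trial_inclusion(small_fix(0, 37130, 0, 0), cfg))
})

test_that("frame mapping matches an interval-overlap oracle", {
  fps <- 24.39; n_frames <- 1488; duration_s <- n_frames / fps
  oracle_span <- function(start, end) {
    f <- 0:(n_frames - 1)
    lo <- f * 1000 / fps; hi <- (f + 1) * 1000 / fps
    which(pmin(hi, end) > pmax(lo, start)) - 1
  }
  set.seed(8)
  for (rep in 1:25) {
    start <- runif(1, 0, 60000); end <- start + runif(1, 10, 3000)
    fx <- map_fixations_to_frames(small_fix(start, end, 0, 0),
                                  n_frames, duration_s)
    sp <- oracle_span(start, end)
    expect_equal(fx$first_frame, min(sp))
    expect_equal(fx$last_frame, max(sp))
  }
  # 41 ms fixation at ~24.39 fps covers exactly frame 0
  fx0 <- map_fixations_to_frames(small_fix(0, 41, 0, 0), n_frames,
                                 duration_s)
  expect_equal(c(fx0$first_frame, fx0$last_frame), c(0, 0))
  # a fixation spanning the whole video covers all frames
  fxall <- map_fixations_to_frames(small_fix(0, duration_s * 1000, 0, 0),
                                   n_frames, duration_s)
  expect_equal(c(fxall$first_frame, fxall$last_frame), c(0, n_frames - 1))
  # entirely outside -> empty span
  fxout <- map_fixations_to_frames(small_fix(duration_s * 1000 + 5,
                                             duration_s * 1000 + 10, 0, 0),
                                   n_frames, duration_s)
  expect_true(is.na(fxout$first_frame))
})

test_that("calibration accuracy is the mean centroid-to-point distance", {
  fx <- rbind(small_fix(0, 100, 103, 100), small_fix(100, 200, 100, 105))
  expect_equal(calibration_accuracy(fx, c(100, 100)), 4)
  expect_equal(calibration_accuracy(small_fix(0, 100, 7, 9), c(7, 9)), 0)
  expect_error(calibration_accuracy(NULL, c(0, 0)), "undefined")
})
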