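test_that("confusion-count metrics reproduce the reference operating points", {
  # diagnosis: 57 true positives, 4 false alarms among 17 controls
  m <- metrics_from_confusion(tp = 57, fn = 0, tn = 13, fp = 4)
  expect_equal(round(m$accuracy, 2), 94.59)
  expect_equal(m$sensitivity, 100)
  expect_equal(round(m$specificity, 2), 76.47)
  # severity: 21/24 high correctly flagged, all 33 moderate kept
  m2 <- metrics_from_confusion(tp = 21, fn = 3, tn = 33, fp = 0)
  expect_equal(round(m2$accuracy, 2), 94.74)
  expect_equal(m2$sensitivity, 87.5)
  expect_equal(m2$specificity, 100)
  m3 <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(c(m3$accuracy, m3$sensitivity, m3$specificity),
               c(100, 100, 100))
  expect_warning(m4 <- metrics_from_confusion(0, 0, 5, 0), "sensitivity")
  expect_true(is.na(m4$sensitivity))
  expect_error(metrics_from_confusion(-1, 0, 0, 0), "non-negative")
})

test_that("rank-based AUC matches all-pairs counting on exhaustive inputs", {
  pair_auc <- function(scores, labels) {
    pos <- which(labels == 1); neg <- which(labels == 0)
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    tot / (length(pos) * length(neg))
  }
  # exhaustive: every labelling of n <= 8 scores with ties
  set.seed(41)
  for (n in c(4, 6, 8)) {
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    for (mask in 1:(2^n - 2)) {
      labels <- as.integer(intToBits(mask))[1:n]
      if (sum(labels) == 0 || sum(labels) == n) next
      expect_equal(auc_from_probabilities(scores, labels, positive = 1),
                   pair_auc(scores, labels), tolerance = 1e-12)
    }
  }
  expect_equal(auc_from_probabilities(c(.9, .8, .2, .1), c(1, 1, 0, 0), 1), 1)
  expect_equal(auc_from_probabilities(rep(.5, 6), c(1, 1, 1, 0, 0, 0), 1),
               0.5)
  expect_error(auc_from_probabilities(1:3, c(1, 1, 1), 1), "both classes")
})

test_that("pooled t test reproduces the four printed %Geo statistics", {
  # ASD vs TD
  t1 <- pooled_t_test(49.37, 24.14, 57, 35.97, 18.58, 17)
  expect_equal(t1$t, 2.11, tolerance = 0.005)
  expect_equal(t1$df, 72)
  expect_lt(t1$p, 0.05)
  # moderate vs high (printed as magnitude)
  t2 <- pooled_t_test(48.21, 23.82, 33, 50.98, 25.00, 24)
  expect_equal(abs(t2$t), 0.424, tolerance = 0.005)
  expect_gt(t2$p, 0.5)
  # high vs TD and moderate vs TD
  expect_equal(pooled_t_test(50.98, 25.00, 24, 35.97, 18.58, 17)$t, 2.096,
               tolerance = 0.005)
  expect_equal(pooled_t_test(48.21, 23.82, 33, 35.97, 18.58, 17)$t, 1.846,
               tolerance = 0.005)
})

test_that("pooled t test is antisymmetric with sane degenerate behaviour", {
  a <- c(12, 3, 20); b <- c(9, 4, 15)
  t_ab <- pooled_t_test(a[1], a[2], a[3], b[1], b[2], b[3])
  t_ba <- pooled_t_test(b[1], b[2], b[3], a[1], a[2], a[3])
  expect_equal(t_ab$t, -t_ba$t)
  expect_equal(t_ab$p, t_ba$p)
  t_id <- pooled_t_test(5, 2, 10, 5, 2, 10)
  expect_equal(t_id$t, 0)
  expect_equal(t_id$p, 1)
  expect_error(pooled_t_test(1, 1, 1, 2, 1, 5), "n >= 2")
  # Welch variant agrees with stats::t.test on raw data
  set.seed(42)
  x <- rnorm(12, 1); y <- rnorm(9, 0)
  ref <- t.test(x, y)
  tw <- pooled_t_test(mean(x), sd(x), 12, mean(y), sd(y), 9, welch = TRUE)
  expect_equal(tw$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(tw$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(tw$p, ref$p.value, tolerance = 1e-9)
})

test_that("%Geo is the duration share on the geometric side", {
  aoi <- data.frame(scene = 0, first_frame = 0, last_frame = 99,
                    geo_side = "left")
  fx <- rbind(small_fix(0, 3000, 10, 10),     # left (geo): 3 s
              small_fix(3000, 4000, 100, 10)) # right (social): 1 s
  fx$first_frame <- c(0L, 5L); fx$last_frame <- c(4L, 7L)
  expect_equal(percent_geo(fx, aoi, stim_w = 128), 75)
  # all on the geometric side -> 100
  fx_g <- fx; fx_g$cx_px <- c(10, 20)
  expect_equal(percent_geo(fx_g, aoi, 128), 100)
  # equal durations both sides -> 50
  fx_e <- rbind(small_fix(0, 1000, 10, 10), small_fix(1000, 2000, 100, 10))
  fx_e$first_frame <- c(0L, 2L); fx_e$last_frame <- c(1L, 3L)
  expect_equal(percent_geo(fx_e, aoi, 128), 50)
  # side flips when the scene schedule flips
  aoi_r <- aoi; aoi_r$geo_side <- "right"
  expect_equal(percent_geo(fx, aoi_r, 128), 25)
  expect_warning(pg <- percent_geo(fx[0, ], aoi, 128), "undefined")
  expect_true(is.na(pg))
})

test_that("%Geo is invariant to fixation order and duration rescaling", {
  aoi <- data.frame(scene = 0, first_frame = 0, last_frame = 99,
                    geo_side = "left")
  set.seed(43)
  fx <- do.call(rbind, lapply(1:8, function(i) {
    f <- small_fix((i - 1) * 500, (i - 1) * 500 + runif(1, 100, 400),
                   runif(1, 0, 128), 10)
    f$first_frame <- i - 1L; f$last_frame <- i - 1L
    f
  }))
  base <- percent_geo(fx, aoi, 128)
  expect_equal(percent_geo(fx[sample(8), ], aoi, 128), base)
  fx2 <- fx; fx2$duration_ms <- fx$duration_ms * 3.7
  expect_equal(percent_geo(fx2, aoi, 128), base, tolerance = 1e-12)
})

test_that("threshold classifier uses a strict cutoff at 69", {
  expect_equal(threshold_classifier(69.0), "TD")
  expect_equal(threshold_classifier(69.1), "ASD")
  expect_equal(threshold_classifier(0), "TD")
  expect_equal(threshold_classifier(c(80, 10, 69),
                                    positive = "high", negative = "moderate"),
               c("high", "moderate", "moderate"))
})

test_that("group_summary collects mean, SD and n", {
  g <- group_summary(c(1, 2, 3, NA))
  expect_equal(g$n, 3)
  expect_equal(g$mean, 2)
  expect_equal(g$sd, 1)
  expect_error(group_summary(1), "n >= 2")
})

test_that("handcrafted baselines separate planted cohorts and not null ones", {
  stim <- make_stimulus(20, seed = 44)
  geom <- stimulus_geometry(stim)
  # plant strong signals: the groups differ both in screen side (gaze
  # coordinates) and in fixation duration, so either feature family separates
  make_half <- function(group, meanlog, geo, seed) {
    spec <- cohort_spec(fixation_meanlog = meanlog, fixation_sdlog = 0.1,
                        seed = seed)
    set.seed(seed)
    lapply(1:6, function(i) {
      r <- simulate_recording(spec, stim, group = group,
                              participant_id = paste0(group, i),
                              percent_geo = geo, geometry = geom)
      process_recording(r, fixation_filter_config(), geom, stim$n_frames,
                        stim$duration_s)
    })
  }
  recs <- c(make_half("ASD", log(700), geo = 97, seed = 44),
            make_half("TD", log(150), geo = 3, seed = 45))
  lab <- vapply(recs, `[[`, "", "group")
  for (learner in c("forest-regressor", "decision-tree")) {
    cv <- handcrafted_baseline(recs, lab, learner = learner, seed = 45)
    expect_gte(metrics_from_cv(cv)$accuracy, 90)
  }
  # permuted labels: near-chance accuracy
  set.seed(46)
  lab_p <- sample(lab)
  while (all(lab_p == lab)) lab_p <- sample(lab)
  cv_n <- handcrafted_baseline(recs, lab_p, learner = "forest-regressor",
                               seed = 46)
  expect_lte(metrics_from_cv(cv_n)$accuracy, 75)
})
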