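#' Diagnostic metrics from confusion counts
#'
#' Accuracy, sensitivity (true-positive rate) and specificity (true-negative
#' rate) as percentages from raw confusion counts. A metric with a zero
#' denominator is returned as `NA` with a warning.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return List of class `metrics_report` with `accuracy`, `sensitivity`,
#'   `specificity` in percent and the counts.
#' @examples
#' metrics_from_confusion(tp = 57, fn = 0, tn = 13, fp = 4)
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  total <- tp + fp + tn + fn
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else 100 * num / den
  }
  structure(list(accuracy = safe(tp + tn, total, "accuracy"),
                 sensitivity = safe(tp, tp + fn, "sensitivity"),
                 specificity = safe(tn, tn + fp, "specificity"),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%",
              x$accuracy, x$sensitivity, x$specificity))
  if (!is.null(x$auc)) cat(sprintf(", AUC %.3f", x$auc))
  cat(sprintf("  (tp=%d fp=%d tn=%d fn=%d)\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' AUC from pooled per-fold probabilities
#'
#' Rank-based (Mann-Whitney) area under the ROC curve of the pooled
#' leave-one-out probability estimates: the probability that a random
#' positive receives a higher score than a random negative, with ties
#' counted one half.
#'
#' @param scores Numeric scores (positive-class probabilities).
#' @param labels Labels; `positive` marks the positive class.
#' @param positive Positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_probabilities <- function(scores, labels, positive = "ASD") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metrics from a LOOCV result
#'
#' Confusion-matrix metrics plus the pooled-probability AUC of a
#' [loocv_classify()] result.
#'
#' @param cv A `cv_result`.
#' @param positive Positive class; defaults to the attribute stored on `cv`.
#' @return A `metrics_report` with an `auc` element.
#' @export
metrics_from_cv <- function(cv, positive = attr(cv, "positive") %||% "ASD") {
  tp <- sum(cv$true_label == positive & cv$predicted_label == positive)
  fn <- sum(cv$true_label == positive & cv$predicted_label != positive)
  tn <- sum(cv$true_label != positive & cv$predicted_label != positive)
  fp <- sum(cv$true_label != positive & cv$predicted_label == positive)
  m <- metrics_from_confusion(tp, fp, tn, fn)
  m$auc <- auc_from_probabilities(cv$prob_positive, cv$true_label, positive)
  m
}

#' Percentage of fixation time on the geometric stimulus half
#'
#' The preferential-looking statistic: total fixation duration on the
#' geometric area of interest divided by the total duration on either area,
#' times 100. Fixations outside both areas are excluded from the
#' denominator. The side assignment can change across scenes, so the AOI is
#' a per-frame schedule.
#'
#' @param fixations Frame-mapped fixation `data.frame`.
#' @param aoi An AOI schedule as returned by [make_stimulus()] (or a
#'   `data.frame` with `first_frame`, `last_frame`, `geo_side` in
#'   `{"left", "right"}`).
#' @param stim_w Stimulus width in pixels (midline at `stim_w / 2`).
#' @return Percentage in `[0, 100]`, or `NA` with a warning when no
#'   fixation falls on either area.
#' @export
percent_geo <- function(fixations, aoi, stim_w) {
  if (is.null(fixations) || !nrow(fixations)) {
    warning("no fixations: %Geo undefined")
    return(NA_real_)
  }
  geo <- 0; soc <- 0
  for (i in seq_len(nrow(fixations))) {
    f <- fixations$first_frame[i]
    if (is.na(f)) next
    side <- aoi$geo_side[aoi$first_frame <= f & aoi$last_frame >= f]
    if (!length(side)) next
    on_left <- fixations$cx_px[i] < stim_w / 2
    on_geo <- (side[1] == "left") == on_left
    if (on_geo) geo <- geo + fixations$duration_ms[i]
    else soc <- soc + fixations$duration_ms[i]
  }
  if (geo + soc == 0) {
    warning("no fixation on either AOI: %Geo undefined")
    return(NA_real_)
  }
  100 * geo / (geo + soc)
}

#' Threshold classifier on %Geo
#'
#' Labels a participant positive (ASD, or high severity) when their %Geo
#' strictly exceeds the cutoff (default 69, the published preferential-
#' looking decision rule).
#'
#' @param percent_geo %Geo value(s).
#' @param cutoff Decision threshold in percent.
#' @param positive,negative Labels to return.
#' @return Character label(s).
#' @export
threshold_classifier <- function(percent_geo, cutoff = 69,
                                 positive = "ASD", negative = "TD") {
  ifelse(percent_geo > cutoff, positive, negative)
}

#' Pooled-variance two-sample t test from group summaries
#'
#' Independent-samples Student t test computed from summary statistics
#' (mean, SD, n per group) with the pooled variance estimate
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`. A Welch variant is available.
#'
#' @param mean1,sd1,n1 Summary of the first group.
#' @param mean2,sd2,n2 Summary of the second group.
#' @param welch Use the Welch (unequal-variance) statistic instead.
#' @return List of class `t_test_summary` with `t`, `df`, `p` (two-sided).
#' @examples
#' pooled_t_test(49.37, 24.14, 57, 35.97, 18.58, 17)  # t = 2.11, df = 72
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- if (t == 0) 1 else 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, welch = welch),
            class = "t_test_summary")
}

#' @export
print.t_test_summary <- function(x, ...) {
  cat(sprintf("%st(%s) = %.3f, p = %.4f\n",
              if (x$welch) "Welch " else "",
              format(x$df, digits = 4), x$t, x$p))
  invisible(x)
}

#' Group summary (mean, SD, n) of a numeric vector
#'
#' @param x Numeric vector.
#' @return List with `mean`, `sd`, `n`.
#' @export
group_summary <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need n >= 2 for a group summary")
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Handcrafted-feature baseline under LOOCV
#'
#' Reference baseline using simple engineered features: a fixed-length
#' subsample of the raw gaze trajectory (x and y locations), the average
#' fixation duration, the average point-to-point gaze velocity, age and
#' gender. Evaluated with leave-one-out cross-validation using either a
#' random-forest regressor (numeric 0/1 target thresholded at 0.5) or a
#' decision-tree classifier.
#'
#' @param recordings List of processed [gaze_recording()]s.
#' @param labels Participant labels (two classes).
#' @param learner `"forest-regressor"` or `"decision-tree"`.
#' @param positive Positive class.
#' @param n_gaze_points Subsampled trajectory length per participant.
#' @param seed RNG seed (forest bootstrap).
#' @return A `cv_result` as from [loocv_classify()].
#' @export
handcrafted_baseline <- function(recordings, labels,
                                 learner = c("forest-regressor",
                                             "decision-tree"),
                                 positive = "ASD", n_gaze_points = 128,
                                 seed = 1) {
  learner <- match.arg(learner)
  labels <- as.character(labels)
  feat <- function(r) {
    s <- r$samples[r$samples$valid, , drop = FALSE]
    idx <- round(seq(1, nrow(s), length.out = n_gaze_points))
    vel <- if (nrow(s) > 1)
      mean(sqrt(diff(s$x_px)^2 + diff(s$y_px)^2) / pmax(diff(s$t_ms), 1e-9))
      else 0
    gender_num <- as.numeric(factor(r$gender %||% "U",
                                    levels = c("F", "M", "U")))
    c(s$x_px[idx], s$y_px[idx],
      mean_fix_dur = if (!is.null(r$fixations) && nrow(r$fixations))
        mean(r$fixations$duration_ms) else 0,
      mean_velocity = vel,
      age = if (is.finite(r$age_years)) r$age_years else 0,
      gender = if (is.finite(gender_num)) gender_num else 0)
  }
  X <- do.call(rbind, lapply(recordings, feat))
  colnames(X) <- c(paste0("gx", seq_len(n_gaze_points)),
                   paste0("gy", seq_len(n_gaze_points)),
                   "mean_fix_dur", "mean_velocity", "age", "gender")
  ids <- vapply(recordings, function(r) r$participant_id, character(1))
  n <- nrow(X)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    Xtr <- X[-i, , drop = FALSE]; Xte <- X[i, , drop = FALSE]
    ytr <- labels[-i]
    if (learner == "forest-regressor") {
      # regression on a 0/1 target is intentional for this baseline
      fit <- suppressWarnings(
        randomForest::randomForest(Xtr, as.numeric(ytr == positive)))
      prob <- as.numeric(stats::predict(fit, Xte))
      lab <- if (prob > 0.5) positive else setdiff(unique(labels), positive)[1]
    } else {
      df_tr <- data.frame(y = factor(ytr), Xtr)
      df_te <- data.frame(Xte); names(df_te) <- names(df_tr)[-1]
      fit <- rpart::rpart(y ~ ., df_tr, method = "class",
                          control = rpart::rpart.control(
                            minsplit = min(20, max(4, nrow(df_tr) %/% 3)),
                            minbucket = 2))
      pr <- stats::predict(fit, df_te)
      prob <- if (positive %in% colnames(pr)) pr[1, positive] else 0
      lab <- colnames(pr)[which.max(pr[1, ])]
    }
    out[[i]] <- data.frame(participant_id = ids[i], true_label = labels[i],
                           predicted_label = lab, prob_positive = prob)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "positive") <- positive
  class(res) <- c("cv_result", class(res))
  res
}
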