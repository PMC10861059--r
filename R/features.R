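#' Extract per-fixation feature vectors from model feature volumes
#'
#' For each fixation, the (upsampled) feature volume of the fixation's onset
#' frame is indexed at the grid cell nearest to the fixation centroid,
#' mapped proportionally from stimulus coordinates to the volume's spatial
#' grid. One C-vector per fixation, temporal order preserved. Fixations
#' whose onset frame lies beyond the available volumes (or with no frame
#' mapping) are skipped.
#'
#' @param volumes List of `h x w x C` feature volumes, one per frame
#'   (0-based frame `f` is `volumes[[f + 1]]`), typically already passed
#'   through [upsample_features()].
#' @param fixations Frame-mapped fixation `data.frame` (needs
#'   `first_frame`, `cx_px`, `cy_px`).
#' @param stim_shape Integer `c(height, width)` of the stimulus coordinate
#'   space the centroids live in.
#' @return Matrix with one row per used fixation and `C` columns.
#' @export
extract_fixation_features <- function(volumes, fixations, stim_shape) {
  if (!length(volumes)) stop("no feature volumes")
  d <- dim(volumes[[1]])
  rows <- list()
  if (!is.null(fixations) && nrow(fixations)) {
    if (is.null(fixations$first_frame))
      stop("fixations must be frame-mapped")
    for (i in seq_len(nrow(fixations))) {
      f <- fixations$first_frame[i]
      if (is.na(f) || f + 1 > length(volumes)) next
      col <- floor((fixations$cx_px[i] + 0.5) / stim_shape[2] * d[2])
      row <- floor((fixations$cy_px[i] + 0.5) / stim_shape[1] * d[1])
      col <- min(max(col, 0), d[2] - 1)
      row <- min(max(row, 0), d[1] - 1)
      rows[[length(rows) + 1]] <- volumes[[f + 1]][row + 1, col + 1, ]
    }
  }
  if (!length(rows)) return(matrix(numeric(0), 0, d[3]))
  do.call(rbind, rows)
}

#' Cascade per-fixation features into one participant vector
#'
#' Concatenates the first `K` per-fixation C-vectors in temporal order; when
#' fewer than `K` fixations are available the tail is zero-padded, so every
#' participant vector has length exactly `K * C`.
#'
#' @param per_fixation Matrix of per-fixation features (rows = fixations).
#' @param K Number of fixation stages.
#' @return Numeric vector of length `K * ncol(per_fixation)`.
#' @export
cascade_features <- function(per_fixation, K) {
  if (K < 1) stop("K must be >= 1")
  C <- ncol(per_fixation)
  out <- numeric(K * C)
  n <- min(nrow(per_fixation), K)
  if (n > 0)
    out[seq_len(n * C)] <- as.vector(t(per_fixation[seq_len(n), , drop = FALSE]))
  out
}

# Fit a linear SVM and a Platt sigmoid calibration on the training fold.
# Returns a function mapping a feature matrix to positive-class
# probabilities, plus hard labels.
fit_svm_fold <- function(X, y, positive, cost = 1) {
  ylev <- factor(y, levels = c(setdiff(unique(y), positive), positive))
  if (nlevels(droplevels(ylev)) < 2) stop("training fold has a single class")
  fit <- e1071::svm(X, ylev, kernel = "linear", cost = cost, scale = FALSE)
  dec_attr <- attr(stats::predict(fit, X, decision.values = TRUE),
                   "decision.values")
  # orient the margin so larger means positive class
  sgn <- if (startsWith(colnames(dec_attr)[1], paste0(positive, "/"))) 1 else -1
  z <- sgn * dec_attr[, 1]
  ybin <- as.numeric(ylev == positive)
  cal <- suppressWarnings(stats::glm(ybin ~ z, family = stats::binomial()))
  function(Xnew) {
    pd <- stats::predict(fit, Xnew, decision.values = TRUE)
    znew <- sgn * attr(pd, "decision.values")[, 1]
    prob <- as.vector(stats::predict(cal, data.frame(z = znew),
                                     type = "response"))
    list(label = as.character(pd), prob = prob)
  }
}

#' Leave-one-out SVM classification
#'
#' For every participant, a linear SVM (L2 penalty, `C = 1`) is trained on
#' all other participants and used to predict the held-out label together
#' with a positive-class probability from a Platt sigmoid calibration
#' fitted on the training fold's decision values. Deterministic given the
#' input order-independent data (predictions do not depend on participant
#' ordering).
#'
#' @param vectors Numeric feature matrix, one row per participant.
#' @param labels Character/factor labels, two classes.
#' @param positive The positive class (`"ASD"` for diagnosis, `"high"` for
#'   severity).
#' @param cost SVM penalty parameter.
#' @param ids Optional participant identifiers.
#' @param standardise Fit a per-fold feature scaler on the training data
#'   only (off by default).
#' @return A `data.frame` of class `cv_result` with one row per fold:
#'   `participant_id`, `true_label`, `predicted_label`, `prob_positive`.
#' @export
loocv_classify <- function(vectors, labels, positive = "ASD", cost = 1,
                           ids = NULL, standardise = FALSE) {
  vectors <- as.matrix(vectors)
  labels <- as.character(labels)
  if (min(table(labels)) < 2) stop("need >= 2 participants per class")
  n <- nrow(vectors)
  ids <- ids %||% paste0("p", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- vectors[-i, , drop = FALSE]
    Xte <- vectors[i, , drop = FALSE]
    if (standardise) {
      mu <- colMeans(Xtr)
      sd_ <- apply(Xtr, 2, stats::sd); sd_[sd_ == 0] <- 1
      Xtr <- scale(Xtr, mu, sd_); Xte <- scale(Xte, mu, sd_)
    }
    predict_fold <- fit_svm_fold(Xtr, labels[-i], positive, cost)
    pr <- predict_fold(Xte)
    out[[i]] <- data.frame(participant_id = ids[i], true_label = labels[i],
                           predicted_label = pr$label,
                           prob_positive = pr$prob)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "positive") <- positive
  class(res) <- c("cv_result", class(res))
  res
}

#' Sweep the number of fixation stages
#'
#' Runs [loocv_classify()] for every `K` in `K_range` on cascaded feature
#' vectors and reports accuracy / sensitivity / specificity per `K`; the
#' best `K` maximises accuracy with ties broken towards the smallest `K`.
#'
#' @param per_fixation_list List (per participant) of per-fixation feature
#'   matrices from [extract_fixation_features()].
#' @param labels Participant labels.
#' @param K_range Integer vector of fixation-stage counts to evaluate.
#' @inheritParams loocv_classify
#' @return List with `metrics` (`data.frame`: `K`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`), `best_K`, and `cv` (the
#'   [loocv_classify()] result at `best_K`).
#' @export
sweep_fixation_length <- function(per_fixation_list, labels, K_range,
                                  positive = "ASD", cost = 1, ids = NULL) {
  if (!length(K_range)) stop("K_range must be non-empty")
  rows <- list(); cvs <- list()
  for (K in K_range) {
    X <- do.call(rbind, lapply(per_fixation_list, cascade_features, K = K))
    cv <- loocv_classify(X, labels, positive, cost, ids)
    met <- metrics_from_cv(cv)
    rows[[length(rows) + 1]] <- data.frame(K = K, accuracy = met$accuracy,
                                           sensitivity = met$sensitivity,
                                           specificity = met$specificity,
                                           auc = met$auc)
    cvs[[as.character(K)]] <- cv
  }
  metrics <- do.call(rbind, rows)
  best_K <- metrics$K[which.max(metrics$accuracy)]  # first max = smallest K
  list(metrics = metrics, best_K = best_K, cv = cvs[[as.character(best_K)]])
}

#' End-to-end classification pipeline on processed recordings
#'
#' Shared machinery for the diagnosis and severity tasks: builds per-frame
#' DoF maps between the two cohorts, fine-tunes a saliency model on the
#' stimulus clip with those targets, extracts and cascades per-fixation
#' features from the upsampled recurrent feature volumes, and evaluates a
#' linear SVM under LOOCV. By default the DoF targets and the fine-tuned
#' model are built once from the full cohort; `fold_safe = TRUE` rebuilds
#' both without the held-out participant for every fold (slower, but free of
#' target leakage).
#'
#' @param recordings List of processed (fixation-populated, frame-mapped)
#'   [gaze_recording()]s, all of one task's cohort.
#' @param stimulus A [make_stimulus()] object (frames + geometry info).
#' @param task `"diagnosis"` (TD vs ASD, positive ASD) or `"severity"`
#'   (moderate vs high, positive high).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [training_config()].
#' @param K Number of fixation stages; `NULL` sweeps `K_range`.
#' @param K_range Sweep range used when `K` is `NULL`.
#' @param geometry A [screen_geometry()].
#' @param fold_safe Rebuild DoF targets and model per LOOCV fold.
#' @return List with `cv` (a `cv_result`), `metrics`, `model`, `best_K`,
#'   and (when swept) the per-K `sweep` table.
#' @export
classify_cohort <- function(recordings, stimulus,
                            task = c("diagnosis", "severity"),
                            model_cfg = model_config("tiny"),
                            train_cfg = training_config(),
                            K = 16, K_range = c(4, 8, 16, 32),
                            geometry = screen_geometry(),
                            fold_safe = FALSE) {
  task <- match.arg(task)
  split <- switch(task,
    diagnosis = list(by = "group", neg = "TD", pos = "ASD"),
    severity = list(by = "severity", neg = "moderate", pos = "high"))
  lab <- vapply(recordings, function(r) r[[split$by]], character(1))
  if (task == "severity" && any(lab == "none"))
    stop("severity task requires an ASD-only cohort with severity labels")
  ids <- vapply(recordings, function(r) r$participant_id, character(1))
  stim_shape <- dim(stimulus$frames[[1]])

  run_branch <- function(recs) {
    dof <- dof_sequence(recs, split$neg, split$pos,
                        n_frames = stimulus$n_frames,
                        stim_shape = stim_shape, geometry = geometry,
                        map_shape = c(model_cfg$out_s, model_cfg$out_s),
                        by = split$by)
    clip <- list(frames = stimulus$frames,
                 targets = lapply(dof, `[[`, "grid"))
    model <- init_saliency_model(model_cfg, seed = train_cfg$seed)
    model <- finetune(model, list(clip), train_cfg)
    fw <- saliency_forward(model, stimulus$frames)
    vols <- lapply(fw$volumes, upsample_features,
                   factor = model_cfg$upsample_factor)
    list(model = model, vols = vols)
  }

  feats_for <- function(vols, recs) {
    lapply(recs, function(r)
      extract_fixation_features(vols, r$fixations, stim_shape))
  }

  if (!fold_safe) {
    br <- run_branch(recordings)
    pf <- feats_for(br$vols, recordings)
    if (is.null(K)) {
      sw <- sweep_fixation_length(pf, lab, K_range, positive = split$pos,
                                  ids = ids)
      cv <- sw$cv; best_K <- sw$best_K; sweep_tab <- sw$metrics
    } else {
      X <- do.call(rbind, lapply(pf, cascade_features, K = K))
      cv <- loocv_classify(X, lab, positive = split$pos, ids = ids)
      best_K <- K; sweep_tab <- NULL
    }
    model <- br$model
  } else {
    if (is.null(K)) stop("fold_safe requires a fixed K")
    out <- vector("list", length(recordings))
    for (i in seq_along(recordings)) {
      br <- run_branch(recordings[-i])
      pf_tr <- feats_for(br$vols, recordings[-i])
      Xtr <- do.call(rbind, lapply(pf_tr, cascade_features, K = K))
      pf_te <- feats_for(br$vols, recordings[i])
      Xte <- matrix(cascade_features(pf_te[[1]], K), 1)
      predict_fold <- fit_svm_fold(Xtr, lab[-i], split$pos)
      pr <- predict_fold(Xte)
      out[[i]] <- data.frame(participant_id = ids[i], true_label = lab[i],
                             predicted_label = pr$label,
                             prob_positive = pr$prob)
    }
    cv <- do.call(rbind, out)
    attr(cv, "positive") <- split$pos
    class(cv) <- c("cv_result", class(cv))
    best_K <- K; sweep_tab <- NULL; model <- NULL
  }
  list(cv = cv, metrics = metrics_from_cv(cv), model = model,
       best_K = best_K, sweep = sweep_tab)
}

#' Severity-prediction pipeline
#'
#' Convenience wrapper over [classify_cohort()] for the moderate-vs-high
#' task: DoF maps are recomputed between the moderate (reference) and high
#' (contrast) strata of an ASD-only cohort, a second saliency model is
#' fine-tuned on them, and LOOCV classification uses high severity as the
#' positive class.
#'
#' @inheritParams classify_cohort
#' @return As [classify_cohort()].
#' @export
severity_pipeline <- function(recordings, stimulus,
                              model_cfg = model_config("tiny"),
                              train_cfg = training_config(), K = 16,
                              geometry = screen_geometry(), ...) {
  sev <- vapply(recordings, function(r) r$severity, character(1))
  if (any(!sev %in% c("moderate", "high")))
    stop("every recording needs severity 'moderate' or 'high'")
  classify_cohort(recordings, stimulus, task = "severity",
                  model_cfg = model_cfg, train_cfg = train_cfg, K = K,
                  geometry = geometry, ...)
}
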