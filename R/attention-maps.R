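#' Binary group fixation map for one frame
#'
#' Overlays the fixation centroids of a participant group for one frame on a
#' zero background: every (rounded) fixated pixel is set to 1, regardless of
#' how many fixations land there. Centroids falling outside the map are
#' skipped.
#'
#' @param centroids Two-column matrix or `data.frame` of `(x, y)` centroids
#'   in map coordinates (0-based, origin top-left).
#' @param map_shape Integer `c(height, width)` of the map.
#' @return A `height x width` binary matrix.
#' @export
build_binary_fixation_map <- function(centroids, map_shape) {
  h <- map_shape[1]; w <- map_shape[2]
  m <- matrix(0, h, w)
  if (is.null(centroids) || NROW(centroids) == 0) return(m)
  centroids <- as.matrix(as.data.frame(centroids))
  cx <- round(centroids[, 1])
  cy <- round(centroids[, 2])
  ok <- cx >= 0 & cx <= w - 1 & cy >= 0 & cy <= h - 1
  m[cbind(cy[ok] + 1, cx[ok] + 1)] <- 1
  m
}

# 1-D Gaussian kernel truncated at 3 sigma, unit sum
gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k / sum(k)
}

# separable 2-D convolution with zero padding outside the map
convolve_separable <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  pad_rows <- matrix(0, r, ncol(m))
  mp <- rbind(pad_rows, m, pad_rows)
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
  pad_cols <- matrix(0, nrow(out), r)
  mp <- cbind(pad_cols, out, pad_cols)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k))
    out2 <- out2 + k[j] * mp[, j:(j + ncol(m) - 1L), drop = FALSE]
  out2
}

#' Smooth a fixation map and normalise it to unit sum
#'
#' Convolves a non-negative fixation map with an isotropic Gaussian kernel
#' (default bandwidth 1 degree of visual angle, truncated at 3 sigma, zero
#' padding at the borders) and divides by the sum, producing a per-frame
#' attention heatmap that integrates to 1. An all-zero input is returned
#' unchanged with a warning rather than divided by zero.
#'
#' @param map Non-negative matrix (typically from
#'   [build_binary_fixation_map()]).
#' @param geometry A [screen_geometry()]; used to convert the bandwidth to
#'   map pixels via [degrees_to_stimulus_px()] and `map_scale`.
#' @param bandwidth_deg Gaussian bandwidth (sigma) in degrees.
#' @param map_scale Ratio of map resolution to stimulus resolution (1 when
#'   the map is built at stimulus resolution).
#' @return Matrix of the same shape summing to 1 (or all zeros).
#' @export
smooth_and_normalise <- function(map, geometry = screen_geometry(),
                                 bandwidth_deg = 1, map_scale = 1) {
  if (any(map < 0)) stop("fixation map must be non-negative")
  total <- sum(map)
  if (total == 0) {
    warning("all-zero fixation map: returning zeros")
    return(map)
  }
  sigma_px <- degrees_to_stimulus_px(bandwidth_deg, geometry) * map_scale
  sm <- convolve_separable(map, gaussian_kernel_1d(sigma_px))
  sm / sum(sm)
}

#' Area-averaging resize
#'
#' Exact box-filter (interval-overlap) resampling used to bring
#' stimulus-resolution maps down to the training-target resolution. Each
#' output cell is the average of the input area it covers, so a constant
#' matrix stays constant and total mass scales by the area ratio.
#'
#' @param m Input matrix.
#' @param out_shape Integer `c(height, width)`.
#' @return Resized matrix.
#' @export
resize_area <- function(m, out_shape) {
  overlap_matrix <- function(n_out, n_in) {
    # rows: output cells covering [i-1, i) * n_in/n_out in input units
    A <- matrix(0, n_out, n_in)
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale; hi <- i * scale
      j0 <- floor(lo) + 1; j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in)) {
        A[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
      }
    }
    A / scale
  }
  Ah <- overlap_matrix(out_shape[1], nrow(m))
  Aw <- overlap_matrix(out_shape[2], ncol(m))
  Ah %*% m %*% t(Aw)
}

#' Difference-of-fixation (DoF) map
#'
#' Computes the per-frame DoF map from two smoothed-normalised group
#' heatmaps. With `I` the pixel-wise difference between the reference-group
#' map (`map_neg`, e.g. TD) and the contrast-group map (`map_pos`, e.g. ASD),
#' the DoF value at each pixel is the logistic transform
#' `D = 1 / (1 + exp(-I / sigma_I))` where `sigma_I` is the population
#' standard deviation of `I` over the frame. Cells where the groups attend
#' equally sit at 0.5; values above 0.5 mark reference-group (white)
#' attention, below 0.5 contrast-group (black) attention. When `sigma_I = 0`
#' (identical maps) the whole map is the degenerate constant 0.5.
#'
#' @param map_neg Reference-group heatmap (plays the positive role in `I`).
#' @param map_pos Contrast-group heatmap (subtracted).
#' @return A list of class `dof_map` with elements `grid` (matrix in (0,1))
#'   and `sigma_I`.
#' @export
compute_dof <- function(map_neg, map_pos) {
  if (!all(dim(map_neg) == dim(map_pos)))
    stop("fixation maps must have identical shapes")
  I <- map_neg - map_pos
  n <- length(I)
  sigma_I <- sqrt(sum((I - mean(I))^2) / n)
  grid <- if (sigma_I == 0) matrix(0.5, nrow(I), ncol(I))
          else 1 / (1 + exp(-I / sigma_I))
  structure(list(grid = grid, sigma_I = sigma_I), class = "dof_map")
}

#' @export
print.dof_map <- function(x, ...) {
  cat(sprintf("<dof_map> %dx%d, sigma_I = %.3g, range [%.3f, %.3f]\n",
              nrow(x$grid), ncol(x$grid), x$sigma_I,
              min(x$grid), max(x$grid)))
  invisible(x)
}

# per-frame group centroids: list (by frame, 1-based index frame+1) of
# data.frames of centroids for recordings in `ids`
frame_centroids <- function(recordings, n_frames) {
  per_frame <- vector("list", n_frames)
  for (r in recordings) {
    fx <- r$fixations
    if (is.null(fx) || !nrow(fx)) next
    if (is.null(fx$first_frame))
      stop("fixations must be frame-mapped (see map_fixations_to_frames)")
    for (i in seq_len(nrow(fx))) {
      if (is.na(fx$first_frame[i])) next
      for (f in fx$first_frame[i]:fx$last_frame[i]) {
        per_frame[[f + 1]] <- rbind(per_frame[[f + 1]],
                                    data.frame(x = fx$cx_px[i],
                                               y = fx$cy_px[i]))
      }
    }
  }
  per_frame
}

#' Per-frame DoF map sequence for two groups
#'
#' Builds, for every frame, the binary fixation map of each group at
#' stimulus resolution, smooths and normalises it, optionally downsamples by
#' area averaging to `map_shape`, and applies [compute_dof()]. For the
#' severity task pass the moderate group as `neg_label` and the high group
#' as `pos_label`.
#'
#' @param recordings List of frame-mapped [gaze_recording()]s.
#' @param neg_label,pos_label Group labels selecting the reference (white)
#'   and contrast (black) cohorts; matched against `group` unless
#'   `by = "severity"`.
#' @param n_frames Number of stimulus frames.
#' @param stim_shape Integer `c(height, width)` of the stimulus.
#' @param geometry A [screen_geometry()].
#' @param map_shape Output DoF resolution (default 28x28); `NULL` keeps
#'   stimulus resolution.
#' @param by Metadata field used for the split: `"group"` or `"severity"`.
#' @return List of `dof_map` objects, one per frame.
#' @export
dof_sequence <- function(recordings, neg_label = "TD", pos_label = "ASD",
                         n_frames, stim_shape, geometry = screen_geometry(),
                         map_shape = c(28, 28), by = c("group", "severity")) {
  by <- match.arg(by)
  lab <- vapply(recordings, function(r) r[[by]], character(1))
  neg <- recordings[lab == neg_label]
  pos <- recordings[lab == pos_label]
  if (!length(neg) || !length(pos))
    stop("both groups must be non-empty: ", neg_label, " n=", length(neg),
         ", ", pos_label, " n=", length(pos))
  cen_neg <- frame_centroids(neg, n_frames)
  cen_pos <- frame_centroids(pos, n_frames)
  group_map <- function(cen) {
    m <- build_binary_fixation_map(cen, stim_shape)
    if (sum(m) == 0) return(if (is.null(map_shape)) m
                            else matrix(0, map_shape[1], map_shape[2]))
    m <- smooth_and_normalise(m, geometry,
                              map_scale = stim_shape[2] /
                                geometry$stimulus_w_px)
    if (!is.null(map_shape)) {
      m <- resize_area(m, map_shape)
      m <- m / sum(m)
    }
    m
  }
  lapply(seq_len(n_frames), function(f) {
    compute_dof(group_map(cen_neg[[f]]), group_map(cen_pos[[f]]))
  })
}
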