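# Convolution primitives -------------------------------------------------
#
# All convolutions are stride-1, odd-kernel, zero-padded ("same"), built on
# an im2col expansion so both the forward pass and the weight/input
# gradients reduce to dense matrix products. Feature maps are stored either
# as H x W x C arrays or as (H*W) x C matrices (column-major vectorisation
# of each channel); the two layouts are interchangeable via array()/matrix().

im2col <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  r <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2 * r, W + 2 * r, C))
  xp[r + seq_len(H), r + seq_len(W), ] <- x
  cols <- matrix(0, H * W, k * k * C)
  idx <- 1L
  for (c in seq_len(C)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    cols[, idx] <- as.vector(xp[di + seq_len(H), dj + seq_len(W), c])
    idx <- idx + 1L
  }
  cols
}

col2im <- function(cols, H, W, C, k) {
  r <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2 * r, W + 2 * r, C))
  idx <- 1L
  for (c in seq_len(C)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    xp[di + seq_len(H), dj + seq_len(W), c] <-
      xp[di + seq_len(H), dj + seq_len(W), c] + matrix(cols[, idx], H, W)
    idx <- idx + 1L
  }
  xp[r + seq_len(H), r + seq_len(W), , drop = FALSE]
}

avgpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], 2); o2 <- seq(2, d[1], 2)
  p1 <- seq(1, d[2], 2); p2 <- seq(2, d[2], 2)
  (x[o1, p1, , drop = FALSE] + x[o2, p1, , drop = FALSE] +
   x[o1, p2, , drop = FALSE] + x[o2, p2, , drop = FALSE]) / 4
}

avgpool2_back <- function(dy) {
  d <- dim(dy)
  dx <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  o1 <- seq(1, 2 * d[1], 2); o2 <- seq(2, 2 * d[1], 2)
  p1 <- seq(1, 2 * d[2], 2); p2 <- seq(2, 2 * d[2], 2)
  dx[o1, p1, ] <- dy / 4; dx[o2, p1, ] <- dy / 4
  dx[o1, p2, ] <- dy / 4; dx[o2, p2, ] <- dy / 4
  dx
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Model configuration ----------------------------------------------------

#' Saliency model configuration
#'
#' Architecture hyper-parameters of the video saliency network: a small
#' convolutional encoder (two 3x3 conv + ReLU + 2x2 average-pool stages), a
#' static 1x1-conv sigmoid attention gate that reweights encoder features
#' (`F = E * (1 + A)`), a convolutional tanh recurrence over frames whose
#' hidden state is the per-frame feature volume, and a 1x1-conv sigmoid
#' decoder producing the predicted DoF map in `[0,1]`.
#'
#' Two presets are provided: `"paper"` (256 feature channels, 28x28 output,
#' 112x112 input) matching the published operating point, and `"tiny"`
#' (16 channels, 7x7 output, 28x28 input) for desk-scale experiments and
#' tests.
#'
#' @param scale_preset `"tiny"` or `"paper"`.
#' @param feature_channels Channels `C` of the recurrent feature volume.
#' @param output_shape Side length of the square predicted map.
#' @param attention_enabled Gate encoder features with the attention map.
#' @param upsample_factor Bilinear upsampling factor applied to feature
#'   volumes before fixation indexing (see [upsample_features()]).
#' @return A list of class `model_config`.
#' @export
model_config <- function(scale_preset = c("tiny", "paper"),
                         feature_channels = NULL, output_shape = NULL,
                         attention_enabled = TRUE, upsample_factor = 4) {
  scale_preset <- match.arg(scale_preset)
  defaults <- switch(scale_preset,
    tiny = list(C = 16L, out = 7L),
    paper = list(C = 256L, out = 28L))
  C <- as.integer(feature_channels %||% defaults$C)
  out <- as.integer(output_shape %||% defaults$out)
  if (C < 1 || upsample_factor < 1) stop("invalid model configuration")
  structure(list(scale_preset = scale_preset, C = C, C1 = max(4L, C %/% 2L),
                 out_s = out, in_s = 4L * out, k = 3L,
                 attention_enabled = isTRUE(attention_enabled),
                 upsample_factor = as.integer(upsample_factor)),
            class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialise a saliency model
#'
#' He-scaled Gaussian initialisation of all convolutional weights,
#' deterministic given `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `saliency_model` with `config`, `params`, `seed`.
#' @export
init_saliency_model <- function(config = model_config(), seed = 1) {
  set.seed(seed)
  k2 <- config$k^2
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                nr, nc)
  params <- list(
    W1 = he(k2 * 1, config$C1),          b1 = numeric(config$C1),
    W2 = he(k2 * config$C1, config$C),   b2 = numeric(config$C),
    va = stats::rnorm(config$C, sd = sqrt(1 / config$C)), ba = 0,
    Wx = he(k2 * config$C, config$C),    Wh = he(k2 * config$C, config$C) / 2,
    bh = numeric(config$C),
    wd = stats::rnorm(config$C, sd = sqrt(1 / config$C)), bd = 0
  )
  structure(list(config = config, params = params, seed = seed),
            class = "saliency_model")
}

#' @export
print.saliency_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<saliency_model> preset '%s': C=%d, output %dx%d, %d parameters\n",
              x$config$scale_preset, x$config$C, x$config$out_s,
              x$config$out_s, np))
  invisible(x)
}

prep_frame <- function(frame, in_s) {
  if (is.null(dim(frame))) stop("frames must be matrices")
  if (all(dim(frame) == c(in_s, in_s))) return(frame)
  resize_area(frame, c(in_s, in_s))
}

# Full forward pass over a frame sequence; returns predictions, feature
# volumes and (optionally) the caches needed for backpropagation.
forward_pass <- function(model, frames, H0 = NULL, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  s <- cfg$out_s; s2 <- 2L * s; C <- cfg$C; k <- cfg$k
  Hmat <- H0 %||% matrix(0, s * s, C)
  preds <- vector("list", length(frames))
  volumes <- vector("list", length(frames))
  caches <- if (keep_cache) vector("list", length(frames))
  for (t in seq_along(frames)) {
    x <- array(prep_frame(frames[[t]], cfg$in_s), c(cfg$in_s, cfg$in_s, 1))
    cols1 <- im2col(x, k)
    Z1 <- sweep(cols1 %*% p$W1, 2, p$b1, "+")
    E1 <- pmax(Z1, 0)
    P1 <- avgpool2(array(E1, c(cfg$in_s, cfg$in_s, cfg$C1)))
    cols2 <- im2col(P1, k)
    Z2 <- sweep(cols2 %*% p$W2, 2, p$b2, "+")
    E2 <- pmax(Z2, 0)
    P2 <- avgpool2(array(E2, c(s2, s2, C)))
    P2m <- matrix(P2, s * s, C)
    if (cfg$attention_enabled) {
      A <- sigmoid(as.vector(P2m %*% p$va) + p$ba)
      Fm <- P2m * (1 + A)
    } else {
      A <- NULL
      Fm <- P2m
    }
    colsF <- im2col(array(Fm, c(s, s, C)), k)
    colsH <- im2col(array(Hmat, c(s, s, C)), k)
    Zh <- sweep(colsF %*% p$Wx + colsH %*% p$Wh, 2, p$bh, "+")
    Hnew <- tanh(Zh)
    yz <- as.vector(Hnew %*% p$wd) + p$bd
    Y <- matrix(sigmoid(yz), s, s)
    preds[[t]] <- Y
    volumes[[t]] <- array(Hnew, c(s, s, C))
    if (keep_cache)
      caches[[t]] <- list(cols1 = cols1, m1 = Z1 > 0, cols2 = cols2,
                          m2 = Z2 > 0, P2m = P2m, A = A, colsF = colsF,
                          colsH = colsH, Hmat = Hnew, Y = Y)
    Hmat <- Hnew
  }
  list(preds = preds, volumes = volumes, caches = caches, H_last = Hmat)
}

#' Run the saliency network over a frame sequence
#'
#' Deterministic forward pass: per-frame predicted DoF maps in `[0,1]`
#' (decoder sigmoid) and per-frame feature volumes (the recurrent hidden
#' state, `out_s x out_s x C`).
#'
#' @param model A [init_saliency_model()] (possibly fine-tuned).
#' @param frames Non-empty list of grayscale frame matrices in `[0,1]`; each
#'   is resampled to the model input size.
#' @return List with `preds` (list of matrices) and `volumes` (list of 3-D
#'   arrays).
#' @export
saliency_forward <- function(model, frames) {
  if (!length(frames)) stop("empty frame sequence")
  out <- forward_pass(model, frames, keep_cache = FALSE)
  list(preds = out$preds, volumes = out$volumes)
}

# Backward pass through a cached chunk. dYs: list of dL/dY matrices.
# Returns gradient list matching the parameter list.
backward_pass <- function(model, frames, caches, dYs, H0 = NULL) {
  cfg <- model$config; p <- model$params
  s <- cfg$out_s; s2 <- 2L * s; C <- cfg$C; k <- cfg$k
  g <- lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
              else numeric(length(x)))
  dHnext <- matrix(0, s * s, C)
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    yv <- as.vector(cc$Y)
    dyz <- as.vector(dYs[[t]]) * yv * (1 - yv)
    g$wd <- g$wd + as.vector(crossprod(cc$Hmat, dyz))
    g$bd <- g$bd + sum(dyz)
    dH <- outer(dyz, p$wd) + dHnext
    dZh <- dH * (1 - cc$Hmat^2)
    g$Wx <- g$Wx + crossprod(cc$colsF, dZh)
    g$Wh <- g$Wh + crossprod(cc$colsH, dZh)
    g$bh <- g$bh + colSums(dZh)
    dFm <- matrix(col2im(dZh %*% t(p$Wx), s, s, C, k), s * s, C)
    dHnext <- matrix(col2im(dZh %*% t(p$Wh), s, s, C, k), s * s, C)
    if (cfg$attention_enabled) {
      dP2m <- dFm * (1 + cc$A)
      dA <- rowSums(dFm * cc$P2m)
      dza <- dA * cc$A * (1 - cc$A)
      g$va <- g$va + as.vector(crossprod(cc$P2m, dza))
      g$ba <- g$ba + sum(dza)
      dP2m <- dP2m + outer(dza, p$va)
    } else {
      dP2m <- dFm
    }
    dE2 <- matrix(avgpool2_back(array(dP2m, c(s, s, C))), s2 * s2, C)
    dZ2 <- dE2 * cc$m2
    g$W2 <- g$W2 + crossprod(cc$cols2, dZ2)
    g$b2 <- g$b2 + colSums(dZ2)
    dP1 <- col2im(dZ2 %*% t(p$W2), s2, s2, cfg$C1, k)
    dE1 <- matrix(avgpool2_back(dP1), cfg$in_s^2, cfg$C1)
    dZ1 <- dE1 * cc$m1
    g$W1 <- g$W1 + crossprod(cc$cols1, dZ1)
    g$b1 <- g$b1 + colSums(dZ1)
  }
  g
}

#' Bilinearly upsample a feature volume
#'
#' Multiplies each spatial dimension by `factor` using bilinear
#' interpolation with edge clamping; channels are untouched. Constant
#' volumes stay constant, and `factor = 1` is the identity.
#'
#' @param volume `h x w x C` array (a matrix is treated as one channel).
#' @param factor Integer upsampling factor `>= 1`.
#' @return Upsampled `h*factor x w*factor x C` array.
#' @export
upsample_features <- function(volume, factor = 4) {
  if (factor < 1) stop("factor must be >= 1")
  if (is.matrix(volume)) volume <- array(volume, c(dim(volume), 1))
  if (factor == 1) return(volume)
  d <- dim(volume)
  U <- function(n) {
    m <- matrix(0, n * factor, n)
    for (i in seq_len(n * factor)) {
      pos <- (i - 0.5) / factor - 0.5          # 0-based input position
      pos <- min(max(pos, 0), n - 1)           # replicate edges
      lo <- floor(pos)
      whi <- pos - lo
      hi <- min(lo + 1, n - 1)
      m[i, lo + 1] <- m[i, lo + 1] + (1 - whi)
      m[i, hi + 1] <- m[i, hi + 1] + whi
    }
    m
  }
  Uh <- U(d[1]); Uw <- U(d[2])
  out <- array(0, c(d[1] * factor, d[2] * factor, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Uh %*% volume[, , c] %*% t(Uw)
  out
}
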