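#' Training configuration
#'
#' Optimisation hyper-parameters for fine-tuning the saliency network on DoF
#' targets: Adam with learning rate 1e-4 for 20 epochs, one clip-step per
#' optimiser update. Because the recurrence ties frames together, "batch
#' size one" is realised as truncated backpropagation through time over
#' chunks of `tbptt` frames, with one Adam update per chunk.
#'
#' @param epochs Number of passes over the clips.
#' @param learning_rate Adam step size.
#' @param tbptt Truncation length (frames) for backpropagation through time.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @param weights Loss weights passed to [combined_loss()].
#' @param seed Integer seed controlling any training-time randomness.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 20, learning_rate = 1e-4, tbptt = 8,
                            beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                            weights = c(1, 0.1, 0.1), seed = 1) {
  if (epochs <= 0 || learning_rate < 0 || tbptt < 1)
    stop("invalid training configuration")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 tbptt = as.integer(tbptt), beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, weights = weights,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Fine-tune the saliency network on DoF-map targets
#'
#' Minimises the sequence loss `L_d = sum_t L(Y_t, Q_t)` over one or more
#' clips with Adam, where `L` is the combined KL + 0.1 LCC + 0.1 NSS loss.
#' Gradients flow through the decoder, the convolutional recurrence
#' (truncated at `cfg$tbptt` frames), the attention gate and the encoder.
#' The per-epoch loss trace (averaged loss components over all frames) is
#' recorded; training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model A [init_saliency_model()].
#' @param clips List of clips; each clip is a list with `frames` (list of
#'   grayscale matrices) and `targets` (list of DoF target matrices at the
#'   model output resolution, values in `[0,1]`).
#' @param cfg A [training_config()].
#' @return The model with updated parameters and a `trace` element: a
#'   `data.frame` with columns `epoch`, `l_kl`, `l_lcc`, `l_nss`, `total`
#'   (`total` is the summed sequence loss `L_d` per epoch).
#' @export
finetune <- function(model, clips, cfg = training_config()) {
  if (!length(clips)) stop("at least one clip is required")
  for (cl in clips) {
    if (length(cl$frames) != length(cl$targets))
      stop("frames and targets differ in length")
    bad <- vapply(cl$targets, function(q) sum(q) == 0, logical(1))
    if (any(bad)) stop("all-zero DoF target at frame(s): ",
                       paste(which(bad), collapse = ", "))
  }
  set.seed(cfg$seed)
  p <- model$params
  m1 <- lapply(p, function(x) x * 0)
  m2 <- lapply(p, function(x) x * 0)
  step <- 0L
  trace <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    comp <- c(l_kl = 0, l_lcc = 0, l_nss = 0, total = 0)
    n_frames <- 0L
    for (cl in clips) {
      T_ <- length(cl$frames)
      H0 <- NULL
      for (start in seq(1, T_, by = cfg$tbptt)) {
        idx <- start:min(start + cfg$tbptt - 1L, T_)
        model$params <- p
        fw <- forward_pass(model, cl$frames[idx], H0 = H0, keep_cache = TRUE)
        dYs <- vector("list", length(idx))
        for (j in seq_along(idx)) {
          lb <- suppressWarnings(
            combined_loss(fw$preds[[j]], cl$targets[[idx[j]]], cfg$weights))
          if (!is.finite(lb$total))
            stop(sprintf("non-finite loss at epoch %d frame %d (KL=%.3g, LCC=%.3g, NSS=%.3g)",
                         epoch, idx[j], lb$l_kl, lb$l_lcc, lb$l_nss))
          comp <- comp + c(lb$l_kl, lb$l_lcc, lb$l_nss, lb$total)
          dYs[[j]] <- suppressWarnings(
            grad_combined_loss(fw$preds[[j]], cl$targets[[idx[j]]],
                               cfg$weights))
        }
        n_frames <- n_frames + length(idx)
        g <- backward_pass(model, cl$frames[idx], fw$caches, dYs, H0 = H0)
        step <- step + 1L
        for (nm in names(p)) {
          m1[[nm]] <- cfg$beta1 * m1[[nm]] + (1 - cfg$beta1) * g[[nm]]
          m2[[nm]] <- cfg$beta2 * m2[[nm]] + (1 - cfg$beta2) * g[[nm]]^2
          mhat <- m1[[nm]] / (1 - cfg$beta1^step)
          vhat <- m2[[nm]] / (1 - cfg$beta2^step)
          p[[nm]] <- p[[nm]] - cfg$learning_rate * mhat /
            (sqrt(vhat) + cfg$adam_eps)
        }
        H0 <- fw$H_last          # detached carry-over between chunks
      }
    }
    trace[[epoch]] <- data.frame(epoch = epoch,
                                 l_kl = comp["l_kl"] / n_frames,
                                 l_lcc = comp["l_lcc"] / n_frames,
                                 l_nss = comp["l_nss"] / n_frames,
                                 total = comp["total"])
  }
  model$params <- p
  model$trace <- do.call(rbind, trace)
  rownames(model$trace) <- NULL
  model
}

#' Sequence loss of a model on a clip
#'
#' Evaluates `L_d` for the current parameters without updating them.
#'
#' @inheritParams finetune
#' @param clip A single clip (`frames` + `targets`).
#' @param weights Loss weights.
#' @return Scalar `L_d`.
#' @export
evaluate_clip_loss <- function(model, clip, weights = c(1, 0.1, 0.1)) {
  fw <- saliency_forward(model, clip$frames)
  suppressWarnings(sequence_loss(fw$preds, clip$targets, weights))
}
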