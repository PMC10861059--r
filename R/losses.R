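#' Saliency losses for DoF-map prediction
#'
#' Three standard saliency evaluation measures turned into losses, combined
#' as `L = L_KL + 0.1 * L_LCC + 0.1 * L_NSS`:
#'
#' * `loss_kl(Y, Q)` — Kullback-Leibler divergence `sum(Q * log(Q / Y))`
#'   after both maps are epsilon-regularised and renormalised to probability
#'   distributions. Non-negative; zero iff `Y` is proportional to `Q`.
#' * `loss_lcc(Y, Q)` — negative Pearson correlation between the raw maps,
#'   in `[-1, 1]`; `-1` at perfect linear agreement. Defined as 0 (with a
#'   warning) when either map is constant.
#' * `loss_nss(Y, Q)` — negative `Q`-weighted mean of the standardised
#'   prediction `(Y - mean(Y)) / sd(Y)` with `N = sum(Q)` and population
#'   standard deviation; invariant under positive affine maps of `Y`.
#'
#' Gradients of the combined loss with respect to `Y` are available through
#' [grad_combined_loss()] and are exact (verified against finite
#' differences in the test-suite).
#'
#' @param Y Predicted map, numeric matrix.
#' @param Q Target map, numeric matrix of the same shape.
#' @param eps Additive regulariser inside the KL log/division terms.
#' @return A scalar loss; [combined_loss()] returns a list of class
#'   `loss_breakdown` with `l_kl`, `l_lcc`, `l_nss`, `total`.
#' @name saliency_losses
NULL

check_same_shape <- function(Y, Q) {
  if (!all(dim(Y) == dim(Q))) stop("Y and Q must have identical shapes")
}

#' @rdname saliency_losses
#' @export
loss_kl <- function(Y, Q, eps = 1e-7) {
  check_same_shape(Y, Q)
  if (sum(Q) == 0) stop("loss_kl is undefined for an all-zero target")
  q <- (Q + eps) / sum(Q + eps)
  y <- (Y + eps) / sum(Y + eps)
  sum(q * log(q / y))
}

#' @rdname saliency_losses
#' @export
loss_lcc <- function(Y, Q) {
  check_same_shape(Y, Q)
  if (stats::sd(Y) == 0 || stats::sd(Q) == 0) {
    warning("constant map: correlation undefined, returning 0")
    return(0)
  }
  -stats::cor(as.vector(Y), as.vector(Q))
}

#' @rdname saliency_losses
#' @export
loss_nss <- function(Y, Q) {
  check_same_shape(Y, Q)
  N <- sum(Q)
  if (N == 0) stop("loss_nss is undefined for an all-zero target")
  n <- length(Y)
  sigma <- sqrt(sum((Y - mean(Y))^2) / n)
  if (sigma == 0) {
    warning("constant prediction: NSS undefined, returning 0")
    return(0)
  }
  Ybar <- (Y - mean(Y)) / sigma
  -sum(Ybar * Q) / N
}

#' @rdname saliency_losses
#' @param weights Numeric length-3 vector of (KL, LCC, NSS) weights.
#' @export
combined_loss <- function(Y, Q, weights = c(1, 0.1, 0.1), eps = 1e-7) {
  l_kl <- loss_kl(Y, Q, eps)
  l_lcc <- loss_lcc(Y, Q)
  l_nss <- loss_nss(Y, Q)
  structure(list(l_kl = l_kl, l_lcc = l_lcc, l_nss = l_nss,
                 total = weights[1] * l_kl + weights[2] * l_lcc +
                   weights[3] * l_nss),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.5f (KL %.5f, LCC %.5f, NSS %.5f)\n",
              x$total, x$l_kl, x$l_lcc, x$l_nss))
  invisible(x)
}

#' Sequence loss over a clip
#'
#' Sum of the per-frame combined losses `L_d = sum_t L(Y_t, Q_t)` over a
#' predicted/target map sequence.
#'
#' @param Ys,Qs Lists of predicted and target maps of equal length.
#' @inheritParams saliency_losses
#' @return Scalar total loss.
#' @export
sequence_loss <- function(Ys, Qs, weights = c(1, 0.1, 0.1), eps = 1e-7) {
  if (length(Ys) != length(Qs)) stop("sequence lengths differ")
  if (!length(Ys)) stop("empty sequence")
  sum(vapply(seq_along(Ys),
             function(t) combined_loss(Ys[[t]], Qs[[t]], weights, eps)$total,
             numeric(1)))
}

#' Analytic gradient of the combined loss with respect to the prediction
#'
#' @inheritParams combined_loss
#' @return Matrix of `d total / d Y`, same shape as `Y`.
#' @export
grad_combined_loss <- function(Y, Q, weights = c(1, 0.1, 0.1), eps = 1e-7) {
  check_same_shape(Y, Q)
  n <- length(Y)
  # KL term: q fixed, y = (Y+eps)/S; dL/dY_j = (1 - q_j/y_j)/S
  S <- sum(Y + eps)
  y <- (Y + eps) / S
  q <- (Q + eps) / sum(Q + eps)
  g_kl <- (1 - q / y) / S
  # LCC term: L = -r
  Yc <- Y - mean(Y); Qc <- Q - mean(Q)
  b <- sum(Yc^2); cc <- sum(Qc^2)
  if (b == 0 || cc == 0) {
    g_lcc <- matrix(0, nrow(Y), ncol(Y))
  } else {
    a <- sum(Yc * Qc)
    # dr/dY_j = (Qc_j - (a/b) Yc_j) / sqrt(b*cc); the 1/n centering terms
    # vanish because Yc and Qc are centred
    g_lcc <- -(Qc - (a / b) * Yc) / sqrt(b * cc)
  }
  # NSS term
  N <- sum(Q)
  sigma <- sqrt(sum(Yc^2) / n)
  if (sigma == 0 || N == 0) {
    g_nss <- matrix(0, nrow(Y), ncol(Y))
  } else {
    Ybar <- Yc / sigma
    S1 <- sum(Q); S2 <- sum(Q * Ybar)
    g_nss <- -((Q - S1 / n) / sigma - S2 * Ybar / (n * sigma)) / N
  }
  weights[1] * g_kl + weights[2] * g_lcc + weights[3] * g_nss
}
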