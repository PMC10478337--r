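#' Soft Dice loss
#'
#' `1 - (2*sum(p*g) + s) / (sum(p) + sum(g) + s)` with smoothing constant `s`
#' (default 1) to keep the ratio defined on empty masks. Computed per image
#' and averaged when given a batch (third array dimension).
#'
#' @param p probability map in [0, 1].
#' @param g binary target of the same shape.
#' @param smooth smoothing constant `s`.
#' @return scalar loss in [0, 1).
#' @export
dice_loss <- function(p, g, smooth = 1) {
  p <- as_prob_array(p); g <- as_target_array(g, dim(p))
  mean(vapply(seq_len(dim(p)[3]), function(i) {
    pi <- p[, , i]; gi <- g[, , i]
    1 - (2 * sum(pi * gi) + smooth) / (sum(pi) + sum(gi) + smooth)
  }, numeric(1)))
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[g log p + (1-g) log(1-p)]`, with `p` clamped to
#' `[eps, 1-eps]` for numerical safety.
#'
#' @inheritParams dice_loss
#' @param eps clamping constant.
#' @return scalar loss, non-negative.
#' @export
bce_loss <- function(p, g, eps = 1e-6) {
  p <- as_prob_array(p); g <- as_target_array(g, dim(p))
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' Combined segmentation loss
#'
#' `0.5 * (dice_loss + bce_loss)`, the standard composite used for all three
#' stream losses (manual, pseudo-clean, pseudo-noisy).
#'
#' @inheritParams dice_loss
#' @param eps clamping constant for the cross-entropy term.
#' @return scalar loss.
#' @export
seg_loss <- function(p, g, smooth = 1, eps = 1e-6) {
  0.5 * (dice_loss(p, g, smooth) + bce_loss(p, g, eps))
}

as_prob_array <- function(p) {
  if (is.list(p) && !is.null(p$prob)) p <- p$prob
  p <- as.array(p)
  if (length(dim(p)) == 2L) dim(p) <- c(dim(p), 1L)
  p
}

as_target_array <- function(g, dm) {
  if (inherits(g, "label_mask")) g <- g$voxels
  g <- as.array(g) * 1
  if (length(dim(g)) == 2L) dim(g) <- c(dim(g), 1L)
  if (!identical(dim(g), dm)) stop("prediction and target shapes differ")
  g
}

#' Clean-branch objective
#'
#' `L_clean = L_mseg + lambda * L_pseg_clean`: the segmentation loss on the
#' manually labelled stream plus the lambda-weighted segmentation loss of the
#' clean branch's predictions on pseudo-labelled images against their HU
#' pseudo-labels.
#'
#' @param p_labeled,g_manual clean-branch predictions and expert labels.
#' @param p_pseudo,g_pseudo clean-branch predictions on pseudo-labelled
#'   images and the HU pseudo-labels; may be `NULL` when training without a
#'   pseudo stream.
#' @param lambda_weight non-negative weight of the pseudo term.
#' @return a `loss_breakdown` list with fields `l_mseg`, `l_pseg_clean`,
#'   `l_clean`, `lambda_weight`.
#' @export
clean_branch_loss <- function(p_labeled, g_manual, p_pseudo = NULL,
                              g_pseudo = NULL, lambda_weight = 1) {
  if (lambda_weight < 0) stop("lambda_weight must be >= 0")
  l_mseg <- seg_loss(p_labeled, g_manual)
  l_pseg <- if (is.null(p_pseudo)) 0 else seg_loss(p_pseudo, g_pseudo)
  structure(list(l_mseg = l_mseg, l_pseg_clean = l_pseg,
                 l_clean = l_mseg + lambda_weight * l_pseg,
                 lambda_weight = lambda_weight),
            class = "loss_breakdown")
}

#' Noisy-branch objective
#'
#' `L_noisy = lambda * L_pseg_noisy`: the lambda-weighted segmentation loss
#' of the noisy branch's predictions on pseudo-labelled images against the
#' automatically selected supervision target (HU pseudo-label or switched
#' clean-branch prediction).
#'
#' @param p_pseudo_noisy noisy-branch predictions on pseudo-labelled images.
#' @param gt_atst the selected supervision targets (array or mask).
#' @param lambda_weight non-negative weight.
#' @return a `loss_breakdown` list with fields `l_pseg_noisy`, `l_noisy`,
#'   `lambda_weight`.
#' @export
noisy_branch_loss <- function(p_pseudo_noisy, gt_atst, lambda_weight = 1) {
  if (lambda_weight < 0) stop("lambda_weight must be >= 0")
  l_pseg <- seg_loss(p_pseudo_noisy, gt_atst)
  structure(list(l_pseg_noisy = l_pseg,
                 l_noisy = lambda_weight * l_pseg,
                 lambda_weight = lambda_weight),
            class = "loss_breakdown")
}

#' Pseudo-stream weight schedule
#'
#' Sigmoid ramp of the pseudo-supervision weight lambda from ~0 to
#' `lambda_max` over the first `ramp_fraction` of training, constant
#' afterwards: `lambda(i) = lambda_max * exp(-5 (1 - i / ramp_len)^2)` during
#' the ramp. This is the ramp shape customary in mean-teacher style training;
#' the weight itself is otherwise unconstrained.
#'
#' @param i current iteration (0-based).
#' @param iters total iterations (> 0).
#' @param lambda_max plateau value.
#' @param ramp_fraction fraction of training spent ramping.
#' @return scalar lambda in [0, lambda_max].
#' @export
lambda_schedule <- function(i, iters, lambda_max = 1.0, ramp_fraction = 0.1) {
  if (iters <= 0) stop("iters must be > 0")
  ramp_len <- max(1, ramp_fraction * iters)
  if (i >= ramp_len) return(lambda_max)
  phase <- 1 - i / ramp_len
  lambda_max * exp(-5 * phase^2)
}

# gradient of seg_loss wrt the output LOGIT z (p = sigmoid(z)), per-image
# then averaged over the batch. Composing through the sigmoid analytically
# keeps the cross-entropy term exact ((p - g)/N) even when p saturates:
# d(dice)/dz_i = -(2 g_i (Sp+Sg+s) - (2 Spg + s)) / (Sp+Sg+s)^2 * p(1-p)
# d(bce)/dz_i  = (p_i - g_i) / N
seg_loss_grad <- function(p, g, smooth = 1) {
  p <- as_prob_array(p); g <- as_target_array(g, dim(p))
  nb <- dim(p)[3]
  np <- prod(dim(p)[1:2])
  out <- array(0, dim(p))
  for (i in seq_len(nb)) {
    pi <- p[, , i]; gi <- g[, , i]
    den <- sum(pi) + sum(gi) + smooth
    num <- 2 * sum(pi * gi) + smooth
    ddice <- -(2 * gi * den - num) / den^2 * pi * (1 - pi)
    dbce <- (pi - gi) / np
    out[, , i] <- 0.5 * (ddice + dbce) / nb
  }
  out
}
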