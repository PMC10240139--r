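#' Loss weighting for multi-task training
#'
#' The training objective is `alpha * L_rec + L_seg` where
#' `L_seg = beta * L_primary + (1 - beta) * (L_aux1 + L_aux2 + L_aux3)`:
#' `alpha` scales the unsupervised reconstruction term, `beta` trades the
#' primary lesion's dice loss against the summed auxiliary dice losses.
#'
#' @param alpha Non-negative reconstruction weight (default 1).
#' @param beta Primary-task weight in `[0,1]` (default 0.7: the primary
#'   dominates, auxiliaries still contribute).
#' @param epsilon Small positive dice smoothing constant (default 1e-6),
#'   applied to numerator and denominator so empty prediction/target pairs
#'   give loss 0.
#' @return An object of class `"loss_weights"`.
#' @export
loss_weights <- function(alpha = 1, beta = 0.7, epsilon = 1e-6) {
  stopifnot(alpha >= 0, beta >= 0, beta <= 1, epsilon > 0)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "loss_weights")
}

#' Mean-squared-error reconstruction loss
#'
#' Mean over batch, channels and pixels of the squared difference between the
#' input image(s) and the reconstruction, so the loss (and its weight `alpha`)
#' is independent of image resolution and batch size.
#'
#' @param x Input image array or batch, values in `[0,1]`.
#' @param xhat Reconstruction of the same shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, xhat) {
  if (!identical(dim(x), dim(xhat))) stop("reconstruction_loss: shape mismatch")
  mean((x - xhat)^2)
}

# dL/dxhat for the MSE above.
reconstruction_loss_grad <- function(x, xhat) 2 * (xhat - x) / length(x)

#' Soft dice loss
#'
#' `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)` with
#' `p = sigmoid(logits)`.  The denominator is the sum of the two masses (not a
#' literal set union), which is what makes the dice of two identical nonempty
#' masks equal 1.  Differentiable everywhere in the logits.
#'
#' @param logits Pre-sigmoid prediction array.
#' @param gt Binary ground-truth array of the same shape.
#' @param epsilon Smoothing constant (see [loss_weights()]).
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(logits, gt, epsilon = 1e-6) {
  dice_loss_pair(logits, gt, epsilon)$loss
}

# Loss plus gradient w.r.t. logits, shared by dice_loss() and the trainer.
dice_loss_pair <- function(logits, gt, epsilon = 1e-6) {
  if (!identical(dim(logits), dim(gt)) &&
      !identical(length(logits), length(gt)))
    stop("dice_loss: shape mismatch")
  p <- sigmoid(logits)
  num <- 2 * sum(p * gt) + epsilon
  den <- sum(p) + sum(gt) + epsilon
  dl_dp <- -(2 * gt * den - num) / den^2
  list(loss = 1 - num / den, dlogits = dl_dp * p * (1 - p))
}

#' Combined segmentation loss over the four lesion tasks
#'
#' `beta * L_primary + (1 - beta) * sum(L_auxiliary)`.
#'
#' @param task_losses Named numeric vector (or list) of per-task dice losses;
#'   names identify the lesions.
#' @param primary Name of the primary task (must appear in `task_losses`).
#' @param beta Primary weight in `[0,1]`.
#' @return Scalar.
#' @export
segmentation_loss <- function(task_losses, primary, beta) {
  task_losses <- unlist(task_losses)
  if (!primary %in% names(task_losses))
    stop("unknown primary task: ", primary)
  beta * task_losses[[primary]] +
    (1 - beta) * sum(task_losses[setdiff(names(task_losses), primary)])
}

#' Total multi-task loss
#'
#' `alpha * rec_loss + seg_loss`.
#'
#' @param rec_loss Reconstruction loss (non-negative scalar).
#' @param seg_loss Combined segmentation loss (non-negative scalar).
#' @param alpha Reconstruction weight.
#' @return Scalar.
#' @export
total_loss <- function(rec_loss, seg_loss, alpha) {
  stopifnot(rec_loss >= 0, seg_loss >= 0)
  alpha * rec_loss + seg_loss
}
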