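#' Fit a semi-supervised multi-decoder U-Net for one primary lesion
#'
#' The top-level modelling interface.  Training runs in two phases: if an
#' unlabeled pool is supplied (and `epochs_unsup > 0`), the shared encoder
#' and the reconstruction decoder are first pre-trained to reconstruct the
#' input images; the supervised phase then minimizes
#' `alpha * L_rec + beta * L_primary + (1 - beta) * sum(L_aux)` over the
#' labeled pool, with the lesion named in `primary` as the primary task and
#' the remaining lesions as auxiliary regularizers of the shared encoder.
#' The returned fit keeps the parameters with the best validation dice.
#'
#' @param labeled Labeled data: a `"fundus_pool"` or `"dataset_manifest"`
#'   with `train` (and ideally `val`) splits.
#' @param unlabeled Optional unlabeled pool/manifest for pre-training.
#' @param primary Primary lesion (`"MA"`, `"HE"`, `"EX"`, `"SE"`).
#' @param net_cfg A [network_config()].
#' @param cfg A [train_config()]; its `primary` is overridden by the
#'   `primary` argument.
#' @param seed Seed for parameter initialization.
#' @return An object of class `"mdunet"` with components `net` (best
#'   validation parameters), `final_net`, `primary`, `history`,
#'   `best_val_dsc`, `best_epoch`, `pretrained`, `net_cfg`, `cfg`, `call`.
#' @seealso [predict.mdunet()], [evaluate_model()], [train_all_primaries()]
#' @examples
#' syn <- synthetic_config(image_size = 64, n_labeled = 6, n_unlabeled = 4,
#'                         seed = 7)
#' labeled <- split_pool(generate_pool(syn, 6, 0), c(0.7, 0.3, 0), seed = 1)
#' unlabeled <- generate_pool(synthetic_config(image_size = 64, seed = 8), 0, 4)
#' fit <- mdunet_fit(labeled, unlabeled, primary = "EX",
#'                   net_cfg = network_config(depth = 2, base_channels = 2),
#'                   cfg = train_config(batch_size = 4, learning_rate = 0.05,
#'                                      epochs_unsup = 1, epochs_sup = 2))
#' fit
#' @export
mdunet_fit <- function(labeled, unlabeled = NULL, primary = "EX",
                       net_cfg = network_config(), cfg = train_config(),
                       seed = 1L) {
  cl <- match.call()
  cfg$primary <- primary
  if (inherits(labeled, "dataset_manifest"))
    labeled <- load_pool(labeled, c("train", "val"))
  if (inherits(unlabeled, "dataset_manifest"))
    unlabeled <- load_pool(unlabeled, "unlabeled")
  net <- build_network(net_cfg, seed)
  pretrained <- FALSE
  state <- net
  if (!is.null(unlabeled) && cfg$epochs_unsup > 0L && net_cfg$recon_decoder) {
    state <- pretrain_reconstruction(net, unlabeled, cfg)
    pretrained <- TRUE
  }
  ts <- train_supervised(state, labeled, cfg)
  structure(list(net = ts$best_net %||% ts$net, final_net = ts$net,
                 primary = primary, history = ts$history,
                 best_val_dsc = ts$best_val_dsc, best_epoch = ts$best_epoch,
                 pretrained = pretrained, net_cfg = net_cfg, cfg = cfg,
                 call = cl),
            class = "mdunet")
}

#' @export
print.mdunet <- function(x, ...) {
  cat("Semi-supervised multi-decoder U-Net fit\n")
  cat("  primary task:", x$primary,
      " (auxiliary:", paste(setdiff(x$net_cfg$seg_decoders, x$primary),
                            collapse = ", "), ")\n")
  cat("  pre-trained on unlabeled data:", x$pretrained, "\n")
  cat("  best validation DSC:",
      if (is.na(x$best_val_dsc)) "n/a" else sprintf("%.4f", x$best_val_dsc),
      "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' @export
summary.mdunet <- function(object, ...) {
  h <- object$history
  sup <- h[h$phase == "sup", ]
  uns <- h[h$phase == "unsup", ]
  s <- list(
    primary = object$primary,
    pretrained = object$pretrained,
    best_val_dsc = object$best_val_dsc,
    best_epoch = object$best_epoch,
    n_params = param_count(object$net),
    unsup = if (nrow(uns)) c(first_epoch_L_rec = mean(uns$L_rec[uns$epoch == min(uns$epoch)]),
                             last_epoch_L_rec = mean(uns$L_rec[uns$epoch == max(uns$epoch)])),
    sup = if (nrow(sup)) c(first_epoch_L_seg = mean(sup$L_seg[sup$epoch == min(sup$epoch)]),
                           last_epoch_L_seg = mean(sup$L_seg[sup$epoch == max(sup$epoch)]))
  )
  class(s) <- "summary.mdunet"
  s
}

#' @export
print.summary.mdunet <- function(x, ...) {
  cat("mdunet fit: primary", x$primary, "| pretrained:", x$pretrained,
      "|", format(x$n_params, big.mark = ","), "parameters\n")
  if (!is.null(x$unsup))
    cat(sprintf("  unsupervised L_rec: %.5f (first epoch) -> %.5f (last)\n",
                x$unsup[1], x$unsup[2]))
  if (!is.null(x$sup))
    cat(sprintf("  supervised  L_seg: %.4f (first epoch) -> %.4f (last)\n",
                x$sup[1], x$sup[2]))
  cat(sprintf("  best validation DSC: %.4f (epoch %d)\n",
              x$best_val_dsc, x$best_epoch))
  invisible(x)
}

#' Predict lesion probability maps
#'
#' @param object An `"mdunet"` fit.
#' @param newdata An `(H, W, 3)` image array, a list of such arrays, or a
#'   `"fundus_pool"`.
#' @param type `"prob"` (sigmoid probability maps), `"mask"` (thresholded
#'   binary masks), or `"recon"` (the reconstruction decoder's output).
#' @param lesions Which decoders to run (default: all segmentation decoders).
#' @param threshold Threshold for `type = "mask"`.
#' @param ... Unused.
#' @return For a single image, a named list of `(H, W)` maps (or the
#'   reconstruction array); for multiple images, a list of such results.
#' @export
predict.mdunet <- function(object, newdata, type = c("prob", "mask", "recon"),
                           lesions = NULL, threshold = 0.5, ...) {
  type <- match.arg(type)
  net <- object$net
  imgs <- if (inherits(newdata, "fundus_pool")) newdata$images
          else if (is.list(newdata)) newdata
          else list(newdata)
  lesions <- lesions %||% net$config$seg_decoders
  one <- function(img) {
    if (type == "recon") {
      fw <- net_forward(net, stack_images(list(img)), heads = "recon")
      return(fw$recon[, , , 1])
    }
    fw <- net_forward(net, stack_images(list(img)), heads = lesions)
    out <- lapply(fw$seg_logits, function(z) sigmoid(z[, , 1, 1]))
    if (type == "mask") out <- lapply(out, function(p) (p > threshold) * 1)
    out
  }
  res <- lapply(imgs, one)
  if (length(res) == 1L) res[[1]] else res
}

#' @export
coef.mdunet <- function(object, ...) object$net$params

#' Plot training curves of a fit
#'
#' Shows the per-step total loss of both phases and, for the supervised
#' phase, the primary task's dice loss.
#'
#' @param x An `"mdunet"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mdunet <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no training history"); return(invisible(x)) }
  graphics::plot(seq_len(nrow(h)), h$total, type = "l", col = "grey30",
                 xlab = "step", ylab = "loss",
                 main = paste("Training curves (primary:", x$primary, ")"), ...)
  pc <- paste0("L_", x$primary)
  sup <- which(h$phase == "sup")
  if (length(sup))
    graphics::lines(sup, h[[pc]][sup], col = "firebrick")
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("grey30", "firebrick"),
                   legend = c("total loss", paste0("dice loss (", x$primary, ")")))
  invisible(x)
}

#' Write the per-step loss table of a fit or train state as CSV
#'
#' Source data for learning-curve figures: columns `phase`, `epoch`, `step`,
#' `L_rec`, `L_MA`, `L_HE`, `L_EX`, `L_SE`, `L_seg`, `total`.
#'
#' @param x An `"mdunet"` fit or `"mdunet_train_state"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_log <- function(x, path) {
  h <- if (inherits(x, "mdunet")) x$history else x$history
  write.csv(h, path, row.names = FALSE)
  invisible(path)
}
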