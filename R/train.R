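#' Training configuration
#'
#' Defaults mirror the reference training recipe for real fundus data
#' (plain SGD, learning rate 1e-4, batch size 16); desk-scale synthetic runs
#' use the smaller presets from [default_benchmark()].
#'
#' @param batch_size Images per SGD step (default 16).  The final incomplete
#'   batch of an epoch is dropped in training (kept in evaluation), unless it
#'   is the only batch.
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param momentum Classical momentum (default 0 = plain SGD).
#' @param epochs_unsup Epochs of unsupervised reconstruction pre-training.
#' @param epochs_sup Epochs of supervised multi-task training.
#' @param weights A [loss_weights()] (alpha, beta, dice epsilon).
#' @param primary Primary lesion task, one of `"MA"`, `"HE"`, `"EX"`, `"SE"`.
#' @param seed Integer seed driving batch shuffling.
#' @param supervised_recon Keep the `alpha * L_rec` reconstruction term (and
#'   reconstruction-decoder updates) during the supervised phase (default
#'   `TRUE`; `FALSE` updates only encoder + segmentation decoders).
#' @param verbose Print per-epoch losses.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-4, momentum = 0,
                         epochs_unsup = 20L, epochs_sup = 50L,
                         weights = loss_weights(), primary = "EX",
                         seed = 1L, supervised_recon = TRUE, verbose = FALSE) {
  stopifnot(batch_size >= 1, learning_rate > 0, momentum >= 0, momentum < 1,
            epochs_unsup >= 0, epochs_sup >= 0,
            inherits(weights, "loss_weights"), primary %in% LESIONS)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs_unsup = as.integer(epochs_unsup),
                 epochs_sup = as.integer(epochs_sup),
                 weights = weights, primary = primary, seed = as.integer(seed),
                 supervised_recon = isTRUE(supervised_recon),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

stack_images <- function(lst) {
  d <- dim(lst[[1]])
  x <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) x[, , , i] <- lst[[i]]
  x
}

stack_masks <- function(lst) {
  d <- dim(lst[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(lst)))
  for (i in seq_along(lst)) x[, , 1L, i] <- lst[[i]]
  x
}

# Batch index list for one epoch: seeded shuffle upstream; drops the final
# incomplete batch when there is more than one batch.
epoch_batches <- function(n, batch_size, shuffle = TRUE) {
  perm <- if (shuffle) sample.int(n) else seq_len(n)
  nb <- n %/% batch_size
  if (nb == 0L) return(list(perm))
  lapply(seq_len(nb), function(b) perm[(b - 1L) * batch_size + seq_len(batch_size)])
}

empty_history <- function() {
  data.frame(phase = character(), epoch = integer(), step = integer(),
             L_rec = numeric(), L_MA = numeric(), L_HE = numeric(),
             L_EX = numeric(), L_SE = numeric(), L_seg = numeric(),
             total = numeric())
}

history_row <- function(phase, epoch, step, L_rec = NA, task = NULL,
                        L_seg = NA, total = NA) {
  r <- data.frame(phase = phase, epoch = epoch, step = step, L_rec = L_rec,
                  L_MA = NA_real_, L_HE = NA_real_, L_EX = NA_real_,
                  L_SE = NA_real_, L_seg = L_seg, total = total)
  for (L in names(task)) r[[paste0("L_", L)]] <- task[[L]]
  r
}

new_train_state <- function(net, history) {
  structure(list(net = net, history = history), class = "mdunet_train_state")
}

#' Unsupervised reconstruction pre-training
#'
#' Optimizes only the mean-squared reconstruction error over the unlabeled
#' pool, updating the shared encoder and the reconstruction decoder.
#' Segmentation decoders are never executed, so their parameters (and
#' batch-norm buffers) are bit-identical before and after.
#'
#' @param net An `"mdunet_net"` with a reconstruction decoder.
#' @param pool A `"fundus_pool"` (images only are used).
#' @param cfg A [train_config()] (`epochs_unsup`, `learning_rate`,
#'   `batch_size`, `seed`).
#' @return An `"mdunet_train_state"`: list with `net` (updated network) and
#'   `history` (per-step loss table).
#' @export
pretrain_reconstruction <- function(net, pool, cfg = train_config()) {
  stopifnot(inherits(net, "mdunet_net"), inherits(pool, "fundus_pool"))
  if (!net$config$recon_decoder)
    stop("network has no reconstruction decoder")
  n <- pool_size(pool)
  if (n < 1) stop("unlabeled pool is empty")
  history <- empty_history()
  if (cfg$epochs_unsup == 0L) return(new_train_state(net, history))
  vel <- list(); step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs_unsup)) {
      ep_losses <- c()
      for (idx in epoch_batches(n, cfg$batch_size)) {
        x <- stack_images(pool$images[idx])
        fw <- net_forward(net, x, heads = "recon", training = TRUE)
        loss <- reconstruction_loss(x, fw$recon)
        if (!is.finite(loss)) stop("NaN/Inf reconstruction loss at step ", step)
        grads <- net_backward(fw$state, list(seg = list(),
                                             recon = reconstruction_loss_grad(x, fw$recon)))
        net$buffers <- fw$state$bf
        up <- sgd_step(net, grads, cfg$learning_rate, cfg$momentum, vel)
        net <- up$net; vel <- up$vel
        step <- step + 1L
        ep_losses <- c(ep_losses, loss)
        history <- rbind(history, history_row("unsup", ep, step, L_rec = loss,
                                              total = loss))
      }
      if (cfg$verbose)
        cat(sprintf("[unsup] epoch %d  L_rec %.5f\n", ep, mean(ep_losses)))
    }
  })
  new_train_state(net, history)
}

# Mean primary-lesion dice over a pool split, in evaluation mode.
val_primary_dsc <- function(net, pool, primary, threshold = 0.5) {
  idx <- which(pool$split == "val" & pool$labeled)
  if (!length(idx)) idx <- which(pool$labeled)
  scores <- vapply(idx, function(i) {
    fw <- net_forward(net, stack_images(pool$images[i]), heads = primary)
    p <- sigmoid(fw$seg_logits[[primary]][, , 1, 1])
    dice_score((p > threshold) * 1, pool$masks[[i]][[primary]])
  }, 0)
  mean(scores)
}

#' Supervised multi-task training
#'
#' Each step computes the four per-lesion dice losses, combines them as
#' `beta * L_primary + (1 - beta) * sum(L_aux)`, optionally adds
#' `alpha * L_rec`, and applies one SGD update to the encoder and the
#' segmentation decoders (plus the reconstruction decoder iff
#' `supervised_recon`).  After every epoch the primary lesion's dice is
#' evaluated on the pool's `val` split and the best-validation parameters are
#' retained.
#'
#' @param net An `"mdunet_net"` or an `"mdunet_train_state"` from
#'   [pretrain_reconstruction()].
#' @param pool A labeled `"fundus_pool"`; its `split` column selects the
#'   training (`"train"`) and validation (`"val"`) samples.  A pool without a
#'   `val` split trains on everything and validates on the training samples.
#' @param cfg A [train_config()].
#' @return An `"mdunet_train_state"` with `net` (final parameters),
#'   `best_net` (best-validation parameters), `best_val_dsc`, `best_epoch`,
#'   and `history`.
#' @export
train_supervised <- function(net, pool, cfg = train_config()) {
  if (inherits(net, "mdunet_train_state")) {
    prev <- net$history; net <- net$net
  } else prev <- empty_history()
  stopifnot(inherits(net, "mdunet_net"), inherits(pool, "fundus_pool"))
  heads <- net$config$seg_decoders
  if (!cfg$primary %in% heads)
    stop("primary task ", cfg$primary, " has no decoder in this network")
  tr <- which(pool$split == "train")
  if (!length(tr)) tr <- which(pool$labeled)
  if (!length(tr)) stop("no labeled training samples")
  if (!all(pool$labeled[tr])) stop("training split contains unlabeled entries")
  w <- cfg$weights
  use_recon <- cfg$supervised_recon && net$config$recon_decoder
  run_heads <- c(heads, if (use_recon) "recon")
  aux <- setdiff(heads, cfg$primary)
  history <- prev
  # best-checkpoint tracking starts at the initialization (epoch 0), so a
  # run that never improves on validation returns its starting parameters
  best_net <- net; best_dsc <- val_primary_dsc(net, pool, cfg$primary)
  best_epoch <- 0L
  vel <- list(); step <- 0L
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs_sup)) {
      for (idx in epoch_batches(length(tr), cfg$batch_size)) {
        ii <- tr[idx]
        x <- stack_images(pool$images[ii])
        fw <- net_forward(net, x, heads = run_heads, training = TRUE)
        task <- list(); douts <- list(seg = list(), recon = NULL)
        for (h in heads) {
          gt <- stack_masks(lapply(pool$masks[ii], `[[`, h))
          dl <- dice_loss_pair(fw$seg_logits[[h]], gt, w$epsilon)
          task[[h]] <- dl$loss
          wt <- if (h == cfg$primary) w$beta else 1 - w$beta
          douts$seg[[h]] <- wt * dl$dlogits
        }
        L_seg <- segmentation_loss(task, cfg$primary, w$beta)
        L_rec <- NA_real_
        if (use_recon) {
          L_rec <- reconstruction_loss(x, fw$recon)
          douts$recon <- w$alpha * reconstruction_loss_grad(x, fw$recon)
        }
        tot <- total_loss(if (use_recon) L_rec else 0, L_seg, w$alpha)
        if (!is.finite(tot)) stop("NaN/Inf loss at supervised step ", step)
        grads <- net_backward(fw$state, douts)
        net$buffers <- fw$state$bf
        up <- sgd_step(net, grads, cfg$learning_rate, cfg$momentum, vel)
        net <- up$net; vel <- up$vel
        step <- step + 1L
        history <- rbind(history, history_row("sup", ep, step, L_rec = L_rec,
                                              task = task, L_seg = L_seg,
                                              total = tot))
      }
      vd <- val_primary_dsc(net, pool, cfg$primary)
      if (vd > best_dsc) { best_dsc <- vd; best_net <- net; best_epoch <- ep }
      if (cfg$verbose)
        cat(sprintf("[sup] epoch %d  L_seg %.4f  val DSC(%s) %.4f\n", ep,
                    mean(history$L_seg[history$phase == "sup" &
                                         history$epoch == ep], na.rm = TRUE),
                    cfg$primary, vd))
    }
  })
  out <- new_train_state(net, history)
  out$best_net <- best_net
  out$best_val_dsc <- if (is.finite(best_dsc)) best_dsc else NA_real_
  out$best_epoch <- best_epoch
  out
}

#' Train one model per lesion from a shared pre-trained snapshot
#'
#' Runs reconstruction pre-training once, then four supervised runs that all
#' start from the identical pre-trained parameters, each with a different
#' primary lesion (the other three act as auxiliary tasks).
#'
#' @param labeled Labeled `"fundus_pool"` (with train/val splits).
#' @param unlabeled Unlabeled `"fundus_pool"` (or `NULL` to skip
#'   pre-training).
#' @param cfg A [train_config()]; its `primary` is ignored and replaced per
#'   run.
#' @param net_cfg A [network_config()] with all four segmentation decoders.
#' @param seed Seed for network initialization.
#' @return An `"mdunet_registry"`: named list (MA, HE, EX, SE) of
#'   `"mdunet_train_state"` objects, with the shared pre-trained snapshot in
#'   `attr(, "pretrained_net")`.
#' @export
train_all_primaries <- function(labeled, unlabeled, cfg = train_config(),
                                net_cfg = network_config(), seed = 1L) {
  stopifnot(setequal(net_cfg$seg_decoders, LESIONS))
  net <- build_network(net_cfg, seed)
  if (!is.null(unlabeled) && cfg$epochs_unsup > 0L)
    net <- pretrain_reconstruction(net, unlabeled, cfg)$net
  snapshot <- net
  runs <- sapply(LESIONS, function(L) {
    cfg$primary <- L
    train_supervised(snapshot, labeled, cfg)
  }, simplify = FALSE)
  structure(runs, class = "mdunet_registry", pretrained_net = snapshot)
}
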