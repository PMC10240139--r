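#' Dice similarity coefficient of two binary masks
#'
#' `2 |pred & gt| / (|pred| + |gt|)`; the degenerate empty/empty case is
#' defined as 1 (perfect agreement).  Symmetric in its arguments.
#'
#' @param pred,gt Binary arrays/matrices of equal shape.
#' @return Scalar in `[0,1]`.
#' @export
dice_score <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("dice_score: shape mismatch")
  sp <- sum(pred); sg <- sum(gt)
  if (sp + sg == 0) return(1)
  2 * sum(pred * gt) / (sp + sg)
}

#' Mean absolute error between a probability map and ground truth
#'
#' `(1 / (w*h)) * sum(|S_p - G|)` over all pixels.
#'
#' @param s_p Probability raster in `[0,1]`.
#' @param g Binary ground-truth raster of the same shape.
#' @return Scalar in `[0,1]`.
#' @export
mae <- function(s_p, g) {
  if (!identical(dim(s_p), dim(g))) stop("mae: shape mismatch")
  mean(abs(s_p - g))
}

#' Pixel sensitivity (recall) of a binary prediction
#'
#' `|pred & gt| / |gt|`.  Undefined for an empty ground truth: returns `NA`
#' with a warning, and aggregation excludes such images.
#'
#' @param pred,gt Binary arrays of equal shape.
#' @return Scalar in `[0,1]`, or `NA` when `gt` is empty.
#' @export
sensitivity <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("sensitivity: shape mismatch")
  if (sum(gt) == 0) {
    warning("sensitivity undefined for empty ground truth", call. = FALSE)
    return(NA_real_)
  }
  sum(pred * gt) / sum(gt)
}

#' Area under the ROC curve of pixel scores
#'
#' Rank (Mann-Whitney) formulation with ties averaged: the probability that a
#' random positive pixel outranks a random negative one.
#'
#' @param scores Numeric vector/array of pixel scores.
#' @param labels Binary vector/array of the same length.
#' @return Scalar in `[0,1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
auc_roc <- function(scores, labels) {
  scores <- as.vector(scores); labels <- as.vector(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC-ROC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve of pixel scores
#'
#' Interpolation-free step summation: thresholds sweep the distinct scores in
#' decreasing order (tied scores enter together) and each step contributes
#' `precision * delta_recall`.
#'
#' @inheritParams auc_roc
#' @return Scalar in `(0,1]`, or `NA` with a warning when no positives are
#'   present.
#' @export
auc_pr <- function(scores, labels) {
  scores <- as.vector(scores); labels <- as.vector(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels)) {
    warning("AUC-PR undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

model_net <- function(model) {
  if (inherits(model, "mdunet")) return(model$net)
  if (inherits(model, "mdunet_train_state"))
    return(model$best_net %||% model$net)
  if (inherits(model, "mdunet_net")) return(model)
  stop("not a model object")
}

#' Evaluate a model on a labeled pool
#'
#' Sigmoid probability maps are computed for every segmentation decoder;
#' dice, sensitivity (threshold at `threshold`) and MAE are computed per
#' image and averaged (images with empty ground truth are excluded from the
#' sensitivity mean), while AUC-ROC and AUC-PR pool all pixels of the
#' evaluation set so class prevalence is represented.
#'
#' @param model An `"mdunet"` fit, `"mdunet_train_state"`, or `"mdunet_net"`.
#' @param pool A labeled `"fundus_pool"` (or `"dataset_manifest"`).
#' @param split Optional split filter applied to the pool (e.g. `"test"`).
#' @param threshold Binarization threshold for dice/sensitivity (default 0.5).
#' @param dice_pooling `"image"` (per-image average, default) or `"pixel"`
#'   (pool all pixels into one dice).
#' @return A `"metrics_report"`: list with `per_lesion` (data frame of dsc,
#'   auc_roc, auc_pr, mae, sensitivity per lesion), `n_images`, `threshold`,
#'   `dice_pooling`.
#' @export
evaluate_model <- function(model, pool, split = NULL, threshold = 0.5,
                           dice_pooling = c("image", "pixel")) {
  dice_pooling <- match.arg(dice_pooling)
  net <- model_net(model)
  if (inherits(pool, "dataset_manifest")) pool <- load_pool(pool, split)
  else if (!is.null(split)) pool <- pool_subset(pool, pool$split %in% split)
  idx <- which(pool$labeled)
  if (!length(idx)) stop("no labeled samples to evaluate")
  heads <- net$config$seg_decoders
  acc <- sapply(heads, function(h)
    list(dsc = c(), sen = c(), mae = c(), sc = list(), lb = list()),
    simplify = FALSE)
  for (i in idx) {
    fw <- net_forward(net, stack_images(pool$images[i]), heads = heads)
    for (h in heads) {
      p <- sigmoid(fw$seg_logits[[h]][, , 1, 1])
      gt <- pool$masks[[i]][[h]]
      pm <- (p > threshold) * 1
      acc[[h]]$dsc <- c(acc[[h]]$dsc, dice_score(pm, gt))
      acc[[h]]$sen <- c(acc[[h]]$sen,
                        if (sum(gt) > 0) sensitivity(pm, gt) else NA_real_)
      acc[[h]]$mae <- c(acc[[h]]$mae, mae(p, gt))
      acc[[h]]$sc[[length(acc[[h]]$sc) + 1L]] <- as.vector(p)
      acc[[h]]$lb[[length(acc[[h]]$lb) + 1L]] <- as.vector(gt)
    }
  }
  per <- do.call(rbind, lapply(heads, function(h) {
    sc <- unlist(acc[[h]]$sc); lb <- unlist(acc[[h]]$lb)
    dsc <- if (dice_pooling == "image") mean(acc[[h]]$dsc)
           else dice_score((sc > threshold) * 1, lb)
    data.frame(lesion = h, dsc = dsc,
               auc_roc = auc_roc(sc, lb), auc_pr = auc_pr(sc, lb),
               mae = mean(acc[[h]]$mae),
               sensitivity = mean(acc[[h]]$sen, na.rm = TRUE))
  }))
  structure(list(per_lesion = per, n_images = length(idx),
                 threshold = threshold, dice_pooling = dice_pooling),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (", x$n_images, " images, threshold ",
      x$threshold, ", dice pooling: ", x$dice_pooling, ")\n", sep = "")
  print(x$per_lesion, row.names = FALSE, digits = 4)
  invisible(x)
}
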