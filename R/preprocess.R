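#' Preprocessing configuration
#'
#' @param crop_threshold Intensity in `[0,1]` below which a pixel (max over
#'   channels) counts as blank border / outside the retinal field-of-view
#'   (default 0.02: fundus borders are near-black in all channels).
#' @param target_size Output side length in pixels (default 512); must be at
#'   least 32 and divisible by `2^(depth-1)` of the paired network.
#' @param equalize Apply per-channel global histogram equalization restricted
#'   to the field-of-view (default `TRUE`).
#' @param pad_value Intensity used for the padding that squares the image
#'   (default 0).
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(crop_threshold = 0.02, target_size = 512L,
                              equalize = TRUE, pad_value = 0) {
  stopifnot(crop_threshold >= 0, crop_threshold < 1, target_size >= 32,
            pad_value >= 0, pad_value <= 1)
  structure(list(crop_threshold = crop_threshold,
                 target_size = as.integer(target_size),
                 equalize = isTRUE(equalize), pad_value = pad_value),
            class = "preprocess_config")
}

max_channel <- function(img) {
  if (length(dim(img)) == 2L) img else pmax(img[, , 1], img[, , 2], img[, , 3])
}

#' Crop blank borders from a fundus photograph
#'
#' Finds the tight bounding box of pixels whose maximum channel intensity
#' exceeds `threshold` and crops to it.  The crop box is returned so the same
#' crop can be applied to the masks.
#'
#' @param img `(H, W, 3)` array in `[0,1]`.
#' @param threshold Blank-border intensity threshold.
#' @return A list with `image` (cropped array) and `box`
#'   (`c(row1, row2, col1, col2)`, 1-based inclusive).
#' @export
crop_blank_borders <- function(img, threshold = 0.02) {
  mc <- max_channel(img)
  rows <- which(apply(mc > threshold, 1, any))
  cols <- which(apply(mc > threshold, 2, any))
  if (!length(rows))
    stop("image is entirely blank at threshold ", threshold)
  box <- c(min(rows), max(rows), min(cols), max(cols))
  list(image = img[box[1]:box[2], box[3]:box[4], , drop = FALSE], box = box)
}

crop_to_box <- function(x, box) {
  if (length(dim(x)) == 2L) x[box[1]:box[2], box[3]:box[4], drop = FALSE]
  else x[box[1]:box[2], box[3]:box[4], , drop = FALSE]
}

#' Global histogram equalization inside the retinal field
#'
#' Each channel's 256-bin histogram is computed over field-of-view pixels
#' (max-channel intensity above `fov_threshold`), and the standard CDF mapping
#' `(cdf(v) - cdf_min) / (1 - cdf_min)` is applied to the whole channel.
#' A constant channel is returned unchanged.
#'
#' @param img `(H, W, 3)` array in `[0,1]`.
#' @param fov_threshold Field-of-view threshold (same convention as
#'   [crop_blank_borders()]).
#' @param nbins Number of histogram bins (default 256).
#' @return Equalized array in `[0,1]`.
#' @export
equalize_histogram <- function(img, fov_threshold = 0.02, nbins = 256L) {
  stopifnot(min(img) >= 0, max(img) <= 1)
  fov <- max_channel(img) > fov_threshold
  if (!any(fov)) return(img)
  out <- img
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    bins <- pmin(floor(ch * nbins), nbins - 1L) + 1L
    counts <- tabulate(bins[fov], nbins)
    if (sum(counts > 0) <= 1L) next   # degenerate histogram: leave unchanged
    cdf <- cumsum(counts) / sum(counts)
    cdf_min <- cdf[which(counts > 0)[1]]
    mapped <- (cdf[bins] - cdf_min) / (1 - cdf_min)
    out[, , c] <- pmin(pmax(matrix(mapped, nrow(ch), ncol(ch)), 0), 1)
  }
  out
}

resize_nearest <- function(x, outH, outW) {
  ri <- pmin(pmax(floor((seq_len(outH) - 0.5) * nrow(x) / outH) + 1L, 1L), nrow(x))
  ci <- pmin(pmax(floor((seq_len(outW) - 0.5) * ncol(x) / outW) + 1L, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' Aspect-preserving bicubic resize and padding to a square target
#'
#' The image is scaled with bicubic (Catmull-Rom) interpolation so its longer
#' side equals `target_size`, then padded symmetrically with `pad_value` to
#' `target_size x target_size`.  Masks undergo the identical geometry with
#' nearest-neighbor sampling and re-binarization, so they stay strictly
#' binary and aligned with the image.
#'
#' @param img `(H, W, 3)` array in `[0,1]`.
#' @param masks Optional named list of binary `(H, W)` matrices.
#' @param cfg A [preprocess_config()].
#' @return A list with `image` (`target x target x 3`, clipped to `[0,1]`) and
#'   `masks` (resized list or `NULL`).
#' @export
resize_to_target <- function(img, masks = NULL, cfg = preprocess_config()) {
  H <- dim(img)[1]; W <- dim(img)[2]; S <- cfg$target_size
  if (H >= W) { newH <- S; newW <- max(1L, as.integer(round(W * S / H))) }
  else        { newW <- S; newH <- max(1L, as.integer(round(H * S / W))) }
  im <- pmin(pmax(cpp_resize_bicubic(img, newH, newW), 0), 1)
  top <- (S - newH) %/% 2L; left <- (S - newW) %/% 2L
  out <- array(cfg$pad_value, c(S, S, dim(img)[3]))
  out[top + seq_len(newH), left + seq_len(newW), ] <- im
  rmasks <- NULL
  if (!is.null(masks)) {
    rmasks <- lapply(masks, function(m) {
      mm <- matrix(0, S, S)
      mm[top + seq_len(newH), left + seq_len(newW)] <-
        (resize_nearest(m, newH, newW) > 0.5) * 1
      mm
    })
  }
  list(image = out, masks = rmasks)
}

#' Full preprocessing pipeline
#'
#' Composition crop -> histogram equalization -> bicubic resize/pad ->
#' per-image min-max normalization to `[0,1]`.  Masks receive the crop and the
#' resize only (geometry, never intensity transforms).
#'
#' @param img `(H, W, 3)` array in `[0,1]`.
#' @param masks Optional named list of binary masks aligned with `img`.
#' @param cfg A [preprocess_config()].
#' @return A list with `image`, `masks` (or `NULL`), and `crop_box`.
#' @export
preprocess <- function(img, masks = NULL, cfg = preprocess_config()) {
  cr <- crop_blank_borders(img, cfg$crop_threshold)
  img <- cr$image
  if (!is.null(masks)) masks <- lapply(masks, crop_to_box, box = cr$box)
  if (cfg$equalize) img <- equalize_histogram(img, cfg$crop_threshold)
  rs <- resize_to_target(img, masks, cfg)
  img <- rs$image
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  list(image = img, masks = rs$masks, crop_box = cr$box)
}

#' Preprocess every image referenced by a manifest
#'
#' Writes processed images (and masks, where present) under `out_dir` and
#' returns a manifest pointing at the processed files.
#'
#' @param m A `"dataset_manifest"`.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [preprocess_config()].
#' @return The new `"dataset_manifest"`.
#' @export
preprocess_manifest <- function(m, out_dir, cfg = preprocess_config()) {
  validate_manifest(m)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- m
  for (i in seq_len(nrow(m))) {
    img <- load_image(m$image_path[i])
    masks <- NULL
    if (m$labeled[i])
      masks <- sapply(LESIONS, function(L)
        load_mask(m[[paste0(L, "_mask")]][i]), simplify = FALSE)
    pp <- preprocess(img, masks, cfg)
    ip <- file.path(out_dir, paste0(m$id[i], ".png"))
    save_image(pp$image, ip)
    out$image_path[i] <- normalizePath(ip)
    if (m$labeled[i]) {
      for (L in LESIONS) {
        mp <- file.path(out_dir, paste0(m$id[i], "_", L, ".png"))
        save_image(pp$masks[[L]], mp)
        out[[paste0(L, "_mask")]][i] <- normalizePath(mp)
      }
    }
  }
  out
}
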