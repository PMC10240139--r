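#' Read a fundus image
#'
#' PNG, TIFF and JPEG (8- or 16-bit) are supported; values are scaled to
#' `[0,1]` doubles.  Grayscale images are replicated to three channels and an
#' alpha channel, if present, is dropped.
#'
#' @param path Image file path.
#' @return An `(H, W, 3)` array in `[0,1]`.
#' @export
load_image <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, " (", path, ")"))
  if (!is.numeric(img)) stop("not a raster image: ", path)
  pmin(pmax(img, 0), 1)
}

#' Write an image as PNG
#'
#' @param img Numeric array/matrix with values in `[0,1]` (clipped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a binary lesion mask
#'
#' Expects a single-channel raster with two intensity levels; anything else is
#' binarized by thresholding at 0.5 of full scale, with a warning when more
#' than two distinct levels are present.
#'
#' @param path Mask file path.
#' @return An `(H, W)` matrix with values strictly in `{0, 1}`.
#' @export
load_mask <- function(path) {
  m <- read_raster(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lv <- unique(as.vector(m))
  if (length(lv) > 2L)
    warning("mask ", path, " has ", length(lv),
            " intensity levels; binarizing at 0.5", call. = FALSE)
  (m > 0.5) * 1
}

#' Save / load a network checkpoint
#'
#' The checkpoint stores the network configuration (also serialized as YAML
#' for inspection), all trainable parameters and batch-norm buffers, and any
#' `extra` metadata.  A save/load round trip restores every parameter
#' bit-identically, so forward outputs are reproduced exactly.
#'
#' @param net An `"mdunet_net"`.
#' @param path Checkpoint file path.
#' @param extra Optional named list stored alongside the network.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `net` and `extra`.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  stopifnot(inherits(net, "mdunet_net"))
  saveRDS(list(format = "mdunet-checkpoint-1",
               config_yaml = yaml::as.yaml(unclass(net$config)),
               config = net$config,
               params = net$params,
               buffers = net$buffers,
               extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "mdunet-checkpoint-1"))
    stop("not an mdunet checkpoint: ", path)
  net <- structure(list(config = ck$config, params = ck$params,
                        buffers = ck$buffers),
                   class = "mdunet_net")
  list(net = net, extra = ck$extra)
}
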