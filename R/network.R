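#' Network topology configuration
#'
#' Describes the single-encoder, multi-decoder U-Net: a contracting encoder of
#' `depth` resolution levels (double 3x3 conv -> batch-norm -> ReLU blocks with
#' 2x2 max-pooling between levels) shared by up to four segmentation decoders
#' (one per lesion) and one reconstruction decoder.  Every decoder mirrors the
#' encoder, upsampling with 2x2 stride-2 transposed convolutions and merging
#' the matching encoder level's features through skip connections.
#'
#' @param depth Number of encoder resolution levels (default 5).
#' @param base_channels Feature channels at the first level; level `l` has
#'   `base_channels * 2^(l-1)` channels (default 32; tests use 4--8).
#' @param seg_decoders Character vector naming the segmentation decoders,
#'   a subset of `c("MA","HE","EX","SE")` (order = decoder order).
#' @param recon_decoder Logical; include the 3-channel reconstruction decoder.
#' @param in_channels Input channels (3 for RGB fundus photographs).
#' @param conv_per_block 2 (U-Net double conv, default) or 1.
#' @param skip_mode `"concat"` (U-Net channel concatenation, default) or
#'   `"add"` (additive merge).
#' @param recon_skips Logical; give the reconstruction decoder skip
#'   connections too (default `TRUE`).  Turning this off forces reconstruction
#'   through the bottleneck alone.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(depth = 5L, base_channels = 32L,
                           seg_decoders = c("MA", "HE", "EX", "SE"),
                           recon_decoder = TRUE, in_channels = 3L,
                           conv_per_block = 2L,
                           skip_mode = c("concat", "add"),
                           recon_skips = TRUE) {
  skip_mode <- match.arg(skip_mode)
  stopifnot(depth >= 2, base_channels >= 1, in_channels >= 1,
            conv_per_block %in% c(1L, 2L),
            all(seg_decoders %in% LESIONS), !anyDuplicated(seg_decoders))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 seg_decoders = seg_decoders,
                 recon_decoder = isTRUE(recon_decoder),
                 in_channels = as.integer(in_channels),
                 conv_per_block = as.integer(conv_per_block),
                 skip_mode = skip_mode,
                 recon_skips = isTRUE(recon_skips)),
            class = "network_config")
}

net_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

net_heads <- function(cfg) c(cfg$seg_decoders, if (cfg$recon_decoder) "recon")

head_out_channels <- function(cfg, head) if (head == "recon") cfg$in_channels else 1L

head_has_skips <- function(cfg, head) head != "recon" || cfg$recon_skips

# Decoder block input channels at level l (after the merge with the skip).
dec_block_in <- function(cfg, head, l) {
  C <- net_channels(cfg, l)
  if (head_has_skips(cfg, head) && cfg$skip_mode == "concat") 2L * C else C
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

new_conv <- function(k, cin, cout) {
  w <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             dim = c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

#' Build a multi-decoder U-Net with seeded random initialization
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for parameter initialization; two builds with the
#'   same seed are bit-identical.
#' @return An object of class `"mdunet_net"`: a list with `config`, flat named
#'   lists `params` (trainable tensors) and `buffers` (batch-norm running
#'   statistics).
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  p <- list(); bf <- list()
  add_conv <- function(name, k, cin, cout) {
    cv <- new_conv(k, cin, cout)
    p[[paste0(name, ".w")]] <<- cv$w
    p[[paste0(name, ".b")]] <<- cv$b
  }
  add_bn <- function(name, c) {
    p[[paste0(name, ".gamma")]] <<- rep(1, c)
    p[[paste0(name, ".beta")]] <<- numeric(c)
    bf[[paste0(name, ".rmean")]] <<- numeric(c)
    bf[[paste0(name, ".rvar")]] <<- rep(1, c)
  }
  add_block <- function(base, cin, cout) {
    for (j in seq_len(cfg$conv_per_block)) {
      add_conv(paste0(base, ".conv", j), 3L, if (j == 1) cin else cout, cout)
      add_bn(paste0(base, ".bn", j), cout)
    }
  }
  with_seed(seed, {
    for (l in seq_len(cfg$depth)) {
      cin <- if (l == 1) cfg$in_channels else net_channels(cfg, l - 1L)
      add_block(paste0("enc", l), cin, net_channels(cfg, l))
    }
    for (h in net_heads(cfg)) {
      for (l in rev(seq_len(cfg$depth - 1L))) {
        add_conv(paste0("dec.", h, ".up", l), 2L,
                 net_channels(cfg, l + 1L), net_channels(cfg, l))
        add_block(paste0("dec.", h, ".lvl", l),
                  dec_block_in(cfg, h, l), net_channels(cfg, l))
      }
      add_conv(paste0("dec.", h, ".out"), 1L,
               net_channels(cfg, 1L), head_out_channels(cfg, h))
    }
  })
  structure(list(config = cfg, params = p, buffers = bf),
            class = "mdunet_net")
}

#' Count trainable parameters
#'
#' @param net An `"mdunet_net"`; `prefix` optionally restricts the count to
#'   parameter names starting with that string (e.g. `"enc"`, `"dec.MA."`).
#' @return Integer count.
#' @export
param_count <- function(net, prefix = NULL) {
  nm <- names(net$params)
  if (!is.null(prefix)) nm <- nm[startsWith(nm, prefix)]
  sum(vapply(net$params[nm], length, 1L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# --- forward/backward engine -------------------------------------------------
# `st` is a private environment: p = params, bf = buffers (updated in-place
# when training), cache = per-layer saved tensors, g = accumulated gradients.

new_state <- function(net, training) {
  st <- new.env(parent = emptyenv())
  st$p <- net$params; st$bf <- net$buffers; st$cfg <- net$config
  st$cache <- new.env(parent = emptyenv())
  st$g <- new.env(parent = emptyenv())
  st$training <- training
  st
}

gacc <- function(st, name, v) {
  old <- st$g[[name]]
  st$g[[name]] <- if (is.null(old)) v else old + v
}

conv_bn_relu_fw <- function(st, x, cbase, bbase) {
  z1 <- cpp_conv2d_fw(x, st$p[[paste0(cbase, ".w")]], st$p[[paste0(cbase, ".b")]])
  if (st$training) {
    s <- cpp_bn_stats(z1)
    mean <- s$mean; var <- s$var
    st$bf[[paste0(bbase, ".rmean")]] <-
      (1 - BN_MOMENTUM) * st$bf[[paste0(bbase, ".rmean")]] + BN_MOMENTUM * mean
    st$bf[[paste0(bbase, ".rvar")]] <-
      (1 - BN_MOMENTUM) * st$bf[[paste0(bbase, ".rvar")]] + BN_MOMENTUM * var
  } else {
    mean <- st$bf[[paste0(bbase, ".rmean")]]
    var <- st$bf[[paste0(bbase, ".rvar")]]
  }
  invstd <- 1 / sqrt(var + BN_EPS)
  z2 <- cpp_bn_apply(z1, st$p[[paste0(bbase, ".gamma")]],
                     st$p[[paste0(bbase, ".beta")]], mean, invstd)
  a <- cpp_relu_fw(z2)
  st$cache[[cbase]] <- list(x = x, z1 = z1, z2 = z2, mean = mean, invstd = invstd)
  a
}

conv_bn_relu_bw <- function(st, d, cbase, bbase) {
  cc <- st$cache[[cbase]]
  dz2 <- cpp_relu_bw(cc$z2, d)
  bb <- cpp_bn_bw(cc$z1, st$p[[paste0(bbase, ".gamma")]], cc$mean, cc$invstd, dz2)
  gacc(st, paste0(bbase, ".gamma"), bb$dgamma)
  gacc(st, paste0(bbase, ".beta"), bb$dbeta)
  cb <- cpp_conv2d_bw(cc$x, st$p[[paste0(cbase, ".w")]], bb$dx)
  gacc(st, paste0(cbase, ".w"), cb$dw)
  gacc(st, paste0(cbase, ".b"), cb$db)
  cb$dx
}

block_fw <- function(st, x, base) {
  for (j in seq_len(st$cfg$conv_per_block))
    x <- conv_bn_relu_fw(st, x, paste0(base, ".conv", j), paste0(base, ".bn", j))
  x
}

block_bw <- function(st, d, base) {
  for (j in rev(seq_len(st$cfg$conv_per_block)))
    d <- conv_bn_relu_bw(st, d, paste0(base, ".conv", j), paste0(base, ".bn", j))
  d
}

encoder_fw <- function(st, x) {
  feats <- vector("list", st$cfg$depth)
  for (l in seq_len(st$cfg$depth)) {
    x <- block_fw(st, x, paste0("enc", l))
    feats[[l]] <- x
    if (l < st$cfg$depth) {
      mp <- cpp_maxpool_fw(x)
      st$cache[[paste0("pool", l)]] <- list(idx = mp$idx, H = dim(x)[1], W = dim(x)[2])
      x <- mp$y
    }
  }
  feats
}

encoder_bw <- function(st, dfeats) {
  d <- dfeats[[st$cfg$depth]]
  for (l in rev(seq_len(st$cfg$depth))) {
    d <- block_bw(st, d, paste0("enc", l))
    if (l > 1) {
      pc <- st$cache[[paste0("pool", l - 1L)]]
      d <- cpp_maxpool_bw(d, pc$idx, pc$H, pc$W)
      d <- d + dfeats[[l - 1L]]
    }
  }
  d
}

decoder_fw <- function(st, feats, head) {
  cfg <- st$cfg
  x <- feats[[cfg$depth]]
  skips <- head_has_skips(cfg, head)
  for (l in rev(seq_len(cfg$depth - 1L))) {
    ub <- paste0("dec.", head, ".up", l)
    st$cache[[ub]] <- x
    x <- cpp_convt2d_fw(x, st$p[[paste0(ub, ".w")]], st$p[[paste0(ub, ".b")]])
    if (skips) {
      x <- if (cfg$skip_mode == "concat") cat_channels(feats[[l]], x)
           else x + feats[[l]]
    }
    x <- block_fw(st, x, paste0("dec.", head, ".lvl", l))
  }
  ob <- paste0("dec.", head, ".out")
  st$cache[[ob]] <- x
  cpp_conv2d_fw(x, st$p[[paste0(ob, ".w")]], st$p[[paste0(ob, ".b")]])
}

decoder_bw <- function(st, d, head, dfeats) {
  cfg <- st$cfg
  skips <- head_has_skips(cfg, head)
  ob <- paste0("dec.", head, ".out")
  cb <- cpp_conv2d_bw(st$cache[[ob]], st$p[[paste0(ob, ".w")]], d)
  gacc(st, paste0(ob, ".w"), cb$dw); gacc(st, paste0(ob, ".b"), cb$db)
  d <- cb$dx
  for (l in seq_len(cfg$depth - 1L)) {
    d <- block_bw(st, d, paste0("dec.", head, ".lvl", l))
    if (skips) {
      if (cfg$skip_mode == "concat") {
        C <- net_channels(cfg, l)
        dfeats[[l]] <- dfeats[[l]] + d[, , seq_len(C), , drop = FALSE]
        d <- d[, , C + seq_len(C), , drop = FALSE]
      } else {
        dfeats[[l]] <- dfeats[[l]] + d
      }
    }
    ub <- paste0("dec.", head, ".up", l)
    tb <- cpp_convt2d_bw(st$cache[[ub]], st$p[[paste0(ub, ".w")]], d)
    gacc(st, paste0(ub, ".w"), tb$dw); gacc(st, paste0(ub, ".b"), tb$db)
    d <- tb$dx
  }
  dfeats[[cfg$depth]] <- dfeats[[cfg$depth]] + d
  dfeats
}

check_input <- function(cfg, x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L) stop("input must be an (H, W, C) or (H, W, C, N) array")
  if (d[3] != cfg$in_channels)
    stop("input has ", d[3], " channels; network expects ", cfg$in_channels)
  div <- 2L^(cfg$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("spatial size ", d[1], "x", d[2], " not divisible by 2^(depth-1) = ", div)
  x
}

#' Forward pass through the network
#'
#' In evaluation mode (`training = FALSE`, the default) batch-norm uses running
#' statistics and the call is a pure deterministic function of
#' `(parameters, input)`.
#'
#' @param net An `"mdunet_net"`.
#' @param x Input array `(H, W, C)` or batch `(H, W, C, N)`; spatial size must
#'   be divisible by `2^(depth-1)`.
#' @param heads Which decoder heads to run (default: all built heads).
#' @param training Logical; use batch statistics and keep caches for
#'   backpropagation.
#' @return A list with `recon` (sigmoid-activated 3-channel reconstruction in
#'   `[0,1]`, or `NULL`), `seg_logits` (named list of pre-sigmoid 1-channel
#'   maps), and when `training = TRUE` the internal `state` (layer caches and
#'   updated batch-norm buffers) used by the training loop.
#' @export
net_forward <- function(net, x, heads = NULL, training = FALSE) {
  cfg <- net$config
  x <- check_input(cfg, x)
  heads <- heads %||% net_heads(cfg)
  stopifnot(all(heads %in% net_heads(cfg)))
  st <- new_state(net, training)
  feats <- encoder_fw(st, x)
  st$feats <- feats
  seg <- list(); recon <- NULL
  for (h in heads) {
    out <- decoder_fw(st, feats, h)
    if (h == "recon") recon <- sigmoid(out) else seg[[h]] <- out
  }
  st$recon <- recon
  list(recon = recon, seg_logits = seg,
       state = if (training) st else NULL)
}

# Backward pass: douts$seg[[h]] are gradients w.r.t. segmentation logits,
# douts$recon w.r.t. the sigmoid-activated reconstruction.  Returns the flat
# gradient list for every parameter on an executed path.
net_backward <- function(st, douts) {
  cfg <- st$cfg
  dfeats <- lapply(st$feats, function(f) array(0, dim(f)))
  for (h in names(douts$seg))
    dfeats <- decoder_bw(st, douts$seg[[h]], h, dfeats)
  if (!is.null(douts$recon)) {
    dlog <- douts$recon * st$recon * (1 - st$recon)
    dfeats <- decoder_bw(st, dlog, "recon", dfeats)
  }
  encoder_bw(st, dfeats)
  as.list(st$g)
}

#' Encode an input into bottleneck and skip features
#'
#' Runs only the shared encoder (evaluation mode).
#'
#' @param net An `"mdunet_net"`.
#' @param x Input array or batch.
#' @return A list with `bottleneck` (the deepest feature map, with
#'   `base_channels * 2^(depth-1)` channels) and `skips` (per-level features
#'   consumed by the decoders).
#' @export
net_encode <- function(net, x) {
  x <- check_input(net$config, x)
  st <- new_state(net, FALSE)
  feats <- encoder_fw(st, x)
  list(bottleneck = feats[[net$config$depth]], skips = feats)
}

# One SGD update: p <- p - lr * g (optionally with classical momentum).
# Only parameters that received a gradient move; `vel` carries momentum state.
sgd_step <- function(net, grads, lr, momentum = 0, vel = NULL) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (momentum > 0) {
      v <- vel[[nm]]
      v <- if (is.null(v)) g else momentum * v + g
      vel[[nm]] <- v
      g <- v
    }
    net$params[[nm]] <- net$params[[nm]] - lr * g
  }
  list(net = net, vel = vel)
}

#' @export
print.mdunet_net <- function(x, ...) {
  cfg <- x$config
  cat("Multi-decoder U-Net\n")
  cat("  depth:", cfg$depth, " base channels:", cfg$base_channels,
      " conv/block:", cfg$conv_per_block, "\n")
  cat("  segmentation decoders:", paste(cfg$seg_decoders, collapse = ", "), "\n")
  cat("  reconstruction decoder:", cfg$recon_decoder,
      if (cfg$recon_decoder) paste0("(skips: ", cfg$recon_skips, ")"), "\n")
  cat("  skip mode:", cfg$skip_mode, "\n")
  cat("  parameters:", format(param_count(x), big.mark = ","),
      "(encoder", format(param_count(x, "enc"), big.mark = ","), ")\n")
  invisible(x)
}

#' Layer table of a network
#'
#' @param net An `"mdunet_net"`.
#' @return A data frame with one row per parameter tensor (name, shape, count).
#' @export
describe_network <- function(net) {
  data.frame(
    name = names(net$params),
    shape = vapply(net$params, function(p)
      paste(dim(p) %||% length(p), collapse = "x"), ""),
    n = vapply(net$params, length, 1L),
    row.names = NULL
  )
}
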