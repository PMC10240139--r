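test_that("encoder downsamples to the expected bottleneck", {
  # depth-5 encoder on 128x128: bottleneck 8x8 with base*2^4 channels
  cfg <- network_config(depth = 5, base_channels = 1)
  net <- build_network(cfg, seed = 1)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3, 1))
  enc <- net_encode(net, x)
  expect_equal(dim(enc$bottleneck)[1:2], c(8, 8))
  expect_equal(dim(enc$bottleneck)[3], 1 * 2^4)
  expect_length(enc$skips, 5)
  expect_equal(dim(enc$skips[[1]])[1:2], c(128, 128))
})

test_that("initialization is seeded and decoder parameter counts line up", {
  cfg <- tiny_net_cfg()
  n1 <- build_network(cfg, seed = 7)
  n2 <- build_network(cfg, seed = 7)
  expect_identical(n1$params, n2$params)
  expect_false(identical(build_network(cfg, seed = 8)$params, n1$params))

  cfg4 <- network_config(depth = 3, base_channels = 4)
  net <- build_network(cfg4, seed = 1)
  counts <- vapply(c("MA", "HE", "EX", "SE"),
                   function(h) param_count(net, paste0("dec.", h, ".")), 0)
  expect_true(all(counts == counts[1]))  # all four seg decoders equal
  # reconstruction decoder differs only in its final 1x1 conv (3 vs 1 outputs)
  C1 <- 4
  expect_equal(unname(param_count(net, "dec.recon.") - counts[1]),
               (3 - 1) * (C1 * 1 * 1 + 1))
})

test_that("forward obeys the shape contract and output ranges", {
  cfg <- tiny_net_cfg()
  net <- build_network(cfg, seed = 3)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  out <- net_forward(net, x)
  expect_equal(dim(out$recon), c(32, 32, 3, 2))
  expect_length(out$seg_logits, 4)
  for (h in names(out$seg_logits))
    expect_equal(dim(out$seg_logits[[h]]), c(32, 32, 1, 2))
  expect_true(all(out$recon >= 0 & out$recon <= 1))
  # evaluation-mode forward is deterministic
  out2 <- net_forward(net, x)
  expect_identical(out2$recon, out$recon)
  expect_identical(out2$seg_logits, out$seg_logits)
  # shape errors
  net3 <- build_network(network_config(depth = 3, base_channels = 2), seed = 1)
  expect_error(net_forward(net3, array(0, c(30, 30, 3, 1))), "divisible")
  expect_error(net_forward(net, array(0, c(32, 32, 4, 1))), "channels")
})

test_that("the encoder is shared: decoder edits never change the latent code", {
  net <- build_network(tiny_net_cfg(), seed = 5)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  z1 <- net_encode(net, x)
  net2 <- net
  net2$params[["dec.MA.out.w"]] <- net2$params[["dec.MA.out.w"]] + 1
  net2$params[["dec.recon.up1.w"]] <- net2$params[["dec.recon.up1.w"]] * 2
  z2 <- net_encode(net2, x)
  expect_identical(z1$bottleneck, z2$bottleneck)
  # but segmentation output does change
  expect_false(identical(net_forward(net2, x, heads = "MA")$seg_logits$MA,
                         net_forward(net, x, heads = "MA")$seg_logits$MA))
})

test_that("with one decoder and no reconstruction the topology is a plain U-Net", {
  cfg <- network_config(depth = 3, base_channels = 2, seg_decoders = "EX",
                        recon_decoder = FALSE)
  net <- build_network(cfg, seed = 1)
  nm <- names(net$params)
  expect_false(any(grepl("recon", nm)))
  expect_setequal(unique(sub("\\..*$", "", nm)), c("enc1", "enc2", "enc3", "dec"))
  expect_true(all(grepl("^dec\\.EX\\.", nm[startsWith(nm, "dec")])))
  out <- net_forward(net, array(runif(32 * 32 * 3), c(32, 32, 3, 1)))
  expect_null(out$recon)
  expect_named(out$seg_logits, "EX")
})

test_that("analytic gradients match finite differences", {
  cfg <- network_config(depth = 2, base_channels = 2,
                        seg_decoders = c("MA", "EX"), recon_decoder = TRUE)
  net <- build_network(cfg, seed = 3)
  set.seed(42)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  gtM <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  gtE <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
  alpha <- 0.5; beta <- 0.7
  loss_fn <- function(nn) {
    fw <- mdunet:::net_forward(nn, x, training = TRUE)
    lM <- mdunet:::dice_loss_pair(fw$seg_logits$MA, gtM)
    lE <- mdunet:::dice_loss_pair(fw$seg_logits$EX, gtE)
    lR <- reconstruction_loss(x, fw$recon)
    list(loss = alpha * lR + beta * lM$loss + (1 - beta) * lE$loss, fw = fw,
         dM = beta * lM$dlogits, dE = (1 - beta) * lE$dlogits,
         dR = alpha * mdunet:::reconstruction_loss_grad(x, fw$recon))
  }
  l0 <- loss_fn(net)
  g <- mdunet:::net_backward(l0$fw$state,
                             list(seg = list(MA = l0$dM, EX = l0$dE),
                                  recon = l0$dR))
  eps <- 1e-6
  for (nm in c("enc1.conv1.w", "enc2.bn1.gamma", "dec.MA.up1.w",
               "dec.EX.out.w", "dec.recon.lvl1.conv2.b")) {
    for (i in sample(length(net$params[[nm]]), 2)) {
      n2 <- net; n2$params[[nm]][i] <- net$params[[nm]][i] + eps
      lp <- loss_fn(n2)$loss
      n2$params[[nm]][i] <- net$params[[nm]][i] - eps
      lm <- loss_fn(n2)$loss
      fd <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})
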