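test_that("reconstruction pre-training descends and touches only its own path", {
  pool <- tiny_unlabeled_pool(9, size = 32)
  net <- build_network(tiny_net_cfg(), seed = 1)
  cfg <- tiny_train_cfg(epochs_unsup = 3L)
  ts <- pretrain_reconstruction(net, pool, cfg)
  h <- ts$history
  expect_true(all(h$phase == "unsup"))
  expect_true(all(diff(h$step) > 0))  # strictly increasing step index
  expect_lt(mean(h$L_rec[h$epoch == max(h$epoch)]),
            mean(h$L_rec[h$epoch == 1]))
  # segmentation decoders bit-identical before vs after (params and buffers)
  for (L in c("MA", "HE", "EX", "SE")) {
    expect_true(params_identical(net, ts$net, paste0("dec.", L, ".")))
    nms <- grep(paste0("^dec\\.", L, "\\."), names(net$buffers), value = TRUE)
    expect_identical(net$buffers[nms], ts$net$buffers[nms])
  }
  # encoder and reconstruction decoder did move
  expect_false(params_identical(net, ts$net, "enc"))
  expect_false(params_identical(net, ts$net, "dec.recon."))
  # zero epochs: network entirely unchanged
  ts0 <- pretrain_reconstruction(net, pool, tiny_train_cfg(epochs_unsup = 0L))
  expect_identical(ts0$net$params, net$params)
  expect_identical(ts0$net$buffers, net$buffers)
  expect_equal(nrow(ts0$history), 0)
  # empty pool is an error
  expect_error(pretrain_reconstruction(net, pool_subset(pool, integer()), cfg),
               "empty")
})

test_that("supervised training reduces the primary dice loss and isolates the reconstruction decoder", {
  pool <- tiny_labeled_pool(6, size = 32)
  net <- build_network(tiny_net_cfg(), seed = 2)
  cfg <- tiny_train_cfg(epochs_sup = 4L, supervised_recon = FALSE)
  ts <- train_supervised(net, pool, cfg)
  h <- ts$history
  expect_lt(mean(h$L_EX[h$epoch == max(h$epoch)]),
            mean(h$L_EX[h$epoch == 1]))
  expect_true(is.finite(ts$best_val_dsc))
  # reconstruction decoder untouched when supervised_recon = FALSE
  expect_true(params_identical(net, ts$net, "dec.recon."))
  rn <- grep("^dec\\.recon\\.", names(net$buffers), value = TRUE)
  expect_identical(net$buffers[rn], ts$net$buffers[rn])
  expect_false(params_identical(net, ts$net, "enc"))
})

test_that("beta = 1 reduces the update to single-task training (bitwise)", {
  pool <- tiny_labeled_pool(6, size = 32)
  cfg4 <- network_config(depth = 2, base_channels = 2, recon_decoder = FALSE)
  cfg1 <- network_config(depth = 2, base_channels = 2, seg_decoders = "EX",
                         recon_decoder = FALSE)
  net4 <- build_network(cfg4, seed = 7)
  net1 <- build_network(cfg1, seed = 99)
  for (nm in names(net1$params)) net1$params[[nm]] <- net4$params[[nm]]
  for (nm in names(net1$buffers)) net1$buffers[[nm]] <- net4$buffers[[nm]]
  tc <- tiny_train_cfg(epochs_sup = 2L,
                       weights = loss_weights(alpha = 1, beta = 1))
  t4 <- train_supervised(net4, pool, tc)
  t1 <- train_supervised(net1, pool, tc)
  expect_true(params_identical(t4$net, t1$net, "enc"))
  expect_true(params_identical(t4$net, t1$net, "dec.EX."))
  # auxiliary decoders received exactly zero gradient
  for (L in c("MA", "HE", "SE"))
    expect_true(params_identical(t4$net, net4, paste0("dec.", L, ".")))
})

test_that("alpha = 0 removes the reconstruction term from the supervised update", {
  pool <- tiny_labeled_pool(6, size = 32)
  net <- build_network(tiny_net_cfg(), seed = 4)
  tA <- train_supervised(net, pool, tiny_train_cfg(
    epochs_sup = 2L, supervised_recon = TRUE,
    weights = loss_weights(alpha = 0, beta = 0.7)))
  tB <- train_supervised(net, pool, tiny_train_cfg(
    epochs_sup = 2L, supervised_recon = FALSE,
    weights = loss_weights(alpha = 1, beta = 0.7)))
  expect_identical(tA$net$params, tB$net$params)
  # and with alpha > 0 the encoder update does differ
  tC <- train_supervised(net, pool, tiny_train_cfg(
    epochs_sup = 2L, supervised_recon = TRUE,
    weights = loss_weights(alpha = 5, beta = 0.7)))
  expect_false(params_identical(tC$net, tB$net, "enc"))
})

test_that("training is deterministic under a fixed seed", {
  pool <- tiny_labeled_pool(5, size = 32)
  unl <- tiny_unlabeled_pool(5, size = 32)
  run <- function() {
    net <- build_network(tiny_net_cfg(), seed = 11)
    ts <- pretrain_reconstruction(net, unl, tiny_train_cfg())
    train_supervised(ts, pool, tiny_train_cfg())
  }
  a <- run(); b <- run()
  expect_identical(a$net$params, b$net$params)
  expect_identical(a$history, b$history)
})

test_that("train_all_primaries shares one pretrained snapshot across four models", {
  labeled <- split_pool(tiny_labeled_pool(8, size = 32, seed = 31),
                        c(0.75, 0.25, 0), seed = 1)
  unl <- tiny_unlabeled_pool(6, size = 32, seed = 32)
  cfg <- tiny_train_cfg(epochs_unsup = 2L, epochs_sup = 3L)
  reg <- train_all_primaries(labeled, unl, cfg,
                             net_cfg = tiny_net_cfg(), seed = 3)
  expect_s3_class(reg, "mdunet_registry")
  expect_named(reg, c("MA", "HE", "EX", "SE"))
  snap <- attr(reg, "pretrained_net")
  expect_s3_class(snap, "mdunet_net")
  # each model's best-val DSC for its own primary >= its DSC at the shared
  # initialization (training helps over the pretrained starting point)
  for (L in c("MA", "HE", "EX", "SE")) {
    init_dsc <- mdunet:::val_primary_dsc(snap, labeled, L)
    expect_gte(reg[[L]]$best_val_dsc, init_dsc)
  }
  # and for the easiest lesion training genuinely improves on the init
  expect_gt(reg$EX$best_val_dsc, mdunet:::val_primary_dsc(snap, labeled, "EX"))
  expect_gte(reg$EX$best_epoch, 1)
})

test_that("mdunet_fit returns a working classed model object", {
  labeled <- split_pool(tiny_labeled_pool(6, size = 32), c(0.7, 0.3, 0),
                        seed = 2)
  unl <- tiny_unlabeled_pool(4, size = 32)
  fit <- mdunet_fit(labeled, unl, primary = "EX", net_cfg = tiny_net_cfg(),
                    cfg = tiny_train_cfg())
  expect_s3_class(fit, "mdunet")
  expect_true(fit$pretrained)
  expect_output(print(fit), "primary task: EX")
  expect_output(print(summary(fit)), "best validation DSC")
  pr <- predict(fit, labeled$images[[1]])
  expect_named(pr, c("MA", "HE", "EX", "SE"))
  expect_true(all(pr$EX >= 0 & pr$EX <= 1))
  mk <- predict(fit, labeled$images[[1]], type = "mask")
  expect_setequal(unique(as.vector(mk$EX)), intersect(c(0, 1), mk$EX))
  rc <- predict(fit, labeled$images[[1]], type = "recon")
  expect_equal(dim(rc), c(32, 32, 3))
  expect_named(coef(fit), names(fit$net$params), ignore.order = TRUE)
  f <- tempfile(fileext = ".csv")
  write_loss_log(fit, f)
  expect_true(all(c("phase", "L_rec", "L_EX", "total") %in%
                    names(read.csv(f))))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
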