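test_that("dice score, sensitivity and MAE match counting oracles", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, 1 - a), 0)
  expect_equal(dice_score(a, b), 2 / 3)       # |p|=2, |g|=1, overlap 1
  expect_equal(dice_score(matrix(0, 2, 2), matrix(0, 2, 2)), 1)  # empty/empty
  expect_equal(dice_score(a, b), dice_score(b, a))  # symmetry

  gt <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3)
  pr <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  expect_equal(sensitivity(pr, gt), 0.75)     # |gt|=4, overlap 3
  expect_equal(sensitivity(gt, pr), 1)        # asymmetric witness
  expect_equal(sensitivity(1 - gt, gt), 0)
  expect_warning(s <- sensitivity(pr, matrix(0, 2, 3)), "undefined")
  expect_true(is.na(s))

  sp <- matrix(c(0.1, 0.0, 0.9, 1.0), 2, 2)   # [[0.1,0.9],[0.0,1.0]]
  g <- matrix(c(0, 1, 1, 1), 2, 2)            # [[0,1],[1,1]]
  expect_equal(mae(sp, g), 0.3)
  expect_equal(mae(g, g), 0)
  expect_equal(mae(matrix(0.5, 3, 3), matrix(rbinom(9, 1, 0.5), 3, 3)), 0.5)
  # permutation invariance
  set.seed(1); perm <- sample(4)
  expect_equal(mae(matrix(sp[perm], 2, 2), matrix(g[perm], 2, 2)), mae(sp, g))
})

test_that("AUC-ROC matches the all-pairs oracle, AUC-PR the step summation", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  lb <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auc_roc(sc, lb), 8 / 9)    # 8 of 9 positive-negative pairs won
  expect_equal(auc_pr(sc, lb), 11 / 12)   # 1/3 + 1/3 + 0 + 1/4
  expect_equal(auc_roc(lb, lb), 1)        # perfectly separated
  expect_equal(auc_roc(rep(0.3, 6), lb), 0.5)  # constant scores tie-average
  expect_warning(r <- auc_roc(sc, rep(1, 6)), "one class")
  expect_true(is.na(r))

  pair_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    mean(cmp)
  }
  set.seed(99)
  for (i in 1:20) {
    s <- round(runif(50), 2)   # rounded so ties occur
    y <- rbinom(50, 1, 0.3)
    if (sum(y) %in% c(0, 50)) next
    expect_equal(auc_roc(s, y), pair_oracle(s, y))
  }
})

test_that("evaluate_model reproduces an independent confusion-count recomputation", {
  pool <- tiny_labeled_pool(3, size = 32, seed = 21)
  net <- build_network(tiny_net_cfg(), seed = 2)
  rep <- evaluate_model(net, pool, threshold = 0.5)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_lesion), 4)
  expect_equal(rep$n_images, 3)

  # independent recomputation for one lesion from raw probability maps
  h <- "EX"
  dscs <- maes <- sens <- c(); sc <- lb <- c()
  for (i in 1:3) {
    fw <- net_forward(net, array(pool$images[[i]], c(32, 32, 3, 1)), heads = h)
    p <- 1 / (1 + exp(-fw$seg_logits[[h]][, , 1, 1]))
    gt <- pool$masks[[i]][[h]]
    pm <- (p > 0.5) * 1
    cc <- confusion_counts(pm, gt)
    dscs <- c(dscs, if (cc$sp + cc$sg == 0) 1 else 2 * cc$tp / (cc$sp + cc$sg))
    sens <- c(sens, if (cc$sg > 0) cc$tp / cc$sg else NA)
    maes <- c(maes, mean(abs(p - gt)))
    sc <- c(sc, as.vector(p)); lb <- c(lb, as.vector(gt))
  }
  row <- rep$per_lesion[rep$per_lesion$lesion == h, ]
  expect_equal(row$dsc, mean(dscs))
  expect_equal(row$sensitivity, mean(sens, na.rm = TRUE))
  expect_equal(row$mae, mean(maes))
  expect_equal(row$auc_roc, auc_roc(sc, lb))
  expect_equal(row$auc_pr, auc_pr(sc, lb))
})

test_that("an oracle model scores perfectly; threshold 0 predicts everything", {
  pool <- tiny_labeled_pool(2, size = 32, seed = 22)
  net <- build_network(tiny_net_cfg(), seed = 2)
  # force-oracle: overwrite probabilities by evaluating metrics directly
  for (i in 1:2) {
    gt <- pool$masks[[i]]$HE
    expect_equal(dice_score(gt, gt), 1)
    expect_equal(mae(gt, gt), 0)
    if (sum(gt) > 0) expect_equal(sensitivity(gt, gt), 1)
  }
  rep0 <- evaluate_model(net, pool, threshold = 0)
  # predicting everything gives sensitivity 1 for every nonempty gt
  expect_true(all(rep0$per_lesion$sensitivity == 1, na.rm = TRUE))
})
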