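#' @keywords internal
#' MD5 hash of an arbitrary configuration object (for result provenance).
cfg_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

prefix_pool <- function(pool, prefix) {
  pool$ids <- paste0(prefix, pool$ids)
  pool
}

combine_pools <- function(a, b) {
  stopifnot(!length(intersect(a$ids, b$ids)))
  structure(list(ids = c(a$ids, b$ids), images = c(a$images, b$images),
                 masks = c(a$masks, b$masks), labeled = c(a$labeled, b$labeled),
                 split = c(a$split, b$split)),
            class = "fundus_pool")
}

# Fixed auxiliary inclusion order (so ablation cells are comparable):
# candidates EX, SE, MA, HE minus the primary, first k taken.
aux_order <- function(primary, k) {
  setdiff(c("EX", "SE", "MA", "HE"), primary)[seq_len(k)]
}

run_one_cell <- function(labeled, unlabeled, primary, k, ssl, net_cfg, cfg,
                         seed) {
  nc <- network_config(depth = net_cfg$depth,
                       base_channels = net_cfg$base_channels,
                       seg_decoders = c(primary, aux_order(primary, k)),
                       recon_decoder = ssl,
                       conv_per_block = net_cfg$conv_per_block,
                       skip_mode = net_cfg$skip_mode,
                       recon_skips = net_cfg$recon_skips)
  cfg$primary <- primary
  cfg$seed <- seed
  net <- build_network(nc, seed)
  if (ssl && !is.null(unlabeled) && cfg$epochs_unsup > 0L)
    net <- pretrain_reconstruction(net, unlabeled, cfg)
  ts <- train_supervised(net, labeled, cfg)
  ts$best_val_dsc
}

#' Auxiliary-task ablation
#'
#' For `k` in `n_aux` auxiliary segmentation tasks (network built with `1+k`
#' segmentation decoders, auxiliaries added in the fixed order EX, SE, MA, HE
#' minus the primary), with and without semi-supervised pre-training (SSL),
#' trains on a freshly generated synthetic benchmark per seed and records the
#' best-validation primary dice.  Data are shared across cells within a seed
#' so comparisons are paired.
#'
#' @param seeds Integer seeds (one benchmark replicate each).
#' @param primary Primary lesion.
#' @param n_aux Auxiliary-task counts to sweep (subset of `0:3`).
#' @param ssl Logical vector: pre-train or not.
#' @param syn_cfg A [synthetic_config()] for the generated benchmark.
#' @param net_cfg,cfg Base [network_config()] and [train_config()].
#' @param fractions Labeled train/val/test fractions.
#' @return A data frame with columns `seed`, `n_aux`, `ssl`, `dsc`,
#'   `cfg_hash`.
#' @export
run_auxiliary_ablation <- function(seeds = 1:5, primary = "EX", n_aux = 0:3,
                                   ssl = c(FALSE, TRUE),
                                   syn_cfg = trend_benchmark()$syn,
                                   net_cfg = trend_benchmark()$net,
                                   cfg = trend_benchmark()$cfg,
                                   fractions = c(0.75, 0.25, 0)) {
  stopifnot(all(n_aux %in% 0:3))
  rows <- list()
  for (s in seeds) {
    sc <- syn_cfg; sc$seed <- sc$seed + 1000L * s
    labeled <- split_pool(generate_pool(sc, sc$n_labeled, 0L), fractions,
                          seed = s)
    unlabeled <- if (any(ssl)) {
      su <- sc; su$seed <- su$seed + 1L
      generate_pool(su, 0L, sc$n_unlabeled)
    }
    for (k in n_aux) for (use_ssl in ssl) {
      dsc <- run_one_cell(labeled, unlabeled, primary, k, use_ssl,
                          net_cfg, cfg, seed = s)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, n_aux = k, ssl = use_ssl, dsc = dsc,
        cfg_hash = cfg_hash(list(sc, primary, k, use_ssl, net_cfg, cfg)))
    }
  }
  do.call(rbind, rows)
}

#' Unlabeled-data-amount sweep
#'
#' Pre-trains on increasing amounts of unlabeled data (0 = supervised-only)
#' and records the best-validation primary dice.  The `n = 0` cell is by
#' construction identical to a purely supervised run with the same seed.
#'
#' @param n_unlabeled Vector of unlabeled pool sizes (0 allowed).
#' @inheritParams run_auxiliary_ablation
#' @return A data frame with columns `seed`, `n_unlabeled`, `dsc`,
#'   `cfg_hash`.
#' @export
run_unlabeled_sweep <- function(n_unlabeled = c(0L, 20L, 40L), seeds = 1:5,
                                primary = "EX",
                                syn_cfg = trend_benchmark()$syn,
                                net_cfg = trend_benchmark()$net,
                                cfg = trend_benchmark()$cfg,
                                fractions = c(0.75, 0.25, 0)) {
  rows <- list()
  for (s in seeds) {
    sc <- syn_cfg; sc$seed <- sc$seed + 1000L * s
    labeled <- split_pool(generate_pool(sc, sc$n_labeled, 0L), fractions,
                          seed = s)
    su <- sc; su$seed <- su$seed + 1L
    pool_max <- generate_pool(su, 0L, max(n_unlabeled))
    for (n in n_unlabeled) {
      unlabeled <- if (n > 0) pool_subset(pool_max, seq_len(n))
      dsc <- run_one_cell(labeled, unlabeled, primary, k = 3L,
                          ssl = n > 0, net_cfg, cfg, seed = s)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, n_unlabeled = n, dsc = dsc,
        cfg_hash = cfg_hash(list(sc, primary, n, net_cfg, cfg)))
    }
  }
  do.call(rbind, rows)
}

#' Domain-shifted copy of a synthetic configuration
#'
#' Default shift: lesion contrast scaled by 0.7 and noise raised by 1.5,
#' emulating a harder acquisition domain.
#'
#' @param cfg A [synthetic_config()].
#' @param contrast_factor,noise_factor Multipliers.
#' @return A shifted `"synthetic_config"`.
#' @export
shift_domain <- function(cfg, contrast_factor = 0.7, noise_factor = 1.5) {
  cfg$contrast <- min(1, cfg$contrast * contrast_factor)
  cfg$noise_sd <- cfg$noise_sd * noise_factor
  cfg
}

#' Cross-dataset robustness protocol
#'
#' Trains on a source domain (plus, optionally, a fraction of the target
#' domain's training pool) and evaluates on a held-out target pool that never
#' enters training; the id audit is asserted on every run.
#'
#' @param source_cfg,target_cfg [synthetic_config()]s that differ in at least
#'   one generative parameter (see [shift_domain()]).
#' @param mix_fraction Fraction of the target training pool added to the
#'   training set, in `[0, 1)`; the added count is
#'   `ceiling(mix_fraction * n_target_train)`.
#' @param seed Replicate seed.
#' @param net_cfg,cfg Base network and training configurations.
#' @param n_target Total target-domain samples (half train-candidate pool,
#'   half held-out evaluation).
#' @return A `"metrics_report"` on the target evaluation pool, with
#'   attributes `train_ids`, `eval_ids`, `n_target_added`, `cfg_hash`.
#' @export
run_cross_dataset <- function(source_cfg = trend_benchmark()$syn,
                              target_cfg = shift_domain(source_cfg),
                              mix_fraction = 0, seed = 1L,
                              net_cfg = trend_benchmark()$net,
                              cfg = trend_benchmark()$cfg,
                              n_target = 20L) {
  if (mix_fraction < 0 || mix_fraction >= 1)
    stop("mix_fraction must be in [0, 1)")
  if (identical(source_cfg[c("contrast", "noise_sd", "lesion_radii")],
                target_cfg[c("contrast", "noise_sd", "lesion_radii")]))
    stop("source and target configs must differ in a generative parameter")
  sc <- source_cfg; sc$seed <- sc$seed + 1000L * seed
  labeled <- prefix_pool(
    split_pool(generate_pool(sc, sc$n_labeled, 0L), c(0.75, 0.25, 0),
               seed = seed), "src_")
  su <- sc; su$seed <- su$seed + 1L
  unlabeled <- generate_pool(su, 0L, sc$n_unlabeled)
  tc <- target_cfg; tc$seed <- tc$seed + 2000L * seed
  target <- prefix_pool(generate_pool(tc, n_target, 0L), "tgt_")
  n_tr_pool <- n_target %/% 2L
  tgt_train_pool <- pool_subset(target, seq_len(n_tr_pool))
  tgt_eval <- pool_subset(target, (n_tr_pool + 1L):n_target)
  n_add <- as.integer(ceiling(mix_fraction * n_tr_pool))
  if (n_add > 0) {
    add <- pool_subset(tgt_train_pool, seq_len(n_add))
    add$split <- rep("train", n_add)
    labeled <- combine_pools(labeled, add)
  }
  cfg$seed <- seed
  nc <- network_config(depth = net_cfg$depth,
                       base_channels = net_cfg$base_channels,
                       seg_decoders = net_cfg$seg_decoders,
                       recon_decoder = TRUE,
                       conv_per_block = net_cfg$conv_per_block,
                       skip_mode = net_cfg$skip_mode,
                       recon_skips = net_cfg$recon_skips)
  net <- build_network(nc, seed)
  if (cfg$epochs_unsup > 0L)
    net <- pretrain_reconstruction(net, unlabeled, cfg)
  ts <- train_supervised(net, labeled, cfg)
  train_ids <- labeled$ids[labeled$split == "train"]
  stopifnot(!length(intersect(train_ids, tgt_eval$ids)))   # leakage audit
  rep <- evaluate_model(ts, tgt_eval)
  attr(rep, "train_ids") <- train_ids
  attr(rep, "eval_ids") <- tgt_eval$ids
  attr(rep, "n_target_added") <- n_add
  attr(rep, "cfg_hash") <- cfg_hash(list(source_cfg, target_cfg, mix_fraction,
                                         seed, net_cfg, cfg))
  rep
}
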