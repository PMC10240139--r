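# Shared desk-scale fixtures: tiny networks and small synthetic pools so each
# test runs in seconds.

tiny_net_cfg <- function(...) {
  network_config(depth = 2L, base_channels = 2L, ...)
}

tiny_syn_cfg <- function(size = 32L, seed = 11L, ...) {
  synthetic_config(
    image_size = size,
    lesion_counts = list(MA = c(1, 3), HE = c(1, 3), EX = c(2, 4), SE = c(1, 2)),
    lesion_radii = list(MA = c(1, 2), HE = c(2, 4), EX = c(2, 5), SE = c(2, 4)),
    vessel_count = 3L, seed = seed, ...)
}

tiny_labeled_pool <- function(n = 6L, size = 32L, seed = 11L) {
  generate_pool(tiny_syn_cfg(size, seed), n_labeled = n, n_unlabeled = 0L)
}

tiny_unlabeled_pool <- function(n = 6L, size = 32L, seed = 12L) {
  generate_pool(tiny_syn_cfg(size, seed), n_labeled = 0L, n_unlabeled = n)
}

tiny_train_cfg <- function(...) {
  args <- list(batch_size = 3L, learning_rate = 0.5, epochs_unsup = 2L,
               epochs_sup = 2L, primary = "EX", seed = 5L)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(train_config, args)
}

# Write a labeled synthetic sample (image + masks) into dir under `id`.
write_sample_files <- function(dir, id, masks = LESIONS, size = 32L) {
  s <- with_seed_local(abs(sum(utf8ToInt(id))), {
    generate_sample(tiny_syn_cfg(size, seed = 1L))
  })
  save_image(s$image, file.path(dir, paste0(id, ".png")))
  for (L in masks)
    save_image(s$masks[[L]], file.path(dir, paste0(id, "_", L, ".png")))
  invisible(s)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Confusion-count oracle for binary masks: returns TP and mass sums.
confusion_counts <- function(pred, gt) {
  list(tp = sum(pred == 1 & gt == 1), sp = sum(pred), sg = sum(gt))
}

# All 512 binary 3x3 masks as a list of matrices.
all_3x3_masks <- function() {
  lapply(0:511, function(k) {
    matrix(as.integer(intToBits(k)[1:9]), 3, 3)
  })
}

# Modify config fields while keeping the object's class.
within_cfg <- function(cfg, ...) {
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  cfg
}

# Flat parameter comparison helpers.
params_identical <- function(a, b, prefix) {
  nms <- grep(paste0("^", prefix), names(a$params), value = TRUE)
  all(vapply(nms, function(nm) identical(a$params[[nm]], b$params[[nm]]), TRUE))
}
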