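#' Desk-scale synthetic benchmarks
#'
#' `default_benchmark()` is the package's reference study: 128x128 synthetic
#' fundus images, 40 labeled (32 train / 8 val) and 200 unlabeled samples, a
#' tiny depth-3 network, hard exudate (EX) as the primary task.
#' `trend_benchmark()` is the further reduced configuration used for
#' multi-seed trend experiments (auxiliary-task ablation, unlabeled-data
#' sweep, cross-dataset protocol): 64x64 images, 16 labeled / 40 unlabeled,
#' an even smaller network and shorter schedules.
#'
#' The learning rate of these presets (0.5, plain SGD) is sized for the tiny
#' batch-normalized networks and dice objective used at desk scale; the
#' real-data preset in [train_config()] keeps the reference recipe
#' (lr 1e-4, batch 16).
#'
#' @param primary Primary lesion of the preset (default `"EX"`).
#' @return A list with `syn` ([synthetic_config()]), `net`
#'   ([network_config()]), `cfg` ([train_config()]), and `fractions`
#'   (labeled train/val/test fractions).
#' @export
default_benchmark <- function(primary = "EX") {
  list(
    syn = synthetic_config(image_size = 128L, n_labeled = 40L,
                           n_unlabeled = 200L, seed = 101L),
    net = network_config(depth = 3L, base_channels = 8L),
    cfg = train_config(batch_size = 8L, learning_rate = 0.5,
                       epochs_unsup = 3L, epochs_sup = 12L,
                       primary = primary, seed = 1L),
    fractions = c(0.8, 0.2, 0)
  )
}

#' @rdname default_benchmark
#' @export
trend_benchmark <- function(primary = "EX") {
  list(
    syn = synthetic_config(image_size = 64L, n_labeled = 16L,
                           n_unlabeled = 40L,
                           lesion_radii = list(MA = c(1, 2), HE = c(2, 5),
                                               EX = c(3, 8), SE = c(3, 6)),
                           seed = 201L),
    net = network_config(depth = 3L, base_channels = 4L),
    cfg = train_config(batch_size = 4L, learning_rate = 0.5,
                       epochs_unsup = 2L, epochs_sup = 10L,
                       primary = primary, seed = 1L),
    fractions = c(0.75, 0.25, 0)
  )
}
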