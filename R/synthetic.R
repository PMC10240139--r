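#' Configuration of the synthetic fundus generator
#'
#' The generator emulates the gross appearance of color fundus photographs at
#' desk scale: a circular orange-brown retinal field on a black background
#' with curved dark vessels and a bright optic disc, carrying four visually
#' distinct lesion families with exact ground-truth masks --
#' microaneurysms (MA: tiny dark-red dots, the smallest and hardest class),
#' hemorrhages (HE: irregular dark-red blots), hard exudates (EX: vivid
#' yellow-white patches) and soft exudates (SE: pale low-contrast blobs).
#' Under the default count/radius ranges the expected pixel prevalence is
#' ordered EX > HE > SE > MA.
#'
#' @param image_size Side length in pixels (default 128; the network is
#'   size-agnostic given divisibility constraints, so tests run far below the
#'   512 used for real photographs).
#' @param n_labeled,n_unlabeled Pool sizes for [generate_dataset()] /
#'   [generate_pool()].
#' @param lesion_counts Named list of `c(min, max)` per-image lesion counts.
#' @param lesion_radii Named list of `c(min, max)` lesion radii in pixels.
#' @param vessel_count Number of vessel strokes.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (default 0.02).
#' @param contrast Lesion-vs-background contrast multiplier in `(0, 1]`
#'   (default 1); lowering it makes lesions harder to detect and is the
#'   domain-shift dial used by the cross-dataset experiment.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(image_size = 128L, n_labeled = 40L,
                             n_unlabeled = 200L,
                             lesion_counts = list(MA = c(3, 8), HE = c(3, 6),
                                                  EX = c(3, 6), SE = c(1, 3)),
                             lesion_radii = list(MA = c(1, 3), HE = c(3, 8),
                                                 EX = c(5, 12), SE = c(5, 10)),
                             vessel_count = 6L, noise_sd = 0.02,
                             contrast = 1, seed = 1L) {
  stopifnot(image_size >= 32, n_labeled >= 0, n_unlabeled >= 0,
            all(names(lesion_counts) == LESIONS),
            all(names(lesion_radii) == LESIONS),
            all(unlist(lesion_counts) >= 0), all(unlist(lesion_radii) > 0),
            vessel_count >= 0, noise_sd >= 0, contrast > 0, contrast <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 lesion_counts = lesion_counts, lesion_radii = lesion_radii,
                 vessel_count = as.integer(vessel_count),
                 noise_sd = noise_sd, contrast = contrast,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Solid colors and blend opacities of the four lesion families.
LESION_COLOR <- list(MA = c(0.32, 0.05, 0.05), HE = c(0.26, 0.04, 0.04),
                     EX = c(0.98, 0.93, 0.50), SE = c(0.80, 0.78, 0.72))
LESION_ALPHA <- c(MA = 0.90, HE = 0.90, EX = 0.90, SE = 0.45)

#' Generate one synthetic fundus sample
#'
#' Consumes the caller's RNG stream (seed before calling for
#' reproducibility); [generate_pool()] and [generate_dataset()] handle
#' seeding themselves.  Lesions of the same family are placed without mutual
#' overlap (bounded retries; on placement failure the sample simply carries
#' fewer lesions and a message is emitted).  Masks record the exact painted
#' support, always inside the circular field-of-view.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `image` (`(S, S, 3)` array in `[0,1]`) and `masks`
#'   (named list of four `(S, S)` binary matrices).
#' @export
generate_sample <- function(cfg) {
  S <- cfg$image_size
  xm <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ym <- matrix(rep(seq_len(S), S), S, S)          # row index
  ctr <- (S + 1) / 2
  rfov <- 0.47 * S
  d2 <- (xm - ctr)^2 + (ym - ctr)^2
  fov <- d2 <= rfov^2

  img <- array(0, c(S, S, 3))
  shade <- 1 - 0.40 * d2 / rfov^2
  ph <- runif(2, 0, 2 * pi); fr <- runif(2, 1, 3)
  tex <- 0.05 * sin(2 * pi * fr[1] * xm / S + ph[1]) +
         0.05 * sin(2 * pi * fr[2] * ym / S + ph[2])
  base <- c(0.72, 0.40, 0.13)
  for (c in 1:3) {
    ch <- (base[c] * shade + tex) * fov
    img[, , c] <- pmin(pmax(ch, 0), 1)
  }

  # optic disc: bright ellipse at a random position inside the field
  ang <- runif(1, 0, 2 * pi)
  dc <- c(ctr + 0.55 * rfov * cos(ang), ctr + 0.55 * rfov * sin(ang))
  er <- c(0.11, 0.085) * S
  disc <- (((ym - dc[1]) / er[1])^2 + ((xm - dc[2]) / er[2])^2 <= 1) & fov
  dcol <- c(0.95, 0.86, 0.55)
  for (c in 1:3) img[, , c][disc] <- 0.2 * img[, , c][disc] + 0.8 * dcol[c]

  # vessels: dark curved strokes growing out of the optic disc
  if (cfg$vessel_count > 0) {
    ves <- matrix(FALSE, S, S)
    for (v in seq_len(cfg$vessel_count)) {
      pos <- dc
      dir <- runif(1, 0, 2 * pi)
      for (step in seq_len(S)) {
        dir <- dir + rnorm(1, 0, 0.25)
        pos <- pos + 1.5 * c(sin(dir), cos(dir))
        r0 <- round(pos[1]); c0 <- round(pos[2])
        if (r0 < 2 || r0 > S - 1 || c0 < 2 || c0 > S - 1) break
        if ((r0 - ctr)^2 + (c0 - ctr)^2 > rfov^2) break
        ves[r0 + (-1:0), c0 + (-1:0)] <- TRUE
      }
    }
    ves <- ves & fov
    for (c in 1:3) img[, , c][ves] <- img[, , c][ves] * 0.45
  }

  # lesions, largest families painted first so small ones stay visible
  masks <- sapply(LESIONS, function(L) matrix(0, S, S), simplify = FALSE)
  placed <- list()
  for (L in c("SE", "EX", "HE", "MA")) {
    cnt <- rint(cfg$lesion_counts[[L]][1], cfg$lesion_counts[[L]][2])
    if (cnt == 0) next
    for (k in seq_len(cnt)) {
      rad <- runif(1, cfg$lesion_radii[[L]][1], cfg$lesion_radii[[L]][2])
      ok <- FALSE
      for (try in 1:40) {
        a <- runif(1, 0, 2 * pi)
        rr <- sqrt(runif(1)) * max(rfov - rad - 3, 1)
        cen <- c(ctr + rr * sin(a), ctr + rr * cos(a))
        clash <- FALSE
        for (p in placed)
          if (p$L == L &&
              sum((p$cen - cen)^2) < (p$rad + rad + 3)^2) { clash <- TRUE; break }
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) { message("placement failed for one ", L, " lesion; skipped"); next }
      placed[[length(placed) + 1L]] <- list(L = L, cen = cen, rad = rad)
      nlobes <- switch(L, MA = 1L, HE = 3L, EX = 3L, SE = 2L)
      supp <- matrix(FALSE, S, S)
      for (b in seq_len(nlobes)) {
        off <- if (b == 1) c(0, 0) else runif(2, -0.5, 0.5) * rad
        br <- if (b == 1) rad else runif(1, 0.6, 0.9) * rad
        supp <- supp | ((ym - cen[1] - off[1])^2 + (xm - cen[2] - off[2])^2 <= br^2)
      }
      supp <- supp & fov
      a <- min(1, LESION_ALPHA[[L]] * cfg$contrast)
      col <- LESION_COLOR[[L]]
      for (c in 1:3)
        img[, , c][supp] <- (1 - a) * img[, , c][supp] + a * col[c]
      masks[[L]][supp] <- 1
    }
  }

  if (cfg$noise_sd > 0)
    img <- pmin(pmax(img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img)), 0), 1)
  list(image = img, masks = masks)
}

#' Generate an in-memory pool of synthetic samples
#'
#' Produces `n_labeled` samples with masks followed by `n_unlabeled`
#' image-only samples, all seeded by `cfg$seed` (same config, same pool).
#'
#' @param cfg A [synthetic_config()].
#' @param n_labeled,n_unlabeled Overrides of the config counts.
#' @return A `"fundus_pool"`: list with `ids`, `images` (list of arrays),
#'   `masks` (list; `NULL` where unlabeled), `labeled`, and `split`
#'   (`"train"` for labeled, `"unlabeled"` otherwise).
#' @export
generate_pool <- function(cfg, n_labeled = cfg$n_labeled,
                          n_unlabeled = cfg$n_unlabeled) {
  with_seed(cfg$seed, {
    n <- n_labeled + n_unlabeled
    ids <- sprintf("syn%04d", seq_len(n))
    images <- vector("list", n); masks <- vector("list", n)
    for (i in seq_len(n)) {
      s <- generate_sample(cfg)
      images[[i]] <- s$image
      masks[[i]] <- if (i <= n_labeled) s$masks else NULL
    }
    structure(list(ids = ids, images = images, masks = masks,
                   labeled = seq_len(n) <= n_labeled,
                   split = ifelse(seq_len(n) <= n_labeled, "train", "unlabeled")),
              class = "fundus_pool")
  })
}

pool_subset <- function(pool, idx) {
  structure(list(ids = pool$ids[idx], images = pool$images[idx],
                 masks = pool$masks[idx], labeled = pool$labeled[idx],
                 split = pool$split[idx]),
            class = "fundus_pool")
}

pool_size <- function(pool) length(pool$ids)

#' Assign train/val/test splits inside a labeled pool
#'
#' Same rounding rule and seeded shuffle as [split_manifest()].
#'
#' @param pool A `"fundus_pool"` of labeled samples.
#' @param fractions Train/val/test fractions.
#' @param seed Shuffle seed.
#' @return The pool with `split` reassigned.
#' @export
split_pool <- function(pool, fractions = c(0.70, 0.05, 0.25), seed = 1L) {
  stopifnot(all(pool$labeled))
  n <- pool_size(pool)
  sz <- split_sizes(n, fractions)
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(sz["train"])]] <- "train"
  split[perm[sz["train"] + seq_len(sz["val"])]] <- "val"
  split[perm[sz["train"] + sz["val"] + seq_len(sz["test"])]] <- "test"
  pool$split <- split
  pool
}

#' Write a synthetic dataset to disk
#'
#' Writes `n_labeled` labeled samples (image plus four `<id>_<lesion>.png`
#' masks) and `n_unlabeled` image-only samples under `out_dir` and returns
#' the corresponding manifest (`split = "unlabeled"` for the image-only
#' pool).
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Writable output directory.
#' @return A `"dataset_manifest"`.
#' @export
generate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pool <- generate_pool(cfg)
  rows <- lapply(seq_len(pool_size(pool)), function(i) {
    id <- pool$ids[i]
    ip <- file.path(out_dir, paste0(id, ".png"))
    save_image(pool$images[[i]], ip)
    masks <- rep(NA_character_, 4); names(masks) <- LESIONS
    if (pool$labeled[i]) {
      for (L in LESIONS) {
        mp <- file.path(out_dir, paste0(id, "_", L, ".png"))
        save_image(pool$masks[[i]][[L]], mp)
        masks[[L]] <- normalizePath(mp)
      }
    }
    data.frame(id = id, image_path = normalizePath(ip),
               MA_mask = masks[["MA"]], HE_mask = masks[["HE"]],
               EX_mask = masks[["EX"]], SE_mask = masks[["SE"]],
               labeled = pool$labeled[i], split = pool$split[i])
  })
  as_manifest(do.call(rbind, rows))
}

#' Load manifest entries into an in-memory pool
#'
#' @param m A `"dataset_manifest"`.
#' @param split Optional split filter (e.g. `"train"`, `"unlabeled"`).
#' @return A `"fundus_pool"`.
#' @export
load_pool <- function(m, split = NULL) {
  validate_manifest(m)
  if (!is.null(split)) m <- m[m$split %in% split, ]
  images <- lapply(m$image_path, load_image)
  masks <- lapply(seq_len(nrow(m)), function(i) {
    if (!m$labeled[i]) return(NULL)
    sapply(LESIONS, function(L) load_mask(m[[paste0(L, "_mask")]][i]),
           simplify = FALSE)
  })
  structure(list(ids = m$id, images = images, masks = masks,
                 labeled = m$labeled, split = m$split),
            class = "fundus_pool")
}
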