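test_that("crop_blank_borders finds the tight bounding box", {
  img <- array(0, c(40, 60, 3))
  img[11:30, 21:50, ] <- 0.8   # bright rectangle on black
  cr <- crop_blank_borders(img, 0.02)
  expect_equal(cr$box, c(11, 30, 21, 50))
  expect_equal(dim(cr$image), c(20, 30, 3))

  # no blank border: box is the full frame
  full <- array(0.5, c(8, 8, 3))
  expect_equal(crop_blank_borders(full)$box, c(1, 8, 1, 8))

  expect_error(crop_blank_borders(array(0, c(8, 8, 3))), "blank")
})

test_that("histogram equalization matches a hand-computed CDF mapping", {
  # two-level image {0.2, 0.8} in equal proportion: CDF(0.2)=0.5, CDF(0.8)=1;
  # mapping (cdf - cdf_min)/(1 - cdf_min) sends 0.2 -> 0 and 0.8 -> 1
  ch <- matrix(c(rep(0.2, 8), rep(0.8, 8)), 4, 4)
  img <- array(rep(ch, 3), c(4, 4, 3))
  eq <- equalize_histogram(img, fov_threshold = 0.01)
  expect_equal(sort(unique(as.vector(eq))), c(0, 1))
  expect_equal(eq[, , 1] == 1, ch == 0.8)

  # constant channel is left unchanged
  const <- array(0.4, c(4, 4, 3))
  expect_equal(equalize_histogram(const), const)

  # equalization flattens the within-field histogram of a natural image
  s <- generate_sample(tiny_syn_cfg(64, seed = 3))
  eq2 <- equalize_histogram(s$image)
  fov <- pmax(s$image[, , 1], s$image[, , 2], s$image[, , 3]) > 0.02
  binvar <- function(v) var(tabulate(pmin(floor(v * 32), 31) + 1, 32))
  expect_lt(binvar(eq2[, , 2][fov]), binvar(s$image[, , 2][fov]))
})

test_that("resize preserves aspect ratio, pads symmetrically, keeps masks binary", {
  cfg <- preprocess_config(target_size = 512)
  img <- array(runif(400 * 800 * 3), c(400, 800, 3))
  mask <- matrix(rbinom(400 * 800, 1, 0.2), 400, 800)
  rs <- resize_to_target(img, list(EX = mask), cfg)
  expect_equal(dim(rs$image), c(512, 512, 3))
  # 400x800 scales to 256x512 with 128 pad rows top and bottom
  expect_true(all(rs$image[1:128, , ] == cfg$pad_value))
  expect_true(all(rs$image[385:512, , ] == cfg$pad_value))
  expect_false(all(rs$image[129:384, , ] == 0))
  expect_setequal(unique(as.vector(rs$masks$EX)), c(0, 1))
  expect_true(all(rs$masks$EX[1:128, ] == 0))
  expect_true(all(range(rs$image) >= 0) && max(rs$image) <= 1)

  # integer downscale: no padding
  sq <- resize_to_target(array(runif(64 * 64 * 3), c(64, 64, 3)),
                         cfg = preprocess_config(target_size = 32))
  expect_equal(dim(sq$image), c(32, 32, 3))
})

test_that("full pipeline is near-idempotent and keeps masks aligned", {
  s <- generate_sample(tiny_syn_cfg(96, seed = 7))
  cfg <- preprocess_config(target_size = 96)
  p1 <- preprocess(s$image, s$masks, cfg)
  p2 <- preprocess(p1$image, p1$masks, cfg)
  expect_lt(mean(abs(p2$image - p1$image)), 0.05)

  # mask-image geometric consistency: lesion centroid maps through the
  # crop + scale + pad transform to the centroid of the transformed mask
  m <- s$masks$EX
  expect_gt(sum(m), 0)
  cen <- c(mean(which(m == 1, arr.ind = TRUE)[, 1]),
           mean(which(m == 1, arr.ind = TRUE)[, 2]))
  box <- p1$crop_box
  ch <- box[2] - box[1] + 1; cw <- box[4] - box[3] + 1
  scale <- 96 / max(ch, cw)
  top <- (96 - round(ch * scale)) %/% 2; left <- (96 - round(cw * scale)) %/% 2
  expected <- c((cen[1] - box[1] + 0.5) * scale + top,
                (cen[2] - box[3] + 0.5) * scale + left)
  mt <- p1$masks$EX
  got <- c(mean(which(mt == 1, arr.ind = TRUE)[, 1]),
           mean(which(mt == 1, arr.ind = TRUE)[, 2]))
  expect_lt(max(abs(got - expected)), 2)

  # unlabeled sample: image-only output
  p3 <- preprocess(s$image, NULL, cfg)
  expect_null(p3$masks)
  expect_equal(dim(p3$image), c(96, 96, 3))
})

test_that("preprocess_manifest writes processed files and a valid manifest", {
  dir <- withr::local_tempdir()
  write_sample_files(dir, "s1", size = 48)
  write_sample_files(dir, "s2", masks = character(), size = 48)
  m <- build_manifest(dir)
  out <- file.path(dir, "proc")
  m2 <- preprocess_manifest(m, out, preprocess_config(target_size = 32))
  expect_equal(nrow(m2), 2)
  img <- load_image(m2$image_path[m2$id == "s1"])
  expect_equal(dim(img), c(32, 32, 3))
  mk <- load_mask(m2$EX_mask[m2$id == "s1"])
  expect_setequal(unique(as.vector(mk)), c(0, 1))
})
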