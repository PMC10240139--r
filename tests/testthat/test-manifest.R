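test_that("split sizes follow the documented rounding rule", {
  expect_equal(split_sizes(1842, c(0.70, 0.05, 0.25)),
               c(train = 1290, val = 92, test = 460))
  expect_equal(split_sizes(10, c(1, 0, 0)), c(train = 10, val = 0, test = 0))
  # N = 7, fractions (0.5, 0.25, 0.25): ceiling(3.5)=4, round(1.75)=2, rest 1
  expect_equal(split_sizes(7, c(0.5, 0.25, 0.25)),
               c(train = 4, val = 2, test = 1))
  expect_equal(sum(split_sizes(7, c(0.5, 0.25, 0.25))), 7)
  expect_error(split_sizes(10, c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("split_manifest partitions deterministically", {
  n <- 57
  m <- as_manifest(data.frame(
    id = sprintf("im%03d", 1:n), image_path = sprintf("im%03d.png", 1:n),
    MA_mask = "a", HE_mask = "b", EX_mask = "c", SE_mask = "d"))
  s1 <- split_manifest(m, c(0.7, 0.1, 0.2), seed = 42)
  s2 <- split_manifest(m, c(0.7, 0.1, 0.2), seed = 42)
  expect_identical(s1$split, s2$split)
  # a partition: every id in exactly one split, union equals input
  expect_setequal(s1$id, m$id)
  expect_equal(as.vector(table(s1$split)[c("train", "val", "test")]),
               as.vector(split_sizes(n, c(0.7, 0.1, 0.2))))
  s3 <- split_manifest(m, c(0.7, 0.1, 0.2), seed = 43)
  expect_false(identical(s1$split, s3$split))
  # unlabeled entries are rejected
  m2 <- m; m2$MA_mask[1] <- NA; m2$labeled[1] <- FALSE; m2$split[1] <- "unlabeled"
  expect_error(split_manifest(as_manifest(m2)), "labeled")
})

test_that("build_manifest discovers images and masks by naming convention", {
  dir <- withr::local_tempdir()
  for (id in c("a1", "a2", "a3")) write_sample_files(dir, id)
  for (id in c("u1", "u2")) write_sample_files(dir, id, masks = character())
  m <- build_manifest(dir)
  expect_s3_class(m, "dataset_manifest")
  expect_equal(nrow(m), 5)
  expect_equal(sum(m$labeled), 3)
  expect_equal(m$id, sort(m$id))  # deterministic ordering
  expect_equal(m$split[!m$labeled], c("unlabeled", "unlabeled"))

  # 3 of 4 masks: labeled = FALSE plus a warning
  write_sample_files(dir, "p1", masks = c("MA", "HE", "EX"))
  expect_warning(m2 <- build_manifest(dir), "3 of 4")
  expect_false(m2$labeled[m2$id == "p1"])

  # mask without an image is a hard error
  dir2 <- withr::local_tempdir()
  s <- generate_sample(tiny_syn_cfg(32))
  save_image(s$masks$MA, file.path(dir2, "ghost_MA.png"))
  expect_error(build_manifest(dir2), "without a matching image")
})

test_that("manifest serialization round-trips losslessly (CSV and JSON)", {
  dir <- withr::local_tempdir()
  write_sample_files(dir, "x1")
  write_sample_files(dir, "x2", masks = character())
  m <- build_manifest(dir)
  for (ext in c("csv", "json")) {
    p <- file.path(dir, paste0("m.", ext))
    write_manifest(m, p)
    m2 <- read_manifest(p)
    expect_equal(as.data.frame(m2), as.data.frame(m), ignore_attr = TRUE)
  }
})

test_that("manifest invariants are enforced", {
  df <- data.frame(id = c("a", "a"), image_path = "x.png",
                   MA_mask = "m", HE_mask = "m", EX_mask = "m", SE_mask = "m")
  expect_error(as_manifest(df), "unique")
  df2 <- data.frame(id = "a", image_path = "x.png",
                    MA_mask = NA, HE_mask = "m", EX_mask = "m", SE_mask = "m",
                    labeled = TRUE, split = "train")
  expect_error(as_manifest(df2), "labeled")
  df3 <- data.frame(id = "a", image_path = "x.png",
                    MA_mask = "m", HE_mask = "m", EX_mask = "m", SE_mask = "m",
                    labeled = TRUE, split = "unlabeled")
  expect_error(as_manifest(df3), "unlabeled")
})

test_that("merging manifests pools entries and keeps ids unique", {
  mk <- function(pre, n) as_manifest(data.frame(
    id = sprintf("%s%05d", pre, 1:n), image_path = sprintf("%s%05d.png", pre, 1:n)))
  a <- mk("a", 100); b <- mk("b", 50)
  expect_equal(nrow(merge_manifests(a, b)), 150)
  expect_error(merge_manifests(a, a), "unique")
})
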