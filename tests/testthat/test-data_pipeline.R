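# Image/mask IO, resizing and tiling to the network grid, seeded splits.

make_pair_dirs <- function(n = 3, h = 40, w = 40) {
  root <- tempfile("pairs")
  dir.create(file.path(root, "images"), recursive = TRUE)
  dir.create(file.path(root, "masks"), recursive = TRUE)
  for (i in seq_len(n)) {
    img <- array(runif(h * w * 3), c(h, w, 3))
    msk <- matrix(as.numeric(runif(h * w) > 0.6), h, w)
    png::writePNG(img, file.path(root, "images", sprintf("s%02d.png", i)))
    png::writePNG(msk, file.path(root, "masks", sprintf("s%02d.png", i)))
  }
  root
}

test_that("load_image_mask_pairs pairs by stem, sorts and binarizes", {
  set.seed(41)
  root <- make_pair_dirs(3)
  samples <- load_image_mask_pairs(file.path(root, "images"),
                                   file.path(root, "masks"))
  expect_length(samples, 3)
  expect_equal(sapply(samples, `[[`, "image_id"), c("s01", "s02", "s03"))
  for (s in samples) expect_true(all(s$mask %in% c(0, 1)))
  # grayscale mask {0, 255} binarizes to {0, 1} (writePNG scales to [0,1])
  # unpaired file is an explicit error naming the stem
  png::writePNG(matrix(0.2, 4, 4), file.path(root, "images", "zzz.png"))
  expect_error(load_image_mask_pairs(file.path(root, "images"),
                                     file.path(root, "masks")), "zzz")
  # size mismatch between image and mask errors
  unlink(file.path(root, "images", "zzz.png"))
  png::writePNG(matrix(1, 10, 10), file.path(root, "masks", "s01.png"))
  expect_error(load_image_mask_pairs(file.path(root, "images"),
                                     file.path(root, "masks")), "mismatch")
})

test_that("preprocess_resize yields 256x256 with binary masks", {
  set.seed(42)
  s <- new_seg_sample_for_test(300, 400)
  r <- preprocess_resize(s, 256)
  expect_equal(dim(r$image), c(256, 256, 3))
  expect_equal(dim(r$mask), c(256, 256))
  expect_true(all(r$mask %in% c(0, 1)))
  # idempotent pixel dims at target size
  r2 <- preprocess_resize(r, 256)
  expect_equal(dim(r2$image), dim(r$image))
  # constant mask stays constant
  s1 <- s; s1$mask[] <- 1
  expect_true(all(preprocess_resize(s1, 256)$mask == 1))
})

test_that("preprocess_crop tiles cover every pixel and stitch back exactly", {
  set.seed(43)
  s <- new_seg_sample_for_test(512, 512)
  tiles <- preprocess_crop(s, 256, "tile")
  expect_length(tiles, 4)
  s2 <- new_seg_sample_for_test(300, 300)
  tiles2 <- preprocess_crop(s2, 256, "tile")
  expect_length(tiles2, 4)            # ceil(300/256)^2 with edge anchors
  # stitch-back: reassemble the mask from tiles (edge anchored)
  rec <- matrix(NA_real_, 300, 300)
  anchors <- c(0, 300 - 256)
  k <- 0
  for (r0 in anchors) for (c0 in anchors) {
    k <- k + 1
    rec[r0 + 1:256, c0 + 1:256] <- tiles2[[k]]$mask
  }
  expect_equal(rec, s2$mask)
  # center crop
  cc <- preprocess_crop(s2, 256, "center")
  expect_length(cc, 1)
  expect_equal(dim(cc[[1]]$mask), c(256, 256))
  # too-small input reflect-pads with a warning
  s3 <- new_seg_sample_for_test(100, 100)
  expect_warning(t3 <- preprocess_crop(s3, 256, "tile"), "padding")
  expect_equal(dim(t3[[1]]$mask), c(256, 256))
})

test_that("split_dataset reproduces the printed 9:1 arithmetic", {
  ids <- seq_len(2693)
  sp <- split_dataset(ids, split_spec(seed = 7))
  expect_length(sp$test, 269)
  expect_length(sp$train, 2693 - 269 - length(sp$val))
  expect_equal(length(sp$train) + length(sp$val), 2424)
  # round-number case: 100 -> 80/10/10
  sp100 <- split_dataset(seq_len(100), split_spec(seed = 1))
  expect_equal(sapply(sp100, length), c(train = 80, val = 10, test = 10))
  # disjoint and exhaustive
  all_ids <- c(sp100$train, sp100$val, sp100$test)
  expect_equal(sort(all_ids), 1:100)
  # determinism
  spA <- split_dataset(seq_len(57), split_spec(seed = 5))
  spB <- split_dataset(seq_len(57), split_spec(seed = 5))
  expect_identical(spA, spB)
  spC <- split_dataset(seq_len(57), split_spec(seed = 6))
  expect_false(identical(spA$test, spC$test))
  expect_error(split_dataset(1:5, split_spec()), "at least 10")
})

test_that("split manifest writes one row per sample", {
  root <- tempfile(); dir.create(root)
  sp <- split_dataset(sprintf("im%03d", 1:20), split_spec(seed = 2))
  path <- file.path(root, "split.csv")
  df <- write_split_manifest(sp, path)
  expect_equal(nrow(read.csv(path)), 20)
  expect_equal(sort(unique(df$partition)), c("test", "train", "val"))
})
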