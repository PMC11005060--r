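# Data pipeline: paired image/mask loading, normalization to the network's
# 256x256 input grid (resize for dermoscopy-style data, tiling crops for
# histology-style data), and seeded train/val/test splits.
#
# Images are PNG (the package's fixture format; single-channel masks with
# 8-bit values binarized at 127/255).

new_seg_sample <- function(image_id, image, mask,
                           provenance = c("resized", "cropped", "synthetic",
                                          "loaded")) {
  provenance <- match.arg(provenance)
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            all(dim(mask) == dim(image)[1:2]))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary after loading")
  structure(list(image_id = image_id, image = image, mask = mask,
                 provenance = provenance), class = "seg_sample")
}

#' @export
print.seg_sample <- function(x, ...) {
  cat(sprintf("<seg_sample %s: %dx%d, %.1f%% foreground, %s>\n", x$image_id,
              dim(x$image)[1], dim(x$image)[2], 100 * mean(x$mask),
              x$provenance))
  invisible(x)
}

read_image_rgb <- function(path) {
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop("unreadable image (only PNG is supported): ", path)
  im <- png::readPNG(path)
  if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
  if (dim(im)[3] == 4) im <- im[, , 1:3, drop = FALSE]
  im[, , 1:3, drop = FALSE]
}

read_mask_binary <- function(path) {
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop("unreadable mask (only PNG is supported): ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 127 / 255) * 1
}

#' Load matched image/mask pairs from a directory pair
#'
#' Files are matched by stem equality (filename without extension); any
#' unpaired file is an error naming the offenders.  Masks are binarized at
#' 127/255.  Samples are returned sorted by image id.
#'
#' @param image_dir directory of RGB PNG images.
#' @param mask_dir directory of single-channel PNG masks.
#' @return list of `seg_sample` objects.
#' @export
load_image_mask_pairs <- function(image_dir, mask_dir) {
  imgs <- sort(list.files(image_dir, pattern = "\\.png$", ignore.case = TRUE))
  msks <- sort(list.files(mask_dir, pattern = "\\.png$", ignore.case = TRUE))
  istem <- sub("\\.[^.]*$", "", imgs)
  mstem <- sub("\\.[^.]*$", "", msks)
  if (length(setdiff(istem, mstem)) || length(setdiff(mstem, istem)))
    stop("unpaired files: images without mask [",
         paste(setdiff(istem, mstem), collapse = ", "),
         "], masks without image [",
         paste(setdiff(mstem, istem), collapse = ", "), "]")
  lapply(seq_along(imgs), function(i) {
    im <- read_image_rgb(file.path(image_dir, imgs[i]))
    mk <- read_mask_binary(file.path(mask_dir, msks[match(istem[i], mstem)]))
    if (!all(dim(mk) == dim(im)[1:2]))
      stop(sprintf("size mismatch for '%s': image %dx%d vs mask %dx%d",
                   istem[i], dim(im)[1], dim(im)[2], dim(mk)[1], dim(mk)[2]))
    new_seg_sample(istem[i], im, mk, "loaded")
  })
}

# generic bilinear resize of a 2-D matrix (align_corners = FALSE)
resize_bilinear_2d <- function(m, th, tw) {
  sh <- nrow(m); sw <- ncol(m)
  map <- function(t, s) {
    src <- ((seq_len(t) - 0.5) * s / t) - 0.5
    i0 <- pmin(pmax(floor(src), 0), s - 1)
    fr <- pmin(pmax(src - i0, 0), 1)
    i1 <- pmin(i0 + 1, s - 1)
    list(i0 = i0 + 1, i1 = i1 + 1, fr = fr)
  }
  mh <- map(th, sh); mw <- map(tw, sw)
  a <- m[mh$i0, mw$i0, drop = FALSE] * (1 - mh$fr) +
       m[mh$i1, mw$i0, drop = FALSE] * mh$fr
  a * rep(1 - mw$fr, each = th) +
    (m[mh$i0, mw$i1, drop = FALSE] * (1 - mh$fr) +
     m[mh$i1, mw$i1, drop = FALSE] * mh$fr) * rep(mw$fr, each = th)
}

resize_nearest_2d <- function(m, th, tw) {
  ri <- pmin(pmax(ceiling((seq_len(th) - 0.5) * nrow(m) / th), 1), nrow(m))
  ci <- pmin(pmax(ceiling((seq_len(tw) - 0.5) * ncol(m) / tw), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Resize a sample to the network input size
#'
#' Image channels are bilinearly resized; the mask is nearest-neighbor
#' resized and re-binarized.
#'
#' @param sample a `seg_sample`.
#' @param size target square size (default 256).
#' @export
preprocess_resize <- function(sample, size = 256L) {
  im <- array(0, c(size, size, 3))
  for (ch in 1:3) im[, , ch] <- resize_bilinear_2d(sample$image[, , ch], size, size)
  mk <- (resize_nearest_2d(sample$mask, size, size) >= 0.5) * 1
  new_seg_sample(sample$image_id, im, mk, "resized")
}

#' Crop a sample into network-sized tiles
#'
#' `tile` mode produces non-overlapping `size` x `size` tiles covering the
#' image; remainder tiles at the right/bottom are anchored to the edge (so
#' they may overlap their neighbors but every pixel is retained).  `center`
#' mode returns the single central crop.  Inputs smaller than `size` are
#' reflect-padded to one tile, with a warning.
#'
#' @param sample a `seg_sample`.
#' @param size tile size (default 256).
#' @param mode `"tile"` or `"center"`.
#' @return list of `seg_sample` tiles named `<id>_r<row>_c<col>` (a
#'   single-element list in center mode).
#' @export
preprocess_crop <- function(sample, size = 256L, mode = c("tile", "center")) {
  mode <- match.arg(mode)
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  if (h < size || w < size) {
    warning(sprintf("input %dx%d smaller than %d; reflect-padding to one tile",
                    h, w, size))
    padref <- function(n, target) {
      if (n >= target) return(seq_len(target))
      idx <- seq_len(n)
      while (length(idx) < target)
        idx <- c(idx, rev(idx)[-1])  # reflect without repeating the edge
      idx[seq_len(target)]
    }
    ri <- padref(h, size); ci <- padref(w, size)
    im <- sample$image[ri, ci, , drop = FALSE]
    mk <- sample$mask[ri, ci, drop = FALSE]
    return(list(new_seg_sample(paste0(sample$image_id, "_r1_c1"), im, mk,
                               "cropped")))
  }
  if (mode == "center") {
    r0 <- floor((h - size) / 2); c0 <- floor((w - size) / 2)
    return(list(new_seg_sample(paste0(sample$image_id, "_r1_c1"),
                               sample$image[r0 + 1:size, c0 + 1:size, , drop = FALSE],
                               sample$mask[r0 + 1:size, c0 + 1:size, drop = FALSE],
                               "cropped")))
  }
  anchors <- function(n) {
    k <- ceiling(n / size)
    a <- (seq_len(k) - 1) * size
    a[k] <- n - size                    # anchor the last tile to the edge
    a
  }
  out <- list()
  for (r in seq_along(anchors(h))) {
    for (cc in seq_along(anchors(w))) {
      r0 <- anchors(h)[r]; c0 <- anchors(w)[cc]
      out[[length(out) + 1]] <-
        new_seg_sample(sprintf("%s_r%d_c%d", sample$image_id, r, cc),
                       sample$image[r0 + 1:size, c0 + 1:size, , drop = FALSE],
                       sample$mask[r0 + 1:size, c0 + 1:size, drop = FALSE],
                       "cropped")
    }
  }
  out
}

#' Split specification for train/validation/test partitioning
#'
#' The 9:1 train/test split assigns `floor(N/10)` samples to the test set
#' (remainder to training), matching the printed dermoscopy split
#' 2693 -> 2424 train / 269 test; the remaining samples are split 8:1 into
#' train/validation the same way (val = floor(n/9)).
#'
#' @param test_fraction fraction held out for testing (1/10).
#' @param val_fraction_of_train validation fraction of the non-test part
#'   (1/9, i.e. the 8:1 ratio).
#' @param seed integer seed; the split is fully determined by (inputs, seed).
#' @export
split_spec <- function(test_fraction = 1 / 10, val_fraction_of_train = 1 / 9,
                       seed = 1L) {
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Seeded dataset split into train/validation/test
#'
#' @param samples list of samples (or a vector of ids).
#' @param spec a [split_spec()].
#' @return list with elements `train`, `val`, `test` (disjoint, exhaustive),
#'   each a subset of `samples` in shuffled order.
#' @export
split_dataset <- function(samples, spec = split_spec()) {
  n <- length(samples)
  if (n < 10)
    stop("split_dataset needs at least 10 samples, got ", n)
  set.seed(spec$seed)
  ord <- sample.int(n)
  n_test <- floor(n * spec$test_fraction)
  n_rest <- n - n_test
  n_val <- floor(n_rest * spec$val_fraction_of_train)
  test_i <- ord[seq_len(n_test)]
  val_i <- ord[n_test + seq_len(n_val)]
  train_i <- ord[(n_test + n_val + 1):n]
  list(train = samples[train_i], val = samples[val_i], test = samples[test_i])
}

#' Write a split manifest as CSV (image_id, partition)
#'
#' @param split result of [split_dataset()] on `seg_sample` lists.
#' @param path output CSV path.
#' @export
write_split_manifest <- function(split, path) {
  ids <- function(part) vapply(split[[part]],
                               function(s) if (is.list(s)) s$image_id else as.character(s),
                               character(1))
  df <- rbind(data.frame(image_id = ids("train"), partition = "train"),
              data.frame(image_id = ids("val"), partition = "val"),
              data.frame(image_id = ids("test"), partition = "test"))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
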