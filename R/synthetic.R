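# Synthetic image/mask generator emulating the two target domains:
# histology-style tiles with many small bright nuclei (circular, elliptical
# or filamentous) on a dark textured background, and dermoscopy-style images
# with one large irregular lesion on a skin-toned background, optionally
# occluded by dark hair-like polylines that are drawn over the image but
# never enter the mask.  Everything is deterministic given the seed.

#' Configuration of the synthetic sample generator
#'
#' @param kind `"nuclei"` or `"lesion"`.
#' @param size square image size (default 256).
#' @param n_objects integer range (min, max) of nuclei per image.
#' @param radius range of nucleus radius / lesion base radius in pixels.
#' @param eccentricity range of ellipse axis ratios (1 = circle).
#' @param filament_fraction expected fraction of filamentous nuclei.
#' @param ellipse_fraction expected fraction of elliptical nuclei (the rest
#'   are circular).
#' @param fg_color,bg_color RGB ranges (2x3 matrices, rows = min/max) of
#'   foreground and background.
#' @param hair_artifacts draw hair-like occluders (lesion kind only)?
#' @param hair_count integer range of hairs per image.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param overlap allow nuclei to overlap (FALSE places them disjointly).
#' @param placement `"random"` or `"center"` (lesion centroid inside the
#'   central half of the image).
#' @param seed integer seed; fully determines the output.
#' @export
synthetic_config <- function(kind = c("nuclei", "lesion"), size = 256L,
                             n_objects = c(4L, 10L), radius = c(8, 22),
                             eccentricity = c(1.4, 2.8),
                             filament_fraction = 0.2, ellipse_fraction = 0.4,
                             fg_color = NULL, bg_color = NULL,
                             hair_artifacts = TRUE, hair_count = c(3L, 8L),
                             noise_sigma = 0.03, overlap = FALSE,
                             placement = c("random", "center"), seed = 1L) {
  kind <- match.arg(kind)
  placement <- match.arg(placement)
  if (is.null(fg_color))
    fg_color <- if (kind == "nuclei")
      rbind(c(0.55, 0.45, 0.75), c(0.85, 0.70, 0.95))  # bright violet nuclei
    else rbind(c(0.25, 0.15, 0.10), c(0.95, 0.75, 0.65))  # dark..light lesion
  if (is.null(bg_color))
    bg_color <- if (kind == "nuclei")
      rbind(c(0.05, 0.05, 0.10), c(0.25, 0.20, 0.30))   # dark stroma
    else rbind(c(0.75, 0.55, 0.45), c(0.90, 0.75, 0.65))  # skin tones
  stopifnot(diff(range(radius)) >= 0, radius[1] > 0,
            n_objects[1] >= 1, n_objects[2] >= n_objects[1])
  structure(list(kind = kind, size = as.integer(size),
                 n_objects = as.integer(n_objects), radius = radius,
                 eccentricity = eccentricity,
                 filament_fraction = filament_fraction,
                 ellipse_fraction = ellipse_fraction,
                 fg_color = fg_color, bg_color = bg_color,
                 hair_artifacts = isTRUE(hair_artifacts),
                 hair_count = as.integer(hair_count),
                 noise_sigma = noise_sigma, overlap = isTRUE(overlap),
                 placement = placement, seed = as.integer(seed)),
            class = "synthetic_config")
}

runif1 <- function(lo, hi = NULL) {
  if (is.null(hi)) { hi <- lo[2]; lo <- lo[1] }
  runif(1, lo, hi)
}

# integer draw from an inclusive range (safe for degenerate ranges, unlike
# sample(n:n, 1))
rint1 <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  as.integer(sample(range[1]:range[2], 1))
}

# smooth low-frequency texture field in [0,1]
texture_field <- function(size, cells = 16, amp = 1) {
  coarse <- matrix(runif(cells * cells), cells, cells)
  f <- resize_bilinear_2d(coarse, size, size)
  (f - min(f)) / max(1e-12, diff(range(f))) * amp
}

rand_color <- function(range) sapply(1:3, function(k) runif(1, range[1, k], range[2, k]))

disk_mask <- function(size, cx, cy, r) {
  x <- matrix(rep(seq_len(size), size), size)       # row coordinate
  y <- t(x)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

ellipse_mask <- function(size, cx, cy, r, ecc, theta) {
  x <- matrix(rep(seq_len(size), size), size) - cx
  y <- t(matrix(rep(seq_len(size), size), size)) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  a <- r * sqrt(ecc); b <- r / sqrt(ecc)
  (u / a)^2 + (v / b)^2 <= 1
}

# dilated random walk, constrained to stay within radius r of the seed
# point: filamentous nucleus
filament_mask <- function(size, cx, cy, r, width) {
  steps <- max(10L, as.integer(3 * r))
  ang <- runif(1, 0, 2 * pi)
  px <- cx; py <- cy
  m <- matrix(FALSE, size, size)
  half <- max(1, round(width / 2))
  for (s in seq_len(steps)) {
    ang <- ang + rnorm(1, 0, 0.35)
    if (sqrt((px - cx)^2 + (py - cy)^2) > r - 1)
      ang <- atan2(cy - py, cx - px) + rnorm(1, 0, 0.3)  # steer back inside
    px <- pmin(pmax(px + cos(ang), half + 1), size - half)
    py <- pmin(pmax(py + sin(ang), half + 1), size - half)
    ri <- round(px) + (-half:half); ci <- round(py) + (-half:half)
    m[ri, ci] <- TRUE
  }
  m
}

#' Generate one synthetic nuclei sample
#'
#' A dark textured background carrying `n_objects` bright nuclei (disks,
#' rotated ellipses or dilated-random-walk filaments, per the configured
#' class fractions) with per-object color jitter and additive Gaussian
#' noise.  The mask is the exact union of the rendered shapes (noise-free).
#' The realized shape classes are attached as attribute `"shapes"`.
#'
#' @param cfg a [synthetic_config()] with `kind = "nuclei"`.
#' @return a `seg_sample` with provenance `"synthetic"`.
#' @export
generate_nuclei_sample <- function(cfg = synthetic_config("nuclei")) {
  stopifnot(cfg$kind == "nuclei")
  set.seed(cfg$seed)
  sz <- cfg$size
  bg <- rand_color(cfg$bg_color)
  tex <- texture_field(sz, amp = 0.25)
  img <- array(0, c(sz, sz, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch] * (0.8 + tex)
  n <- rint1(cfg$n_objects)
  mask <- matrix(FALSE, sz, sz)
  shapes <- character(n)
  centers <- matrix(NA_real_, n, 2)
  reff_all <- numeric(n)
  margin <- 2
  for (i in seq_len(n)) {
    r <- runif1(cfg$radius)
    u <- runif(1)
    shapes[i] <- if (u < cfg$filament_fraction) "filament"
                 else if (u < cfg$filament_fraction + cfg$ellipse_fraction) "ellipse"
                 else "circle"
    ecc <- runif1(cfg$eccentricity)
    theta <- runif(1, 0, pi)
    fil_w <- runif(1, 2, 4)
    # placement uses each shape's effective (outer) radius so the
    # non-overlap contract yields exactly n connected components; a shape
    # that cannot be placed shrinks until it fits
    ok <- FALSE
    for (shrink in 1:12) {
      reff <- switch(shapes[i], circle = r, ellipse = r * sqrt(ecc),
                     filament = r + fil_w / 2)
      if (2 * (reff + 3) >= sz - 1) { r <- 0.8 * r; next }  # must fit canvas
      for (attempt in 1:200) {
        cx <- runif(1, reff + 3, sz - reff - 3)
        cy <- runif(1, reff + 3, sz - reff - 3)
        if (cfg$overlap || i == 1) { ok <- TRUE; break }
        d <- sqrt((centers[seq_len(i - 1), 1] - cx)^2 +
                  (centers[seq_len(i - 1), 2] - cy)^2)
        if (all(d > reff + reff_all[seq_len(i - 1)] + margin, na.rm = TRUE)) {
          ok <- TRUE; break
        }
      }
      if (ok) break
      r <- 0.8 * r
    }
    centers[i, ] <- c(cx, cy); reff_all[i] <- reff
    m <- switch(shapes[i],
                filament = filament_mask(sz, cx, cy, r, width = fil_w),
                ellipse = ellipse_mask(sz, cx, cy, r, ecc, theta),
                circle = disk_mask(sz, cx, cy, r))
    col <- rand_color(cfg$fg_color)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- col[ch] * (0.85 + 0.3 * tex[m])
      img[, , ch] <- pl
    }
    mask <- mask | m
  }
  img <- img + array(rnorm(sz * sz * 3, 0, cfg$noise_sigma), c(sz, sz, 3))
  img <- pmin(pmax(img, 0), 1)
  out <- new_seg_sample(sprintf("nuclei_seed%d", cfg$seed), img, mask * 1,
                        "synthetic")
  attr(out, "shapes") <- shapes[shapes != "skipped"]
  out
}

# irregular closed contour: radius as a truncated Fourier series of angle
lesion_radius_fn <- function(r0, nharm = 5) {
  a <- rnorm(nharm, 0, 0.12 / seq_len(nharm))
  ph <- runif(nharm, 0, 2 * pi)
  function(theta) {
    pert <- rowSums(sapply(seq_len(nharm),
                           function(k) a[k] * cos(k * theta + ph[k])))
    r0 * pmax(0.4, 1 + pert)
  }
}

draw_hairs <- function(img, n_hairs) {
  sz <- dim(img)[1]
  for (h in seq_len(n_hairs)) {
    px <- runif(1, 1, sz); py <- runif(1, 1, sz)
    ang <- runif(1, 0, 2 * pi)
    curv <- rnorm(1, 0, 0.02)
    len <- runif(1, 0.4, 1.2) * sz
    shade <- runif(1, 0.05, 0.25)
    alpha <- runif(1, 0.55, 0.9)
    for (s in seq_len(round(len))) {
      ang <- ang + curv
      px <- px + cos(ang); py <- py + sin(ang)
      if (px < 1 || px > sz || py < 1 || py > sz) break
      ri <- round(px); ci <- round(py)
      img[ri, ci, ] <- (1 - alpha) * img[ri, ci, ] + alpha * shade
    }
  }
  img
}

#' Generate one synthetic skin-lesion sample
#'
#' One large irregular blob (perturbed-radius polar contour), randomly
#' lighter or darker than the skin-toned background; optional dark hair-like
#' polylines are drawn over the image only -- they are occluders, not lesion,
#' so the mask ignores them.
#'
#' @param cfg a [synthetic_config()] with `kind = "lesion"`.
#' @return a `seg_sample` with provenance `"synthetic"`.
#' @export
generate_lesion_sample <- function(cfg = synthetic_config("lesion")) {
  stopifnot(cfg$kind == "lesion")
  set.seed(cfg$seed)
  sz <- cfg$size
  bg <- rand_color(cfg$bg_color)
  tex <- texture_field(sz, amp = 0.15)
  img <- array(0, c(sz, sz, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch] * (0.9 + tex)
  r0 <- runif(1, 0.18, 0.30) * sz
  if (cfg$placement == "center") {
    cx <- sz / 2 + runif(1, -0.1, 0.1) * sz
    cy <- sz / 2 + runif(1, -0.1, 0.1) * sz
  } else {
    cx <- runif(1, 0.3, 0.7) * sz
    cy <- runif(1, 0.3, 0.7) * sz
  }
  rf <- lesion_radius_fn(r0)
  x <- matrix(rep(seq_len(sz), sz), sz) - cx
  y <- t(matrix(rep(seq_len(sz), sz), sz)) - cy
  theta <- atan2(y, x)
  mask <- sqrt(x^2 + y^2) <= rf(as.numeric(theta))
  col <- rand_color(cfg$fg_color)
  edge <- 0.85 + 0.3 * tex                 # soft internal structure
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask] <- col[ch] * edge[mask]
    img[, , ch] <- pl
  }
  if (cfg$hair_artifacts) {
    n_hairs <- rint1(cfg$hair_count)
    img <- draw_hairs(img, n_hairs)
  }
  img <- img + array(rnorm(sz * sz * 3, 0, cfg$noise_sigma), c(sz, sz, 3))
  img <- pmin(pmax(img, 0), 1)
  new_seg_sample(sprintf("lesion_seed%d", cfg$seed), img, mask * 1,
                 "synthetic")
}

#' Generate a synthetic sample of the configured kind
#'
#' @param cfg a [synthetic_config()].
#' @export
generate_sample <- function(cfg) {
  if (cfg$kind == "nuclei") generate_nuclei_sample(cfg)
  else generate_lesion_sample(cfg)
}

#' Write a synthetic dataset to an image/mask directory pair
#'
#' Writes `n` PNG image/mask pairs under `out_dir/images` and
#' `out_dir/masks` (consumable by [load_image_mask_pairs()]) plus a manifest
#' CSV.  Sample i is generated with seed `cfg$seed + i - 1`, so a dataset
#' can be extended without changing earlier samples.
#'
#' @param cfg a [synthetic_config()].
#' @param n number of samples (>= 1).
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest (image_id, kind, seed, image, mask),
#'   invisibly; also written as `manifest.csv`.
#' @export
generate_dataset <- function(cfg, n, out_dir) {
  stopifnot(n >= 1)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg; ci$seed <- cfg$seed + i - 1L
    s <- generate_sample(ci)
    id <- sprintf("%s_%04d", cfg$kind, i)
    ipath <- file.path(img_dir, paste0(id, ".png"))
    mpath <- file.path(msk_dir, paste0(id, ".png"))
    png::writePNG(s$image, ipath)
    png::writePNG(s$mask, mpath)
    rows[[i]] <- data.frame(image_id = id, kind = cfg$kind, seed = ci$seed,
                            image = ipath, mask = mpath,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Generate an in-memory list of synthetic samples
#'
#' Convenience wrapper used by tests and the training examples; sample i
#' uses seed `cfg$seed + i - 1` like [generate_dataset()].
#'
#' @param cfg a [synthetic_config()].
#' @param n number of samples.
#' @export
generate_samples <- function(cfg, n) {
  lapply(seq_len(n), function(i) {
    ci <- cfg; ci$seed <- cfg$seed + i - 1L
    generate_sample(ci)
  })
}
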