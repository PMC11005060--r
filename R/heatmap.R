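# Activation heatmaps: channel-mean activation of a tapped layer, min-max
# normalized, colormapped and written as a PNG at input resolution.

# registered tap names for a model
heatmap_taps <- function(model) {
  taps <- "head"
  for (k in 1:5) {
    if (!is.null(model$decoder[[k]]$mfe)) taps <- c(taps, sprintf("mfe_%d", k))
    if (!is.null(model$decoder[[k]]$da)) taps <- c(taps, sprintf("da_%d", k))
  }
  sort(taps)
}

#' Export an activation heatmap of a tapped layer
#'
#' Runs a forward pass on one sample, takes the channel-mean activation of
#' the named tap (MFE outputs `mfe_*`, DA outputs `da_*` at the levels the
#' model carries them, or `head`, the probability map produced by the final
#' 1x1 convolution), min-max normalizes it to `[0, 1]` (a constant
#' map normalizes to 0), bilinearly upscales to the input resolution,
#' applies a viridis colormap and writes a PNG.
#'
#' @param model an `mdunet_model`.
#' @param sample a `seg_sample` (or a (1,3,H,W) array).
#' @param layer_name one of the registered taps (see error message).
#' @param out_path output PNG path.
#' @return the normalized heatmap matrix (input resolution), invisibly.
#' @export
export_activation_heatmap <- function(model, sample, layer_name, out_path) {
  taps_avail <- heatmap_taps(model)
  if (!layer_name %in% taps_avail)
    stop("unknown layer '", layer_name, "'; registered taps: ",
         paste(taps_avail, collapse = ", "))
  x <- if (inherits(sample, "seg_sample")) {
    d <- dim(sample$image)
    array(sample$image, c(d[1], d[2], 3, 1))
  } else to_internal(sample)
  taps <- new.env(parent = emptyenv())
  invisible(ag_val(model_forward_ag(model, ag_var(x), taps = taps)))
  act <- taps[[layer_name]]                    # (H, W, C, 1)
  da <- dim(act)
  hm <- matrix(rowMeans(matrix(act, da[1] * da[2])), da[1], da[2])
  rng <- range(hm)
  hm <- if (diff(rng) > 0) (hm - rng[1]) / diff(rng) else hm * 0
  sz <- model$config$input_size
  if (!all(dim(hm) == sz)) hm <- resize_bilinear_2d(hm, sz, sz)
  pal <- hcl.colors(256, "viridis")
  rgb <- col2rgb(pal[pmin(255, floor(hm * 255)) + 1]) / 255
  img <- array(0, c(sz, sz, 3))
  img[, , 1] <- rgb[1, ]; img[, , 2] <- rgb[2, ]; img[, , 3] <- rgb[3, ]
  png::writePNG(img, out_path)
  invisible(hm)
}
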