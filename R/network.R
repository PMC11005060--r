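# Assembly of the five-level encoder-decoder from Token-MLP stages, DA skip
# gates and MFE decoder modules; ablation variants; forward pass; weight
# checkpointing.
#
# Wiring per level k (resolutions r_k = input_size / 2^(k-1)):
#   encoder k: tokenize-project (3x3) to width w_k, shifted-MLP block, skip
#   tap, 2x2 max-pool.  The bottleneck is the pooled stage-5 output.
#   decoder k (k = 5..1): MFE on the incoming stream (width w_k), bilinear
#   2x upsample to r_k giving the gate signal g, DA gate over (skip_k, g)
#   (plain skip when DA is off), fusion (add or concat), tokenize-project to
#   w_{k-1} (w_0 := w_1), shifted-MLP block.  Head: 1x1 conv + sigmoid.

#' Model configuration
#'
#' Declarative description of the architecture; the single source of truth
#' for building, profiling and serializing models.  Defaults are the
#' calibrated reference configuration.
#'
#' @param in_channels input image channels (3).
#' @param out_channels output mask channels (1).
#' @param input_size square input resolution; must be divisible by 2^5.
#' @param stage_widths integer vector of 5 encoder widths, mirrored by the
#'   decoder.
#' @param pool_first logical vector of 5: stages with `TRUE` downsample
#'   before their tokenize-project + shifted-MLP block (the stride-2
#'   patch-embedding arrangement), stages with `FALSE` run the block at the
#'   incoming resolution and pool afterwards.  Stage 5 must be `FALSE` so
#'   the deepest skip stays distinct from the bottleneck.  Parameter counts
#'   are unaffected; FLOPs of a `TRUE` stage drop fourfold.
#' @param shift_size,n_partitions axial-shift parameters of the token MLPs.
#' @param hidden_ratio token-MLP hidden width as a multiple of the stage
#'   width.
#' @param use_da gate skips with depthwise attention?
#' @param use_mfe insert the multi-branch feature-extraction module before
#'   each decoder level?
#' @param se_ratio squeeze-and-excitation reduction ratio inside MFE.
#' @param fusion_mode skip fusion: `"add"` or `"concat"`.
#' @param da_levels,mfe_levels integer subsets of 1:5 naming the levels that
#'   carry a DA gate / an MFE module (level 1 is the finest).
#' @param da_int_mult F_int of the DA gate as a multiple of the skip width.
#' @param da_gate_pool number of 2x average-poolings before the DA gate
#'   convolutions.
#' @param seed seed used for weight initialization at build time.
#' @return a `model_config` list.
#' @export
model_config <- function(in_channels = 3L, out_channels = 1L,
                         input_size = 256L,
                         stage_widths = c(5L, 8L, 40L, 52L, 136L),
                         pool_first = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                         shift_size = 5L, n_partitions = 5L,
                         hidden_ratio = 1,
                         use_da = TRUE, use_mfe = TRUE,
                         se_ratio = 4L, fusion_mode = c("add", "concat"),
                         da_levels = c(1L, 2L, 3L, 5L),
                         mfe_levels = c(1L, 2L, 4L),
                         da_int_mult = 6.25, da_gate_pool = 2L,
                         seed = 42L) {
  fusion_mode <- match.arg(fusion_mode)
  if (length(stage_widths) != 5)
    stop("stage_widths: exactly 5 encoder widths are required, got ",
         length(stage_widths))
  if (any(stage_widths < 1))
    stop("stage_widths: widths must be positive integers")
  if (input_size %% 32 != 0)
    stop("input_size: must be divisible by 2^5 = 32, got ", input_size)
  if (length(pool_first) != 5 || !is.logical(pool_first))
    stop("pool_first: a logical vector of length 5 is required")
  if (pool_first[5])
    stop("pool_first: stage 5 must pool after its block (FALSE)")
  cfg <- list(in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              input_size = as.integer(input_size),
              stage_widths = as.integer(stage_widths),
              pool_first = as.logical(pool_first),
              shift_size = as.integer(shift_size),
              n_partitions = as.integer(n_partitions),
              hidden_ratio = as.numeric(hidden_ratio),
              use_da = isTRUE(use_da), use_mfe = isTRUE(use_mfe),
              se_ratio = as.integer(se_ratio),
              fusion_mode = fusion_mode,
              da_levels = as.integer(sort(da_levels)),
              mfe_levels = as.integer(sort(mfe_levels)),
              da_int_mult = as.numeric(da_int_mult),
              da_gate_pool = as.integer(da_gate_pool),
              seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

#' Read / write a model configuration (YAML or JSON)
#'
#' Round-trips all fields losslessly.
#'
#' @param cfg a `model_config`.
#' @param path file path ending in .yaml, .yml or .json.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  lst <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(model_config, lst)
}

# decoder output width at level k: mirrors the encoder level it feeds
decoder_out_width <- function(widths, k) if (k >= 2) widths[k - 1] else widths[1]

#' Build the segmentation network from a configuration
#'
#' @param config a [model_config()].
#' @param seed overrides `config$seed` for weight initialization.
#' @return an object of class `mdunet_model`.
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed %||% config$seed)
  w <- config$stage_widths
  enc <- list()
  cin <- config$in_channels
  for (k in 1:5) {
    enc[[k]] <- list(
      proj = layer_conv2d(sprintf("enc%d.proj", k), cin, w[k], 3),
      blk = new_shifted_mlp_block(w[k], config$shift_size,
                                  config$n_partitions, config$hidden_ratio,
                                  name = sprintf("enc%d.blk", k)))
    cin <- w[k]
  }
  dec <- list()
  for (k in 5:1) {
    wout <- decoder_out_width(w, k)
    has_mfe <- config$use_mfe && (k %in% config$mfe_levels)
    has_da <- config$use_da && (k %in% config$da_levels)
    fuse_cin <- if (config$fusion_mode == "concat") 2L * w[k] else w[k]
    dec[[k]] <- list(
      mfe = if (has_mfe) new_mfe_module(w[k], config$se_ratio,
                                        name = sprintf("dec%d.mfe", k)),
      da = if (has_da) new_da_block(w[k], w[k], config$da_int_mult,
                                    config$da_gate_pool,
                                    name = sprintf("dec%d.da", k)),
      proj = layer_conv2d(sprintf("dec%d.proj", k), fuse_cin, wout, 3),
      blk = new_shifted_mlp_block(wout, config$shift_size,
                                  config$n_partitions, config$hidden_ratio,
                                  name = sprintf("dec%d.blk", k)))
  }
  head <- layer_conv2d("head", w[1], config$out_channels, 1)
  model <- structure(list(config = config, encoder = enc, decoder = dec,
                          head = head),
                     class = "mdunet_model")
  model
}

# list of all parameter nodes of a model
model_params <- function(model) {
  mods <- list(model$head)
  for (s in model$encoder) mods <- c(mods, list(s$proj, s$blk))
  for (s in model$decoder) {
    if (!is.null(s$mfe)) mods <- c(mods, list(s$mfe))
    if (!is.null(s$da)) mods <- c(mods, list(s$da))
    mods <- c(mods, list(s$proj, s$blk))
  }
  out <- list()
  for (m in mods) out <- c(out, collect_params(m))
  out
}

#' Count trainable parameters
#'
#' @param model an `mdunet_model`.
#' @return parameter count in millions (full precision; round to 2 decimals
#'   for reporting).
#' @export
count_parameters <- function(model) {
  sum(vapply(model_params(model), function(p) length(p$val), numeric(1))) / 1e6
}

# graph-building forward over ag nodes in the INTERNAL (H, W, C, B) layout;
# taps optionally collects named activations (an environment)
model_forward_ag <- function(model, x, taps = NULL) {
  cfg <- model$config
  skips <- vector("list", 5)
  h <- x
  for (k in 1:5) {
    s <- model$encoder[[k]]
    if (cfg$pool_first[k]) h <- ag_maxpool2(h)
    h <- s$blk$forward(s$proj$forward(h))
    skips[[k]] <- h
    if (!cfg$pool_first[k]) h <- ag_maxpool2(h)
  }
  for (k in 5:1) {
    s <- model$decoder[[k]]
    g <- h
    target <- dim(ag_val(skips[[k]]))[1]
    while (dim(ag_val(g))[1] < target) g <- ag_upsample2(g)
    if (!is.null(s$mfe)) {
      g <- s$mfe$forward(g)
      if (!is.null(taps)) taps[[sprintf("mfe_%d", k)]] <- ag_val(g)
    }
    fused_skip <- if (!is.null(s$da)) s$da$forward(skips[[k]], g) else skips[[k]]
    if (!is.null(taps) && !is.null(s$da)) taps[[sprintf("da_%d", k)]] <- ag_val(fused_skip)
    f <- if (cfg$fusion_mode == "add") ag_add(g, fused_skip)
         else ag_concat_ch(g, fused_skip)
    h <- s$blk$forward(s$proj$forward(f))
  }
  while (dim(ag_val(h))[1] < cfg$input_size) h <- ag_upsample2(h)
  out <- ag_sigmoid(model$head$forward(h))
  # the "head" tap is the activation of the final 1x1 convolution, i.e. the
  # probability map it produces
  if (!is.null(taps)) taps[["head"]] <- ag_val(out)
  out
}

#' Forward pass: images to probability maps
#'
#' @param model an `mdunet_model`.
#' @param batch array (B, 3, H, W) with values in `[0, 1]`, H = W =
#'   `config$input_size`.
#' @return array (B, 1, H, W) of probabilities, strictly in (0, 1);
#'   deterministic.
#' @export
forward_pass <- function(model, batch) {
  batch <- feature_map(batch)
  d <- dim(batch)
  sz <- model$config$input_size
  if (d[2] != model$config$in_channels)
    stop(sprintf("forward_pass: expected %d input channels, got %d",
                 model$config$in_channels, d[2]))
  if (d[3] != sz || d[4] != sz)
    stop(sprintf(paste0("forward_pass: expected %dx%d input, got %dx%d; ",
                        "resize or crop images to %dx%d first (see ",
                        "preprocess_resize / preprocess_crop)"),
                 sz, sz, d[3], d[4], sz, sz))
  to_public(ag_val(model_forward_ag(model, ag_var(to_internal(batch)))))
}

#' Build a named ablation variant
#'
#' Variants toggle the DA gate and MFE module on the reference configuration:
#' `baseline` (neither), `baseline_da`, `baseline_mfe`, `full` (both).
#'
#' @param name one of `"baseline"`, `"baseline_da"`, `"baseline_mfe"`,
#'   `"full"`.
#' @param config base configuration (default: the reference
#'   [model_config()]).
#' @param seed weight-init seed override.
#' @return an `mdunet_model`.
#' @export
build_variant <- function(name, config = model_config(), seed = NULL) {
  toggles <- list(baseline = c(FALSE, FALSE), baseline_da = c(TRUE, FALSE),
                  baseline_mfe = c(FALSE, TRUE), full = c(TRUE, TRUE))
  if (!name %in% names(toggles))
    stop("unknown variant '", name, "'; valid names: ",
         paste(names(toggles), collapse = ", "))
  config$use_da <- toggles[[name]][1]
  config$use_mfe <- toggles[[name]][2]
  build_model(config, seed = seed)
}

#' @export
print.mdunet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("MD-UNet model: widths [%s], DA=%s, MFE=%s, fusion=%s\n",
              paste(cfg$stage_widths, collapse = ", "),
              cfg$use_da, cfg$use_mfe, cfg$fusion_mode))
  cat(sprintf("  %.2f M parameters\n", count_parameters(x)))
  invisible(x)
}

# deterministic checksum of all parameter values (diagnostics / tests)
param_checksum <- function(model) {
  ps <- model_params(model)
  v <- unlist(lapply(ps[order(names(ps))], function(p) as.numeric(p$val)))
  sum(v * seq_along(v) %% 97)
}

#' Save / load a model checkpoint (weights + embedded config)
#'
#' @param model an `mdunet_model`.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  ps <- model_params(model)
  saveRDS(list(config = model$config,
               params = lapply(ps, function(p) p$val)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  ps <- model_params(model)
  stopifnot(identical(sort(names(ps)), sort(names(ck$params))))
  for (nm in names(ps)) ps[[nm]]$val <- ck$params[[nm]]
  model
}
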