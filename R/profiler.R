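# Analytic complexity profiling.
#
# Counting convention (reported as "MAC = 1 FLOP"): a convolution at output
# size HxW costs H*W*cout*(cin/groups*kh*kw + bias) multiply-accumulates; a
# fully-connected layer (fin+bias)*fout; elementwise operations cost one
# FLOP per element (layer norm 2 per element, bilinear upsampling 3 per
# output element); pure data movement (axial shifts, concatenation) is free.
# The runtime tape meters the same convention op by op, which the tests use
# as an independent cross-check of this closed-form walk.

prof_row <- function(name, params, flops) {
  data.frame(name = name, params = params, flops = flops,
             stringsAsFactors = FALSE)
}

prof_conv <- function(name, cin, cout, kh, kw, r, groups = 1, bias = TRUE) {
  p <- kh * kw * (cin / groups) * cout + bias * cout
  f <- r * r * cout * (kh * kw * cin / groups + bias)
  prof_row(name, p, f)
}

# shifted-MLP block at resolution r
prof_block <- function(name, E, hidden_ratio, r) {
  H <- max(1, round(E * hidden_ratio))
  rows <- rbind(
    prof_row(paste0(name, ".ln"), 2 * E, 2 * E * r * r),
    prof_conv(paste0(name, ".fc1"), E, H, 1, 1, r),
    prof_conv(paste0(name, ".dw"), H, H, 3, 3, r, groups = H),
    prof_row(paste0(name, ".gelu"), 0, H * r * r),
    prof_conv(paste0(name, ".fc2"), H, E, 1, 1, r),
    prof_row(paste0(name, ".resid"), 0, E * r * r))
  rows
}

prof_se <- function(name, C, ratio, r) {
  Cb <- max(1, C %/% ratio)
  rbind(
    prof_row(paste0(name, ".gap"), 0, C * r * r),
    prof_row(paste0(name, ".fc1"), (C + 1) * Cb, (C + 1) * Cb + Cb),
    prof_row(paste0(name, ".fc2"), (Cb + 1) * C, (Cb + 1) * C + C),
    prof_row(paste0(name, ".scale"), 0, C * r * r))
}

prof_mfe <- function(name, C, se_ratio, r) {
  rows <- rbind(
    prof_conv(paste0(name, ".w13"), C, C, 1, 3, r),
    prof_conv(paste0(name, ".w31"), C, C, 3, 1, r),
    prof_conv(paste0(name, ".w15"), C, C, 1, 5, r),
    prof_conv(paste0(name, ".w51"), C, C, 5, 1, r),
    prof_conv(paste0(name, ".w11"), C, C, 1, 1, r),
    prof_se(paste0(name, ".se1"), C, se_ratio, r),
    prof_se(paste0(name, ".se2"), C, se_ratio, r),
    prof_se(paste0(name, ".se3"), C, se_ratio, r),
    prof_se(paste0(name, ".se4"), C, se_ratio, r),
    prof_conv(paste0(name, ".p1"), C, C, 1, 1, r),
    prof_conv(paste0(name, ".p2"), C, C, 1, 1, r),
    prof_conv(paste0(name, ".p3"), C, C, 1, 1, r),
    prof_conv(paste0(name, ".p4"), C, C, 1, 1, r),
    prof_conv(paste0(name, ".dw1"), C, C, 3, 3, r, groups = C),
    prof_conv(paste0(name, ".dw2"), C, C, 3, 3, r, groups = C),
    prof_conv(paste0(name, ".f1"), C, C, 1, 1, r),
    prof_conv(paste0(name, ".f2"), C, C, 1, 1, r),
    # adds (2), relus (2), sigmoids (2), gate products (2), x product (1)
    prof_row(paste0(name, ".elemwise"), 0, 8 * C * r * r))
  rows
}

prof_da <- function(name, F_l, F_g, int_mult, gate_pool, r) {
  F_int <- round(F_l * int_mult)
  rg <- r / 2^gate_pool
  rows <- prof_row(paste0(name, ".pool"), 0,
                   if (gate_pool > 0)
                     (F_l + F_g) * sum((r / 2^(seq_len(gate_pool) - 1))^2)
                   else 0)
  rows <- rbind(rows,
    prof_conv(paste0(name, ".wx1"), F_l, F_int, 1, 1, rg),
    prof_conv(paste0(name, ".wx3"), F_int, F_int, 3, 3, rg, groups = F_int),
    prof_conv(paste0(name, ".wg1"), F_g, F_int, 1, 1, rg),
    prof_conv(paste0(name, ".wg3"), F_int, F_int, 3, 3, rg, groups = F_int),
    prof_row(paste0(name, ".addrelu"), 0, 2 * F_int * rg * rg),
    prof_conv(paste0(name, ".w3"), F_int, F_int, 3, 3, rg, groups = F_int))
  a_ch <- F_int
  if (F_int != F_l) {
    rows <- rbind(rows, prof_conv(paste0(name, ".proj"), F_int, F_l, 1, 1, rg))
    a_ch <- F_l
  }
  rows <- rbind(rows, prof_row(paste0(name, ".sigmoid"), 0, a_ch * rg * rg))
  if (gate_pool > 0) {
    up <- sum(sapply(seq_len(gate_pool), function(i) 3 * a_ch * (rg * 2^i)^2))
    rows <- rbind(rows, prof_row(paste0(name, ".upsample"), 0, up))
  }
  if (F_g != F_l)
    rows <- rbind(rows, prof_conv(paste0(name, ".adapt"), F_g, F_l, 1, 1, r))
  rows <- rbind(rows, prof_row(paste0(name, ".product"), 0, 2 * F_l * r * r))
  rows
}

#' Per-layer complexity breakdown of a configuration
#'
#' @param config a [model_config()].
#' @param input_size square input resolution (defaults to the config's).
#' @return data.frame with columns name, params, flops (single forward pass,
#'   batch 1, MAC = 1 FLOP convention).
#' @export
profile_layers <- function(config, input_size = config$input_size) {
  w <- config$stage_widths
  rows <- NULL
  cin <- config$in_channels
  r <- input_size
  skip_res <- numeric(5)
  for (k in 1:5) {
    if (config$pool_first[k]) {
      rows <- rbind(rows, prof_row(sprintf("enc%d.pool", k), 0, cin * r * r))
      r <- r / 2
    }
    rows <- rbind(rows,
      prof_conv(sprintf("enc%d.proj", k), cin, w[k], 3, 3, r),
      prof_block(sprintf("enc%d.blk", k), w[k], config$hidden_ratio, r))
    skip_res[k] <- r
    if (!config$pool_first[k]) {
      rows <- rbind(rows, prof_row(sprintf("enc%d.pool", k), 0, w[k] * r * r))
      r <- r / 2
    }
    cin <- w[k]
  }
  for (k in 5:1) {
    rs <- r                           # incoming stream resolution
    r <- skip_res[k]                  # fusion resolution at this level
    wout <- decoder_out_width(w, k)
    while (rs < r) {
      rs <- rs * 2
      rows <- rbind(rows, prof_row(sprintf("dec%d.up", k), 0,
                                   3 * w[k] * rs * rs))
    }
    if (config$use_mfe && (k %in% config$mfe_levels))
      rows <- rbind(rows, prof_mfe(sprintf("dec%d.mfe", k), w[k],
                                   config$se_ratio, r))
    if (config$use_da && (k %in% config$da_levels))
      rows <- rbind(rows, prof_da(sprintf("dec%d.da", k), w[k], w[k],
                                  config$da_int_mult, config$da_gate_pool, r))
    fuse_cin <- if (config$fusion_mode == "concat") 2 * w[k] else w[k]
    if (config$fusion_mode == "add")
      rows <- rbind(rows, prof_row(sprintf("dec%d.fuse", k), 0, w[k] * r * r))
    rows <- rbind(rows,
      prof_conv(sprintf("dec%d.proj", k), fuse_cin, wout, 3, 3, r),
      prof_block(sprintf("dec%d.blk", k), wout, config$hidden_ratio, r))
  }
  while (r < input_size) {
    r <- r * 2
    rows <- rbind(rows, prof_row("final.up", 0, 3 * w[1] * r * r))
  }
  rows <- rbind(rows,
    prof_conv("head", w[1], config$out_channels, 1, 1, input_size),
    prof_row("head.sigmoid", 0, config$out_channels * input_size^2))
  rows
}

#' Analytic FLOP count of a model
#'
#' Closed-form per-layer count for one forward pass on a single
#' `3 x input_size x input_size` image under the MAC = 1 FLOP convention
#' (see `profile_layers` for the convention's details).
#'
#' @param model an `mdunet_model` (or a `model_config`).
#' @param input_size square input resolution.
#' @return total GFLOPs (full precision; round to 3 decimals for reporting).
#' @export
count_flops <- function(model, input_size = NULL) {
  cfg <- if (inherits(model, "model_config")) model else model$config
  sum(profile_layers(cfg, input_size %||% cfg$input_size)$flops) / 1e9
}

#' Complexity report: parameters and FLOPs with per-layer breakdown
#'
#' @param model an `mdunet_model`.
#' @param input_size square input resolution.
#' @return a `complexity_report`: list with `params_millions`, `gflops`,
#'   `convention`, and the per-layer `breakdown` data.frame.
#' @export
complexity_report <- function(model, input_size = NULL) {
  cfg <- if (inherits(model, "model_config")) model else model$config
  br <- profile_layers(cfg, input_size %||% cfg$input_size)
  rep <- list(params_millions = sum(br$params) / 1e6,
              gflops = sum(br$flops) / 1e9,
              convention = "1 multiply-accumulate = 1 FLOP; elementwise ops counted once per element",
              breakdown = br)
  if (inherits(model, "mdunet_model")) {
    built <- count_parameters(model)
    if (abs(built - rep$params_millions) > 1e-9)
      stop(sprintf("profiler drift: analytic %.6f M vs built %.6f M params",
                   rep$params_millions, built))
  }
  class(rep) <- "complexity_report"
  rep
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("Params: %.2f M   FLOPs: %.3f G  (%s)\n",
              x$params_millions, x$gflops, x$convention))
  agg <- stats::aggregate(cbind(params, flops) ~ top,
                          data = transform(x$breakdown,
                                           top = sub("\\..*$", "", name)),
                          FUN = sum)
  agg <- agg[order(-agg$params), ]
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-12s %10d params %12.0f flops\n", agg$top[i],
                agg$params[i], agg$flops[i]))
  invisible(x)
}

#' Runtime (hook-based) FLOP measurement
#'
#' Runs a real forward pass with op-level metering on the tape; an
#' independent check of the analytic counter.
#'
#' @param model an `mdunet_model`.
#' @param batch input array (defaults to a zero image at the config size).
#' @return measured GFLOPs for the batch (divide by batch size to compare
#'   with [count_flops()]).
#' @export
profile_flops_runtime <- function(model, batch = NULL) {
  cfg <- model$config
  if (is.null(batch))
    batch <- array(0, c(1, cfg$in_channels, cfg$input_size, cfg$input_size))
  ag_profile_start()
  invisible(forward_pass(model, batch))
  ag_profile_stop() / 1e9
}
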