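# Token-MLP backbone primitives.
#
# A FeatureMap is a numeric array of dim c(B, C, H, W).  The tokenized-MLP
# block replaces the conv-BN-ReLU stack of a classic U-Net stage: features
# are projected to E "token" channels by a 3x3 convolution, then mixed by an
# MLP applied after shifting contiguous channel partitions along one spatial
# axis (width first, then height), with a depthwise 3x3 convolution inside
# the MLP acting as an implicit positional encoding.

#' Validate and coerce a feature map
#'
#' @param x numeric array of dim (batch, channels, height, width).
#' @return the validated array.
#' @export
feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4)
    stop("a feature map must be a 4-D array (batch, channels, height, width)")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# boundary converters between the public (B, C, H, W) order and the
# internal channel-plane-contiguous (H, W, C, B) order
to_internal <- function(x) aperm(x, c(3, 4, 2, 1))
to_public <- function(x) aperm(x, c(4, 3, 1, 2))

# ---- module infrastructure -------------------------------------------------

new_module <- function(name, params = list(), children = list(),
                       forward = NULL, meta = list()) {
  structure(list(name = name, params = params, children = children,
                 forward = forward, meta = meta),
            class = "md_module")
}

#' @export
print.md_module <- function(x, ...) {
  cat(sprintf("<md_module %s: %s parameters>\n", x$name,
              format(module_n_params(x), big.mark = ",")))
  invisible(x)
}

# recursively collect parameter leaf nodes
collect_params <- function(mod, prefix = mod$name) {
  out <- list()
  for (nm in names(mod$params))
    out[[paste(prefix, nm, sep = ".")]] <- mod$params[[nm]]
  for (ch in mod$children)
    out <- c(out, collect_params(ch, paste(prefix, ch$name, sep = ".")))
  out
}

module_n_params <- function(mod) {
  sum(vapply(collect_params(mod), function(p) length(p$val), numeric(1)))
}

# apply a module to a plain PUBLIC-layout array, returning the same layout
md_forward <- function(mod, x, ...) {
  out <- mod$forward(ag_var(to_internal(x)), ...)
  to_public(ag_val(out))
}

# parameter init: uniform in +-sqrt(1/fan_in) (fan-based, framework default)
init_uniform <- function(dims, fan_in) {
  array(runif(prod(dims), -sqrt(1 / fan_in), sqrt(1 / fan_in)), dims)
}

layer_conv2d <- function(name, cin, cout, kh, kw = kh, groups = 1L,
                         bias = TRUE) {
  fan_in <- (cin / groups) * kh * kw
  w <- ag_var(init_uniform(c(kh, kw, cin / groups, cout), fan_in),
              requires_grad = TRUE, name = paste0(name, ".w"))
  b <- if (bias) ag_var(init_uniform(cout, fan_in), requires_grad = TRUE,
                        name = paste0(name, ".b")) else NULL
  params <- if (bias) list(w = w, b = b) else list(w = w)
  new_module(name, params = params,
             forward = function(x) ag_conv2d(x, w, b, groups = groups),
             meta = list(kind = "conv", cin = cin, cout = cout, kh = kh,
                         kw = kw, groups = groups, bias = bias))
}

layer_layernorm <- function(name, C) {
  g <- ag_var(rep(1, C), requires_grad = TRUE, name = paste0(name, ".gamma"))
  b <- ag_var(rep(0, C), requires_grad = TRUE, name = paste0(name, ".beta"))
  new_module(name, params = list(gamma = g, beta = b),
             forward = function(x) ag_layernorm_ch(x, g, b),
             meta = list(kind = "layernorm", C = C))
}

layer_linear <- function(name, fin, fout, bias = TRUE) {
  w <- ag_var(init_uniform(c(fin, fout), fin), requires_grad = TRUE,
              name = paste0(name, ".w"))
  b <- if (bias) ag_var(init_uniform(fout, fin), requires_grad = TRUE,
                        name = paste0(name, ".b")) else NULL
  params <- if (bias) list(w = w, b = b) else list(w = w)
  new_module(name, params = params,
             forward = function(x) ag_linear(x, w, b),
             meta = list(kind = "linear", fin = fin, fout = fout, bias = bias))
}

# ---- spec operations (functional, array in / array out) --------------------

#' Depthwise 3x3 convolution
#'
#' One 3x3 kernel per channel (groups = channels), stride 1, zero padding 1,
#' so the output shape equals the input shape and output channel c depends
#' only on input channel c.
#'
#' @param x feature map, dim (B, C, H, W).
#' @param weights array of per-channel kernels, dim (3, 3, C) or (3, 3, 1, C).
#' @param bias optional numeric vector of length C.
#' @return feature map of the same shape as `x`.
#' @export
depthwise_conv3x3 <- function(x, weights, bias = NULL) {
  x <- feature_map(x)
  if (length(dim(weights)) == 3) dim(weights) <- c(dim(weights)[1:2], 1, dim(weights)[3])
  C <- dim(x)[2]
  if (dim(weights)[4] != C)
    stop(sprintf("depthwise_conv3x3: input has %d channels, weights have %d",
                 C, dim(weights)[4]))
  to_public(ag_val(ag_conv2d(ag_var(to_internal(x)), ag_var(weights),
                             if (is.null(bias)) NULL else ag_var(bias),
                             groups = C)))
}

#' General 2-D convolution (stride 1, same padding)
#'
#' @param x feature map (B, C, H, W).
#' @param weights array (kh, kw, cin/groups, cout).
#' @param bias optional numeric vector of length cout.
#' @param groups number of channel groups.
#' @export
conv2d_same <- function(x, weights, bias = NULL, groups = 1L) {
  x <- feature_map(x)
  to_public(ag_val(ag_conv2d(ag_var(to_internal(x)), ag_var(weights),
                             if (is.null(bias)) NULL else ag_var(bias),
                             groups = groups)))
}

# offsets of the symmetric shift ladder for n partitions and shift size s
shift_offsets <- function(n_partitions, shift_size) {
  if (shift_size == 0 || n_partitions == 1) return(rep(0L, n_partitions))
  p <- floor(shift_size / 2)
  as.integer(round(seq(-p, p, length.out = n_partitions)))
}

# per-channel offset vector: partition j (contiguous channels, last absorbs
# the remainder) gets the j-th ladder offset
channel_offsets <- function(C, n_partitions, shift_size) {
  off <- shift_offsets(n_partitions, shift_size)
  sizes <- rep(C %/% n_partitions, n_partitions)
  sizes[n_partitions] <- sizes[n_partitions] + C %% n_partitions
  as.integer(rep(off, times = sizes))
}

# internal shift kernel on (H, W, C, B) arrays; invert = TRUE applies the
# negated offsets (both the inverse translation and the adjoint of the
# forward map, since translation-with-zero-fill is a 0/1 selection matrix)
shift_partition_fwd <- function(x, axis, n_partitions, shift_size,
                                invert = FALSE) {
  d <- dim(x)
  off <- channel_offsets(d[3], n_partitions, shift_size)
  if (invert) off <- -off
  if (all(off == 0)) return(x)
  if (!is.double(x)) storage.mode(x) <- "double"
  y <- .cpp_shift_fwd(x, as.integer(d), off,
                      if (axis == "height") 0L else 1L)
  dim(y) <- d
  y
}

#' Axial shift of channel partitions
#'
#' Splits the channels into `n_partitions` contiguous groups (the last group
#' absorbs any remainder) and translates group j along the chosen spatial
#' axis by the j-th offset of the symmetric ladder
#' \{-floor(s/2), ..., 0, ..., +floor(s/2)\}; vacated positions are
#' zero-filled.  With `shift_size = 0` this is the identity.
#'
#' @param x feature map (B, C, H, W).
#' @param axis `"height"` or `"width"`.
#' @param n_partitions number of contiguous channel groups (must not exceed
#'   the channel count).
#' @param shift_size total extent s of the shift ladder, in pixels.
#' @return feature map of the same shape.
#' @export
shift_partition <- function(x, axis = c("width", "height"), n_partitions = 5L,
                            shift_size = 5L) {
  axis <- match.arg(axis)
  x <- feature_map(x)
  if (n_partitions > dim(x)[2])
    stop(sprintf("shift_partition: n_partitions (%d) exceeds channel count (%d)",
                 n_partitions, dim(x)[2]))
  to_public(shift_partition_fwd(to_internal(x), axis, n_partitions, shift_size))
}

#' Tokenize and project features
#'
#' A 3x3 convolution (stride 1, padding 1) that maps the channel count to the
#' embedding dimension E while preserving spatial resolution; the channels of
#' the output are the token dimensions mixed by the subsequent shifted MLP.
#'
#' @param x feature map (B, C, H, W).
#' @param weights array (3, 3, C, E).
#' @param bias optional numeric vector of length E.
#' @export
tokenize_project <- function(x, weights, bias = NULL) {
  conv2d_same(x, weights, bias, groups = 1L)
}

# ---- shifted MLP block -----------------------------------------------------

#' Construct a shifted-MLP token block
#'
#' The residual tokenized-MLP block: layer norm over channels, a width-axis
#' partition shift, a channel MLP (1x1 projection to the hidden width, a
#' depthwise 3x3 positional-encoding convolution, GELU), a height-axis shift,
#' and a final 1x1 projection back to E channels, added to the input.
#'
#' @param E embedding dimension (channel count in and out).
#' @param shift_size shift ladder extent in pixels (default 5).
#' @param n_partitions number of channel partitions (default 5).
#' @param hidden_ratio hidden width of the MLP as a multiple of E (default 1).
#' @param name module name.
#' @return an `md_module`; apply with `md_forward(block, x)`.
#' @export
new_shifted_mlp_block <- function(E, shift_size = 5L, n_partitions = 5L,
                                  hidden_ratio = 1, name = "tokmlp") {
  H <- max(1L, as.integer(round(E * hidden_ratio)))
  np <- min(n_partitions, E)
  ln <- layer_layernorm(paste0(name, ".ln"), E)
  fc1 <- layer_conv2d(paste0(name, ".fc1"), E, H, 1)
  dw <- layer_conv2d(paste0(name, ".dw"), H, H, 3, groups = H)
  fc2 <- layer_conv2d(paste0(name, ".fc2"), H, E, 1)
  fwd <- function(x) {
    h <- ln$forward(x)
    h <- ag_shift(h, "width", np, shift_size)
    h <- fc1$forward(h)
    h <- dw$forward(h)
    h <- ag_gelu(h)
    h <- ag_shift(h, "height", np, shift_size)
    h <- fc2$forward(h)
    ag_add(x, h)
  }
  new_module(name, children = list(ln = ln, fc1 = fc1, dw = dw, fc2 = fc2),
             forward = fwd,
             meta = list(kind = "tokmlp_block", E = E, hidden = H,
                         shift_size = shift_size, n_partitions = np))
}

#' Apply a shifted-MLP block to a feature map
#'
#' @param x feature map with E channels.
#' @param block module from [new_shifted_mlp_block()].
#' @export
shifted_mlp_block <- function(x, block) {
  x <- feature_map(x)
  if (dim(x)[2] != block$meta$E)
    stop(sprintf("shifted_mlp_block: input has %d channels, block expects %d",
                 dim(x)[2], block$meta$E))
  md_forward(block, x)
}

#' Construct an encoder or decoder Token-MLP stage
#'
#' Encode: tokenize-project to E, shifted-MLP block, then 2x2 max-pool
#' (spatial dims must be even).  Decode: bilinear 2x upsample, optional skip
#' fusion, tokenize-project to E, shifted-MLP block.
#'
#' @param cin input channel count (for decode with concat fusion, the channel
#'   count after concatenation).
#' @param E stage width (output channels).
#' @param direction `"encode"` or `"decode"`.
#' @param shift_size,n_partitions,hidden_ratio passed to the block.
#' @param name module name.
#' @return an `md_module`.  The forward takes `(x, skip = NULL,
#'   fusion = "concat"|"add", return_skip = FALSE)`; encode with
#'   `return_skip = TRUE` returns `list(out, skip)` where `skip` is the
#'   pre-pool activation.
#' @export
new_token_mlp_stage <- function(cin, E, direction = c("encode", "decode"),
                                shift_size = 5L, n_partitions = 5L,
                                hidden_ratio = 1, name = direction) {
  direction <- match.arg(direction)
  proj <- layer_conv2d(paste0(name, ".proj"), cin, E, 3)
  blk <- new_shifted_mlp_block(E, shift_size, n_partitions, hidden_ratio,
                               name = paste0(name, ".blk"))
  if (direction == "encode") {
    fwd <- function(x, return_skip = FALSE) {
      d <- dim(ag_val(x))
      if (d[1] %% 2 || d[2] %% 2)
        stop(sprintf("encode stage: spatial dims (%d, %d) must be even",
                     d[1], d[2]))
      h <- blk$forward(proj$forward(x))
      out <- ag_maxpool2(h)
      if (return_skip) list(out = out, skip = h) else out
    }
  } else {
    fwd <- function(x, skip = NULL, fusion = "concat") {
      h <- ag_upsample2(x)
      if (!is.null(skip)) {
        h <- if (fusion == "add") ag_add(h, skip) else ag_concat_ch(h, skip)
      }
      blk$forward(proj$forward(h))
    }
  }
  new_module(name, children = list(proj = proj, blk = blk), forward = fwd,
             meta = list(kind = paste0("stage_", direction), cin = cin, E = E))
}

#' Apply a Token-MLP stage to a feature map
#'
#' @param x feature map.
#' @param stage module from [new_token_mlp_stage()].
#' @param ... passed to the stage forward (`skip`, `fusion`, `return_skip`).
#' @export
token_mlp_stage <- function(x, stage, ...) {
  x <- feature_map(x)
  out <- stage$forward(ag_var(to_internal(x)), ...)
  if (is.list(out) && !is_ag(out)) lapply(out, function(o) to_public(ag_val(o)))
  else to_public(ag_val(out))
}
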