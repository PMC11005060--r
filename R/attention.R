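# Decoder-side attention modules: the multi-branch feature-extraction (MFE)
# module and the depthwise-attention (DA) gate that replaces plain skip
# connections.

#' Construct a squeeze-and-excitation block
#'
#' Channel attention: global average pool, a bottleneck FC pair
#' (C -> max(1, C/r) -> C) with ReLU between, sigmoid gates in (0,1), and a
#' per-channel rescale of the input.
#'
#' @param C channel count.
#' @param r reduction ratio (default 8).
#' @param name module name.
#' @return an `md_module`.
#' @export
new_se_block <- function(C, r = 8, name = "se") {
  Cb <- max(1L, as.integer(C %/% r))
  fc1 <- layer_linear(paste0(name, ".fc1"), C, Cb)
  fc2 <- layer_linear(paste0(name, ".fc2"), Cb, C)
  fwd <- function(x) {
    z <- ag_gap(x)
    gate <- ag_sigmoid(fc2$forward(ag_relu(fc1$forward(z))))
    ag_scale_channels(x, gate)
  }
  new_module(name, children = list(fc1 = fc1, fc2 = fc2), forward = fwd,
             meta = list(kind = "se", C = C, r = r, Cb = Cb))
}

#' Apply a squeeze-and-excitation block
#'
#' @param x feature map (B, C, H, W).
#' @param se module from [new_se_block()]; if missing, a freshly initialized
#'   block with ratio `r` is created.
#' @param r reduction ratio used when `se` is missing.
#' @export
se_block <- function(x, se = NULL, r = 8) {
  x <- feature_map(x)
  if (is.null(se)) se <- new_se_block(dim(x)[2], r)
  md_forward(se, x)
}

#' Construct a multi-branch feature-extraction (MFE) module
#'
#' Five paths over the decoder feature x: four convolutional branches
#' (asymmetric 1x3*3x1, asymmetric 1x5*5x1, a 1x1 convolution, and an
#' identity skip), each followed by its own squeeze-and-excitation block and
#' a 1x1 re-encoding.  Branch pairs are summed, passed through ReLU, a
#' depthwise 3x3 convolution and a sigmoid, giving two spatial gates O1, O2
#' strictly in (0,1); the fifth, multiplicative path re-injects the input:
#' the output is conv1x1(conv1x1(O1*O2) * x).  All kernels pad to preserve
#' shape; channels are preserved.
#'
#' @param C channel count.
#' @param se_ratio squeeze-and-excitation reduction ratio (default 8).
#' @param name module name.
#' @return an `md_module`.
#' @export
new_mfe_module <- function(C, se_ratio = 8, name = "mfe") {
  nm <- function(s) paste0(name, ".", s)
  c13 <- layer_conv2d(nm("w13"), C, C, 1, 3)
  c31 <- layer_conv2d(nm("w31"), C, C, 3, 1)
  c15 <- layer_conv2d(nm("w15"), C, C, 1, 5)
  c51 <- layer_conv2d(nm("w51"), C, C, 5, 1)
  c11 <- layer_conv2d(nm("w11"), C, C, 1, 1)
  se1 <- new_se_block(C, se_ratio, nm("se1"))
  se2 <- new_se_block(C, se_ratio, nm("se2"))
  se3 <- new_se_block(C, se_ratio, nm("se3"))
  se4 <- new_se_block(C, se_ratio, nm("se4"))
  p1 <- layer_conv2d(nm("p1"), C, C, 1, 1)
  p2 <- layer_conv2d(nm("p2"), C, C, 1, 1)
  p3 <- layer_conv2d(nm("p3"), C, C, 1, 1)
  p4 <- layer_conv2d(nm("p4"), C, C, 1, 1)
  dw1 <- layer_conv2d(nm("dw1"), C, C, 3, groups = C)
  dw2 <- layer_conv2d(nm("dw2"), C, C, 3, groups = C)
  f1 <- layer_conv2d(nm("f1"), C, C, 1, 1)
  f2 <- layer_conv2d(nm("f2"), C, C, 1, 1)
  fwd <- function(x, taps = NULL) {
    C1 <- p1$forward(se1$forward(c31$forward(c13$forward(x))))
    C2 <- p2$forward(se2$forward(c51$forward(c15$forward(x))))
    C3 <- p3$forward(se3$forward(c11$forward(x)))
    C4 <- p4$forward(se4$forward(x))
    O1 <- ag_sigmoid(dw1$forward(ag_relu(ag_add(C1, C2))))
    O2 <- ag_sigmoid(dw2$forward(ag_relu(ag_add(C3, C4))))
    out <- f2$forward(ag_mul(f1$forward(ag_mul(O1, O2)), x))
    if (!is.null(taps)) { taps$O1 <- ag_val(O1); taps$O2 <- ag_val(O2) }
    out
  }
  new_module(name,
             children = list(c13 = c13, c31 = c31, c15 = c15, c51 = c51,
                             c11 = c11, se1 = se1, se2 = se2, se3 = se3,
                             se4 = se4, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                             dw1 = dw1, dw2 = dw2, f1 = f1, f2 = f2),
             forward = fwd,
             meta = list(kind = "mfe", C = C, se_ratio = se_ratio))
}

#' Apply an MFE module to a feature map
#'
#' @param x feature map (B, C, H, W), the decoder-side Token-MLP output.
#' @param mfe module from [new_mfe_module()].
#' @export
mfe_forward <- function(x, mfe) {
  x <- feature_map(x)
  if (dim(x)[2] != mfe$meta$C)
    stop(sprintf("mfe_forward: input has %d channels, module expects %d",
                 dim(x)[2], mfe$meta$C))
  md_forward(mfe, x)
}

#' Construct a depthwise-attention (DA) skip gate
#'
#' Symmetric additive attention over an encoder skip `x_l` (coarse semantics)
#' and a decoder gating signal `g` (fine semantics) at the same resolution.
#' Each input passes a 1x1 convolution to `F_int` channels followed by a
#' depthwise 3x3 convolution; the sum is rectified, passed through a final
#' depthwise 3x3 convolution and a sigmoid to give attention coefficients
#' alpha strictly in (0,1) with `F_int` channels.  The block output is the
#' elementwise triple product `x_l * alpha * g`.
#'
#' `F_int = F_l` by default so the per-channel product is well defined; when
#' `int_mult > 1` the gate stack works in `F_int = int_mult * F_l` channels
#' and a 1x1 projection returns the pre-sigmoid map to `F_l` channels.  When
#' `gate_pool > 1` the gate is computed on 2^gate_pool-fold average-pooled
#' inputs and the attention map is bilinearly upsampled back before the
#' product (the resolution at which additive gates are computed is a free
#' choice in attention-gate designs).  The classic gate's collapse vector
#' psi in R^(F_int x 1) and its bias b_psi have no counterpart here: the
#' final depthwise convolution takes their place, so they are not
#' instantiated as parameters.
#'
#' @param F_l encoder skip channel count.
#' @param F_g decoder gate channel count (a 1x1 adapter maps g to F_l when
#'   the two differ).
#' @param int_mult F_int as a multiple of F_l (default 1).
#' @param gate_pool number of 2x average-poolings applied before the gate
#'   convolutions (default 0 = full resolution).
#' @param name module name.
#' @return an `md_module`.
#' @export
new_da_block <- function(F_l, F_g = F_l, int_mult = 1, gate_pool = 0,
                         name = "da") {
  F_int <- as.integer(round(F_l * int_mult))
  nm <- function(s) paste0(name, ".", s)
  wx1 <- layer_conv2d(nm("wx1"), F_l, F_int, 1, 1)
  wx3 <- layer_conv2d(nm("wx3"), F_int, F_int, 3, groups = F_int)
  wg1 <- layer_conv2d(nm("wg1"), F_g, F_int, 1, 1)
  wg3 <- layer_conv2d(nm("wg3"), F_int, F_int, 3, groups = F_int)
  w3 <- layer_conv2d(nm("w3"), F_int, F_int, 3, groups = F_int)
  wproj <- if (F_int != F_l) layer_conv2d(nm("proj"), F_int, F_l, 1, 1) else NULL
  wadapt <- if (F_g != F_l) layer_conv2d(nm("adapt"), F_g, F_l, 1, 1) else NULL
  children <- list(wx1 = wx1, wx3 = wx3, wg1 = wg1, wg3 = wg3, w3 = w3)
  if (!is.null(wproj)) children$proj <- wproj
  if (!is.null(wadapt)) children$adapt <- wadapt
  attn <- function(x_l, g) {
    dx <- dim(ag_val(x_l)); dg <- dim(ag_val(g))
    if (!all(dx[c(1, 2, 4)] == dg[c(1, 2, 4)]))
      stop("da block: x_l and g must share batch and spatial dims")
    xi <- x_l; gi <- g
    if (gate_pool > 0) for (k in seq_len(gate_pool)) {
      xi <- ag_avgpool2(xi); gi <- ag_avgpool2(gi)
    }
    ci <- ag_relu(ag_add(wx3$forward(wx1$forward(xi)),
                         wg3$forward(wg1$forward(gi))))
    pre <- w3$forward(ci)
    if (!is.null(wproj)) pre <- wproj$forward(pre)
    a <- ag_sigmoid(pre)
    if (gate_pool > 0) for (k in seq_len(gate_pool)) a <- ag_upsample2(a)
    a
  }
  fwd <- function(x_l, g) {
    a <- attn(x_l, g)
    g_c <- if (!is.null(wadapt)) wadapt$forward(g) else g
    ag_mul(ag_mul(x_l, a), g_c)
  }
  new_module(name, children = children, forward = fwd,
             meta = list(kind = "da", F_l = F_l, F_g = F_g, F_int = F_int,
                         gate_pool = gate_pool, attn = attn))
}

#' Attention coefficients of a DA block
#'
#' @param x_l encoder skip feature map (B, F_l, H, W).
#' @param g decoder gating feature map at the same spatial size.
#' @param da module from [new_da_block()].
#' @return array of attention coefficients, all strictly in (0, 1).
#' @export
da_attention_map <- function(x_l, g, da) {
  x_l <- feature_map(x_l); g <- feature_map(g)
  to_public(ag_val(da$meta$attn(ag_var(to_internal(x_l)),
                                ag_var(to_internal(g)))))
}

#' DA block output: elementwise x_l * alpha * g
#'
#' @inheritParams da_attention_map
#' @export
da_forward <- function(x_l, g, da) {
  x_l <- feature_map(x_l); g <- feature_map(g)
  to_public(ag_val(da$forward(ag_var(to_internal(x_l)),
                              ag_var(to_internal(g)))))
}
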