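# Minimal reverse-mode autodiff over 4-D feature maps.
#
# INTERNAL layout: feature maps on the tape are arrays of dim c(H, W, C, B)
# so that every channel plane is a contiguous block (the public API uses
# the documented (B, C, H, W) order and converts at the boundary).  Graph
# nodes are
# environments holding the value, accumulated gradient, parent nodes and a
# backward closure mapping the output gradient to parent gradients.  The
# graph is rebuilt on every forward pass (define-by-run); parameters are
# persistent leaf nodes.
#
# Runtime op-level FLOP metering (the "hook" profiler) charges one FLOP per
# multiply-accumulate for convolutions and a small per-element cost for
# elementwise ops; the same convention is used by the analytic profiler in
# profiler.R, which the tests cross-check against this one.

.ag <- new.env(parent = emptyenv())
.ag$profiling <- FALSE
.ag$flops <- 0
.ag$next_id <- 0

ag_profile_start <- function() { .ag$profiling <- TRUE; .ag$flops <- 0 }
ag_profile_stop <- function() { .ag$profiling <- FALSE; .ag$flops }
ag_charge <- function(n) if (.ag$profiling) .ag$flops <- .ag$flops + n

#' Create an autodiff leaf node
#'
#' @param val numeric array (any dim) or scalar.
#' @param requires_grad should gradients accumulate into this node?
#' @param name optional label (used for parameters).
#' @return an `ag_node` environment.
#' @keywords internal
ag_var <- function(val, requires_grad = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  .ag$next_id <- .ag$next_id + 1
  e$id <- .ag$next_id
  e$val <- val
  e$grad <- NULL
  e$parents <- list()
  e$bwd <- NULL
  e$req <- requires_grad
  e$name <- name
  class(e) <- "ag_node"
  e
}

ag_op <- function(val, parents, bwd) {
  e <- new.env(parent = emptyenv())
  .ag$next_id <- .ag$next_id + 1
  e$id <- .ag$next_id
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$bwd <- bwd
  e$req <- any(vapply(parents, function(p) isTRUE(p$req) || length(p$parents) > 0,
                      logical(1)))
  class(e) <- "ag_node"
  e
}

is_ag <- function(x) inherits(x, "ag_node")
ag_val <- function(x) if (is_ag(x)) x$val else x
as_ag <- function(x) if (is_ag(x)) x else ag_var(x)

# topological sort (iterative DFS; graphs can be deep)
ag_topo <- function(root) {
  order <- vector("list", 256); n <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n <- n + 1L
      if (n > length(order)) order <- c(order, vector("list", length(order)))
      order[[n]] <- node
    }
  }
  order[seq_len(n)]
}

#' Run backpropagation from a scalar (or any) node
#'
#' Accumulates gradients into every reachable node with `requires_grad`.
#' @param root output node; `seed` defaults to ones of the same shape.
#' @keywords internal
ag_backward <- function(root, seed = NULL) {
  if (is.null(seed)) {
    seed <- ag_val(root)
    seed[] <- 1
  }
  order <- ag_topo(root)
  for (nd in order) nd$grad <- NULL
  root$grad <- seed
  root_val <- root$val
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    if (is.null(nd$bwd) || is.null(nd$grad)) next
    gs <- nd$bwd(nd$grad)
    for (j in seq_along(gs)) {
      if (is.null(gs[[j]])) next
      p <- nd$parents[[j]]
      if (is.null(p$grad)) p$grad <- gs[[j]] else p$grad <- p$grad + gs[[j]]
    }
    # this node's activation and gradient are no longer needed: free them
    # (leaf parameters keep both; their bwd is NULL so they never get here)
    nd$val <- NULL
    nd$grad <- NULL
    nd$bwd <- NULL
    nd$parents <- list()
  }
  root$val <- root_val
  invisible(root)
}

# ---- primitive ops ---------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  v <- a$val + b$val
  ag_charge(length(v))
  ag_op(v, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_charge(length(a$val))
  ag_op(a$val - b$val, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  v <- a$val * b$val
  ag_charge(length(v))
  ag_op(v, list(a, b), function(g) list(g * b$val, g * a$val))
}

ag_scale <- function(a, s) {  # scalar multiply
  a <- as_ag(a)
  ag_charge(length(a$val))
  ag_op(a$val * s, list(a), function(g) list(g * s))
}

ag_relu <- function(x) {
  x <- as_ag(x)
  m <- x$val > 0
  ag_charge(length(m))
  ag_op(x$val * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  x <- as_ag(x)
  s <- 1 / (1 + exp(-x$val))
  ag_charge(length(s))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

# GELU, tanh form: 0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))
ag_gelu <- function(x) {
  x <- as_ag(x)
  v <- x$val
  k <- sqrt(2 / pi)
  u <- k * (v + 0.044715 * v^3)
  t <- tanh(u)
  ag_charge(length(v))
  ag_op(0.5 * v * (1 + t), list(x), function(g) {
    du <- k * (1 + 3 * 0.044715 * v^2)
    list(g * (0.5 * (1 + t) + 0.5 * v * (1 - t * t) * du))
  })
}

# per-channel broadcast: vec of length C expands over (H, W, C, B) arrays
# via rep(vec, each = H*W) and R recycling over the batch dimension
bc_ch <- function(vec, P) rep(vec, each = P)

# Layer normalization over the channel dimension at each (b, h, w) location,
# with per-channel affine (gamma, beta).  The tokenized-MLP convention.
ag_layernorm_ch <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$val)
  if (!is.double(x$val)) storage.mode(x$val) <- "double"
  r <- .cpp_ln_fwd(x$val, as.integer(d), as.double(gamma$val),
                   as.double(beta$val), eps)
  y <- r$y; dim(y) <- d
  ag_charge(2 * length(y))
  ag_op(y, list(x, gamma, beta), function(g) {
    if (!is.double(g)) storage.mode(g) <- "double"
    rb <- .cpp_ln_bwd(g, as.integer(d), r$xn, r$inv, as.double(gamma$val))
    gx <- rb$gx; dim(gx) <- d
    list(gx, rb$ggamma, rb$gbeta)
  })
}

# grouped 2-D convolution, stride 1, same padding
ag_conv2d <- function(x, w, b = NULL, groups = 1L) {
  x <- as_ag(x); w <- as_ag(w)
  has_bias <- !is.null(b)
  if (has_bias) b <- as_ag(b)
  xd <- dim(x$val); wd <- dim(w$val)
  if (xd[3] != wd[3] * groups)
    stop(sprintf("conv2d: input has %d channels but weights expect %d (groups=%d)",
                 xd[3], wd[3] * groups, groups))
  if (!is.double(x$val)) storage.mode(x$val) <- "double"
  if (!is.double(w$val)) storage.mode(w$val) <- "double"
  out <- .cpp_conv2d_fwd(x$val, as.integer(xd), w$val, as.integer(wd),
                         if (has_bias) as.double(b$val) else numeric(0),
                         as.integer(groups))
  dim(out) <- c(xd[1], xd[2], wd[4], xd[4])
  ag_charge(prod(xd[1:2]) * wd[4] * (wd[1] * wd[2] * wd[3] + has_bias) * xd[4])
  parents <- if (has_bias) list(x, w, b) else list(x, w)
  ag_op(out, parents, function(g) {
    if (!is.double(g)) storage.mode(g) <- "double"
    r <- .cpp_conv2d_bwd(x$val, as.integer(xd), w$val, as.integer(wd),
                         g, as.integer(groups), has_bias)
    gx <- r$gx; dim(gx) <- xd
    gw <- r$gw; dim(gw) <- wd
    if (has_bias) list(gx, gw, r$gb) else list(gx, gw)
  })
}

# 2x2 max pooling, stride 2 (spatial dims are 1 and 2); gradient flows to
# the first maximum in each cell
ag_maxpool2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  if (d[1] %% 2 || d[2] %% 2)
    stop(sprintf("maxpool2: spatial dims (%d, %d) must be even", d[1], d[2]))
  if (!is.double(x$val)) storage.mode(x$val) <- "double"
  r <- .cpp_mp2_fwd(x$val, as.integer(d))
  y <- r$y
  dim(y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  ag_charge(length(x$val))
  ag_op(y, list(x), function(g) {
    if (!is.double(g)) storage.mode(g) <- "double"
    gx <- .cpp_mp2_bwd(g, r$which, as.integer(d))
    dim(gx) <- d
    list(gx)
  })
}

# 2x2 average pooling, stride 2
ag_avgpool2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  hi <- seq(1, d[1], by = 2); wi <- seq(1, d[2], by = 2)
  y <- (x$val[hi, wi, , , drop = FALSE] + x$val[hi + 1, wi, , , drop = FALSE] +
        x$val[hi, wi + 1, , , drop = FALSE] + x$val[hi + 1, wi + 1, , , drop = FALSE]) / 4
  ag_charge(length(x$val))
  ag_op(y, list(x), function(g) {
    gx <- array(0, d)
    g4 <- g / 4
    gx[hi, wi, , ] <- g4; gx[hi + 1, wi, , ] <- g4
    gx[hi, wi + 1, , ] <- g4; gx[hi + 1, wi + 1, , ] <- g4
    list(gx)
  })
}

# bilinear 2x spatial upsampling (align_corners = FALSE)
ag_upsample2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  if (!is.double(x$val)) storage.mode(x$val) <- "double"
  y <- .cpp_up2_fwd(x$val, as.integer(d))
  dim(y) <- c(2 * d[1], 2 * d[2], d[3], d[4])
  ag_charge(3 * length(y))
  ag_op(y, list(x), function(g) {
    if (!is.double(g)) storage.mode(g) <- "double"
    gx <- .cpp_up2_bwd(g, as.integer(d))
    dim(gx) <- d
    list(gx)
  })
}

# concatenate along the channel dimension (dim 3)
ag_concat_ch <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$val
  y[, , da[3] + seq_len(db[3]), ] <- b$val
  ag_op(y, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# global average pool over H, W -> (B, C) matrix
ag_gap <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  P <- d[1] * d[2]
  y <- t(matrix(colMeans(matrix(x$val, P)), d[3], d[4]))   # (B, C)
  ag_charge(length(x$val))
  ag_op(y, list(x), function(g) {
    gx <- array(rep(as.numeric(t(g)), each = P) / P, d)
    list(gx)
  })
}

# fully-connected layer on (B, F) matrices: y = x %*% W + b
ag_linear <- function(x, w, b = NULL) {
  x <- as_ag(x); w <- as_ag(w)
  has_bias <- !is.null(b)
  if (has_bias) b <- as_ag(b)
  y <- x$val %*% w$val
  if (has_bias) y <- sweep(y, 2, b$val, `+`)
  ag_charge(nrow(x$val) * (ncol(x$val) + has_bias) * ncol(w$val))
  parents <- if (has_bias) list(x, w, b) else list(x, w)
  ag_op(y, parents, function(g) {
    gx <- g %*% t(w$val)
    gw <- t(x$val) %*% g
    if (has_bias) list(gx, gw, colSums(g)) else list(gx, gw)
  })
}

# multiply feature map by per-(batch, channel) gates g: (B, C) matrix
ag_scale_channels <- function(x, gate) {
  x <- as_ag(x); gate <- as_ag(gate)
  d <- dim(x$val)
  P <- d[1] * d[2]
  gv <- rep(as.numeric(t(gate$val)), each = P)  # (c, b) order, plane-expanded
  y <- x$val * gv
  ag_charge(length(y))
  ag_op(y, list(x, gate), function(g) {
    gx <- g * gv
    gg <- t(matrix(colSums(matrix(g * x$val, P)), d[3], d[4]))
    list(gx, gg)
  })
}

# axial shift of contiguous channel partitions (see shift_partition); the
# backward pass is the shift by negated offsets (adjoint of the 0/1
# selection matrix)
ag_shift <- function(x, axis = c("width", "height"), n_partitions = 5L,
                     shift_size = 5L) {
  axis <- match.arg(axis)
  x <- as_ag(x)
  d <- dim(x$val)
  off <- channel_offsets(d[3], n_partitions, shift_size)
  if (all(off == 0)) return(x)
  ax <- if (axis == "height") 0L else 1L
  if (!is.double(x$val)) storage.mode(x$val) <- "double"
  y <- .cpp_shift_fwd(x$val, as.integer(d), off, ax)
  dim(y) <- d
  ag_op(y, list(x), function(g) {
    if (!is.double(g)) storage.mode(g) <- "double"
    gx <- .cpp_shift_fwd(g, as.integer(d), -off, ax)
    dim(gx) <- d
    list(gx)
  })
}

ag_mean_all <- function(x) {
  x <- as_ag(x)
  n <- length(x$val)
  ag_charge(n)
  ag_op(mean(x$val), list(x), function(g) {
    gx <- x$val; gx[] <- as.numeric(g) / n
    list(gx)
  })
}

ag_sum_all <- function(x) {
  x <- as_ag(x)
  ag_charge(length(x$val))
  ag_op(sum(x$val), list(x), function(g) {
    gx <- x$val; gx[] <- as.numeric(g)
    list(gx)
  })
}
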