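# Brute-force oracles and small helpers shared across the test files.
# All oracles work on the public (B, C, H, W) layout and are written as
# direct transcriptions (nested loops / per-pixel arithmetic), independent
# of the package's compiled kernels.

# sliding-window convolution oracle, stride 1, same zero padding
oracle_conv <- function(x, w, bias = NULL, groups = 1L) {
  d <- dim(x); kd <- dim(w)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  kh <- kd[1]; kw <- kd[2]; cing <- kd[3]; cout <- kd[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  coutg <- cout / groups
  out <- array(0, c(B, cout, H, W))
  for (b in seq_len(B)) for (o in seq_len(cout)) {
    g <- ceiling(o / coutg)
    for (h in seq_len(H)) for (ww in seq_len(W)) {
      s <- if (is.null(bias)) 0 else bias[o]
      for (cl in seq_len(cing)) {
        ci <- (g - 1) * cing + cl
        for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
          hh <- h + ki - 1 - ph; wj <- ww + kj - 1 - pw
          if (hh >= 1 && hh <= H && wj >= 1 && wj <= W)
            s <- s + x[b, ci, hh, wj] * w[ki, kj, cl, o]
        }
      }
      out[b, o, h, ww] <- s
    }
  }
  out
}

# per-group roll-and-zero shift oracle (public layout)
oracle_shift <- function(x, axis, n_partitions, shift_size) {
  d <- dim(x); C <- d[2]
  p <- floor(shift_size / 2)
  off <- if (shift_size == 0 || n_partitions == 1) rep(0L, n_partitions)
         else as.integer(round(seq(-p, p, length.out = n_partitions)))
  sizes <- rep(C %/% n_partitions, n_partitions)
  sizes[n_partitions] <- sizes[n_partitions] + C %% n_partitions
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  y <- array(0, d)
  L <- if (axis == "height") d[3] else d[4]
  for (j in seq_len(n_partitions)) {
    o <- off[j]
    for (ci in starts[j]:ends[j]) for (i in seq_len(L)) {
      src <- i - o
      if (src >= 1 && src <= L) {
        if (axis == "height") y[, ci, i, ] <- x[, ci, src, ]
        else y[, ci, , i] <- x[, ci, , src]
      }
    }
  }
  y
}

# sigmoid / relu for oracle transcriptions
sig <- function(x) 1 / (1 + exp(-x))
rlu <- function(x) pmax(x, 0)

# squeeze-and-excitation oracle from a module's own weights
oracle_se <- function(x, se) {
  d <- dim(x)
  out <- array(0, d)
  w1 <- se$children$fc1$params$w$val; b1 <- se$children$fc1$params$b$val
  w2 <- se$children$fc2$params$w$val; b2 <- se$children$fc2$params$b$val
  for (b in seq_len(d[1])) {
    z <- sapply(seq_len(d[2]), function(ci) mean(x[b, ci, , ]))
    gate <- sig(as.numeric(rlu(as.numeric(z %*% w1) + as.numeric(b1)) %*% w2) +
                as.numeric(b2))
    for (ci in seq_len(d[2])) out[b, ci, , ] <- x[b, ci, , ] * gate[ci]
  }
  out
}

# random feature map
rfm <- function(B, C, H, W, sd = 1) array(rnorm(B * C * H * W, sd = sd), c(B, C, H, W))

# zero all parameters of a module (recursively); used for parameter surgery
zero_params <- function(mod) {
  for (p in collect_params_pub(mod)) p$val[] <- 0
  invisible(mod)
}

collect_params_pub <- function(mod) mdunet:::collect_params(mod)

# connected-component count of a binary matrix (8-connectivity, BFS)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  idx <- which(mask == 1)
  H <- nrow(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% H + 1L
      cc <- (cur - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > H || c2 < 1 || c2 > ncol(mask)) next
        j <- (c2 - 1L) * H + rr
        if (mask[j] == 1 && lab[j] == 0L) { lab[j] <- n; queue <- c(queue, j) }
      }
    }
  }
  n
}

# random seg_sample of a given size (for pipeline tests)
new_seg_sample_for_test <- function(h, w, id = "t") {
  mdunet:::new_seg_sample(id, array(runif(h * w * 3), c(h, w, 3)),
                          matrix(as.numeric(runif(h * w) > 0.5), h, w),
                          "loaded")
}

# tiny seeded nuclei config used across training tests
tiny_nuclei_cfg <- function(seed = 1L, size = 64L)
  synthetic_config("nuclei", size = size, n_objects = c(3L, 5L),
                   radius = c(5, 10), seed = seed)
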