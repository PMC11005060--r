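# Token-MLP backbone primitives: convolutions, axial shifts, tokenization,
# residual shifted-MLP blocks and encoder/decoder stages.

test_that("depthwise 3x3 convolution matches its contract and a loop oracle", {
  set.seed(11)
  x <- rfm(1, 2, 4, 4)
  w <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  # zero input, zero bias -> zero output (linearity)
  expect_equal(depthwise_conv3x3(array(0, dim(x)), w, rep(0, 2)),
               array(0, dim(x)))
  # identity kernel -> identity map
  wid <- array(0, c(3, 3, 2)); wid[2, 2, ] <- 1
  expect_equal(depthwise_conv3x3(x, wid, rep(0, 2)), x, tolerance = 1e-12)
  # random case vs. explicit nested-loop oracle
  b <- rnorm(2)
  w4 <- array(w, c(3, 3, 1, 2))
  expect_lt(max(abs(depthwise_conv3x3(x, w, b) -
                    oracle_conv(x, w4, b, groups = 2))), 1e-5)
  # per-channel independence: output channel 1 ignores input channel 2
  x2 <- x; x2[, 2, , ] <- x2[, 2, , ] + 100
  y1 <- depthwise_conv3x3(x, w, b); y2 <- depthwise_conv3x3(x2, w, b)
  expect_equal(y1[, 1, , ], y2[, 1, , ])
  # channel mismatch errors
  expect_error(depthwise_conv3x3(x, array(0, c(3, 3, 5))), "channels")
})

test_that("general and asymmetric convolutions agree with the sliding-window oracle", {
  set.seed(12)
  for (kd in list(c(3, 3), c(1, 3), c(3, 1), c(1, 5), c(5, 1), c(1, 1))) {
    x <- rfm(2, 3, 6, 5)
    w <- array(rnorm(kd[1] * kd[2] * 3 * 4), c(kd[1], kd[2], 3, 4))
    b <- rnorm(4)
    expect_lt(max(abs(conv2d_same(x, w, b) - oracle_conv(x, w, b))), 1e-5,
              label = sprintf("kernel %dx%d", kd[1], kd[2]))
  }
})

test_that("shift_partition translates channel groups along the offset ladder", {
  set.seed(13)
  x <- rfm(1, 5, 8, 8)
  # zero shift is the identity
  expect_identical(shift_partition(x, "width", 5, 0), x)
  # explicit per-group roll-and-zero oracle, both axes
  for (axis in c("width", "height")) {
    y <- shift_partition(x, axis, 5, 5)
    expect_equal(y, oracle_shift(x, axis, 5, 5))
  }
  # remainder handling: 7 channels over 3 partitions (last absorbs 3)
  x7 <- rfm(1, 7, 6, 6)
  y7 <- shift_partition(x7, "height", 3, 5)
  expect_equal(y7, oracle_shift(x7, "height", 3, 5))
  # interior sum conservation per channel group: columns that cannot have
  # been zero-filled keep their per-channel mass under a width shift
  s <- 5; p <- floor(s / 2)
  y <- shift_partition(x, "width", 5, s)
  off <- c(-2, -1, 0, 1, 2)
  inner_src <- seq(1 + p, 8 - p)
  for (j in 1:5)
    expect_equal(sum(y[, j, , inner_src + off[j]]), sum(x[, j, , inner_src]),
                 tolerance = 1e-12)
  # forward then inverted offsets restore everything except the border band
  yi <- mdunet:::to_public(mdunet:::shift_partition_fwd(
    mdunet:::shift_partition_fwd(mdunet:::to_internal(x), "width", 5, 5),
    "width", 5, 5, invert = TRUE))
  expect_equal(yi[, , , inner_src], x[, , , inner_src], tolerance = 1e-12)
  expect_error(shift_partition(x, "width", 99, 5), "n_partitions")
})

test_that("tokenize_project is a shape-preserving linear map to E channels", {
  set.seed(14)
  x <- rfm(1, 3, 8, 8)
  w <- array(rnorm(3 * 3 * 3 * 6), c(3, 3, 3, 6))
  # zero input, zero bias -> zero
  expect_equal(tokenize_project(array(0, dim(x)), w, rep(0, 6)),
               array(0, c(1, 6, 8, 8)))
  # identity-initialized kernels reproduce the input when E = C
  wid <- array(0, c(3, 3, 3, 3))
  for (ci in 1:3) wid[2, 2, ci, ci] <- 1
  expect_equal(tokenize_project(x, wid, rep(0, 3)), x, tolerance = 1e-12)
  # dense oracle
  b <- rnorm(6)
  expect_lt(max(abs(tokenize_project(x, w, b) - oracle_conv(x, w, b))), 1e-5)
})

test_that("shifted MLP block is residual: zeroed final projection gives identity", {
  set.seed(15)
  blk <- new_shifted_mlp_block(8, shift_size = 5, n_partitions = 5)
  x <- rfm(2, 8, 16, 16)
  y <- shifted_mlp_block(x, blk)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  # parameter surgery: zero fc2 weights and bias -> block output equals input
  blk$children$fc2$params$w$val[] <- 0
  blk$children$fc2$params$b$val[] <- 0
  expect_equal(shifted_mlp_block(x, blk), x, tolerance = 1e-12)
  # channel mismatch is a configuration error
  expect_error(shifted_mlp_block(rfm(1, 4, 8, 8), blk), "channels")
})

test_that("shifted MLP block gradient matches finite differences", {
  set.seed(16)
  blk <- new_shifted_mlp_block(4, shift_size = 3, n_partitions = 2)
  x <- array(rnorm(1 * 4 * 4 * 4), c(4, 4, 4, 1))   # internal layout
  xa <- mdunet:::ag_var(x, requires_grad = TRUE)
  loss <- mdunet:::ag_sum_all(blk$forward(xa))
  mdunet:::ag_backward(loss)
  g <- xa$grad
  expect_true(all(is.finite(g)))
  expect_gt(max(abs(g)), 0)
  f <- function() sum(mdunet:::ag_val(blk$forward(mdunet:::ag_var(xa$val))))
  for (i in sample(length(x), 5)) {
    eps <- 1e-5; o <- xa$val[i]
    xa$val[i] <- o + eps; f1 <- f()
    xa$val[i] <- o - eps; f2 <- f()
    xa$val[i] <- o
    expect_equal(g[i], (f1 - f2) / (2 * eps), tolerance = 1e-3)
  }
})

test_that("token MLP stages change shape as specified", {
  set.seed(17)
  enc <- new_token_mlp_stage(16, 32, "encode")
  x <- rfm(1, 16, 64, 64)
  y <- token_mlp_stage(x, enc)
  expect_equal(dim(y), c(1, 32, 32, 32))
  dec <- new_token_mlp_stage(32, 16, "decode")
  z <- token_mlp_stage(y, dec)
  expect_equal(dim(z), c(1, 16, 64, 64))
  # odd input errors on encode
  expect_error(token_mlp_stage(rfm(1, 16, 63, 63), enc), "even")
  # five chained encodes on a 256 input end at 8x8
  h <- rfm(1, 3, 256, 256)
  cin <- 3
  for (k in 1:5) {
    st <- new_token_mlp_stage(cin, 4, "encode")
    h <- token_mlp_stage(h, st)
    cin <- 4
  }
  expect_equal(dim(h)[3:4], c(8, 8))
})
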