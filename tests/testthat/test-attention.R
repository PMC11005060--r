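# MFE and DA attention modules: gate ranges, zero propagation, oracle
# equivalence, differentiability.

test_that("squeeze-and-excitation gates behave as specified", {
  set.seed(21)
  se <- new_se_block(6, r = 2)
  x <- rfm(2, 6, 8, 8)
  # channel-constant input: the squeeze equals that constant exactly
  xc <- rfm(1, 6, 1, 1)[, , rep(1, 8), rep(1, 8), drop = FALSE]
  z <- mdunet:::ag_val(mdunet:::ag_gap(mdunet:::ag_var(mdunet:::to_internal(xc))))
  expect_equal(as.numeric(z), as.numeric(xc[1, , 1, 1]), tolerance = 1e-12)
  # zero input, zero biases: gate = sigmoid(0) = 0.5, output 0 * 0.5 = 0
  zero_params(se)
  y0 <- se_block(array(0, dim(x)), se)
  expect_equal(y0, array(0, dim(x)))
  # saturation surgery: large positive fc2 bias forces gates ~1 -> output ~ input
  se2 <- new_se_block(6, r = 2)
  se2$children$fc2$params$b$val[] <- 50
  se2$children$fc2$params$w$val[] <- 0
  expect_equal(se_block(x, se2), x, tolerance = 1e-8)
  # oracle equivalence on a random instance
  se3 <- new_se_block(6, r = 2)
  expect_lt(max(abs(se_block(x, se3) - oracle_se(x, se3))), 1e-10)
})

test_that("MFE forward matches a literal transcription of its equations", {
  set.seed(22)
  C <- 8
  mfe <- new_mfe_module(C, se_ratio = 4)
  x <- rfm(1, C, 16, 16)
  got <- mfe_forward(x, mfe)
  expect_equal(dim(got), dim(x))

  # compositional oracle from the independently tested conv/SE oracles
  pw <- function(name) mfe$children[[name]]$params$w$val
  pb <- function(name) mfe$children[[name]]$params$b$val
  conv <- function(z, name) oracle_conv(z, pw(name), pb(name))
  dwconv <- function(z, name) oracle_conv(z, pw(name), pb(name), groups = C)
  C1 <- conv(oracle_se(conv(conv(x, "c13"), "c31"), mfe$children$se1), "p1")
  C2 <- conv(oracle_se(conv(conv(x, "c15"), "c51"), mfe$children$se2), "p2")
  C3 <- conv(oracle_se(conv(x, "c11"), mfe$children$se3), "p3")
  C4 <- conv(oracle_se(x, mfe$children$se4), "p4")
  O1 <- sig(dwconv(rlu(C1 + C2), "dw1"))
  O2 <- sig(dwconv(rlu(C3 + C4), "dw2"))
  ora <- conv(conv(O1 * O2, "f1") * x, "f2")
  expect_lt(max(abs(got - ora)), 1e-5)

  # gates strictly inside (0,1)
  taps <- new.env()
  invisible(mfe$forward(mdunet:::ag_var(mdunet:::to_internal(x)), taps = taps))
  expect_true(all(taps$O1 > 0 & taps$O1 < 1))
  expect_true(all(taps$O2 > 0 & taps$O2 < 1))
})

test_that("MFE with zero input and zero biases returns zero", {
  set.seed(23)
  mfe <- new_mfe_module(4, se_ratio = 2)
  # zero every bias (conv biases and the SE bottleneck biases)
  for (nm in names(mfe$children)) {
    prm <- mfe$children[[nm]]$params
    if (!is.null(prm$b)) prm$b$val[] <- 0
    ch2 <- mfe$children[[nm]]$children
    for (nm2 in names(ch2)) if (!is.null(ch2[[nm2]]$params$b)) ch2[[nm2]]$params$b$val[] <- 0
  }
  x0 <- array(0, c(1, 4, 8, 8))
  expect_equal(mfe_forward(x0, mfe), x0)
})

test_that("DA attention map matches a per-pixel transcription and lies in (0,1)", {
  set.seed(24)
  da <- new_da_block(4, 4)
  x_l <- rfm(1, 4, 8, 8); g <- rfm(1, 4, 8, 8)
  a <- da_attention_map(x_l, g, da)
  expect_true(all(a > 0 & a < 1))
  # per-pixel oracle of the gate equations
  pw <- function(name) da$children[[name]]$params$w$val
  pb <- function(name) da$children[[name]]$params$b$val
  xi <- oracle_conv(oracle_conv(x_l, pw("wx1"), pb("wx1")), pw("wx3"), pb("wx3"), groups = 4)
  gi <- oracle_conv(oracle_conv(g, pw("wg1"), pb("wg1")), pw("wg3"), pb("wg3"), groups = 4)
  ci <- rlu(xi + gi)
  ora <- sig(oracle_conv(ci, pw("w3"), pb("w3"), groups = 4))
  expect_lt(max(abs(a - ora)), 1e-6)
  # zero inputs, zero biases -> alpha = 0.5 everywhere
  zero_params(da)
  a0 <- da_attention_map(array(0, dim(x_l)), array(0, dim(g)), da)
  expect_equal(a0, array(0.5, dim(a0)))
})

test_that("DA forward is the elementwise triple product x_l * alpha * g", {
  set.seed(25)
  da <- new_da_block(4, 4)
  x_l <- rfm(1, 4, 8, 8); g <- rfm(1, 4, 8, 8)
  a <- da_attention_map(x_l, g, da)
  expect_equal(da_forward(x_l, g, da), x_l * a * g, tolerance = 1e-12)
  # bias surgery forces alpha ~ 1: with g = 1, output ~ x_l
  da2 <- new_da_block(4, 4)
  zero_params(da2)
  da2$children$w3$params$b$val[] <- 50
  ones <- array(1, dim(g))
  expect_equal(da_forward(x_l, ones, da2), x_l, tolerance = 1e-8)
  # multiplicative annihilation
  expect_equal(da_forward(array(0, dim(x_l)), g, da), array(0, dim(x_l)))
  # boundedness: |x_hat| <= |x_l| * max|g|
  xh <- da_forward(x_l, g, da)
  expect_true(all(abs(xh) <= abs(x_l) * max(abs(g)) + 1e-12))
})

test_that("DA variants with F_int multiple and pooled gates keep the contract", {
  set.seed(26)
  da <- new_da_block(4, 4, int_mult = 2, gate_pool = 1)
  x_l <- rfm(1, 4, 8, 8); g <- rfm(1, 4, 8, 8)
  a <- da_attention_map(x_l, g, da)
  expect_equal(dim(a), dim(x_l))
  expect_true(all(a > 0 & a < 1))
  expect_equal(da_forward(x_l, g, da), x_l * a * g, tolerance = 1e-12)
  # channel adapter path when F_g != F_l
  da3 <- new_da_block(4, 6)
  g6 <- rfm(1, 6, 8, 8)
  xh <- da_forward(x_l, g6, da3)
  expect_equal(dim(xh), dim(x_l))
})

test_that("MFE and DA are differentiable end-to-end", {
  set.seed(27)
  mfe <- new_mfe_module(4, se_ratio = 2)
  da <- new_da_block(4, 4)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  g <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  xa <- mdunet:::ag_var(x, requires_grad = TRUE)
  ga <- mdunet:::ag_var(g, requires_grad = TRUE)
  loss <- mdunet:::ag_sum_all(da$forward(mfe$forward(xa), ga))
  mdunet:::ag_backward(loss)
  expect_true(all(is.finite(xa$grad)) && max(abs(xa$grad)) > 0)
  expect_true(all(is.finite(ga$grad)) && max(abs(ga$grad)) > 0)
  f <- function() sum(mdunet:::ag_val(
    da$forward(mfe$forward(mdunet:::ag_var(xa$val)), mdunet:::ag_var(g))))
  for (i in sample(length(x), 4)) {
    eps <- 1e-5; o <- xa$val[i]
    xa$val[i] <- o + eps; f1 <- f()
    xa$val[i] <- o - eps; f2 <- f()
    xa$val[i] <- o
    expect_equal(xa$grad[i], (f1 - f2) / (2 * eps), tolerance = 1e-3)
  }
})
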