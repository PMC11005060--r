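# BCE + Dice objective and IoU/Dice evaluation metrics.

test_that("BCE loss matches closed forms and a per-pixel oracle", {
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)               # perfect prediction
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  set.seed(31)
  y <- (runif(40) > 0.5) * 1
  p <- runif(40, 0.01, 0.99)
  ora <- mean(sapply(seq_along(y), function(i)
    -(y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))))
  expect_equal(bce_loss(y, p), ora, tolerance = 1e-6)
  expect_gte(bce_loss(y, p), 0)
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0.5, 3, 3)), "shape")
})

test_that("Dice loss follows the smoothed formula", {
  n <- 6
  expect_equal(dice_loss(rep(1, n), rep(1, n)), 0)       # self match
  expect_equal(dice_loss(rep(0, n), rep(0, n)), 0)       # smoothing saves 0/0
  expect_equal(dice_loss(rep(1, 4), rep(0, 4)), 1 - 1 / 5)  # worked example
  # binary self-match is exactly zero for any binary mask
  set.seed(32)
  for (rep in 1:5) {
    y <- (runif(25) > runif(1)) * 1
    expect_equal(dice_loss(y, y), 0)
  }
  # probabilistic self-match is nonnegative
  p <- runif(25)
  expect_gte(dice_loss((p > 0.5) * 1, p), 0)
})

test_that("combined loss is BCE + Dice and has correct gradients", {
  set.seed(33)
  y <- matrix((runif(4) > 0.5) * 1, 2, 2)
  p <- matrix(runif(4, 0.1, 0.9), 2, 2)
  expect_equal(combined_loss(y, p), bce_loss(y, p) + dice_loss(y, p))
  expect_lt(combined_loss(y, pmin(pmax(y, 1e-7), 1 - 1e-7)), 1e-5)
  # autodiff gradient vs finite differences on the 2x2 instance
  pa <- mdunet:::ag_var(p, requires_grad = TRUE)
  loss <- mdunet:::ag_combined_loss(y, pa)
  mdunet:::ag_backward(loss)
  for (i in 1:4) {
    eps <- 1e-6; o <- pa$val[i]
    pa$val[i] <- o + eps; f1 <- combined_loss(y, pa$val)
    pa$val[i] <- o - eps; f2 <- combined_loss(y, pa$val)
    pa$val[i] <- o
    expect_equal(pa$grad[i], (f1 - f2) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("batched autodiff dice averages image-wise losses", {
  set.seed(34)
  y <- array((runif(2 * 9) > 0.5) * 1, c(3, 3, 1, 2))   # internal layout
  p <- array(runif(2 * 9, 0.05, 0.95), c(3, 3, 1, 2))
  got <- mdunet:::ag_val(mdunet:::ag_dice_loss(y, mdunet:::ag_var(p)))
  per <- sapply(1:2, function(b) dice_loss(as.numeric(y[, , , b]),
                                           as.numeric(p[, , , b])))
  expect_equal(got, mean(per), tolerance = 1e-12)
})

test_that("confusion counts partition the pixels", {
  # hand-counted 2x2 case
  cc <- confusion_counts(c(0.9, 0.2, 0.7, 0.1), c(1, 0, 0, 0))
  expect_equal(cc, list(tp = 1, fp = 1, fn = 0, tn = 2))
  # already binary prediction gives no errors
  set.seed(35)
  y <- (runif(50) > 0.3) * 1
  cc2 <- confusion_counts(y, y)
  expect_equal(cc2$fp + cc2$fn, 0)
  # counts sum to the pixel count
  p <- runif(50)
  cc3 <- confusion_counts(p, y)
  expect_equal(cc3$tp + cc3$fp + cc3$fn + cc3$tn, 50)
})

test_that("IoU and Dice follow their closed forms and identity", {
  expect_equal(iou_score(list(tp = 3, fp = 1, fn = 1)), 0.6)
  expect_equal(dice_score(list(tp = 3, fp = 1, fn = 1)), 0.75)
  expect_equal(iou_score(list(tp = 5, fp = 0, fn = 0)), 1)
  expect_equal(dice_score(list(tp = 5, fp = 0, fn = 0)), 1)
  # empty-vs-empty scores 1 by convention
  expect_equal(iou_score(list(tp = 0, fp = 0, fn = 0)), 1)
  expect_equal(dice_score(list(tp = 0, fp = 0, fn = 0)), 1)
  # dice = 2 iou / (1 + iou) over 1000 random confusion triples
  set.seed(36)
  for (i in 1:1000) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1), fn = sample(0:50, 1))
    if (cc$tp + cc$fp + cc$fn == 0) next
    iou <- iou_score(cc)
    expect_equal(dice_score(cc), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("metrics reports are permutation invariant and support pooling", {
  set.seed(37)
  preds <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
  masks <- lapply(1:4, function(i) matrix((runif(64) > 0.5) * 1, 8, 8))
  r1 <- metrics_report(preds, masks, pooled = TRUE)
  ord <- c(3, 1, 4, 2)
  r2 <- metrics_report(preds[ord], masks[ord], pooled = TRUE)
  expect_equal(r1$iou, r2$iou)
  expect_equal(r1$dice, r2$dice)
  expect_equal(r1$iou_pooled, r2$iou_pooled)
  expect_gte(r1$dice, r1$iou)          # dice >= iou always
  # report writing round-trip
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics_report(r1, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 4)
  agg <- jsonlite::read_json(js)
  expect_equal(agg$iou, r1$iou, tolerance = 1e-9)
})
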