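# Training objective: binary cross-entropy plus Dice loss, unweighted.
#
# Predictions are probability maps in (0,1); BCE clamps them to
# [eps, 1 - eps] with eps = 1e-7 before taking logs.  The Dice loss uses
# image-wise sums with smoothing constant exactly 1 in numerator and
# denominator, and is averaged over the batch.

bce_eps <- 1e-7

check_same_shape <- function(y, yhat, what) {
  dy <- dim(y) %||% length(y); dh <- dim(yhat) %||% length(yhat)
  if (!identical(as.integer(dy), as.integer(dh)))
    stop(sprintf("%s: shape mismatch between mask [%s] and prediction [%s]",
                 what, paste(dy, collapse = "x"), paste(dh, collapse = "x")))
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels of -(y log p + (1-y) log(1-p)), with p clamped to
#' [1e-7, 1 - 1e-7].
#'
#' @param y binary mask (array or vector in \{0,1\}).
#' @param yhat predicted probabilities, same shape.
#' @return non-negative scalar.
#' @export
bce_loss <- function(y, yhat) {
  check_same_shape(y, yhat, "bce_loss")
  p <- pmin(pmax(yhat, bce_eps), 1 - bce_eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# batch-aware per-image sums: x is (B,1,H,W) or any array; returns per-image
# vector when batched, else a single total
img_sums <- function(x) {
  d <- dim(x)
  if (!is.null(d) && length(d) == 4) rowSums(matrix(x, d[1])) else sum(x)
}

#' Dice loss
#'
#' `1 - (2*sum(y*p) + 1) / (sum(y) + sum(p) + 1)` with image-wise sums,
#' averaged over the batch for 4-D inputs.  The smoothing constant 1 keeps
#' the loss defined (and zero) for empty masks matched by empty predictions.
#'
#' @inheritParams bce_loss
#' @return scalar in `[0, 1)`.
#' @export
dice_loss <- function(y, yhat) {
  check_same_shape(y, yhat, "dice_loss")
  inter <- img_sums(y * yhat)
  tot <- img_sums(y) + img_sums(yhat)
  mean(1 - (2 * inter + 1) / (tot + 1))
}

#' Combined segmentation loss: BCE + Dice, unweighted sum
#'
#' @inheritParams bce_loss
#' @export
combined_loss <- function(y, yhat) {
  bce_loss(y, yhat) + dice_loss(y, yhat)
}

# ---- autodiff versions (used by the training loop) -------------------------

ag_bce_loss <- function(y, p) {
  p <- as_ag(p)
  pv <- pmin(pmax(p$val, bce_eps), 1 - bce_eps)
  n <- length(pv)
  v <- -mean(y * log(pv) + (1 - y) * log(1 - pv))
  ag_charge(3 * n)
  ag_op(v, list(p), function(g) {
    inside <- (p$val > bce_eps) & (p$val < 1 - bce_eps)
    list(as.numeric(g) / n * (pv - y) / (pv * (1 - pv)) * inside)
  })
}

# internal-layout per-image sums: x is (H, W, C, B), batch last
img_sums_int <- function(x) {
  d <- dim(x)
  if (!is.null(d) && length(d) == 4) colSums(matrix(x, prod(d[1:3]))) else sum(x)
}

ag_dice_loss <- function(y, p) {
  p <- as_ag(p)
  d <- dim(p$val)
  B <- if (length(d) == 4) d[4] else 1L
  inter <- img_sums_int(y * p$val)
  sy <- img_sums_int(y)
  sp <- img_sums_int(p$val)
  den <- sy + sp + 1
  v <- mean(1 - (2 * inter + 1) / den)
  ag_charge(3 * length(p$val))
  ag_op(v, list(p), function(g) {
    # d/dp_i of image b's term: -2 y_i / den_b + (2 inter_b + 1) / den_b^2
    gy <- as.numeric(g) / B
    if (length(d) == 4) {
      n_img <- prod(d[1:3])
      co1 <- rep(2 / den, each = n_img)
      co2 <- rep((2 * inter + 1) / den^2, each = n_img)
      list(gy * (-(y * co1) + co2))
    } else {
      list(gy * (-(2 * y / den) + (2 * inter + 1) / den^2))
    }
  })
}

ag_combined_loss <- function(y, p) ag_add(ag_bce_loss(y, p), ag_dice_loss(y, p))
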