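# Training loop: Adam with cosine-annealed learning rate on the BCE+Dice
# objective, per-epoch validation IoU/Dice, best-checkpoint retention.

#' Training configuration
#'
#' Defaults are the reference schedule: Adam (first-moment decay 0.9) from a
#' learning rate of 1e-3 annealed along a half-cosine to 1e-5 over
#' `max_epochs`, batch size 32, up to 500 epochs.
#'
#' @param lr_max initial learning rate.
#' @param lr_min final learning rate of the cosine schedule.
#' @param adam_beta1 Adam first-moment decay ("momentum" 0.9).
#' @param adam_beta2 Adam second-moment decay.
#' @param batch_size minibatch size.
#' @param max_epochs cosine period and maximum epoch count.
#' @param seed RNG seed for shuffling (weight init is seeded at build time).
#' @param shuffle shuffle the training set each epoch?
#' @param resplit_each_epoch re-draw the train/val split every epoch (the
#'   literal per-epoch allocation; leaks validation data across epochs, off
#'   by default).
#' @export
train_config <- function(lr_max = 1e-3, lr_min = 1e-5, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, batch_size = 32L,
                         max_epochs = 500L, seed = 1L, shuffle = TRUE,
                         resplit_each_epoch = FALSE) {
  stopifnot(0 < lr_min, lr_min < lr_max, batch_size >= 1)
  structure(list(lr_max = lr_max, lr_min = lr_min, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle),
                 resplit_each_epoch = isTRUE(resplit_each_epoch)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_min + (lr_max - lr_min) (1 + cos(pi e / max_epochs)) / 2`;
#' monotone non-increasing from `lr_max` at epoch 0 to `lr_min` at
#' `max_epochs`.
#'
#' @param epoch epoch index in `[0, max_epochs]`.
#' @param cfg a [train_config()].
#' @export
cosine_annealing_lr <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0 | epoch > cfg$max_epochs))
    stop(sprintf("epoch %s out of range [0, %d]", toString(epoch),
                 cfg$max_epochs))
  cfg$lr_min + 0.5 * (cfg$lr_max - cfg$lr_min) *
    (1 + cos(pi * epoch / cfg$max_epochs))
}

# stack seg_samples into internal-layout tensors: x (H,W,3,B), y (H,W,1,B)
samples_to_batch <- function(samples) {
  B <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 3, B))
  y <- array(0, c(d[1], d[2], 1, B))
  for (b in seq_len(B)) {
    x[, , , b] <- samples[[b]]$image
    y[, , 1, b] <- samples[[b]]$mask
  }
  list(x = x, y = y)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p$val * 0, v = p$val * 0))
}

adam_step <- function(params, state, lr, beta1, beta2, t, eps = 1e-8) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
    state[[nm]] <- st
  }
  state
}

#' Train a model
#'
#' Per epoch: shuffle, Adam minibatch steps on the combined BCE+Dice loss at
#' the cosine-annealed learning rate, then validation IoU/Dice.  The
#' parameter set with the best validation IoU is restored into the model at
#' the end (when a validation set is given).
#'
#' @param model an `mdunet_model` (modified in place: parameters are
#'   environments).
#' @param train_set,val_set lists of `seg_sample`s (`val_set` may be NULL).
#' @param cfg a [train_config()].
#' @param epochs number of epochs to run (default `cfg$max_epochs`); the
#'   cosine period stays `cfg$max_epochs`.
#' @param history_csv optional path for the per-epoch history CSV.
#' @param verbose print one line per epoch?
#' @param eval_every validate every this many epochs (1 = every epoch).
#' @param stop_when_val_dice optional early-stopping threshold: training
#'   stops once the validation Dice reaches this value.
#' @return list with the trained `model` and `history` data.frame (epoch,
#'   lr, train_loss, val_iou, val_dice).
#' @export
train_loop <- function(model, train_set, val_set = NULL,
                       cfg = train_config(), epochs = cfg$max_epochs,
                       history_csv = NULL, verbose = FALSE,
                       eval_every = 1L, stop_when_val_dice = NULL) {
  if (!length(train_set)) stop("train_loop: empty training set")
  set.seed(cfg$seed)
  params <- model_params(model)
  state <- adam_init(params)
  t_step <- 0L
  hist <- vector("list", epochs)
  best <- list(iou = -Inf, params = NULL)
  pool <- c(train_set, val_set)
  for (epoch in seq_len(epochs)) {
    if (cfg$resplit_each_epoch && length(val_set)) {
      idx <- sample.int(length(pool))
      n_val <- length(val_set)
      val_set <- pool[idx[seq_len(n_val)]]
      train_set <- pool[idx[-seq_len(n_val)]]
    }
    lr <- cosine_annealing_lr(epoch - 1, cfg)
    ord <- if (cfg$shuffle) sample.int(length(train_set)) else seq_along(train_set)
    losses <- c()
    for (i0 in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[i0:min(i0 + cfg$batch_size - 1, length(ord))]
      batch <- samples_to_batch(train_set[bidx])
      out <- model_forward_ag(model, ag_var(batch$x))
      loss <- ag_combined_loss(batch$y, out)
      lv <- ag_val(loss)
      if (!is.finite(lv))
        stop(sprintf("NaN/Inf loss at epoch %d, batch starting %d, lr %.3g",
                     epoch, i0, lr))
      ag_backward(loss)
      t_step <- t_step + 1L
      state <- adam_step(params, state, lr, cfg$adam_beta1, cfg$adam_beta2,
                         t_step)
      losses <- c(losses, lv)
    }
    val_iou <- NA_real_; val_dice <- NA_real_
    if (length(val_set) && (epoch %% eval_every == 0 || epoch == epochs)) {
      vm <- evaluate(model, val_set)
      val_iou <- vm$iou; val_dice <- vm$dice
      if (val_iou > best$iou) {
        best$iou <- val_iou
        best$params <- lapply(params, function(p) p$val)
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = mean(losses),
                                val_iou = val_iou, val_dice = val_dice)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val IoU %s", epoch, lr,
                      mean(losses),
                      ifelse(is.na(val_iou), "-", sprintf("%.4f", val_iou))))
    if (!is.null(stop_when_val_dice) && !is.na(val_dice) &&
        val_dice >= stop_when_val_dice) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  if (!is.null(best$params)) {
    for (nm in names(params)) params[[nm]]$val <- best$params[[nm]]
  }
  if (!is.null(history_csv)) write.csv(history, history_csv, row.names = FALSE)
  list(model = model, history = history)
}

#' Evaluate a model on a sample set
#'
#' Forward passes in evaluation mode, per-image confusion counts at the 0.5
#' threshold, aggregated per the metrics defaults (mean of per-image
#' scores).
#'
#' @param model an `mdunet_model`.
#' @param test_set list of `seg_sample`s.
#' @param threshold binarization threshold.
#' @param batch_size forward batch size.
#' @param pooled also compute pixel-pooled aggregates?
#' @return a `metrics_report`.
#' @export
evaluate <- function(model, test_set, threshold = 0.5, batch_size = 4L,
                     pooled = FALSE) {
  if (!length(test_set)) stop("evaluate: empty test set")
  preds <- vector("list", length(test_set))
  masks <- vector("list", length(test_set))
  ids <- vapply(test_set, function(s) s$image_id, character(1))
  for (i0 in seq(1, length(test_set), by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, length(test_set))
    batch <- samples_to_batch(test_set[idx])
    p <- ag_val(model_forward_ag(model, ag_var(batch$x)))
    for (j in seq_along(idx)) {
      preds[[idx[j]]] <- p[, , , j, drop = FALSE]
      masks[[idx[j]]] <- batch$y[, , , j, drop = FALSE]
    }
  }
  metrics_report(preds, masks, ids, threshold, pooled)
}
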