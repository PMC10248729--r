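#' Training configuration
#'
#' The training recipe: Adam, 100 epochs, batch size 8, training order
#' reshuffled every epoch, and a reduce-on-plateau schedule that multiplies
#' the learning rate by 0.8 after 5 consecutive epochs without improvement
#' of the monitored validation loss.
#'
#' @param epochs Training epochs.
#' @param batch_size Patches per optimizer step.
#' @param learning_rate Initial Adam learning rate.
#' @param plateau_factor Multiplier applied to the learning rate on plateau.
#' @param plateau_patience Epochs without improvement before a drop.
#' @param min_delta Minimum absolute decrease of validation loss that
#'   counts as an improvement.
#' @param min_lr Learning-rate floor.
#' @param loss_name Training loss: `"bce"`, `"dice"` or `"jaccard"`.
#' @param shuffle_each_epoch Reshuffle the training order every epoch.
#' @param seed Seed for shuffling (and anything stochastic in the loop).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, learning_rate = 1e-3,
                         plateau_factor = 0.8, plateau_patience = 5L,
                         min_delta = 1e-4, min_lr = 1e-6,
                         loss_name = c("bce", "dice", "jaccard"),
                         shuffle_each_epoch = TRUE, seed = 42L) {
  if (plateau_factor <= 0 || plateau_factor >= 1)
    stop("train_config: plateau_factor must be in (0, 1)")
  if (plateau_patience < 1L) stop("train_config: plateau_patience must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_delta = min_delta, min_lr = min_lr,
                 loss_name = match.arg(loss_name),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Reduce-on-plateau learning-rate trace
#'
#' Pure reconstruction of the learning-rate schedule from a validation-loss
#' sequence: the best loss so far must improve by at least `min_delta`
#' within `patience` consecutive epochs, otherwise the rate is multiplied
#' by `factor` (never below `min_lr`) and the patience counter restarts.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param factor,patience,min_delta,min_lr Schedule parameters.
#' @param init_lr Starting learning rate.
#' @return Numeric vector: the learning rate in effect at each epoch.
#' @export
plateau_schedule <- function(val_losses, factor = 0.8, patience = 5L,
                             min_delta = 1e-4, init_lr = 1e-3, min_lr = 1e-6) {
  lr <- init_lr
  best <- Inf
  wait <- 0L
  trace <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    trace[e] <- lr
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- max(lr * factor, min_lr)
        wait <- 0L
      }
    }
  }
  trace
}

#' Split a patch dataset into training and validation parts
#'
#' Deterministic seeded split at the patch level; the two parts are an
#' exact disjoint partition. With the standard pipeline counts (3,675
#' patches at 80/20) this yields 2,940 training and 735 validation patches.
#'
#' @param items List (or vector) of records.
#' @param train_fraction Fraction assigned to training (0 < f < 1).
#' @param seed Integer seed.
#' @return List with `train` and `validation`.
#' @export
split_dataset <- function(items, train_fraction = 0.8, seed = 42L) {
  n <- length(items)
  if (n == 0L) stop("split_dataset: empty input")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("split_dataset: train_fraction must be in (0, 1)")
  n_train <- round(n * train_fraction)
  idx <- with_seed(seed, sample.int(n))
  list(train = items[idx[seq_len(n_train)]],
       validation = items[idx[setdiff(seq_len(n), seq_len(n_train))]])
}

# ---- optimizer --------------------------------------------------------------

adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7, t) {
  for (p in params) {
    if (is.null(p$grad) || isFALSE(p$trainable)) { p$grad <- NULL; next }
    if (is.null(p$m)) { p$m <- p$value * 0; p$v <- p$value * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

snapshot_params <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, snap) {
  for (k in seq_along(params)) params[[k]]$value <- snap[[k]]
  invisible(NULL)
}

stack_batch <- function(items, field) {
  x1 <- items[[1]][[field]]
  if (field == "mask") {
    arr <- array(unlist(lapply(items, `[[`, field), use.names = FALSE),
                 dim = c(dim(x1), 1L, length(items)))
  } else {
    arr <- array(unlist(lapply(items, `[[`, field), use.names = FALSE),
                 dim = c(dim(x1), length(items)))
  }
  arr
}

# ---- training loop ----------------------------------------------------------

#' Train the segmentation network
#'
#' Runs the full recipe: per-epoch shuffling, Adam updates, per-epoch
#' validation (loss plus hard accuracy/Dice/Jaccard at threshold 0.5),
#' the reduce-on-plateau schedule, and retention of the parameters with
#' the lowest validation loss (restored into the model when training
#' ends). Patch images are scaled to [0, 1] internally.
#'
#' @param model A [build_network()] model (modified in place).
#' @param train_set,val_set Lists of records, each with `image`
#'   (H x W x 3, 0-255) and `mask` (H x W in \{0, 1\}).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `dcsa_train_state` with the epoch `history`
#'   data frame and `best_epoch`.
#' @export
train_network <- function(model, train_set, val_set, config = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "dcsa_net"), inherits(config, "train_config"))
  params <- collect_params(model)
  lr <- config$learning_rate
  best <- Inf
  wait <- 0L
  best_snap <- NULL
  best_epoch <- NA_integer_
  hist <- vector("list", config$epochs)
  t_step <- 0L
  n <- length(train_set)
  rng_seed <- config$seed
  for (epoch in seq_len(config$epochs)) {
    order <- if (config$shuffle_each_epoch)
      with_seed(rng_seed + epoch, sample.int(n)) else seq_len(n)
    train_loss <- 0
    n_batches <- 0L
    for (at in seq(1L, n, by = config$batch_size)) {
      idx <- order[at:min(at + config$batch_size - 1L, n)]
      xb <- stack_batch(train_set[idx], "image") / 255
      yb <- stack_batch(train_set[idx], "mask")
      fw <- network_forward(model, xb, training = TRUE)
      p <- fw$value
      lv <- loss_value(config$loss_name, p, yb)
      if (!is.finite(lv))
        stop(sprintf(
          "train_network: non-finite %s loss at epoch %d, step %d (lr %.3g)",
          config$loss_name, epoch, n_batches + 1L, lr))
      g <- loss_grad(config$loss_name, p, yb)
      dim(g) <- dim(p)
      seed_id <- if (config$loss_name == "bce") fw$logits else fw$prob
      tape_backward(fw$tape, seed_id, g)
      t_step <- t_step + 1L
      adam_step(params, lr, t = t_step)
      train_loss <- train_loss + lv
      n_batches <- n_batches + 1L
    }
    val <- evaluate_loss(model, val_set, config$loss_name, config$batch_size)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = train_loss / n_batches,
                                val_loss = val$loss,
                                val_accuracy = val$accuracy,
                                val_dice = val$dice,
                                val_jaccard = val$jaccard,
                                lr = lr)
    if (verbose)
      cat(sprintf("epoch %3d  train %.4f  val %.4f  dice %.3f  lr %.2e\n",
                  epoch, train_loss / n_batches, val$loss, val$dice, lr))
    if (val$loss < best - config$min_delta) {
      best <- val$loss
      wait <- 0L
      best_snap <- snapshot_params(params)
      best_epoch <- epoch
    } else {
      wait <- wait + 1L
      if (wait >= config$plateau_patience) {
        lr <- max(lr * config$plateau_factor, config$min_lr)
        wait <- 0L
      }
    }
  }
  if (!is.null(best_snap)) restore_params(params, best_snap)
  structure(list(history = do.call(rbind, hist), best_epoch = best_epoch,
                 config = config),
            class = "dcsa_train_state")
}

evaluate_loss <- function(model, val_set, loss_name, batch_size) {
  tot <- c(loss = 0, accuracy = 0, dice = 0, jaccard = 0)
  npx <- 0
  nb <- 0L
  for (at in seq(1L, length(val_set), by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, length(val_set))
    xb <- stack_batch(val_set[idx], "image") / 255
    yb <- stack_batch(val_set[idx], "mask")
    p <- network_forward(model, xb, training = FALSE)$value
    w <- length(idx)
    tot["loss"] <- tot["loss"] + w * loss_value(loss_name, p, yb)
    tot["accuracy"] <- tot["accuracy"] + w * seg_accuracy(p, yb)
    tot["dice"] <- tot["dice"] + w * dice_score(p, yb)
    tot["jaccard"] <- tot["jaccard"] + w * jaccard_score(p, yb)
    nb <- nb + w
  }
  as.list(tot / nb)
}

# ---- inference pipeline -----------------------------------------------------

#' Predict a full tile through the patch pipeline
#'
#' Extracts overlapping patches, runs the model on each, and merges the
#' predicted probability patches back to the tile shape (mean fusion in
#' overlaps by default).
#'
#' @param model Anything with a [predict_probs()] method.
#' @param tile H x W x 3 image (0-255 scale), already stain-normalized with
#'   the same settings as training.
#' @param patch_size,stride Window geometry.
#' @param reduce Overlap fusion rule for [merge_patches()].
#' @return H x W probability map in [0, 1].
#' @export
predict_tile <- function(model, tile, patch_size = 128L, stride = 64L,
                         reduce = "mean") {
  grid <- compute_grid(nrow(tile), ncol(tile), patch_size, stride)
  ps <- extract_patches(tile, grid)
  imgs <- array(unlist(ps$patches, use.names = FALSE),
                dim = c(patch_size, patch_size, dim(tile)[3], length(ps$patches)))
  probs <- predict_probs(model, imgs / 255)
  ps$patches <- lapply(seq_len(dim(probs)[3]), function(k) probs[, , k])
  merge_patches(ps, reduce = reduce)
}

#' Post-process a probability map into a clean binary mask
#'
#' Binarizes at `threshold` and removes connected components (8-connected)
#' whose pixel area is below `min_area`; the default of 30 removes the
#' small background noise specks while retaining any component of area 30
#' or more.
#'
#' @param prob_map H x W map in [0, 1].
#' @param threshold Binarization threshold.
#' @param min_area Minimum component area kept, in pixels.
#' @return H x W integer mask in \{0, 1\}.
#' @export
postprocess <- function(prob_map, threshold = 0.5, min_area = 30L) {
  bin <- matrix(as.integer(prob_map >= threshold), nrow = nrow(prob_map))
  lab <- cpp_label_components(bin)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_area)
    if (length(drop) > 0L) bin[lab %in% drop] <- 0L
  }
  bin
}

#' Evaluate a model on labeled tiles, patch by patch
#'
#' Patches every tile with the standard geometry, scores each patch
#' (accuracy, Dice, Jaccard, hard at threshold 0.5), and aggregates the
#' per-patch scores into a [metric_report()] with mean and 95\% bootstrap
#' CI. Six 512 x 512 tiles at patch 128 / stride 64 give 294 patches.
#'
#' @param model Anything with a [predict_probs()] method.
#' @param tiles List of `labeled_tile` records.
#' @param patch_size,stride Window geometry.
#' @param threshold Binarization threshold for the hard scores.
#' @param n_boot,seed Bootstrap settings.
#' @return A [metric_report()].
#' @export
evaluate_model <- function(model, tiles, patch_size = 128L, stride = 64L,
                           threshold = 0.5, n_boot = 1000L, seed = 1L) {
  if (length(tiles) == 0L) stop("evaluate_model: no tiles")
  rows <- list()
  for (ti in seq_along(tiles)) {
    tile <- tiles[[ti]]
    grid <- compute_grid(nrow(tile$mask), ncol(tile$mask), patch_size, stride)
    imgs <- extract_patches(tile$image, grid)$patches
    msks <- extract_patches(tile$mask, grid)$patches
    arr <- array(unlist(imgs, use.names = FALSE),
                 dim = c(patch_size, patch_size, 3L, length(imgs)))
    probs <- predict_probs(model, arr / 255)
    for (k in seq_along(msks)) {
      p <- probs[, , k]
      y <- msks[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        tile = ti, patch = k,
        accuracy = seg_accuracy(p, y, threshold),
        dice = dice_score(p, y, threshold = threshold),
        jaccard = jaccard_score(p, y, threshold = threshold))
    }
  }
  metric_report(do.call(rbind, rows), n_boot = n_boot, seed = seed)
}

#' Overlay a segmentation mask on an image
#'
#' Tints the masked region with a fixed color (alpha-blended); pixels
#' outside the mask are returned unchanged.
#'
#' @param image H x W x 3 array (0-255).
#' @param mask H x W mask in \{0, 1\}.
#' @param color RGB triple of the tint.
#' @param alpha Blend weight of the tint inside the mask.
#' @return H x W x 3 array.
#' @export
colorize_overlay <- function(image, mask, color = c(60, 200, 60), alpha = 0.5) {
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("colorize_overlay: image and mask shapes differ")
  out <- image
  idx <- which(mask == 1)
  if (length(idx) > 0L) {
    hw <- prod(dim(mask))
    for (ch in 1:3)
      out[idx + (ch - 1L) * hw] <-
        (1 - alpha) * image[idx + (ch - 1L) * hw] + alpha * color[ch]
  }
  out
}
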