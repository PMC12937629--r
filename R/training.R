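#' Training configuration
#'
#' Hyperparameters of the study's training procedure: Adam
#' (beta1 = 0.9, beta2 = 0.999) at an initial learning rate of 1e-4, cosine
#' annealing with warm restarts, batch size 8, at most 60 epochs with early
#' stopping at patience 8 on the validation loss, and categorical
#' cross-entropy computed from logits.  The restart schedule's period
#' parameters are configurable (defaults: first cycle of 10 epochs, period
#' doubling, floor learning rate 0).
#'
#' @param learning_rate Initial (cycle-peak) learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param adam_eps Adam denominator stabiliser.
#' @param restart_period Epochs in the first cosine cycle (T0).
#' @param period_multiplier Cycle-length multiplier at each restart (T_mult).
#' @param min_lr Learning-rate floor of the cosine schedule.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience Consecutive epochs without validation-loss
#'   improvement tolerated before stopping.
#' @param mixed_precision Present for configuration completeness; all
#'   computation here is double precision and the flag has no effect.
#' @param seed Seed covering data order, weight initialisation and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, restart_period = 10L,
                         period_multiplier = 2, min_lr = 0,
                         batch_size = 8L, max_epochs = 60L,
                         early_stop_patience = 8L, mixed_precision = FALSE,
                         seed = 42L) {
  cfg <- list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
              adam_eps = adam_eps, restart_period = as.integer(restart_period),
              period_multiplier = period_multiplier, min_lr = min_lr,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              mixed_precision = isTRUE(mixed_precision),
              seed = as.integer(seed))
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (cfg$batch_size < 1L) stop("batch_size must be at least 1", call. = FALSE)
  if (cfg$early_stop_patience < 1L) stop("early_stop_patience must be at least 1",
                                         call. = FALSE)
  if (cfg$restart_period < 1L) stop("restart_period must be at least 1", call. = FALSE)
  class(cfg) <- "train_config"
  cfg
}

#' Cosine-annealing learning rate within a cycle
#'
#' `lr_at()` evaluates the cosine annealing curve at a position within the
#' current cycle: `eta = min_lr + (learning_rate - min_lr) / 2 *
#' (1 + cos(pi * fraction))`.  `lr_at_epoch()` maps a 1-based epoch number
#' onto the warm-restart schedule, whose cycle length multiplies by
#' `period_multiplier` at each restart.
#'
#' @param config A [train_config()].
#' @param fraction Position in the current cycle, in `[0, 1]`.
#' @return The learning rate.
#' @export
lr_at <- function(config, fraction) {
  if (any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]", call. = FALSE)
  config$min_lr +
    0.5 * (config$learning_rate - config$min_lr) * (1 + cos(pi * fraction))
}

#' @rdname lr_at
#' @param epoch 1-based epoch number.
#' @export
lr_at_epoch <- function(config, epoch) {
  e <- as.integer(epoch) - 1L # 0-based position in the schedule
  len <- config$restart_period
  while (e >= len) {
    e <- e - len
    len <- max(1L, as.integer(round(len * config$period_multiplier)))
  }
  lr_at(config, e / len)
}

#' Categorical cross-entropy on logits
#'
#' Numerically stable softmax cross-entropy, averaged over the batch, with
#' its gradient with respect to the logits.
#'
#' @param logits A `K x N` matrix.
#' @param labels 0-based integer class labels of length `N`.
#' @return List with `loss`, `dlogits` (`K x N`) and `pred` (0-based argmax).
#' @export
softmax_crossentropy <- function(logits, labels) {
  n <- ncol(logits)
  stopifnot(length(labels) == n)
  p <- softmax_cols(logits)
  idx <- cbind(as.integer(labels) + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / n,
       pred = max.col(t(p), ties.method = "first") - 1L)
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (l in model$layers) {
    for (f in layer_param_fields(l)) {
      key <- paste0(l$name, ".", f)
      st$m[[key]] <- array(0, dim = dim(l[[f]]) %||% length(l[[f]]))
      st$v[[key]] <- st$m[[key]]
    }
  }
  st
}

adam_step <- function(model, st, lr, config) {
  st$t <- st$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (l in model$layers) {
    for (f in layer_param_fields(l)) {
      key <- paste0(l$name, ".", f)
      g <- l[[layer_grad_field(f)]]
      st$m[[key]] <- b1 * st$m[[key]] + (1 - b1) * g
      st$v[[key]] <- b2 * st$v[[key]] + (1 - b2) * g * g
      l[[f]] <- l[[f]] - lr * (st$m[[key]] / bc1) /
        (sqrt(st$v[[key]] / bc2) + config$adam_eps)
    }
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Early stopping ------------------------------------------------------

#' Early-stopping trace on a validation-loss sequence
#'
#' Pure form of the patience rule used by [train_model()]: any decrease of
#' the running best resets the counter; training stops once the loss has
#' failed to improve for `patience` consecutive epochs.
#'
#' @param val_losses Per-epoch validation losses.
#' @param patience Number of tolerated non-improving epochs.
#' @return List with `stop_epoch` (last epoch run), `best_epoch`, and
#'   `stopped_early`.
#' @export
early_stop_trace <- function(val_losses, patience) {
  best <- Inf; best_epoch <- 0L; since <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience)
      return(list(stop_epoch = e, best_epoch = best_epoch, stopped_early = TRUE))
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch,
       stopped_early = FALSE)
}

# Forward a dataset in inference mode, in chunks, returning loss/accuracy
# and (optionally) the probability matrix.
eval_pass <- function(model, data, chunk = 32L, probs = FALSE) {
  n <- length(data$y)
  loss_sum <- 0; correct <- 0L
  pmat <- if (probs) matrix(NA_real_, n, model$config$num_classes)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    logits <- forward_logits(model, data$x[, , , idx, drop = FALSE],
                             training = FALSE)
    ce <- softmax_crossentropy(logits, data$y[idx])
    loss_sum <- loss_sum + ce$loss * length(idx)
    correct <- correct + sum(ce$pred == data$y[idx])
    if (probs) pmat[idx, ] <- t(softmax_cols(logits))
  }
  list(loss = loss_sum / n, accuracy = correct / n, probs = pmat)
}

#' Train a Bone-CNN model
#'
#' Minimises categorical cross-entropy with Adam under the cosine
#' warm-restart schedule (one scheduler step per epoch), evaluates the
#' validation set after every epoch, keeps the weights of the epoch with
#' the lowest validation loss, and stops early when the validation loss has
#' not improved for `early_stop_patience` consecutive epochs.  All
#' randomness (mini-batch order, dropout) is drawn from the R RNG seeded
#' with `config$seed`; build the model under the same seed for a fully
#' reproducible run.
#'
#' @param model A `bone_cnn` model (modified in place; the best epoch's
#'   weights are restored before returning).
#' @param train,val Datasets as lists with `x` (an `(H, W, C, N)` array) and
#'   `y` (0-based integer labels); see [load_split()].
#' @param config A [train_config()].
#' @param stop_at_train_accuracy Optional threshold in `(0, 1]`: stop as
#'   soon as the epoch's training accuracy reaches it (used by capacity
#'   checks, not part of the study protocol).  The in-loop training
#'   accuracy is computed under dropout and batch statistics; for a
#'   noise-free readout evaluate the training set in inference mode.
#' @param stop_at_val_accuracy Optional threshold in `(0, 1]`: stop once
#'   the epoch's validation accuracy (inference mode) reaches it.
#' @param verbose Print one line per epoch.
#' @return List of class `bone_training` with `model`, `history` (one row
#'   per epoch), `best_epoch`, `best_val_loss` and `stopped_early`.
#' @export
train_model <- function(model, train, val, config = train_config(),
                        stop_at_train_accuracy = NULL,
                        stop_at_val_accuracy = NULL, verbose = FALSE) {
  if (is.null(train$y) || length(train$y) == 0L)
    stop("training set is empty", call. = FALSE)
  if (is.null(val$y) || length(val$y) == 0L)
    stop("validation set is empty", call. = FALSE)
  set.seed(config$seed)
  st <- adam_init(model)
  n <- length(train$y)
  best <- Inf; best_epoch <- 0L; best_weights <- NULL
  since <- 0L; stopped_early <- FALSE
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(n)
    loss_sum <- 0; correct <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- train$x[, , , idx, drop = FALSE]
      yb <- train$y[idx]
      logits <- forward_logits(model, xb, training = TRUE)
      ce <- softmax_crossentropy(logits, yb)
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
      backward_bone_cnn(model, ce$dlogits)
      st <- adam_step(model, st, lr, config)
      loss_sum <- loss_sum + ce$loss * length(idx)
      correct <- correct + sum(ce$pred == yb)
    }
    train_loss <- loss_sum / n
    train_acc <- correct / n
    ve <- eval_pass(model, val)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                train_accuracy = train_acc,
                                val_loss = ve$loss, val_accuracy = ve$accuracy,
                                learning_rate = lr)
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.2e  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
        epoch, lr, train_loss, train_acc, ve$loss, ve$accuracy))
    if (ve$loss < best) {
      best <- ve$loss; best_epoch <- epoch; since <- 0L
      best_weights <- get_weights(model)
    } else {
      since <- since + 1L
    }
    if (since >= config$early_stop_patience) { stopped_early <- TRUE; break }
    if (!is.null(stop_at_train_accuracy) &&
        train_acc >= stop_at_train_accuracy) break
    if (!is.null(stop_at_val_accuracy) &&
        ve$accuracy >= stop_at_val_accuracy) break
  }

  if (!is.null(best_weights)) set_weights(model, best_weights)
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  out <- list(model = model, history = history, best_epoch = best_epoch,
              best_val_loss = best, stopped_early = stopped_early)
  class(out) <- "bone_training"
  out
}

#' @export
print.bone_training <- function(x, ...) {
  cat(sprintf("Bone-CNN training: %d epochs (best epoch %d, val loss %.4f%s)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss,
              if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

#' Training diagnostics
#'
#' `overfit_gap` is the final validation loss minus the final training
#' loss.  `epoch_to_plateau` is the first epoch after which the running
#' minimum of the validation loss never improves by `epsilon` or more.
#'
#' @param history A training history data frame (see [train_model()]).
#' @param epsilon Improvement threshold defining the plateau.
#' @return List with `overfit_gap` and `epoch_to_plateau`.
#' @export
training_diagnostics <- function(history, epsilon = 1e-3) {
  stopifnot(nrow(history) >= 1L)
  gap <- history$val_loss[nrow(history)] - history$train_loss[nrow(history)]
  run_min <- cummin(history$val_loss)
  plateau <- nrow(history)
  for (e in seq_len(nrow(history))) {
    later <- if (e < nrow(history)) min(history$val_loss[(e + 1):nrow(history)]) else Inf
    if (later >= run_min[e] - epsilon) { plateau <- e; break }
  }
  list(overfit_gap = gap, epoch_to_plateau = plateau)
}

#' Write a training history as CSV
#'
#' @param history Training history data frame.
#' @param path Output CSV path.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
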