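#' Training configuration
#'
#' Defaults follow standard practice for a compact image-regression U-Net:
#' mean-squared-error loss on the raw tanh outputs against `[0,1]` targets,
#' Adam with learning rate 0.001 (beta1 0.9, beta2 0.999, epsilon 1e-7),
#' batches of 32 slices drawn randomly each step, up to 120 epochs with
#' early stopping on validation loss at patience 20, keeping the
#' best-validation-epoch weights.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size slices per gradient update (>= 1).
#' @param max_epochs maximum training epochs.
#' @param steps_per_epoch gradient updates per epoch; default
#'   `ceiling(n_train / batch_size)`.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed driving batch sampling and dropout.
#' @param keep_best return the weights of the best validation epoch rather
#'   than the last epoch.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         max_epochs = 120L, steps_per_epoch = NULL,
                         patience = 20L, seed = 1L, keep_best = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 1,
            max_epochs >= 1)
  structure(list(loss = "MSE", optimizer = "adam",
                 learning_rate = learning_rate,
                 beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 steps_per_epoch = steps_per_epoch,
                 patience = as.integer(patience),
                 monitor = "val_loss",
                 seed = as.integer(seed),
                 keep_best = isTRUE(keep_best)),
            class = "train_config")
}

#' Early-stopping decision on a validation-loss sequence
#'
#' Returns the first epoch `e` at which the best validation loss so far
#' occurred `patience` or more epochs before `e` (i.e. `patience`
#' consecutive epochs brought no strict improvement), or `NULL` if the
#' rule never triggers.
#'
#' @param validation_losses numeric vector, one loss per epoch.
#' @param patience number of epochs to wait for improvement (>= 1).
#' @return integer stopping epoch, or `NULL`.
#' @export
early_stop_decision <- function(validation_losses, patience) {
  stopifnot(patience >= 1)
  if (length(validation_losses) == 0L)
    stop("validation loss sequence is empty")
  best <- Inf; best_e <- 0L
  for (e in seq_along(validation_losses)) {
    if (validation_losses[e] < best) {
      best <- validation_losses[e]; best_e <- e
    } else if (e - best_e >= patience) {
      return(e)
    }
  }
  NULL
}

mse_loss <- function(y, t) mean((y - t)^2)

# Full-pass loss over a dataset in evaluation mode.
dataset_loss <- function(net, dataset, batch_size) {
  d <- dim(dataset$source)
  tot <- 0
  for (at in seq(1L, d[3], by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, d[3])
    xb <- array(dataset$source[, , idx], dim = c(d[1], d[2], 1L, length(idx)))
    yb <- network_forward(net, xb, training = FALSE)
    tb <- array(dataset$target[, , idx], dim = dim(xb))
    tot <- tot + sum((yb - tb)^2)
  }
  tot / (prod(d[1:2]) * d[3])
}

adam_update <- function(params, pgrads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    if (is.null(pgrads[[i]])) next
    if (is.null(state$m[[i]]))
      state$m[[i]] <- list(w = 0 * params[[i]]$w, b = 0 * params[[i]]$b)
    if (is.null(state$v[[i]]))
      state$v[[i]] <- state$m[[i]]
    for (k in c("w", "b")) {
      g <- pgrads[[i]][[k]]
      state$m[[i]][[k]] <- b1 * state$m[[i]][[k]] + (1 - b1) * g
      state$v[[i]][[k]] <- b2 * state$v[[i]][[k]] + (1 - b2) * g^2
      params[[i]][[k]] <- params[[i]][[k]] -
        lr * (state$m[[i]][[k]] / c1) /
        (sqrt(state$v[[i]][[k]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train a U-Net on paired slices
#'
#' Minimises the mean squared error between the network output and the
#' target slices with Adam. Each step draws a random batch from the
#' training set; the validation loss is evaluated with a full pass after
#' every epoch; training stops at `max_epochs` or when
#' [early_stop_decision()] triggers. With `keep_best` the returned model
#' carries the weights of the epoch with minimal validation loss.
#' Deterministic for fixed seeds.
#'
#' @param network a `unet_network` from [instantiate_network()].
#' @param train,val `slice_pair_dataset`s with slices matching the
#'   network's input shape.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return object of class `unet_fit`: list with `network` (selected
#'   weights), `history` (data frame: epoch, train_loss, val_loss),
#'   `best_epoch`, `stopped_early`, `config`, and the translation
#'   direction.
#' @export
train_model <- function(network, train, val, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(network, "unet_network"),
            inherits(train, "slice_pair_dataset"),
            inherits(val, "slice_pair_dataset"))
  d <- dim(train$source)
  in_shape <- network$graph$config$input_shape
  if (!all(d[1:2] == in_shape[1:2]))
    stop("training slices are ", d[1], "x", d[2],
         " but the network expects ", in_shape[1], "x", in_shape[2])
  n_train <- d[3]
  steps <- config$steps_per_epoch
  if (is.null(steps)) steps <- ceiling(n_train / config$batch_size)
  hist_train <- hist_val <- numeric(0)
  best_val <- Inf; best_epoch <- 0L; best_params <- network$params
  stopped_early <- FALSE
  with_seed(config$seed, {
    state <- list(t = 0L, m = vector("list", length(network$params)),
                  v = vector("list", length(network$params)))
    for (epoch in seq_len(config$max_epochs)) {
      batch_losses <- numeric(steps)
      for (s in seq_len(steps)) {
        idx <- sample(n_train, min(config$batch_size, n_train),
                      replace = n_train < config$batch_size)
        xb <- array(train$source[, , idx],
                    dim = c(d[1], d[2], 1L, length(idx)))
        tb <- array(train$target[, , idx], dim = dim(xb))
        fw <- network_forward(network, xb, training = TRUE)
        batch_losses[s] <- mse_loss(fw$out, tb)
        dout <- 2 * (fw$out - tb) / length(tb)
        pg <- network_backward(network, xb, fw, dout)
        up <- adam_update(network$params, pg, state, config$learning_rate,
                          config$beta1, config$beta2, config$epsilon)
        network$params <- up$params; state <- up$state
      }
      hist_train[epoch] <- mean(batch_losses)
      hist_val[epoch] <- dataset_loss(network, val, config$batch_size)
      if (hist_val[epoch] < best_val) {
        best_val <- hist_val[epoch]; best_epoch <- epoch
        best_params <- network$params
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.6f  val %.6f", epoch,
                        hist_train[epoch], hist_val[epoch]))
      es <- early_stop_decision(hist_val, config$patience)
      if (!is.null(es)) { stopped_early <- TRUE; break }
    }
  })
  if (config$keep_best) network$params <- best_params
  structure(list(network = network,
                 history = data.frame(epoch = seq_along(hist_train),
                                      train_loss = hist_train,
                                      val_loss = hist_val),
                 best_epoch = best_epoch,
                 stopped_early = stopped_early,
                 config = config,
                 source_contrast = train$source_contrast,
                 target_contrast = train$target_contrast),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("U-Net translation model %s -> %s\n", x$source_contrast,
              x$target_contrast))
  cat(sprintf("  %d epochs trained%s; best epoch %d (val MSE %.6f)\n",
              nrow(x$history),
              if (x$stopped_early) " (stopped early)" else "",
              x$best_epoch, x$history$val_loss[x$best_epoch]))
  cat(sprintf("  %s trainable parameters\n",
              format(network_n_params(x$network), big.mark = ",")))
  invisible(x)
}

#' @export
summary.unet_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("U-Net %s -> %s: %d epochs, best epoch %d\n",
              object$source_contrast, object$target_contrast, nrow(h),
              object$best_epoch))
  cat(sprintf("  final train MSE %.6f, final val MSE %.6f, best val MSE %.6f\n",
              h$train_loss[nrow(h)], h$val_loss[nrow(h)],
              min(h$val_loss)))
  print(object$network$graph)
  invisible(object)
}

#' @export
coef.unet_fit <- function(object, ...) {
  p <- object$network$params
  p[!vapply(p, is.null, logical(1))]
}

#' Plot learning curves of a trained model
#'
#' Training and validation MSE against epoch, with the best epoch marked.
#'
#' @param x a `unet_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.unet_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "MSE loss",
                    main = sprintf("%s → %s", x$source_contrast,
                                   x$target_contrast), ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
predict.unet_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "contrast_volume"))
    return(translate_volume(object, newdata, ...))
  network_infer(object$network, newdata, ...)
}

#' Residuals of a trained model on a slice-pair dataset
#'
#' @param object a `unet_fit`.
#' @param dataset a `slice_pair_dataset` for the model's direction.
#' @param ... unused.
#' @return 3D array of per-pixel residuals, prediction minus target.
#' @export
residuals.unet_fit <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "slice_pair_dataset"))
  network_infer(object$network, dataset$source) - dataset$target
}

#' Synthesise a full volume slice-by-slice
#'
#' Applies the training-time preprocessing to the source volume (null-slice
#' removal, z-score + `[0,1]` normalisation over the retained volume,
#' bicubic resize to the network input shape), runs the forward pass slice
#' by slice, clips outputs to `[0,1]`, and reassembles a volume in source
#' slice order with null slices reproduced as zero slices.
#'
#' @param model a `unet_fit` or `unet_network`.
#' @param source a `contrast_volume` (raw, unnormalised).
#' @param retained optional integer vector of retained slice indices (e.g.
#'   the subject-level union over contrasts); default: slices non-null in
#'   the source volume itself.
#' @return a `contrast_volume` of synthesised slices at the network's
#'   in-plane resolution, with attribute `retained_slices`.
#' @export
translate_volume <- function(model, source, retained = NULL) {
  net <- if (inherits(model, "unet_fit")) model$network else model
  stopifnot(inherits(net, "unet_network"),
            inherits(source, "contrast_volume"))
  in_shape <- net$graph$config$input_shape[1:2]
  nz <- dim(source$intensities)[3]
  if (is.null(retained))
    retained <- which(!null_slice_mask(source$intensities))
  if (length(retained) == 0L) stop("source volume has no non-null slices")
  kept <- source
  kept$intensities <- source$intensities[, , retained, drop = FALSE]
  kept <- zscore_unit_scale(kept)$volume
  pre <- array(0, dim = c(in_shape, length(retained)))
  for (k in seq_along(retained))
    pre[, , k] <- resize_slice(kept$intensities[, , k], in_shape)
  synth <- network_infer(net, pre)
  out <- array(0, dim = c(in_shape, nz))
  out[, , retained] <- synth
  structure(list(subject_id = source$subject_id,
                 contrast_name = if (inherits(model, "unet_fit"))
                   model$target_contrast else "synthetic",
                 intensities = out,
                 voxel_size_mm = source$voxel_size_mm,
                 synthetic = TRUE),
            class = "contrast_volume",
            retained_slices = retained)
}

#' Write a training history to CSV
#' @param fit a `unet_fit`.
#' @param path output CSV path (columns epoch, train_loss, val_loss).
#' @export
write_history <- function(fit, path) {
  write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
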