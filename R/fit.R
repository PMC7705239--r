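# Model fitting: mnlnet() trains one network and returns a classed object.

#' Training configuration
#'
#' The optimisation protocol: Adam with initial learning rate 5e-4,
#' mini-batches of 100, cross-entropy loss; the learning rate is multiplied
#' by `lr_decay` whenever validation accuracy has not improved for
#' `patience` epochs (the schedule then re-arms); training stops after
#' `epochs` epochs or when the learning rate falls below `min_lr`; the
#' checkpoint with the best validation accuracy is kept.
#'
#' @param lr Initial learning rate (default 5e-4).
#' @param lr_decay Multiplicative decay at a plateau (default 0.1).
#' @param patience Plateau patience in epochs (default 10).
#' @param batch_size Mini-batch size (default 100).
#' @param epochs Maximum epochs (default 100).
#' @param seed Integer seed for init, shuffling and the validation split.
#' @param val_fraction Stratified fraction of the training data held out
#'   for the schedule and checkpoint selection (default 0.1, must be in
#'   (0, 0.5)).
#' @param min_lr Early-stop threshold on the learning rate.
#' @param verbose Print per-epoch progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 5e-4, lr_decay = 0.1, patience = 10L,
                         batch_size = 100L, epochs = 100L, seed = 1L,
                         val_fraction = 0.1, min_lr = 1e-7,
                         verbose = FALSE) {
  if (val_fraction <= 0 || val_fraction >= 0.5)
    stop("val_fraction must be in (0, 0.5)")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(lr = lr, lr_decay = lr_decay, patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 val_fraction = val_fraction, min_lr = min_lr,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Stratified index split: for each class, hold out `fraction` (at least 1).
stratified_holdout <- function(y, fraction) {
  val <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_val <- max(1L, round(length(idx) * fraction))
    if (n_val >= length(idx))
      stop("validation slice would consume all of class ", cl)
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Fit a multi-scale non-local network classifier
#'
#' Trains the full network on a matrix of fixed-length, z-scored segments
#' with integer class labels. A stratified validation slice is carved from
#' the training data (seeded) for the plateau learning-rate schedule and
#' checkpoint selection; the returned model carries the weights of the
#' epoch with the highest validation accuracy.
#'
#' @param x Numeric matrix, one segment per row (or a
#'   [segment_table()], whose segments and labels are used).
#' @param y Integer labels `0..n_classes-1` (ignored when `x` is a
#'   segment table).
#' @param n_classes Number of classes (default: inferred from `y`).
#' @param config A [train_config()].
#' @param validation Optional list `list(x, y)` to use instead of an
#'   internal holdout.
#' @param arch Optional [mnl_architecture()]; default is the standard
#'   architecture for `ncol(x)` and `n_classes`.
#' @param ... Arguments forwarded to [mnl_architecture()] when `arch` is
#'   not supplied (e.g. `c_hat`, `affinity`).
#' @return An object of class `mnlnet` with elements `params`, `state`,
#'   `arch`, `history` (per-epoch loss, validation accuracy, learning
#'   rate), `best_epoch`, `best_val_accuracy`, `config`.
#' @seealso [predict.mnlnet()], [cross_validate()]
#' @export
mnlnet <- function(x, y = NULL, n_classes = NULL, config = train_config(),
                   validation = NULL, arch = NULL, ...) {
  if (inherits(x, "segment_table")) {
    y <- x$labels
    x <- x$segments
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  if (is.null(n_classes)) n_classes <- max(y) + 1L
  if (any(y < 0L | y >= n_classes)) stop("labels must be in 0..n_classes-1")
  stopifnot(inherits(config, "train_config"))
  if (is.null(arch))
    arch <- mnl_architecture(input_length = ncol(x), n_classes = n_classes,
                             ...)
  if (ncol(x) != arch$input_length)
    stop("segment length does not match architecture input length")

  set.seed(config$seed)
  if (is.null(validation)) {
    val_idx <- stratified_holdout(y, config$val_fraction)
    x_val <- x[val_idx, , drop = FALSE]; y_val <- y[val_idx]
    x_tr <- x[-val_idx, , drop = FALSE]; y_tr <- y[-val_idx]
  } else {
    x_val <- as.matrix(validation$x); y_val <- as.integer(validation$y)
    x_tr <- x; y_tr <- y
  }

  net <- init_network(arch)
  params <- net$params
  state <- net$state
  opt <- adam_init(params)
  lr <- config$lr
  best_val <- -Inf
  best <- NULL
  best_epoch <- 0L
  since_improve <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_accuracy = numeric(0), lr = numeric(0))
  n_tr <- nrow(x_tr)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    losses <- numeric(0)
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      fwd <- network_forward(params, state, x_tr[idx, , drop = FALSE],
                             arch, training = TRUE)
      state <- fwd$state
      ce <- cross_entropy(fwd$probs, y_tr[idx])
      losses <- c(losses, ce$loss)
      grads <- network_backward(params, arch, fwd, ce$dlogits)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params
      opt <- upd$state
    }
    val_pred <- predict_classes(params, state, x_val, arch,
                                config$batch_size)
    val_acc <- mean(val_pred == y_val)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   val_accuracy = val_acc, lr = lr))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.4f  lr %.2e",
                      epoch, mean(losses), val_acc, lr))
    if (val_acc > best_val) {
      best_val <- val_acc
      best <- list(params = params, state = state)
      best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$patience) {
        lr <- lr * config$lr_decay
        since_improve <- 0L
      }
    }
    if (lr < config$min_lr) break
  }

  structure(
    list(params = best$params, state = best$state, arch = arch,
         history = hist, best_epoch = best_epoch,
         best_val_accuracy = best_val, config = config,
         n_train = n_tr, n_val = length(y_val)),
    class = "mnlnet")
}

# Chunked inference returning 0-based class predictions.
predict_classes <- function(params, state, x, arch, batch_size = 512L) {
  p <- predict_probs(params, state, x, arch, batch_size)
  max.col(p, ties.method = "first") - 1L
}

predict_probs <- function(params, state, x, arch, batch_size = 512L) {
  n <- nrow(x)
  out <- matrix(0, n, arch$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- network_forward(params, state, x[idx, , drop = FALSE],
                                  arch, training = FALSE)$probs
  }
  out
}

#' Predict from a fitted network
#'
#' @param object A fitted [mnlnet()] model.
#' @param newdata Segment matrix (or [segment_table()]) with the model's
#'   input length.
#' @param type `"class"` for 0-based integer labels, `"prob"` for the
#'   class-probability matrix.
#' @param batch_size Inference chunk size.
#' @param ... Unused.
#' @return Integer vector or probability matrix (rows sum to 1).
#' @export
predict.mnlnet <- function(object, newdata, type = c("class", "prob"),
                           batch_size = 512L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "segment_table")) newdata <- newdata$segments
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$arch$input_length)
    stop("segment length does not match model input length")
  if (type == "prob")
    predict_probs(object$params, object$state, newdata, object$arch,
                  batch_size)
  else
    predict_classes(object$params, object$state, newdata, object$arch,
                    batch_size)
}

#' @export
print.mnlnet <- function(x, ...) {
  cat(sprintf("<mnlnet> %d-class network, input length %d, %d parameters\n",
              x$arch$n_classes, x$arch$input_length, n_parameters(x)))
  cat(sprintf("  trained %d epoch(s); best validation accuracy %.4f at epoch %d\n",
              nrow(x$history), x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
summary.mnlnet <- function(object, ...) {
  cat("Multi-scale non-local network classifier\n\n")
  print(shape_trace(object$arch), row.names = FALSE)
  cat(sprintf("\nParameters: %d  (c_hat = %d, affinity = %s, reduce = %s)\n",
              n_parameters(object), object$arch$c_hat,
              object$arch$affinity, object$arch$pooling_reduce))
  cat(sprintf("Training: %d epochs, batch %d, lr %.1e (decay %.2f, patience %d)\n",
              nrow(object$history), object$config$batch_size,
              object$config$lr, object$config$lr_decay,
              object$config$patience))
  cat(sprintf("Best validation accuracy %.4f at epoch %d (train n = %d, val n = %d)\n",
              object$best_val_accuracy, object$best_epoch, object$n_train,
              object$n_val))
  invisible(object)
}

#' @export
coef.mnlnet <- function(object, ...) object$params

#' Plot training history
#'
#' Loss and validation accuracy per epoch, with learning-rate decay epochs
#' marked.
#' @param x A fitted [mnlnet()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mnlnet <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "loss", ...)
  plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
       ylab = "validation accuracy", main = "validation accuracy", ...)
  drops <- which(diff(h$lr) < 0) + 1L
  if (length(drops)) graphics::abline(v = h$epoch[drops], lty = 3)
  invisible(x)
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint embeds the architecture specification, weights, batch
#' norm statistics and training history, so it can be evaluated without
#' any side information.
#'
#' @param model A fitted [mnlnet()].
#' @param path Destination file.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored `mnlnet` object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mnlnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mnlnet")) stop("not an mnlnet checkpoint: ", path)
  model
}
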