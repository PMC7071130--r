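# Training: cross-entropy losses, Adam, the mini-batch loop, grid search
# and model serialization.

#' Training configuration
#'
#' Defaults follow the tuned operating point of the reference grid search:
#' batch size 24, learning rate 0.001, 20 epochs, dropout 0.3.
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Adam step size.
#' @param epochs Number of passes over the training set (>= 1).
#' @param dropout Dropout rate in \[0, 1).
#' @param seed Integer seed: fixes parameter init, epoch shuffles and
#'   dropout masks, so a run is exactly reproducible.
#' @param task `"detection"` or `"location"`.
#' @param hidden,attn_dim,n_kernels Architecture sizes (see
#'   [mla_cnn_bigru()]).
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 24, learning_rate = 0.001, epochs = 20,
                         dropout = 0.3, seed = 1,
                         task = c("detection", "location"),
                         hidden = 64, attn_dim = 32, n_kernels = 20) {
  task <- match.arg(task)
  if (batch_size < 1) stop_invalid("`batch_size` must be >= 1")
  if (epochs < 1) stop_invalid("`epochs` must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_invalid("`dropout` must be in [0, 1)")
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         epochs = as.integer(epochs), dropout = dropout,
         seed = as.integer(seed), task = task, hidden = hidden,
         attn_dim = attn_dim, n_kernels = n_kernels),
    class = "train_config"
  )
}

#' Mean cross-entropy loss
#'
#' Binary cross-entropy for detection (labels 0/1, sigmoid output) or
#' categorical cross-entropy for location (one-hot labels, softmax output),
#' averaged over the batch.
#'
#' @param probs Batch x 1 (detection) or batch x C (location) probability
#'   matrix.
#' @param labels 0/1 vector (detection) or one-hot batch x C matrix
#'   (location).
#' @param task `"detection"` or `"location"`.
#' @param eps Probability floor for numerical safety.
#' @return Scalar mean loss.
#' @export
#' @examples
#' ce_loss(matrix(rep(1/6, 6), 1), diag(6)[1, , drop = FALSE], "location")
#' # = log(6)
ce_loss <- function(probs, labels, task = c("detection", "location"),
                    eps = 1e-12) {
  task <- match.arg(task)
  if (task == "detection") {
    p <- pmin(pmax(as.numeric(probs), eps), 1 - eps)
    y <- as.numeric(labels)
    if (!all(y %in% c(0, 1))) stop_invalid("detection labels must be 0/1")
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    if (!is.matrix(labels) || !all(rowSums(labels) == 1)) {
      stop_invalid("location labels must be one-hot rows")
    }
    p <- pmax(probs, eps)
    -mean(log(p[labels == 1]))
  }
}

# One-hot / numeric encoding of labels against the model's class set.
encode_labels <- function(labels, class_names, task) {
  idx <- match(labels, class_names)
  if (anyNA(idx)) {
    stop_invalid("label(s) outside the class set: ",
                 paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  if (task == "detection") {
    as.numeric(idx == 2L)               # second class is the positive one
  } else {
    Y <- matrix(0, length(idx), length(class_names))
    Y[cbind(seq_along(idx), idx)] <- 1
    Y
  }
}

# --- Adam -----------------------------------------------------------------
# The optimizer state mirrors the gradient tree. Hyper-parameters beyond
# the learning rate are the framework defaults: beta1 0.9, beta2 0.999,
# epsilon 1e-7.

zeros_like_tree <- function(g) {
  if (is.list(g)) lapply(g, zeros_like_tree) else g * 0
}

adam_init <- function() {
  list(m = NULL, v = NULL, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  if (is.null(state$m)) {
    state$m <- zeros_like_tree(grads)
    state$v <- zeros_like_tree(grads)
  }
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      for (nm in tree_keys(g)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# Keys for walking a (possibly unnamed, e.g. per-shape-group) subtree.
tree_keys <- function(g) {
  nms <- names(g)
  if (is.null(nms)) seq_along(g) else nms
}

# Merge a gradient tree back into the full parameter tree (gradients only
# exist for trainable leaves; BN running moments are untouched).
apply_grad_update <- function(params, updated) {
  for (nm in tree_keys(updated)) {
    if (is.list(updated[[nm]])) {
      params[[nm]] <- apply_grad_update(params[[nm]], updated[[nm]])
    } else {
      params[[nm]] <- updated[[nm]]
    }
  }
  params
}

# Extract the trainable subset of the parameter tree, shaped like a
# gradient tree.
trainable_params <- function(params, grads) {
  out <- vector("list", length(grads))
  names(out) <- names(grads)
  for (nm in tree_keys(grads)) {
    out[[nm]] <- if (is.list(grads[[nm]])) {
      trainable_params(params[[nm]], grads[[nm]])
    } else {
      params[[nm]]
    }
  }
  out
}

# --- training loop --------------------------------------------------------

#' Train an MLA-CNN-BiGRU model
#'
#' Mini-batch Adam over `cfg$epochs` passes. Each epoch reshuffles the
#' training set once (seeded) and walks it in sequential slices of
#' `cfg$batch_size`. No early stopping: the final-epoch model is returned,
#' and the validation set is only scored for the history (and for grid
#' search). After the last epoch the batch-norm running moments are
#' recalibrated with one dropout-free pass over the training set (precise
#' BN): with short schedules the momentum-lagged moments otherwise still
#' sit near their initialization, which would corrupt evaluation-mode
#' predictions. Deterministic given `cfg$seed` on a fixed platform.
#'
#' @param train_set,val_set [beat_dataset()] objects with consistent class
#'   sets (`val_set` may be `NULL`).
#' @param cfg A [train_config()].
#' @param class_names Class universe; defaults to the training set's.
#' @param verbose Print one line per epoch.
#' @param validate Score the validation set after every epoch (turn off to
#'   save the evaluation passes when only the final model matters).
#' @return A trained `mla_model` with a `history` data frame
#'   (epoch, train_loss, val_acc).
#' @export
train <- function(train_set, val_set = NULL, cfg = train_config(),
                  class_names = NULL, verbose = FALSE, validate = TRUE) {
  stopifnot(inherits(train_set, "beat_dataset"))
  class_names <- class_names %||% train_set$class_names
  missing_cls <- setdiff(class_names, unique(train_set$labels))
  if (length(missing_cls) > 0) {
    warning("class(es) absent from the training set: ",
            paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  n <- n_beats(train_set)
  d <- dim(train_set$beats)
  model <- NULL
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_acc = numeric(0))
  with_seed(cfg$seed, {
    model <- mla_cnn_bigru(
      task = cfg$task, class_names = class_names,
      input_leads = d[1], input_len = d[2],
      hidden = cfg$hidden, attn_dim = cfg$attn_dim,
      n_kernels = cfg$n_kernels, dropout = cfg$dropout
    )
    y_all <- encode_labels(train_set$labels, class_names, cfg$task)
    opt <- adam_init()
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0; n_batches <- 0L
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        beats <- train_set$beats[, , idx, drop = FALSE]
        fw <- model_forward(model, beats, training = TRUE, keep_cache = TRUE)
        model <- fw$model
        B <- length(idx)
        if (cfg$task == "detection") {
          y <- y_all[idx]
          loss <- ce_loss(fw$probs, y, "detection")
          dlogits <- (fw$probs - y) / B
        } else {
          Y <- y_all[idx, , drop = FALSE]
          loss <- ce_loss(fw$probs, Y, "location")
          dlogits <- (fw$probs - Y) / B
        }
        if (!is.finite(loss)) {
          stop("training aborted: non-finite loss at epoch ", epoch,
               " (consider a lower learning rate)", call. = FALSE)
        }
        grads <- model_backward(model, fw$cache, dlogits)
        st <- adam_step(trainable_params(model$params, grads), grads, opt,
                        cfg$learning_rate)
        model$params <- apply_grad_update(model$params, st$params)
        opt <- st$state
        epoch_loss <- epoch_loss + loss
        n_batches <- n_batches + 1L
      }
      val_acc <- NA_real_
      if (validate && !is.null(val_set) && n_beats(val_set) > 0) {
        pr <- predict(model, val_set)
        val_acc <- mean(pr$class == val_set$labels)
      }
      history[epoch, ] <- list(epoch, epoch_loss / n_batches, val_acc)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val acc %s", epoch,
                        epoch_loss / n_batches,
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      }
    }
    # precise-BN recalibration: running moments <- mean batch statistics
    drop_rate <- model$dropout
    model$dropout <- 0
    k <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- start:min(start + cfg$batch_size - 1, n)
      if (length(idx) < 2) next           # batch stats need >= 2 rows
      k <- k + 1L
      fw <- model_forward(model, train_set$beats[, , idx, drop = FALSE],
                          training = TRUE, bn_momentum = 1 - 1 / k)
      model <- fw$model
    }
    model$dropout <- drop_rate
  })
  model$history <- history
  model
}

#' Exhaustive grid search over training hyper-parameters
#'
#' Trains one model per grid point and selects by validation accuracy.
#' Ties break toward fewer epochs, then smaller batch size. The default
#' grid is the reference search space: dropout 0.2/0.3/0.4, learning rate
#' 0.0008/0.001, batch 16/24/32, epochs 10/20/30.
#'
#' @param train_set,val_set [beat_dataset()] objects.
#' @param grid Named list with vectors `dropout`, `lr`, `batch`, `epochs`.
#' @param base_cfg [train_config()] supplying everything not in the grid.
#' @param verbose Print one line per grid point.
#' @return List: `best_config` (a [train_config()]), `results` (data frame
#'   with one row per grid point and its validation accuracy).
#' @export
grid_search <- function(train_set, val_set,
                        grid = list(dropout = c(0.2, 0.3, 0.4),
                                    lr = c(0.0008, 0.001),
                                    batch = c(16, 24, 32),
                                    epochs = c(10, 20, 30)),
                        base_cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(length(grid) > 0, all(lengths(grid) > 0))
  tab <- expand.grid(dropout = grid$dropout, lr = grid$lr,
                     batch = grid$batch, epochs = grid$epochs,
                     KEEP.OUT.ATTRS = FALSE)
  tab$val_acc <- NA_real_
  for (i in seq_len(nrow(tab))) {
    cfg <- base_cfg
    cfg$dropout <- tab$dropout[i]
    cfg$learning_rate <- tab$lr[i]
    cfg$batch_size <- as.integer(tab$batch[i])
    cfg$epochs <- as.integer(tab$epochs[i])
    fit <- tryCatch(
      train(train_set, val_set, cfg, validate = FALSE),
      error = function(e) NULL              # e.g. divergence at a wild lr
    )
    tab$val_acc[i] <- if (is.null(fit)) NA_real_ else {
      mean(predict(fit, val_set)$class == val_set$labels)
    }
    if (verbose) {
      message(sprintf("grid %d/%d: dropout %.2f lr %g batch %d epochs %d -> %s",
                      i, nrow(tab), tab$dropout[i], tab$lr[i], tab$batch[i],
                      tab$epochs[i],
                      ifelse(is.na(tab$val_acc[i]), "failed",
                             sprintf("%.3f", tab$val_acc[i]))))
    }
  }
  ok <- which(!is.na(tab$val_acc))
  if (length(ok) == 0) stop("every grid point failed to train", call. = FALSE)
  best <- ok[order(-tab$val_acc[ok], tab$epochs[ok], tab$batch[ok])][1]
  cfg <- base_cfg
  cfg$dropout <- tab$dropout[best]
  cfg$learning_rate <- tab$lr[best]
  cfg$batch_size <- as.integer(tab$batch[best])
  cfg$epochs <- as.integer(tab$epochs[best])
  list(best_config = cfg, results = tab)
}

#' Save / load a trained model
#'
#' The whole model (parameters, BN running moments, config, history) is one
#' serializable list; the round trip reproduces predictions bitwise.
#'
#' @param model An `mla_model`.
#' @param path File path (`.rds`).
#' @return `save_model()` invisibly returns `path`; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mla_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "mla_model")
}
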