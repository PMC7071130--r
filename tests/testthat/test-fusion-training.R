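# Fusion head, losses, the training loop, grid search, serialization and
# the end-to-end gradient check. Training tests run on short (12 x 64)
# beats so the convolution stack stays light.

test_that("fuse_and_classify normalizes and concatenates as contracted", {
  set.seed(1)
  fs <- matrix(rnorm(3 * 10), 3, 10)
  ft <- matrix(rnorm(3 * 4), 3, 4)
  fu <- list(bn = mlaecg:::bn_params(14), W = mlaecg:::glorot(5, 14),
             b = rep(0, 5))
  out <- fuse_and_classify(fs, ft, fu, "location")
  expect_equal(dim(out$probs), c(3L, 5L))
  expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
  expect_equal(ncol(fu$W), ncol(fs) + ncol(ft))   # joint feature length

  fu2 <- list(bn = mlaecg:::bn_params(14), W = mlaecg:::glorot(1, 14), b = 0)
  out2 <- fuse_and_classify(fs, ft, fu2, "detection")
  expect_true(all(out2$probs > 0 & out2$probs < 1))
  expect_error(fuse_and_classify(fs, ft[1:2, ], fu2, "detection"), "row")
})

test_that("cross-entropy losses reproduce their closed forms", {
  # perfect prediction -> zero loss
  expect_equal(ce_loss(matrix(1 - 1e-15, 1, 1), 1, "detection"), 0,
               tolerance = 1e-9)
  onehot <- diag(6)[2, , drop = FALSE]
  perfect <- onehot
  expect_equal(ce_loss(pmax(perfect, 1e-300), onehot, "location"), 0,
               tolerance = 1e-9)
  # uniform prediction over six classes -> log(6)
  expect_equal(ce_loss(matrix(1 / 6, 1, 6), onehot, "location"), log(6))
  # batch of two: mean of per-sample binary losses
  p <- matrix(c(0.8, 0.3), 2, 1)
  y <- c(1, 0)
  expect_equal(ce_loss(p, y, "detection"),
               mean(c(-log(0.8), -log(0.7))))
  expect_error(ce_loss(matrix(0.5, 1, 1), 2, "detection"), "0/1")
  expect_error(ce_loss(matrix(0.5, 1, 2), matrix(c(1, 1), 1), "location"),
               "one-hot")
})

test_that("end-to-end gradients match central finite differences", {
  # double-precision instantiation, dropout off, 2-beat batch; parameters
  # sampled from every block of the network
  set.seed(42)
  m <- mla_cnn_bigru("location", c("A", "B", "C"), input_len = 30,
                     hidden = 5, attn_dim = 4, n_kernels = 3, dropout = 0,
                     precision = "double", seed = 11)
  beats <- array(runif(12 * 30 * 2, -1, 1), c(12, 30, 2))
  Y <- matrix(0, 2, 3)
  Y[cbind(1:2, c(1, 3))] <- 1
  loss_fn <- function(model) {
    fw <- model_forward(model, beats, training = TRUE)
    ce_loss(fw$probs, Y, "location")
  }
  fw <- model_forward(m, beats, training = TRUE, keep_cache = TRUE)
  grads <- mlaecg:::model_backward(m, fw$cache, (fw$probs - Y) / 2)

  paths <- list(
    c("mla", "W1"), c("mla", "w1"),
    c("spatial", "conv1", "groups", 1, "W"),
    c("spatial", "conv2", "groups", 3, "W"),
    c("spatial", "bn1", "gamma"), c("spatial", "bn2", "beta"),
    c("spatial", "att", "W"), c("spatial", "att", "w"),
    c("temporal", "gru_f", "Wxz"), c("temporal", "gru_f", "W"),
    c("temporal", "gru_b", "Whr"), c("temporal", "bn", "gamma"),
    c("temporal", "att", "W"),
    c("fusion", "bn", "gamma"), c("fusion", "W"), c("fusion", "b")
  )
  get_leaf <- function(tree, path) {
    for (p in path) tree <- tree[[p]]
    tree
  }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1) {
      tree[[path[[1]]]] <- val
      return(tree)
    }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
    tree
  }
  h <- 1e-5
  for (pth in paths) {
    g <- get_leaf(grads, pth)
    p0 <- get_leaf(m$params, pth)
    for (i in sample(length(p0), min(2, length(p0)))) {
      mp <- m; mm <- m
      vp <- p0; vp[i] <- vp[i] + h
      vm <- p0; vm[i] <- vm[i] - h
      mp$params <- set_leaf(m$params, pth, vp)
      mm$params <- set_leaf(m$params, pth, vm)
      fd <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
      rel <- abs(fd - g[i]) / max(1e-6, abs(fd) + abs(g[i]))
      expect_lt(rel, 1e-3)
    }
  }
})

test_that("training learns a separable task, decreases loss, and is reproducible", {
  ds <- random_beats(72, len = 64, seed = 5)
  val <- random_beats(24, len = 64, seed = 6)
  cfg <- train_config(batch_size = 12, epochs = 3, hidden = 6, attn_dim = 4,
                      n_kernels = 4, seed = 2, task = "detection")
  fit <- train(ds, val, cfg, validate = FALSE)
  expect_s3_class(fit, "mla_model")
  # training loss decreases monotonically over the first three epochs
  expect_true(all(diff(fit$history$train_loss) < 0))
  pr <- predict(fit, val)
  expect_gte(mean(pr$class == val$labels), 0.95)

  # same seed -> bitwise identical parameters
  fit2 <- train(ds, val, cfg, validate = FALSE)
  expect_identical(fit$params, fit2$params)
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("training rejects invalid class situations", {
  ds <- random_beats(24, len = 64, seed = 7)
  cfg <- train_config(batch_size = 8, epochs = 1, hidden = 4, attn_dim = 3,
                      n_kernels = 2, seed = 1, task = "detection")
  expect_warning(
    train(subset_beats(ds, which(ds$labels == "HC")), NULL, cfg,
          class_names = c("HC", "MI"), validate = FALSE),
    "absent"
  )
})

test_that("serialization round-trips to bitwise-identical predictions", {
  ds <- random_beats(24, len = 64, seed = 8)
  cfg <- train_config(batch_size = 8, epochs = 1, hidden = 4, attn_dim = 3,
                      n_kernels = 2, seed = 3, task = "detection")
  fit <- train(ds, NULL, cfg, validate = FALSE)
  path <- file.path(tempdir(), "model.rds")
  save_model(fit, path)
  back <- load_model(path)
  p1 <- predict(fit, ds)
  p2 <- predict(back, ds)
  expect_identical(p1$probs, p2$probs)
})

test_that("grid search enumerates the grid and breaks ties as documented", {
  ds <- random_beats(36, len = 64, seed = 9)
  val <- random_beats(18, len = 64, seed = 10)
  base <- train_config(hidden = 4, attn_dim = 3, n_kernels = 2, seed = 4,
                       task = "detection")
  # singleton grid returns that configuration
  g1 <- grid_search(ds, val, grid = list(dropout = 0.3, lr = 0.001,
                                         batch = 12, epochs = 1),
                    base_cfg = base)
  expect_equal(nrow(g1$results), 1L)
  expect_equal(g1$best_config$learning_rate, 0.001)

  # result table enumerates the full product of grid sizes
  g2 <- grid_search(ds, val, grid = list(dropout = c(0.2, 0.3), lr = 0.001,
                                         batch = 12, epochs = c(1, 2)),
                    base_cfg = base)
  expect_equal(nrow(g2$results), 4L)
  # ties (if any) break toward fewer epochs
  best <- g2$results[which.max(g2$results$val_acc), ]
  if (sum(g2$results$val_acc == max(g2$results$val_acc), na.rm = TRUE) > 1) {
    expect_lte(g2$best_config$epochs,
               max(g2$results$epochs[g2$results$val_acc == best$val_acc]))
  }
})

test_that("a deliberately wild learning rate never wins the grid", {
  # at a scale where the sane configuration genuinely learns
  ds <- random_beats(72, len = 64, seed = 5)
  val <- random_beats(24, len = 64, seed = 6)
  base <- train_config(hidden = 6, attn_dim = 4, n_kernels = 4, seed = 2,
                       task = "detection")
  g <- grid_search(ds, val, grid = list(dropout = 0.3, lr = c(0.001, 10),
                                        batch = 12, epochs = 3),
                   base_cfg = base)
  expect_equal(nrow(g$results), 2L)
  expect_equal(g$best_config$learning_rate, 0.001)
})

test_that("forward passes stay finite at default initialization", {
  set.seed(12)
  m <- mla_cnn_bigru("location", c("a", "b", "c", "d", "e", "f"),
                     input_len = 64, hidden = 6, attn_dim = 4,
                     n_kernels = 4, seed = 9)
  beats <- array(runif(12 * 64 * 8, -1, 1), c(12, 64, 8))
  fw <- model_forward(m, beats, training = TRUE)
  expect_true(all(is.finite(fw$probs)))
  expect_equal(rowSums(fw$probs), rep(1, 8), tolerance = 1e-6)
})
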