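# Spatial branch: convolution, pooling, feature-map attention, shape
# algebra, eval-mode determinism.

conv1x1_identity <- function() {
  list(groups = list(list(W = matrix(1, 1, 1), b = 0)),
       shapes = list(c(1, 1)))
}

test_that("a 1x1 unit kernel reproduces ReLU of the input", {
  set.seed(1)
  x <- matrix(rnorm(6 * 10), 6, 10)
  out <- conv_layer_forward(x, conv1x1_identity())
  expect_equal(out$y[, , 1], pmax(x, 0), tolerance = 1e-6)
})

test_that("zero input responds with ReLU(bias) constants", {
  p <- conv_layer_params(1, n_kernels = 4, shapes = list(c(3, 3)))
  p$groups[[1]]$W[] <- rnorm(length(p$groups[[1]]$W))
  p$groups[[1]]$b <- c(-1, 0, 0.5, 2)
  out <- conv_layer_forward(matrix(0, 5, 7), p)
  for (n in 1:4) {
    expect_equal(out$y[, , n], matrix(max(p$groups[[1]]$b[n], 0), 5, 7),
                 tolerance = 1e-6)
  }
})

test_that("convolution matches the explicit-loop oracle (double and single)", {
  set.seed(2)
  x <- array(rnorm(4 * 4), c(4, 4, 1))
  p <- conv_layer_params(1, n_kernels = 1, shapes = list(c(3, 3)))
  ref <- pmax(oracle_conv(x, p$groups[[1]]$W, p$groups[[1]]$b, 3, 3), 0)
  # double path: exact
  out_d <- conv_layer_forward(x, p, precision = "double")
  expect_equal(out_d$y, ref, tolerance = 1e-12)
  # single path: float32 rounding only
  out_s <- conv_layer_forward(x, p, precision = "single")
  expect_equal(out_s$y, ref, tolerance = 1e-5)

  # multi-channel input, all three reference shapes (the 7x1 kernel needs
  # at least 7 rows), random 8 x 10 maps
  x2 <- array(rnorm(8 * 10 * 3), c(8, 10, 3))
  p2 <- conv_layer_params(3, n_kernels = 2)
  out2 <- conv_layer_forward(x2, p2, precision = "double")
  ref2 <- array(0, c(8, 10, 6))
  for (g in 1:3) {
    sh <- p2$shapes[[g]]
    ref2[, , (g - 1) * 2 + 1:2] <-
      oracle_conv(x2, p2$groups[[g]]$W, p2$groups[[g]]$b, sh[1], sh[2])
  }
  expect_equal(out2$y, pmax(ref2, 0), tolerance = 1e-10)
  expect_error(conv_layer_forward(matrix(0, 2, 10), p2), "taller")
})

test_that("max pooling matches the brute-force oracle and its examples", {
  m <- matrix(c(1, 4, 7, 2, 5, 8, 3, 6, 9), 3, 3)  # [[1,2,3],[4,5,6],[7,8,9]]
  out <- max_pool_forward(m)
  expect_equal(out$y[, , 1], matrix(c(5, 8, 6, 9), 2, 2))

  cst <- max_pool_forward(matrix(3.3, 4, 6))
  expect_equal(cst$y[, , 1], matrix(3.3, 3, 5))

  set.seed(3)
  x <- array(rnorm(6 * 10 * 4), c(6, 10, 4))
  expect_equal(max_pool_forward(x)$y, oracle_pool(x), tolerance = 1e-12)
  # max dominance on a monotone map
  mono <- matrix(seq_len(20), 4, 5)
  expect_true(all(max_pool_forward(mono)$y[, , 1] >= mono[1:3, 1:4]))
  expect_error(max_pool_forward(matrix(0, 1, 5)), "window")
})

test_that("feature attention matches the scalar oracle and its edge cases", {
  # singleton: alpha = 1, output = the vector itself
  p1 <- attention_params(4, 3)
  v <- matrix(rnorm(4), 1, 4)
  out1 <- attention_forward(v, p1)
  expect_equal(out1$alpha, 1)
  expect_equal(out1$out, drop(v))

  # identical vectors -> uniform weights
  p2 <- attention_params(5, 3)
  V2 <- matrix(rep(rnorm(5), each = 6), 6, 5)
  out2 <- attention_forward(V2, p2)
  expect_equal(out2$alpha, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(out2$out, V2[1, ], tolerance = 1e-12)

  # N=3, d=2 toy against the scalar loop oracle
  set.seed(4)
  p3 <- attention_params(2, 3)
  V3 <- matrix(rnorm(6), 3, 2)
  out3 <- attention_forward(V3, p3)
  ref <- oracle_attention(V3, p3$W, p3$b, p3$w)
  expect_equal(out3$alpha, ref$alpha, tolerance = 1e-12)
  expect_equal(out3$out, ref$out, tolerance = 1e-12)
  expect_error(attention_forward(matrix(0, 3, 5), p3), "width")
})

test_that("spatial branch output length follows the documented shape algebra", {
  set.seed(5)
  sp <- with(list(), {
    set.seed(5)
    list(conv1 = conv_layer_params(1, 20), bn1 = mlaecg:::bn_params(60),
         conv2 = conv_layer_params(60, 20), bn2 = mlaecg:::bn_params(60),
         att = attention_params((12 - 2) * (40 - 2), 4))
  })
  X <- list(matrix(rnorm(12 * 40), 12, 40), matrix(rnorm(12 * 40), 12, 40))
  out <- spatial_branch_forward(X, sp, training = FALSE, dropout = 0)
  expect_equal(ncol(out$fs), (12 - 2) * (40 - 2))
  expect_equal(ncol(out$alpha2), 60)       # 3 shapes x 20 kernels
  expect_equal(rowSums(out$alpha2), c(1, 1), tolerance = 1e-6)
  expect_true(all(out$alpha2 >= 0))

  # eval-mode determinism
  out2 <- spatial_branch_forward(X, sp, training = FALSE, dropout = 0)
  expect_identical(out$fs, out2$fs)

  # dropout 0: training and eval agree given identical (frozen) BN stats;
  # freeze by running eval twice vs training with the same running moments
  # is not meaningful for batch stats, so check the dropout mechanism only
  set.seed(9)
  tr1 <- spatial_branch_forward(X, sp, training = TRUE, dropout = 0)
  set.seed(9)
  tr2 <- spatial_branch_forward(X, sp, training = TRUE, dropout = 0)
  expect_equal(tr1$fs, tr2$fs)
})

test_that("the full model keeps its channel algebra on real-size beats", {
  m <- mla_cnn_bigru("detection", c("HC", "MI"), hidden = 8, attn_dim = 4,
                     n_kernels = 20, seed = 1)
  set.seed(6)
  fw <- model_forward(m, array(runif(12 * 651 * 2, -1, 1), c(12, 651, 2)))
  expect_equal(ncol(fw$alpha2), 60)
  expect_equal(ncol(fw$alpha3), 651)
  expect_equal(dim(fw$probs), c(2L, 1L))
})
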