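# The MLA-CNN-BiGRU model: parameter construction, batched forward pass and
# full backward pass. Layout per beat L (12 x 651):
#
#   MLA:      alpha1 = StepReLU(tanh(W1 L + b1) w1),  X = alpha1 (x) L
#   spatial:  [conv(3x3|5x1|7x1, 20 kernels each, SAME, stride 1) -> ReLU
#              -> BN -> 2x2/stride-1 max pool -> dropout] x 2
#             -> 60 flattened maps -> attention -> fs
#   temporal: BiGRU over the 651 columns of X -> H (651 x 2h) -> BN
#             -> dropout -> attention -> ft
#   fusion:   F = [fs, ft] -> BN -> dropout -> fully connected
#             -> sigmoid (detection) / softmax (location)
#
# Batch normalization uses batch statistics while training (running moments
# are updated with momentum 0.99) and running moments in evaluation mode.

orth_init <- function(h) {
  q <- qr.Q(qr(matrix(rnorm(h * h), h, h)))
  q * sign(diag(q))[1]            # fix an arbitrary sign for determinism
}

#' GRU parameter set
#'
#' Input-to-hidden matrices get Glorot-uniform draws; hidden-to-hidden
#' matrices get (sign-fixed) random orthogonal draws; gate biases start at
#' zero. `bh` is the optional candidate-state bias, used only when the
#' model enables it — the printed recurrence has none.
#'
#' @param h Hidden size.
#' @param k Input dimension (12 leads).
#' @return Named list of GRU weight matrices and bias vectors.
#' @export
gru_params <- function(h, k = 12) {
  list(
    Wxz = glorot(h, k), Whz = orth_init(h),
    Wxr = glorot(h, k), Whr = orth_init(h),
    Wxh = glorot(h, k), W = orth_init(h),
    bz = rep(0, h), br = rep(0, h), bh = rep(0, h)
  )
}

#' One GRU step
#'
#' The gated recurrence driving the temporal branch:
#' `z = sigmoid(Wxz x + Whz h + bz)`, `r = sigmoid(Wxr x + Whr h + br)`,
#' `hc = tanh(Wxh x + W (r * h))`, `h' = (1 - z) * h + z * hc`
#' (all products element-wise where unsubscripted).
#'
#' @param xt Input column (12-vector).
#' @param h_prev Previous hidden state.
#' @param params A [gru_params()] set.
#' @param use_candidate_bias Add `bh` to the candidate pre-activation.
#' @return The next hidden state.
#' @export
gru_step <- function(xt, h_prev, params, use_candidate_bias = FALSE) {
  if (length(xt) != ncol(params$Wxz) || length(h_prev) != nrow(params$Wxz)) {
    stop_invalid("`xt` / `h_prev` lengths do not match the GRU parameters")
  }
  sig <- function(v) 1 / (1 + exp(-v))
  z <- sig(drop(params$Wxz %*% xt + params$Whz %*% h_prev) + params$bz)
  r <- sig(drop(params$Wxr %*% xt + params$Whr %*% h_prev) + params$br)
  pre <- drop(params$Wxh %*% xt + params$W %*% (r * h_prev))
  if (use_candidate_bias) pre <- pre + params$bh
  (1 - z) * h_prev + z * tanh(pre)
}

#' Construct an untrained MLA-CNN-BiGRU model
#'
#' @param task `"detection"` (binary, sigmoid output) or `"location"`
#'   (multi-class, softmax output).
#' @param class_names Class labels. Detection needs exactly two (the second
#'   — conventionally the MI class — is the positive one); location needs
#'   two or more.
#' @param input_leads,input_len Beat dimensions (12 x 651).
#' @param hidden GRU hidden size per direction.
#' @param attn_dim Width of both attention layers' tanh projection.
#' @param n_kernels Convolution kernels per shape group (20 gives the
#'   reference 60 feature maps per layer).
#' @param dropout Dropout rate used after every pooling stage, on the
#'   hidden-state stack and on the fused feature (0.3 by default).
#' @param straight_through Use the straight-through StepReLU gradient.
#' @param precision `"single"` runs the convolutions in float32 (the
#'   training workhorse); `"double"` runs them in float64 (used for exact
#'   gradient verification).
#' @param use_candidate_bias Add a bias term to the GRU candidate state
#'   (the printed recurrence has none; off by default).
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `mla_model`.
#' @export
#' @examples
#' m <- mla_cnn_bigru("detection", c("HC", "MI"), hidden = 4, attn_dim = 4,
#'                    n_kernels = 2, input_len = 40, seed = 1)
mla_cnn_bigru <- function(task = c("detection", "location"),
                          class_names,
                          input_leads = 12, input_len = 651,
                          hidden = 64, attn_dim = 32, n_kernels = 20,
                          dropout = 0.3,
                          straight_through = FALSE,
                          use_candidate_bias = FALSE,
                          precision = c("single", "double"),
                          seed = NULL) {
  task <- match.arg(task)
  precision <- match.arg(precision)
  if (task == "detection" && length(class_names) != 2) {
    stop_invalid("detection needs exactly two classes (negative, positive)")
  }
  if (length(class_names) < 2) stop_invalid("need at least two classes")
  if (dropout < 0 || dropout >= 1) stop_invalid("`dropout` must be in [0, 1)")
  n_maps <- 3L * n_kernels
  d_spat <- (input_leads - 2L) * (input_len - 2L)  # two stride-1 2x2 pools
  d_fuse <- d_spat + 2L * hidden
  n_out <- if (task == "detection") 1L else length(class_names)
  params <- with_seed(seed, list(
    mla = mla_params(input_leads, input_len),
    spatial = list(
      conv1 = conv_layer_params(1L, n_kernels),
      bn1 = bn_params(n_maps),
      conv2 = conv_layer_params(n_maps, n_kernels),
      bn2 = bn_params(n_maps),
      att = attention_params(d_spat, attn_dim)
    ),
    temporal = list(
      gru_f = gru_params(hidden, input_leads),
      gru_b = gru_params(hidden, input_leads),
      bn = bn_params(2L * hidden),
      att = attention_params(2L * hidden, attn_dim)
    ),
    fusion = list(
      bn = bn_params(d_fuse),
      W = glorot(n_out, d_fuse),
      b = rep(0, n_out)
    )
  ))
  structure(
    list(task = task, class_names = class_names,
         input_leads = input_leads, input_len = input_len,
         hidden = hidden, attn_dim = attn_dim, n_kernels = n_kernels,
         dropout = dropout, straight_through = straight_through,
         use_candidate_bias = use_candidate_bias, precision = precision,
         params = params, history = NULL),
    class = "mla_model"
  )
}

#' @export
print.mla_model <- function(x, ...) {
  cat(sprintf(paste0("<mla_model> %s over {%s}\n",
                     "  MLA + CNN(3 shapes x %d kernels) + BiGRU(h=%d) ",
                     "+ attention fusion; dropout %.2f\n"),
              x$task, paste(x$class_names, collapse = ", "),
              x$n_kernels, x$hidden, x$dropout))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                nrow(x$history), tail(x$history$train_loss, 1)))
  }
  invisible(x)
}

# --- spatial branch -------------------------------------------------------

#' Spatial branch forward pass
#'
#' Runs the CNN branch over a batch of (already lead-weighted) beats.
#' Exposed mainly for inspection and testing; [model_forward()] drives it.
#'
#' @param Xlist List of `leads x time` matrices.
#' @param sp Spatial parameter set (`model$params$spatial`).
#' @param training Training mode flag (batch statistics + dropout).
#' @param dropout Dropout rate.
#' @return List: `fs` (batch x d matrix of spatial features), `alpha2`
#'   (batch x 60 attention weights), updated `sp`, `cache`.
#' @export
spatial_branch_forward <- function(Xlist, sp, training = FALSE, dropout = 0,
                                   precision = "single", bn_momentum = 0.99) {
  B <- length(Xlist)
  cv1 <- lapply(Xlist, conv_layer_forward, params = sp$conv1,
                precision = precision)
  d1 <- dim(cv1[[1]]$y)                   # H x W x C
  P1 <- d1[1] * d1[2]; C <- d1[3]
  bn1 <- bn_forward(lapply(cv1, function(o) {
    y <- o$y; dim(y) <- c(P1, C); y
  }), sp$bn1, training, momentum = bn_momentum)
  sp$bn1 <- bn1$bn
  pool1 <- vector("list", B); drop1 <- vector("list", B)
  cv2 <- vector("list", B)
  for (b in seq_len(B)) {
    y <- bn1$y[[b]]
    dim(y) <- d1
    pool1[[b]] <- max_pool_forward(y)
    drop1[[b]] <- dropout_forward(pool1[[b]]$y, dropout, training)
    cv2[[b]] <- conv_layer_forward(drop1[[b]]$y, sp$conv2,
                                   precision = precision)
  }
  d2 <- dim(cv2[[1]]$y); P2 <- d2[1] * d2[2]
  bn2 <- bn_forward(lapply(cv2, function(o) {
    y <- o$y; dim(y) <- c(P2, C); y
  }), sp$bn2, training, momentum = bn_momentum)
  sp$bn2 <- bn2$bn
  pool2 <- vector("list", B); drop2 <- vector("list", B)
  att <- vector("list", B)
  fs <- NULL; alpha2 <- NULL
  for (b in seq_len(B)) {
    y <- bn2$y[[b]]
    dim(y) <- d2
    pool2[[b]] <- max_pool_forward(y)
    drop2[[b]] <- dropout_forward(pool2[[b]]$y, dropout, training)
    d3 <- dim(drop2[[b]]$y); P3 <- d3[1] * d3[2]
    V <- drop2[[b]]$y; dim(V) <- c(P3, C)
    att[[b]] <- attention_forward(t(V), sp$att)
    if (is.null(fs)) {
      fs <- matrix(0, B, P3); alpha2 <- matrix(0, B, C)
    }
    fs[b, ] <- att[[b]]$out
    alpha2[b, ] <- att[[b]]$alpha
  }
  list(fs = fs, alpha2 = alpha2, sp = sp,
       cache = list(cv1 = cv1, bn1 = bn1$cache, d1 = d1,
                    pool1 = pool1, drop1 = drop1,
                    cv2 = cv2, bn2 = bn2$cache, d2 = d2,
                    pool2 = pool2, drop2 = drop2, att = att))
}

spatial_branch_backward <- function(dfs, sp, cache, precision = "single") {
  B <- nrow(dfs)
  d1 <- cache$d1; d2 <- cache$d2
  P1 <- d1[1] * d1[2]; P2 <- d2[1] * d2[2]; C <- d1[3]
  g_att <- NULL
  dM2 <- vector("list", B)
  for (b in seq_len(B)) {
    ab <- attention_backward(dfs[b, ], sp$att, cache$att[[b]]$cache)
    g_att <- if (is.null(g_att)) ab[c("dW", "db", "dw")] else {
      Map(`+`, g_att, ab[c("dW", "db", "dw")])
    }
    dV <- t(ab$dV)                        # P3 x C
    dim(dV) <- c(d2[1] - 1L, d2[2] - 1L, C)
    dV <- dropout_backward(dV, cache$drop2[[b]]$mask)
    dpool <- max_pool_backward(dV, cache$pool2[[b]]$cache)
    dim(dpool) <- c(P2, C)
    dM2[[b]] <- dpool
  }
  bn2b <- bn_backward(dM2, sp$bn2, cache$bn2)
  g_conv2 <- NULL
  dM1 <- vector("list", B)
  for (b in seq_len(B)) {
    dy <- bn2b$dx[[b]]
    dim(dy) <- d2
    cb <- conv_layer_backward(dy, sp$conv2, cache$cv2[[b]]$cache, precision)
    g_conv2 <- if (is.null(g_conv2)) cb$grads else {
      list(groups = Map(function(a, b) Map(`+`, a, b),
                        g_conv2$groups, cb$grads$groups))
    }
    dpool_in <- dropout_backward(cb$dx, cache$drop1[[b]]$mask)
    dpool <- max_pool_backward(dpool_in, cache$pool1[[b]]$cache)
    dim(dpool) <- c(P1, C)
    dM1[[b]] <- dpool
  }
  bn1b <- bn_backward(dM1, sp$bn1, cache$bn1)
  g_conv1 <- NULL
  dX <- vector("list", B)
  for (b in seq_len(B)) {
    dy <- bn1b$dx[[b]]
    dim(dy) <- d1
    cb <- conv_layer_backward(dy, sp$conv1, cache$cv1[[b]]$cache, precision)
    g_conv1 <- if (is.null(g_conv1)) cb$grads else {
      list(groups = Map(function(a, b) Map(`+`, a, b),
                        g_conv1$groups, cb$grads$groups))
    }
    dX[[b]] <- cb$dx[, , 1]
  }
  list(dX = dX,
       grads = list(conv1 = g_conv1,
                    bn1 = list(gamma = bn1b$dgamma, beta = bn1b$dbeta),
                    conv2 = g_conv2,
                    bn2 = list(gamma = bn2b$dgamma, beta = bn2b$dbeta),
                    att = list(W = g_att$dW, b = g_att$db, w = g_att$dw)))
}

# --- temporal branch ------------------------------------------------------

run_gru <- function(X, p, use_bh) {
  bh <- if (use_bh) p$bh else numeric(0)
  cpp_gru_forward(X, p$Wxz, p$Whz, p$Wxr, p$Whr, p$Wxh, p$W, p$bz, p$br, bh)
}

#' BiGRU forward pass over one beat
#'
#' Runs the forward GRU over the columns of `X` left to right and the
#' backward GRU right to left (both from zero initial state) and
#' concatenates the two hidden states at each time step.
#'
#' @param X `leads x T` matrix.
#' @param fwd,bwd GRU parameter sets sharing the hidden size.
#' @param use_candidate_bias Add the optional candidate-state bias.
#' @return List: `H` (`T x 2h` hidden-state matrix), `cache`.
#' @export
bigru_forward <- function(X, fwd, bwd, use_candidate_bias = FALSE) {
  stopifnot(is.matrix(X))
  T_ <- ncol(X)
  f <- run_gru(X, fwd, use_candidate_bias)
  Xr <- X[, T_:1, drop = FALSE]
  b <- run_gru(Xr, bwd, use_candidate_bias)
  Hb <- b$H[, T_:1, drop = FALSE]
  list(H = t(rbind(f$H, Hb)), cache = list(f = f, b = b, X = X, Xr = Xr))
}

bigru_backward <- function(dH, fwd, bwd, cache, use_bh) {
  T_ <- nrow(dH); h <- ncol(dH) / 2
  dHf <- t(dH[, seq_len(h), drop = FALSE])
  dHb <- t(dH[, h + seq_len(h), drop = FALSE])[, T_:1, drop = FALSE]
  gf <- cpp_gru_backward(cache$X, fwd$Wxz, fwd$Whz, fwd$Wxr, fwd$Whr,
                         fwd$Wxh, fwd$W, cache$f$H, cache$f$Z, cache$f$R,
                         cache$f$Hc, dHf, use_bh)
  gb <- cpp_gru_backward(cache$Xr, bwd$Wxz, bwd$Whz, bwd$Wxr, bwd$Whr,
                         bwd$Wxh, bwd$W, cache$b$H, cache$b$Z, cache$b$R,
                         cache$b$Hc, dHb, use_bh)
  pick <- function(g) {
    out <- list(Wxz = g$dWxz, Whz = g$dWhz, Wxr = g$dWxr, Whr = g$dWhr,
                Wxh = g$dWxh, W = g$dW, bz = drop(g$dbz), br = drop(g$dbr))
    if (use_bh) out$bh <- drop(g$dbh)
    out
  }
  dX <- gf$dX + gb$dX[, T_:1, drop = FALSE]
  list(dX = dX, g_f = pick(gf), g_b = pick(gb))
}

#' Temporal branch forward pass
#'
#' BiGRU over each beat, batch normalization and dropout on the stacked
#' hidden states, then attention pooling into the temporal feature.
#'
#' @param Xlist List of `leads x T` matrices.
#' @param tp Temporal parameter set (`model$params$temporal`).
#' @param training Training mode flag.
#' @param dropout Dropout rate.
#' @param use_candidate_bias Add the optional GRU candidate bias.
#' @return List: `ft` (batch x 2h), `alpha3` (batch x T), updated `tp`,
#'   `cache`.
#' @export
temporal_branch_forward <- function(Xlist, tp, training = FALSE, dropout = 0,
                                    use_candidate_bias = FALSE,
                                    bn_momentum = 0.99) {
  B <- length(Xlist)
  gru <- lapply(Xlist, bigru_forward, fwd = tp$gru_f, bwd = tp$gru_b,
                use_candidate_bias = use_candidate_bias)
  T_ <- nrow(gru[[1]]$H); d <- ncol(gru[[1]]$H)
  bn <- bn_forward(lapply(gru, `[[`, "H"), tp$bn, training,
                   momentum = bn_momentum)
  tp$bn <- bn$bn
  drop_ <- lapply(bn$y, dropout_forward, rate = dropout, training = training)
  ft <- matrix(0, B, d); alpha3 <- matrix(0, B, T_)
  att <- vector("list", B)
  for (b in seq_len(B)) {
    att[[b]] <- attention_forward(drop_[[b]]$y, tp$att)
    ft[b, ] <- att[[b]]$out
    alpha3[b, ] <- att[[b]]$alpha
  }
  list(ft = ft, alpha3 = alpha3, tp = tp,
       cache = list(gru = gru, bn = bn$cache, drop = drop_, T_ = T_,
                    att = att))
}

temporal_branch_backward <- function(dft, tp, cache, use_bh = FALSE) {
  B <- nrow(dft); T_ <- cache$T_
  g_att <- NULL
  dY <- vector("list", B)
  for (b in seq_len(B)) {
    ab <- attention_backward(dft[b, ], tp$att, cache$att[[b]]$cache)
    g_att <- if (is.null(g_att)) ab[c("dW", "db", "dw")] else {
      Map(`+`, g_att, ab[c("dW", "db", "dw")])
    }
    dY[[b]] <- dropout_backward(ab$dV, cache$drop[[b]]$mask)
  }
  bnb <- bn_backward(dY, tp$bn, cache$bn)
  g_f <- NULL; g_b <- NULL
  dX <- vector("list", B)
  for (b in seq_len(B)) {
    gg <- bigru_backward(bnb$dx[[b]], tp$gru_f, tp$gru_b,
                         cache$gru[[b]]$cache, use_bh)
    dX[[b]] <- gg$dX
    g_f <- if (is.null(g_f)) gg$g_f else Map(`+`, g_f, gg$g_f)
    g_b <- if (is.null(g_b)) gg$g_b else Map(`+`, g_b, gg$g_b)
  }
  list(dX = dX,
       grads = list(gru_f = g_f, gru_b = g_b,
                    bn = list(gamma = bnb$dgamma, beta = bnb$dbeta),
                    att = list(W = g_att$dW, b = g_att$db, w = g_att$dw)))
}

# --- full model -----------------------------------------------------------

#' Fuse branch features and classify
#'
#' Concatenates the spatial and temporal features, applies batch norm,
#' dropout and the single fully connected output layer, and maps to
#' probabilities (sigmoid for detection, softmax for location).
#'
#' @param fs,ft Batch feature matrices (batch x d_s, batch x 2h).
#' @param fu Fusion parameter set (`model$params$fusion`).
#' @param task `"detection"` or `"location"`.
#' @param training Training mode flag.
#' @param dropout Dropout rate.
#' @return List: `probs` (batch x 1 or batch x C), `logits`, updated `fu`,
#'   `cache`.
#' @export
fuse_and_classify <- function(fs, ft, fu, task, training = FALSE, dropout = 0,
                              bn_momentum = 0.99) {
  if (!is.matrix(fs) || !is.matrix(ft) || nrow(fs) != nrow(ft)) {
    stop_invalid("`fs` and `ft` must be matrices with one row per beat")
  }
  FF <- cbind(fs, ft)
  bn <- bn_forward(FF, fu$bn, training, momentum = bn_momentum)
  fu$bn <- bn$bn
  drop_ <- dropout_forward(bn$y, dropout, training)
  logits <- drop_$y %*% t(fu$W) + rep(fu$b, each = nrow(FF))
  probs <- if (task == "detection") {
    1 / (1 + exp(-logits))
  } else {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  }
  list(probs = probs, logits = logits, fu = fu,
       cache = list(bn = bn$cache, drop = drop_, d_s = ncol(fs)))
}

fuse_backward <- function(dlogits, fu, cache) {
  dW <- t(dlogits) %*% cache$drop$y
  db <- colSums(dlogits)
  dF <- dlogits %*% fu$W
  dF <- dropout_backward(dF, cache$drop$mask)
  bnb <- bn_backward(dF, fu$bn, cache$bn)
  d_s <- cache$d_s
  list(dfs = bnb$dx[, seq_len(d_s), drop = FALSE],
       dft = bnb$dx[, -seq_len(d_s), drop = FALSE],
       grads = list(bn = list(gamma = bnb$dgamma, beta = bnb$dbeta),
                    W = dW, b = db))
}

#' Full model forward pass
#'
#' @param model An `mla_model`.
#' @param beats `12 x 651 x B` array (or a single beat matrix).
#' @param training Training mode: batch statistics, dropout, running-moment
#'   updates (the updated model is returned alongside).
#' @param bn_momentum Momentum of the batch-norm running-moment update
#'   (training mode only).
#' @return List: `probs`, `alpha1` (batch x 12 lead weights), `alpha2`,
#'   `alpha3`, updated `model`, and `cache` (when `keep_cache`).
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @export
model_forward <- function(model, beats, training = FALSE, keep_cache = FALSE,
                          bn_momentum = 0.99) {
  if (is.matrix(beats)) beats <- array(beats, dim = c(dim(beats), 1L))
  B <- dim(beats)[3]
  mla <- vector("list", B)
  Xlist <- vector("list", B)
  alpha1 <- matrix(0, B, dim(beats)[1])
  for (b in seq_len(B)) {
    mla[[b]] <- mla_forward(beats[, , b], model$params$mla)
    Xlist[[b]] <- mla[[b]]$X
    alpha1[b, ] <- mla[[b]]$alpha1
  }
  sp <- spatial_branch_forward(Xlist, model$params$spatial, training,
                               model$dropout, model$precision %||% "single",
                               bn_momentum = bn_momentum)
  model$params$spatial <- sp$sp
  tp <- temporal_branch_forward(Xlist, model$params$temporal, training,
                                model$dropout, model$use_candidate_bias,
                                bn_momentum = bn_momentum)
  model$params$temporal <- tp$tp
  fu <- fuse_and_classify(sp$fs, tp$ft, model$params$fusion, model$task,
                          training, model$dropout, bn_momentum = bn_momentum)
  model$params$fusion <- fu$fu
  out <- list(probs = fu$probs, alpha1 = alpha1, alpha2 = sp$alpha2,
              alpha3 = tp$alpha3, model = model)
  if (keep_cache) {
    out$cache <- list(mla = mla, spatial = sp$cache, temporal = tp$cache,
                      fusion = fu$cache)
  }
  out
}

# Backward pass from the gradient w.r.t. the logits; returns a gradient
# tree parallel to the trainable parameters.
model_backward <- function(model, cache, dlogits) {
  fb <- fuse_backward(dlogits, model$params$fusion, cache$fusion)
  sb <- spatial_branch_backward(fb$dfs, model$params$spatial, cache$spatial,
                                model$precision %||% "single")
  tb <- temporal_branch_backward(fb$dft, model$params$temporal,
                                 cache$temporal, model$use_candidate_bias)
  B <- length(sb$dX)
  g_mla <- NULL
  for (b in seq_len(B)) {
    dX <- sb$dX[[b]] + tb$dX[[b]]
    mg <- mla_backward(dX, model$params$mla, cache$mla[[b]]$cache,
                       model$straight_through)
    g <- list(W1 = mg$dW1, b1 = mg$db1, w1 = mg$dw1)
    g_mla <- if (is.null(g_mla)) g else Map(`+`, g_mla, g)
  }
  list(mla = g_mla, spatial = sb$grads, temporal = tb$grads,
       fusion = fb$grads)
}

#' Predict class probabilities for beats
#'
#' Evaluation-mode forward pass in memory-bounded chunks.
#'
#' @param object An `mla_model`.
#' @param beats `12 x 651 x n` array or a [beat_dataset()].
#' @param chunk Beats per forward pass.
#' @param ... Unused.
#' @return List: `probs` (n x C matrix, detection gives the two-class
#'   matrix `1-p, p`), `class` (predicted labels), `alpha1` (n x 12 lead
#'   weights).
#' @export
predict.mla_model <- function(object, beats, chunk = 64, ...) {
  if (inherits(beats, "beat_dataset")) beats <- beats$beats
  if (is.matrix(beats)) beats <- array(beats, dim = c(dim(beats), 1L))
  n <- dim(beats)[3]
  probs <- NULL; alpha1 <- matrix(0, n, dim(beats)[1])
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- model_forward(object, beats[, , idx, drop = FALSE],
                        training = FALSE)
    p <- fw$probs
    if (object$task == "detection") p <- cbind(1 - p[, 1], p[, 1])
    if (is.null(probs)) probs <- matrix(0, n, ncol(p))
    probs[idx, ] <- p
    alpha1[idx, ] <- fw$alpha1
  }
  colnames(probs) <- object$class_names
  list(probs = probs,
       class = object$class_names[max.col(probs, ties.method = "first")],
       alpha1 = alpha1)
}

#' Lead weights for a set of beats
#'
#' Computes the MLA weight vector alpha1 for every beat (this needs only
#' the MLA parameters, not a full network pass) and returns the per-lead
#' mean — the quantity reported as the model's lead ranking.
#'
#' @param model An `mla_model`.
#' @param beats `12 x 651 x n` array or [beat_dataset()].
#' @return Named numeric vector of 12 mean lead weights in \[0, 1\].
#' @export
lead_weights <- function(model, beats) {
  if (inherits(beats, "beat_dataset")) beats <- beats$beats
  if (is.matrix(beats)) beats <- array(beats, dim = c(dim(beats), 1L))
  n <- dim(beats)[3]
  acc <- rep(0, dim(beats)[1])
  for (b in seq_len(n)) {
    acc <- acc + mla_forward(beats[, , b], model$params$mla)$alpha1
  }
  w <- acc / n
  names(w) <- ecg_leads()[seq_along(w)]
  w
}
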