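# Building blocks shared by the two branches and the fusion head: the
# tanh-softmax attention pooling used over feature maps and over hidden
# states, batch normalization, inverted dropout, and thin R wrappers around
# the compiled convolution / pooling kernels.

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Attention pooling over a set of vectors
#'
#' Given N vectors (rows of `V`), scores each with
#' `w' tanh(W V' + b)`, normalizes with softmax, and returns the
#' alpha-weighted sum. Used both over the 60 flattened CNN feature maps and
#' over the 651 BiGRU hidden states.
#'
#' @param V Matrix N x d: one vector per row.
#' @param params List with `W` (a x d), `b` (a), `w` (a).
#' @return List: `out` (length-d pooled vector), `alpha` (N non-negative
#'   weights summing to 1), `cache`.
#' @export
attention_forward <- function(V, params) {
  if (!is.matrix(V) || ncol(V) != ncol(params$W)) {
    stop_invalid("attention input vectors do not match the parameter width")
  }
  Z <- params$W %*% t(V) + params$b       # a x N, b recycles per row
  Tn <- tanh(Z)
  s <- drop(crossprod(Tn, params$w))      # N scores
  s <- s - max(s)                         # softmax stabilization
  e <- exp(s)
  alpha <- e / sum(e)
  out <- drop(crossprod(V, alpha))
  list(out = out, alpha = alpha, cache = list(V = V, Tn = Tn, alpha = alpha))
}

attention_backward <- function(dout, params, cache) {
  V <- cache$V; Tn <- cache$Tn; alpha <- cache$alpha
  dalpha <- drop(V %*% dout)
  dV <- outer(alpha, dout)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  dw <- drop(Tn %*% ds)
  dTn <- outer(params$w, ds)              # a x N
  dZ <- dTn * (1 - Tn^2)
  dW <- dZ %*% V
  db <- rowSums(dZ)
  dV <- dV + t(dZ) %*% params$W
  list(dV = dV, dW = dW, db = db, dw = dw)
}

attention_params <- function(d, a) {
  list(W = glorot(a, d), b = rep(0, a), w = drop(glorot(a, 1)))
}

# --- batch normalization --------------------------------------------------
# Operates on a matrix with observations in rows and features in columns;
# callers reshape feature maps / hidden-state stacks into that layout.
# Training uses biased batch statistics and updates the running moments
# with momentum 0.99; evaluation uses the running moments.

bn_params <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d))
}

# `M` may be a single matrix or a list of per-sample matrices sharing the
# feature axis; the list form normalizes with statistics pooled across the
# whole batch while keeping every memory pass contiguous and sample-sized.
bn_forward <- function(M, bn, training, momentum = 0.99, eps = 1e-3) {
  single <- !is.list(M)
  Ms <- if (single) list(M) else M
  if (training) {
    n_tot <- 0; s <- 0; s2 <- 0
    for (Mb in Ms) {
      st <- cpp_colstats(Mb)
      nb <- nrow(Mb)
      s <- s + drop(st$mean) * nb
      s2 <- s2 + drop(st$meansq) * nb
      n_tot <- n_tot + nb
    }
    mu <- s / n_tot
    v <- pmax(s2 / n_tot - mu^2, 0)
    bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
    bn$run_var <- momentum * bn$run_var + (1 - momentum) * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- vector("list", length(Ms))
  y <- vector("list", length(Ms))
  for (b in seq_along(Ms)) {
    ap <- cpp_bn_apply(Ms[[b]], inv_sd, -mu * inv_sd, bn$gamma, bn$beta)
    xhat[[b]] <- ap$xhat
    y[[b]] <- ap$y
  }
  list(y = if (single) y[[1]] else y, bn = bn,
       cache = list(xhat = if (single) xhat[[1]] else xhat,
                    inv_sd = inv_sd, training = training))
}

bn_backward <- function(dy, bn, cache) {
  single <- !is.list(dy)
  dys <- if (single) list(dy) else dy
  xhats <- if (single) list(cache$xhat) else cache$xhat
  dgamma <- 0; dbeta <- 0; m <- 0
  for (b in seq_along(dys)) {
    dgamma <- dgamma + drop(cpp_colsums_prod(dys[[b]], xhats[[b]]))
    dbeta <- dbeta + colSums(dys[[b]])
    m <- m + nrow(dys[[b]])
  }
  scale <- bn$gamma * cache$inv_sd
  dx <- vector("list", length(dys))
  for (b in seq_along(dys)) {
    dx[[b]] <- if (cache$training) {
      cpp_bn_backward_dx(dys[[b]], xhats[[b]], dbeta / m, dgamma / m, scale)
    } else {
      cpp_colscale_shift(dys[[b]], scale, numeric(length(scale)))
    }
  }
  list(dx = if (single) dx[[1]] else dx, dgamma = dgamma, dbeta = dbeta)
}

# --- inverted dropout -----------------------------------------------------

dropout_forward <- function(M, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = M, mask = NULL))
  }
  mask <- (runif(length(M)) >= rate) / (1 - rate)
  if (!is.null(dim(M))) dim(mask) <- dim(M)
  list(y = M * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# --- convolution / pooling wrappers ---------------------------------------

#' One multi-shape convolutional layer
#'
#' Convolves the input with every kernel-shape group (default 3x3, 5x1 and
#' 7x1, each with `n_kernels` kernels, stride 1, SAME zero padding — the
#' tall 5x1/7x1 kernels span 5 or 7 leads at a single time point) and
#' applies ReLU. SAME padding keeps all groups at the input's spatial size
#' so their maps can be concatenated on the channel axis.
#'
#' @param x Input array `H x W x C_in` (a 12 x 651 beat enters as
#'   `12 x 651 x 1`).
#' @param params Per-shape list of `W` (`n_kernels x C_in*kh*kw`) and `b`,
#'   as built by [conv_layer_params()]; shapes are recorded alongside.
#' @return List: `y` activation maps (`H x W x shapes*n_kernels`), `cache`.
#' @export
conv_layer_forward <- function(x, params, precision = c("single", "double")) {
  precision <- match.arg(precision)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  fwd <- if (precision == "single") cpp_conv_forward else cpp_conv_forward_dbl
  y <- fwd(
    x,
    lapply(params$groups, `[[`, "W"), lapply(params$groups, `[[`, "b"),
    vapply(params$shapes, function(s) as.integer(s[1]), integer(1)),
    vapply(params$shapes, function(s) as.integer(s[2]), integer(1)),
    TRUE
  )
  list(y = y, cache = list(x = x, y = y))
}

conv_layer_backward <- function(dy, params, cache,
                                precision = c("single", "double")) {
  precision <- match.arg(precision)
  dy <- cpp_relu_gate(dy, cache$y)
  bwd <- if (precision == "single") cpp_conv_backward else cpp_conv_backward_dbl
  gb <- bwd(
    cache$x, lapply(params$groups, `[[`, "W"), dy,
    vapply(params$shapes, function(s) as.integer(s[1]), integer(1)),
    vapply(params$shapes, function(s) as.integer(s[2]), integer(1))
  )
  grads <- Map(function(dW, db) list(W = dW, b = drop(db)), gb$dWs, gb$dbs)
  list(dx = gb$dx, grads = list(groups = unname(grads)))
}

#' @rdname conv_layer_forward
#' @param c_in Input channel count.
#' @param n_kernels Kernels per shape group (20 in the reference
#'   architecture, so three groups give 60 feature maps).
#' @param shapes List of kernel shapes `c(kh, kw)`.
#' @export
conv_layer_params <- function(c_in, n_kernels = 20,
                              shapes = list(c(3, 3), c(5, 1), c(7, 1))) {
  groups <- lapply(shapes, function(sh) {
    fan <- c_in * sh[1] * sh[2]
    list(W = glorot(n_kernels, fan), b = rep(0, n_kernels))
  })
  list(groups = groups, shapes = shapes)
}

#' 2x2 max pooling with stride 1
#'
#' Valid pooling: each spatial dimension shrinks by exactly one.
#'
#' @param x Array `H x W x C` with `H, W >= 2`.
#' @return List: `y` (`(H-1) x (W-1) x C`), `cache` with the argmax codes.
#' @export
max_pool_forward <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  out <- cpp_maxpool_forward(x)
  list(y = out$y, cache = list(argmax = out$argmax, H = dim(x)[1], W = dim(x)[2]))
}

max_pool_backward <- function(dy, cache) {
  cpp_maxpool_backward(dy, cache$argmax, cache$H, cache$W)
}
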