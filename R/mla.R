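# Multi-lead attention (MLA): a trainable, input-dependent weight in [0, 1]
# per lead. M1 = tanh(W1 L + b1), scores s = M1 w1, alpha1 = StepReLU(s),
# and the selected signal X scales row i of L by alpha1[i].

#' Initialize MLA parameters
#'
#' `b1` is the small positive constant 0.1; `W1` is drawn uniform with a
#' deliberately small range (so that for standardized beats, whose entries
#' lie in \[-1, 1\], the pre-tanh activations stay near `b1`), and the
#' scoring vector `w1` is drawn positive and scaled so the initial lead
#' weights sit near 0.5 — strictly inside StepReLU's identity branch,
#' where gradients flow. A wide symmetric initialization would scatter the
#' initial lead scores onto the flat branches below 0 or above 1, which
#' are absorbing (zero gradient): leads frozen at birth, by accident
#' rather than by training.
#'
#' @param k Number of leads (12).
#' @param t Beat length (651).
#' @return List with `W1`, `b1`, `w1`.
#' @export
mla_params <- function(k = 12, t = 651) {
  lim <- 0.1 / k
  w1_max <- 2 * 0.5 / (t * tanh(0.1))
  list(
    W1 = matrix(runif(k * k, -lim, lim), k, k),
    b1 = rep(0.1, k),
    w1 = runif(t, 0, w1_max)
  )
}

#' MLA forward pass
#'
#' @param L Beat matrix, leads x time (12 x 651).
#' @param params [mla_params()] list (`W1` k x k, `b1` k, `w1` t).
#' @return List: `X` (weighted beat, same shape as `L`), `alpha1` (k lead
#'   weights in \[0, 1\]), and `cache` for the backward pass.
#' @export
#' @examples
#' set.seed(1)
#' p <- mla_params(2, 3)
#' mla_forward(matrix(1:6 / 6, 2, 3), p)$alpha1
mla_forward <- function(L, params) {
  if (!is.matrix(L) || nrow(L) != nrow(params$W1) ||
      ncol(L) != length(params$w1)) {
    stop_invalid(sprintf("beat must be %d x %d to match the MLA parameters",
                         nrow(params$W1), length(params$w1)))
  }
  M1 <- tanh(params$W1 %*% L + params$b1)   # b1 recycles down columns
  s <- drop(M1 %*% params$w1)
  alpha1 <- step_relu(s)
  X <- L * alpha1                           # row i scaled by alpha1[i]
  list(X = X, alpha1 = alpha1, cache = list(L = L, M1 = M1, s = s))
}

# Backward pass: dX is the loss gradient w.r.t. the weighted beat.
mla_backward <- function(dX, params, cache, straight_through = FALSE) {
  dalpha1 <- rowSums(dX * cache$L)
  ds <- dalpha1 * drop(step_relu_grad(cache$s, straight_through))
  dM1 <- outer(ds, params$w1)
  dw1 <- drop(crossprod(cache$M1, ds))
  dpre <- dM1 * (1 - cache$M1^2)
  list(
    dW1 = dpre %*% t(cache$L),
    db1 = rowSums(dpre),
    dw1 = dw1,
    dL = dX * step_relu(cache$s)            # not used upstream of the input
  )
}
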