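# The clipped-linear activation at the heart of the lead-attention
# mechanism, and its subgradient.

#' StepReLU activation
#'
#' Element-wise clipped identity: 0 below 0, the identity on \[0, 1\], 1
#' above 1 — a trainable surrogate for a step function. Applied to the lead
#' scores it confines every lead weight to \[0, 1\], so a lead can be fully
#' kept (1), fully eliminated (0), or partially weighted.
#'
#' @param x Numeric vector, matrix or array.
#' @return Same shape as `x`.
#' @export
#' @examples
#' step_relu(c(-0.5, 0.5, 2.3))  # 0, 0.5, 1
step_relu <- function(x) {
  pmin(pmax(x, 0), 1)
}

#' @rdname step_relu
#' @details `step_relu_grad()` is the exact subgradient of the clip: 1 on
#'   \[0, 1\] (corners included, so at-bound leads keep training), 0 on the
#'   flat branches. With `straight_through = TRUE` the gradient is 1
#'   everywhere (a straight-through estimator; off by default).
#' @param straight_through Use a gradient of 1 on the flat branches too.
#' @export
step_relu_grad <- function(x, straight_through = FALSE) {
  if (straight_through) {
    g <- x
    g[] <- 1
    return(g)
  }
  (x >= 0 & x <= 1) * 1
}
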