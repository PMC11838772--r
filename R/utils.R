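#' Gaussian-error linear unit
#'
#' Exact GELU, `x * pnorm(x)`. Its global minimum is approximately -0.17
#' (attained near x = -0.752), which bounds every temporal concept entry
#' from below.
#'
#' @param x Numeric vector or matrix.
#' @return Object of the same shape as `x`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

#' @rdname gelu
#' @export
gelu_prime <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

## numerically safe row-wise softmax
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

## fan-in uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nin, nout) {
  b <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -b, b), nin, nout)
}

init_embed <- function(n, d, scale = 0.05) {
  matrix(stats::runif(n * d, -scale, scale), n, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## row-indexed accumulation: add rows of `g` into rows `idx` of `acc`
accumulate_rows <- function(acc, idx, g) {
  s <- rowsum(g, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  acc[rows, ] <- acc[rows, , drop = FALSE] + s
  acc
}

stop_tce <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

#' Gradient-reversal unit
#'
#' The connection used for adversarial balancing: the forward pass is the
#' identity, the backward pass negates and scales the incoming gradient by
#' `lambda`. `gr_forward` and `gr_backward` expose the two halves for
#' composition and testing; the training engine applies the same rule (with
#' per-batch relative normalization) between the sequence representation
#' and the treatment classifier.
#'
#' @param x Forward input (returned unchanged).
#' @param grad Upstream gradient at the unit's output.
#' @param lambda Nonnegative reversal strength.
#' @return `gr_forward`: `x`; `gr_backward`: `-lambda * grad`.
#' @export
gr_forward <- function(x) x

#' @rdname gr_forward
#' @export
gr_backward <- function(grad, lambda = 1) -lambda * grad
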