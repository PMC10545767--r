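# Internal numerical helpers shared by the MIL heads.

#' @keywords internal
#' @useDynLib cytomil, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Numerically stable softplus: log(1 + exp(x))
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

## Mish activation: x * tanh(softplus(x))
mish <- function(x) {
  x * tanh(softplus(x))
}

## Derivative of Mish w.r.t. its input.
mish_grad <- function(x) {
  sp <- softplus(x)
  t <- tanh(sp)
  t + x * (1 - t^2) * sigmoid(x)
}

## Row-wise softmax of a matrix, numerically stable.
row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

## Softmax of a single logit vector.
softmax_vec <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

## Cross-entropy of a logit vector against an integer class in {0, 1, ...}.
cross_entropy <- function(logits, class) {
  z <- logits - max(logits)
  log(sum(exp(z))) - z[class + 1L]
}

## Gradient of cross_entropy w.r.t. the logits.
cross_entropy_grad <- function(logits, class) {
  p <- softmax_vec(logits)
  p[class + 1L] <- p[class + 1L] - 1
  p
}

## L2-normalize matrix rows; guards the zero row.
l2_normalize_rows <- function(m, eps = 1e-12) {
  n <- sqrt(rowSums(m^2))
  m / pmax(n, eps)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

## Scalar integer check used by constructors.
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}
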