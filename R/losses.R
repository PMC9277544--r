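# Training objective: weighted sum of binary cross-entropy and smoothed
# Dice loss. BCE averages over all pixels jointly; the Dice term is computed
# per image and then averaged over the batch so small polyps are not swamped
# by large ones. Probabilities are clamped to [1e-7, 1 - 1e-7] before
# logarithms.

BCE_EPS <- 1e-7

check_pair <- function(t, that) {
  if (!identical(dim(t) %||% length(t), dim(that) %||% length(that)))
    stop("input error: mask and prediction shapes differ", call. = FALSE)
  invisible(NULL)
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels of \eqn{-[t \log \hat t + (1-t) \log(1-\hat t)]},
#' with \eqn{\hat t} clamped to [1e-7, 1 - 1e-7] for log-safety.
#'
#' @param t binary ground-truth mask: numeric vector/array in \{0, 1\}.
#' @param that predicted probabilities, same shape, in [0, 1].
#' @return non-negative scalar.
#' @export
bceLoss <- function(t, that) {
  check_pair(t, that)
  p <- pmin(pmax(that, BCE_EPS), 1 - BCE_EPS)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Smoothed Dice loss
#'
#' \eqn{1 - (2\langle t,\hat t\rangle + \xi)/(\|t\|_1 + \|\hat t\|_1 + \xi)},
#' computed per image and averaged over the batch when given a 4-d
#' (N, 1, H, W) array; a vector or matrix is treated as one image. The
#' Laplace smoothing constant \eqn{\xi} keeps the ratio defined on empty
#' masks and speeds up early convergence.
#'
#' @param t binary ground-truth mask.
#' @param that predicted probabilities, same shape.
#' @param xi smoothing constant (default 1e-8).
#' @return scalar in [0, 1].
#' @export
diceLoss <- function(t, that, xi = 1e-8) {
  check_pair(t, that)
  stopifnot(xi > 0)
  d <- dim(t)
  if (!is.null(d) && length(d) == 4L) {
    n <- d[1]
    ti <- matrix(t, n)
    pi_ <- matrix(that, n)
    per <- 1 - (2 * rowSums(ti * pi_) + xi) / (rowSums(ti) + rowSums(pi_) + xi)
    mean(per)
  } else {
    1 - (2 * sum(t * that) + xi) / (sum(t) + sum(that) + xi)
  }
}

#' Compound segmentation loss
#'
#' \eqn{\lambda_1 L_{BCE} + \lambda_2 L_{Dice}} with the published default
#' weights 0.6 and 0.4.
#'
#' @param t binary ground-truth mask.
#' @param that predicted probabilities, same shape.
#' @param w a [LossWeights-class] (default `lossWeights()`).
#' @return non-negative scalar.
#' @export
totalLoss <- function(t, that, w = lossWeights()) {
  stopifnot(is(w, "LossWeights"))
  w@lambda1 * bceLoss(t, that) + w@lambda2 * diceLoss(t, that, w@xi)
}

# Tape version used during training: `pred` is a tape node with an
# (H, W, 1, N) probability map (internal layout), `t` a plain array of the
# same shape.
f_total_loss <- function(tape, pred, t, w) {
  p <- op_clamp(tape, pred, BCE_EPS, 1 - BCE_EPS)
  tc <- ad_const(tape, t)
  omt <- ad_const(tape, 1 - t)
  logp <- op_log(tape, p)
  log1mp <- op_log(tape, op_sadd(tape, op_smul(tape, p, -1), 1))
  bce <- op_smul(tape, op_mean_all(
    tape, op_add(tape, op_mul(tape, tc, logp), op_mul(tape, omt, log1mp))), -1)
  inter <- op_sum_img(tape, op_mul(tape, tc, p))
  psum <- op_sum_img(tape, p)
  tsum <- ad_const(tape, colSums(matrix(t, ncol = dim(t)[4])))
  num <- op_sadd(tape, op_smul(tape, inter, 2), w@xi)
  den <- op_sadd(tape, op_add(tape, psum, tsum), w@xi)
  dice <- op_mean_all(tape, op_sadd(
    tape, op_smul(tape, op_div(tape, num, den), -1), 1))
  op_add(tape, op_smul(tape, bce, w@lambda1), op_smul(tape, dice, w@lambda2))
}
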