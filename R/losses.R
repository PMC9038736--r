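# Training losses for fractured-vertebra segmentation: binary cross-entropy,
# Dice loss, and a propagation loss that penalises predictions missing
# regions implied by neighbouring slices. All are pure functions of flat
# pixel vectors; no autodiff framework is involved.

.check_len <- function(...) {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1L) stop("input vectors must have equal length")
  if (lens[1] < 1L) stop("inputs must be nonempty")
  invisible(lens[1])
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y * log(x_p) + (1 - y) * log(1 - x_p))`, with predicted
#' probabilities clipped to `[eps, 1 - eps]` to stay finite.
#'
#' @param x_p predicted probabilities in `[0, 1]`.
#' @param y_g ground-truth labels in `{0, 1}`.
#' @param eps clipping constant (default `1e-7`).
#' @return nonnegative scalar.
#' @export
bce_loss <- function(x_p, y_g, eps = 1e-7) {
  n <- .check_len(x_p, y_g)
  if (any(x_p < 0 | x_p > 1)) stop("x_p must lie in [0, 1]")
  if (!all(y_g %in% c(0, 1))) stop("y_g must be binary")
  p <- pmin(pmax(x_p, eps), 1 - eps)
  -sum(y_g * log(p) + (1 - y_g) * log(1 - p)) / n
}

#' Dice loss
#'
#' `1 - 2 * sum(x_g * y_g) / (sum(x_g) + sum(y_g))`, with a smoothing
#' constant `delta` added to numerator and denominator so that two empty
#' masks give loss 0. `x_g` is the predicted label map; a soft variant
#' (probabilities in place of labels) is obtained by passing `x_p` as `x_g`.
#'
#' @param x_g predicted labels (or probabilities) in `[0, 1]`.
#' @param y_g ground-truth labels in `{0, 1}`.
#' @param delta smoothing constant (default `1e-6`).
#' @return value in `[0, 1]`.
#' @export
dice_loss <- function(x_g, y_g, delta = 1e-6) {
  .check_len(x_g, y_g)
  if (any(x_g < 0 | x_g > 1)) stop("x_g must lie in [0, 1]")
  1 - (2 * sum(x_g * y_g) + delta) / (sum(x_g) + sum(y_g) + delta)
}

#' Propagation loss
#'
#' Fraction of propagation-label pixels the prediction misses:
#' `sum(p_g - x_g * p_g) / sum(p_g)`, defined as 0 when the propagation
#' label is empty.
#'
#' @param x_g predicted labels (or probabilities) in `[0, 1]`.
#' @param p_g propagation labels in `{0, 1}` (see
#'   [make_propagation_label()]).
#' @return value in `[0, 1]`.
#' @export
propagation_loss <- function(x_g, p_g) {
  .check_len(x_g, p_g)
  if (!all(p_g %in% c(0, 1))) stop("p_g must be binary")
  s <- sum(p_g)
  if (s == 0) return(0)
  sum(p_g - x_g * p_g) / s
}

#' Combined segmentation loss
#'
#' `alpha * bce + beta * dice + gamma * propagation`. The balancing
#' coefficients default to (1, 1, 1) and must not all be zero.
#'
#' @param x_p predicted probabilities.
#' @param x_g predicted labels (thresholded predictions; pass `x_p` for the
#'   soft variant).
#' @param y_g ground-truth labels.
#' @param p_g propagation labels.
#' @param weights nonnegative `c(alpha, beta, gamma)`.
#' @inheritParams bce_loss
#' @return nonnegative scalar.
#' @export
combined_loss <- function(x_p, x_g, y_g, p_g, weights = c(1, 1, 1), eps = 1e-7) {
  if (length(weights) != 3L || any(weights < 0) || all(weights == 0)) {
    stop("weights must be 3 nonnegative numbers, not all zero")
  }
  weights[1] * bce_loss(x_p, y_g, eps = eps) +
    weights[2] * dice_loss(x_g, y_g) +
    weights[3] * propagation_loss(x_g, p_g)
}
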