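#' Loss configuration for quantile-regression training
#'
#' @param delta Huber transition scale in ppm; below this absolute residual
#'   the loss is quadratic, above it linear. The default 1e-4 is small
#'   enough that the loss is numerically indistinguishable from pinball
#'   loss while keeping a continuous gradient through zero.
#' @param epsilon monotonicity margin: consecutive quantile predictions are
#'   pushed to differ by at least this much (default 1e-6).
#' @param grid quantile grid, see [quantile_grid()].
#' @param mono_weight multiplier on the crossing penalty (default 1; 0
#'   disables it).
#' @return object of class `loss_config`.
#' @export
loss_config <- function(delta = 1e-4, epsilon = 1e-6, grid = quantile_grid(),
                        mono_weight = 1) {
  stopifnot(delta > 0, epsilon > 0, mono_weight >= 0)
  structure(list(delta = delta, epsilon = epsilon, grid = grid,
                 mono_weight = mono_weight), class = "loss_config")
}

#' Quantile grid
#'
#' Strictly increasing probability levels at which the model predicts the
#' inverse CDF of the chemical shift. The default is the 99 percentiles
#' 0.01, 0.02, ..., 0.99; the 0th/100th percentiles are excluded since they
#' correspond to the extremes of the training data rather than to a
#' distribution parameter.
#'
#' @param taus numeric vector in (0, 1), strictly increasing.
#' @return numeric vector of class `quantile_grid`.
#' @export
quantile_grid <- function(taus = seq(0.01, 0.99, by = 0.01)) {
  taus <- as.numeric(taus)
  if (any(taus <= 0) || any(taus >= 1) || any(diff(taus) <= 0))
    stop("quantile grid must be strictly increasing within (0, 1)")
  structure(taus, class = "quantile_grid")
}

#' Modified Huber loss
#'
#' Quadratic `r^2/(2*delta)` for `|r| <= delta`, linear `|r| - delta/2`
#' beyond; continuous with continuous first derivative everywhere, and
#' within `delta/2` of `|r|` for every residual, so the delta -> 0 limit is
#' the absolute error.
#'
#' @param residual numeric residual(s), ppm.
#' @param delta transition scale > 0, ppm.
#' @return loss value(s), same shape as `residual`.
#' @export
huber <- function(residual, delta = 1e-4) {
  stopifnot(delta > 0)
  a <- abs(residual)
  ifelse(a <= delta, residual^2 / (2 * delta), a - delta / 2)
}

# derivative of the modified Huber loss wrt the residual
huber_grad <- function(residual, delta) {
  ifelse(abs(residual) <= delta, residual / delta, sign(residual))
}

#' Single-quantile loss
#'
#' The tau-weighted modified Huber loss for one predicted quantile:
#' under-predictions (`yhat < y`) are weighted by `tau`, over-predictions by
#' `1 - tau`, so at tau = 0.75 a unit under-prediction costs three times a
#' unit over-prediction and at tau = 0.5 the two cost the same. A correct
#' prediction has zero loss. As delta -> 0 this converges to the pinball
#' loss `tau*max(y - yhat, 0) + (1 - tau)*max(yhat - y, 0)` within delta/2.
#'
#' @param y observed shift (ppm).
#' @param yhat predicted quantile value (ppm).
#' @param tau quantile level in (0, 1).
#' @param delta Huber transition scale.
#' @return non-negative loss value (vectorised over `y`/`yhat`).
#' @export
quantile_loss <- function(y, yhat, tau, delta = 1e-4) {
  if (any(tau <= 0) || any(tau >= 1)) stop("tau must lie strictly in (0, 1)")
  r <- y - yhat
  w <- ifelse(r > 0, tau, 1 - tau)   # r > 0: under-prediction
  w * huber(r, delta)
}

#' Sum of quantile losses over a full prediction vector
#'
#' @param y observed shift (ppm), scalar.
#' @param yhat_vec predicted quantile vector, one entry per grid level.
#' @param config a [loss_config()].
#' @return scalar loss: sum of [quantile_loss()] over all grid entries;
#'   zero iff every entry equals `y`.
#' @export
multi_quantile_loss <- function(y, yhat_vec, config = loss_config()) {
  taus <- as.numeric(config$grid)
  if (length(yhat_vec) != length(taus))
    stop("prediction vector length (", length(yhat_vec),
         ") does not match quantile grid length (", length(taus), ")")
  sum(quantile_loss(y, yhat_vec, taus, config$delta))
}

#' Quantile-crossing penalty
#'
#' Hinge penalty on consecutive quantile predictions,
#' `sum_k max(0, yhat_k - yhat_{k+1} + epsilon)`: zero iff each successive
#' quantile exceeds its predecessor by at least epsilon, so minimising it
#' preserves the non-decreasing character of a CDF and suppresses quantile
#' crossing.
#'
#' @param yhat_vec predicted quantile vector (length >= 2) in grid order.
#' @param epsilon positive monotonicity margin.
#' @return non-negative scalar penalty.
#' @export
monotonicity_penalty <- function(yhat_vec, epsilon = 1e-6) {
  stopifnot(length(yhat_vec) >= 2, epsilon > 0)
  d <- yhat_vec[-length(yhat_vec)] - yhat_vec[-1] + epsilon
  sum(pmax(0, d))
}

#' Composite training loss for a batch of atoms
#'
#' Mean over atoms of the multi-quantile loss plus `mono_weight` times the
#' crossing penalty. Differentiable almost everywhere with finite gradients
#' for every residual (including 0 and +/-delta).
#'
#' @param y numeric vector of observed shifts, one per atom.
#' @param yhat matrix of predictions, `length(y)` rows x grid columns.
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
total_loss <- function(y, yhat, config = loss_config()) {
  if (!length(y)) stop("empty batch")
  yhat <- matrix(yhat, nrow = length(y))
  per_atom <- vapply(seq_along(y), function(a) {
    multi_quantile_loss(y[a], yhat[a, ], config) +
      config$mono_weight * monotonicity_penalty(yhat[a, ], config$epsilon)
  }, numeric(1))
  mean(per_atom)
}

# Vectorised loss + gradient used by the training loop: y length n,
# yhat n x q matrix. Returns list(loss, grad) where grad is dL/dyhat
# for the mean-over-atoms composite loss.
total_loss_grad <- function(y, yhat, config) {
  n <- length(y); taus <- as.numeric(config$grid)
  r <- y - yhat                       # n x q
  w <- ifelse(r > 0, rep(taus, each = n), rep(1 - taus, each = n))
  lq <- sum(w * huber(r, config$delta)) / n
  grad <- -w * huber_grad(r, config$delta) / n
  q <- length(taus)
  d <- yhat[, -q, drop = FALSE] - yhat[, -1, drop = FALSE] + config$epsilon
  act <- d > 0
  lm <- sum(pmax(0, d)) / n
  gm <- matrix(0, n, q)
  gm[, -q] <- gm[, -q] + act
  gm[, -1] <- gm[, -1] - act
  list(loss = lq + config$mono_weight * lm,
       quantile_loss = lq, mono_loss = lm,
       grad = grad + config$mono_weight * gm / n)
}
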