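# Focal Tversky loss for imbalanced binary segmentation.
#
# With TI = sum(y*yhat) / (sum(y*yhat) + alpha*sum(y*(1-yhat)) +
# beta*sum((1-y)*yhat) + eps), the loss is (1 - TI)^gamma. alpha > beta
# penalizes false negatives harder than false positives, which suits the
# thin-boundary class imbalance; gamma < 1 focuses the gradient on hard
# examples. The loss lives in [0, 1].

#' Focal Tversky loss parameters
#'
#' @param alpha false-negative penalty (default 0.7).
#' @param beta false-positive penalty (default 0.3).
#' @param gamma focal exponent (default 0.75).
#' @param epsilon smoothing term avoiding division by zero (default 1e-12).
#' @return A validated `loss_params` list.
#' @export
loss_params <- function(alpha = 0.7, beta = 0.3, gamma = 0.75,
                        epsilon = 1e-12) {
  stop_if_not(is_scalar(alpha) && alpha >= 0, "alpha must be >= 0")
  stop_if_not(is_scalar(beta) && beta >= 0, "beta must be >= 0")
  stop_if_not(is_scalar(gamma) && gamma > 0, "gamma must be > 0")
  stop_if_not(is_scalar(epsilon) && epsilon > 0, "epsilon must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon), class = "loss_params")
}

#' Focal Tversky loss
#'
#' @param y ground-truth binary mask (any shape).
#' @param y_hat predicted probabilities in `[0, 1]`, same shape.
#' @param params a [loss_params()].
#' @return scalar loss in `[0, 1]`.
#' @export
#' @examples
#' focal_tversky_loss(c(1, 0), c(0.5, 0.5))  # 0.5^0.75
focal_tversky_loss <- function(y, y_hat, params = loss_params()) {
  stop_if_not(length(y) == length(y_hat), "y and y_hat shapes differ")
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  stop_if_not(all(y %in% c(0, 1)), "y must be binary")
  stop_if_not(all(y_hat >= 0 & y_hat <= 1), "y_hat must lie in [0, 1]")
  tp <- sum(y * y_hat)
  fn <- sum(y * (1 - y_hat))
  fp <- sum((1 - y) * y_hat)
  ti <- tp / (tp + params$alpha * fn + params$beta * fp + params$epsilon)
  (1 - ti)^params$gamma
}

# Gradient of the loss wrt y_hat (vectorized, same shape as y_hat).
focal_tversky_grad <- function(y, y_hat, params = loss_params()) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  a <- params$alpha; b <- params$beta
  tp <- sum(y * y_hat)
  fn <- sum(y * (1 - y_hat))
  fp <- sum((1 - y) * y_hat)
  D <- tp + a * fn + b * fp + params$epsilon
  ti <- tp / D
  # d ti / d y_hat_i = (y_i * D - tp * (y_i - a*y_i + b*(1 - y_i))) / D^2
  dti <- (y * D - tp * (y * (1 - a) + b * (1 - y))) / (D * D)
  -params$gamma * max(1 - ti, 1e-12)^(params$gamma - 1) * dti
}
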