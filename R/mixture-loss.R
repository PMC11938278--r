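# Gaussian-mixture divergence loss for the location model.
#
# Predictions (x_j, w_j) and reference sites (y_i, o_i) are both read as
# isotropic Gaussian mixtures with sigma = 0.5 A: mixture weights are the
# normalized certainty weights (predictions) and normalized occupancies
# (references). The fit term L1 is a component-centered surrogate of the
# symmetrized Kullback-Leibler divergence: the negative cross log-density of
# each mixture evaluated at the other's component centers,
#   L1 = -( sum_j wtil_j log q(x_j) + sum_i otil_i log p(y_i) ).
# L2 = sum_j wtil_j^2 penalizes concentration of the certainty weights, and
# the total loss is L = L1 + alpha * L2. All densities are evaluated in
# log space (log-sum-exp) so far-apart configurations keep usable gradients.

#' Normalize certainty weights
#'
#' Maps raw non-negative certainty weights to mixture weights summing to 1.
#'
#' @param w numeric vector, all `>= 0`, at least one positive.
#' @return `w / sum(w)`.
#' @examples
#' normalize_weights(c(1, 1, 2))
#' @export
normalize_weights <- function(w) {
  if (any(w < 0) || any(!is.finite(w))) {
    abort("Certainty weights must be finite and non-negative.")
  }
  s <- sum(w)
  if (s == 0) abort("All certainty weights are zero: mixture undefined.")
  w / s
}

# log density of an isotropic Gaussian mixture at query points.
# centers: m x 3, log_weights: length m, queries: k x 3. Returns:
#   logdens (k), and resp (k x m) posterior responsibilities.
mixture_log_density <- function(queries, centers, log_weights, sigma) {
  d2 <- cross_distances(queries, centers)^2
  lg <- sweep(-d2 / (2 * sigma^2), 2, log_weights, "+")
  mx <- apply(lg, 1, max)
  lse <- mx + log(rowSums(exp(lg - mx)))
  list(
    logdens = lse - 1.5 * log(2 * pi * sigma^2),
    resp = exp(lg - lse)
  )
}

#' Gaussian-mixture divergence loss
#'
#' Computes the training loss of the location model: the symmetrized
#' cross-likelihood divergence `L1` between the prediction mixture and the
#' reference mixture, plus `alpha` times the weight-concentration penalty
#' `L2`. References must already be restricted to occupancy `>= 0.5`
#' upstream (done by [train_site_model()]).
#'
#' @param preds tibble of raw predictions with columns `x`, `y`, `z`, `w`.
#' @param refs tibble of reference sites with columns `x`, `y`, `z` and
#'   optionally `occupancy` (defaults to uniform reference weights).
#' @param alpha weight of the concentration penalty (`> 0`).
#' @param sigma mixture standard deviation in A.
#' @param gradients also return analytic gradients with respect to the
#'   prediction coordinates and raw weights?
#' @return The scalar loss; with `gradients = TRUE`, a list
#'   `list(loss, l1, l2, grad_x, grad_w)` where `grad_x` is n x 3.
#' @export
mixture_loss <- function(preds, refs, alpha = 0.1, sigma = 0.5,
                         gradients = FALSE) {
  if (nrow(preds) == 0) abort("mixture_loss() needs at least one prediction.")
  if (nrow(refs) == 0) abort("mixture_loss() needs at least one reference site.")
  x <- coord_matrix(preds)
  y <- coord_matrix(refs)
  w <- preds$w
  wt <- normalize_weights(w)
  ot <- if ("occupancy" %in% names(refs)) {
    normalize_weights(refs$occupancy)
  } else {
    rep(1 / nrow(refs), nrow(refs))
  }
  n <- nrow(x); m <- nrow(y)

  q_at_x <- mixture_log_density(x, y, log(ot), sigma)   # log q(x_j), chi (n x m)
  p_at_y <- mixture_log_density(y, x, log(wt), sigma)   # log p(y_i), psi (m x n)

  l1 <- -sum(wt * q_at_x$logdens) - sum(ot * p_at_y$logdens)
  l2 <- sum(wt^2)
  loss <- l1 + alpha * l2
  if (!gradients) return(loss)

  chi <- q_at_x$resp        # n x m: responsibility of ref i for query x_j
  psi <- p_at_y$resp        # m x n: responsibility of pred j for query y_i

  # d l1 / d x_j: through log q(x_j) and through p(y_i)'s component j.
  grad_x <- matrix(0, n, 3)
  for (a in 1:3) {
    diff_xy <- outer(x[, a], y[, a], "-")              # n x m: x_j - y_i
    grad_x[, a] <- wt * rowSums(chi * diff_xy) / sigma^2 +
      colSums(ot * psi * t(diff_xy)) / sigma^2
  }

  # d l1 / d wtil_j, then chain through the normalization.
  dl1_dwt <- -q_at_x$logdens - colSums(ot * psi) / wt
  dl2_dwt <- 2 * wt
  dL_dwt <- dl1_dwt + alpha * dl2_dwt
  sw <- sum(w)
  grad_w <- (dL_dwt - sum(dL_dwt * wt)) / sw

  list(loss = loss, l1 = l1, l2 = l2, grad_x = grad_x, grad_w = grad_w)
}
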