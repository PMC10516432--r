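# Coding step: proximal-gradient iterations finding sparse coefficients r
# for image patches given a fixed dictionary.

#' Upper bound for the gradient Lipschitz constant
#'
#' Largest squared singular value of the dictionary (the spectral norm of
#' \eqn{\Phi^\top\Phi}), the Lipschitz constant L of the gradient of the
#' quadratic data term. The proximal-gradient step size must satisfy
#' \eqn{\mu \le 1/L}.
#'
#' @param dictionary M x N numeric matrix.
#' @return a single number, \eqn{L}.
#' @export
lipschitz_bound <- function(dictionary) {
  stopifnot(is.matrix(dictionary))
  norm(dictionary, type = "2")^2
}

#' Energy of a code
#'
#' The objective of the sparse coding problem,
#' \eqn{E(r, \Phi) = \frac12 \|I - \Phi r\|_2^2 + w\, C(r)}, with outer
#' weight \eqn{w = \lambda} for the soft, half and hard penalties and
#' \eqn{w = 1} for CEL0 (whose weight is internal; see [penalty_value()]).
#'
#' @param patch length-M numeric vector.
#' @param dictionary M x N numeric matrix.
#' @param r length-N coefficient vector.
#' @param penalty a [penalty_spec()].
#' @return a single number.
#' @export
energy <- function(patch, dictionary, r, penalty) {
  stopifnot(length(patch) == nrow(dictionary),
            length(r) == ncol(dictionary))
  0.5 * sum((patch - as.vector(dictionary %*% r))^2) +
    penalty_weight(penalty) * penalty_value(r, penalty)
}

# descent-objective weight: the hard operator with threshold theta = lambda*mu
# is the exact l0 prox for weight theta^2/(2 mu), so that is the weight whose
# energy the iteration provably decreases; identical to penalty_weight()
# for the other three kinds.
descent_weight <- function(spec) {
  if (spec$kind == "hard") spec$theta^2 / (2 * spec$mu)
  else penalty_weight(spec)
}

#' Sparse-code one patch against a fixed dictionary
#'
#' Proximal-gradient iterations starting from the zero code (activities
#' charge up from rest): repeat a gradient step on the quadratic data term
#' followed by the component-wise thresholding operator of the penalty, for
#' a fixed iteration budget. The per-iteration energy trace is recorded so
#' convergence can be audited; for step sizes \eqn{\mu \le 1/L} the trace
#' is non-increasing (for the hard penalty the monitored objective uses the
#' operator's effective weight, see [hard_threshold()]).
#'
#' @param patch length-M numeric vector.
#' @param dictionary M x N numeric matrix with unit-norm columns.
#' @param penalty a [penalty_spec()]; its `mu` is the step size and must
#'   satisfy \eqn{\mu \in (0, 1/L]} for guaranteed descent.
#' @param max_iters iteration budget, at least 1 (default 200; there is no
#'   early stopping).
#' @param active_tol magnitude below which a coefficient counts as
#'   inactive. The operators produce exact zeros, so the default is 0.
#' @return an object of class `sparse_code`: list with `r` (length-N
#'   coefficients), `active_count`, `energy_trace` (length `max_iters`),
#'   `final_mse` (mean squared residual per pixel).
#' @examples
#' phi <- random_unit_dictionary(16, 24, seed = 2)
#' sc <- sparse_code(phi[, 3], phi, penalty_spec("soft", 0.05, 0.4))
#' sc$active_count
#' @export
sparse_code <- function(patch, dictionary, penalty, max_iters = 200,
                        active_tol = 0) {
  stopifnot(length(patch) == nrow(dictionary), max_iters >= 1)
  res <- sparse_code_batch(matrix(patch, nrow = 1), dictionary, penalty,
                           max_iters = max_iters, trace = TRUE)
  r <- res$codes[1, ]
  structure(list(r = r,
                 active_count = sum(abs(r) > active_tol),
                 energy_trace = res$energy_trace[, 1],
                 final_mse = res$mse[1]),
            class = "sparse_code")
}

#' Sparse-code a batch of patches
#'
#' Vectorized proximal-gradient coding of B patches at once (codes held as
#' an N x B matrix). Used by the training loop and the experiment drivers.
#'
#' @param patches B x M matrix, one patch per row.
#' @param dictionary M x N matrix with unit-norm columns.
#' @param penalty a [penalty_spec()].
#' @param max_iters iteration budget.
#' @param trace if `TRUE`, also return the per-iteration descent-objective
#'   trace (max_iters x B matrix).
#' @return list with `codes` (B x N matrix), `mse` (length-B mean squared
#'   residual per pixel), `active` (length-B active-unit counts), and
#'   `energy_trace` when requested.
#' @export
sparse_code_batch <- function(patches, dictionary, penalty,
                              max_iters = 200, trace = FALSE) {
  stopifnot(is.matrix(patches), ncol(patches) == nrow(dictionary),
            inherits(penalty, "penalty_spec"), max_iters >= 1)
  M <- nrow(dictionary); N <- ncol(dictionary); B <- nrow(patches)
  I <- t(patches)                       # M x B
  R <- matrix(0, N, B)                  # codes charge up from zero
  mu <- penalty$mu
  gram <- crossprod(dictionary)         # N x N
  pti <- crossprod(dictionary, I)       # N x B
  w <- descent_weight(penalty)
  pen_spec <- penalty
  etrace <- if (trace) matrix(NA_real_, max_iters, B) else NULL
  for (t in seq_len(max_iters)) {
    Z <- R - mu * (gram %*% R - pti)
    R <- apply_threshold(Z, pen_spec)
    dim(R) <- c(N, B)
    if (trace || t == max_iters) {
      resid <- I - dictionary %*% R
      if (trace) {
        pen <- apply(R, 2, function(rc) penalty_value(rc, pen_spec))
        if (pen_spec$kind == "hard") pen <- colSums(R != 0)
        etrace[t, ] <- 0.5 * colSums(resid^2) + w * pen
        if (any(!is.finite(etrace[t, ])))
          stop("non-finite energy during coding: the step size must ",
               "satisfy mu <= 1/L (see lipschitz_bound())")
      }
    }
    if (!trace && t %% 50L == 0L && any(!is.finite(R)))
      stop("non-finite code during coding: the step size must ",
           "satisfy mu <= 1/L (see lipschitz_bound())")
  }
  resid <- I - dictionary %*% R
  if (any(!is.finite(resid)))
    stop("non-finite residual after coding: the step size must ",
         "satisfy mu <= 1/L (see lipschitz_bound())")
  list(codes = t(R), mse = colMeans(resid^2), active = colSums(R != 0),
       energy_trace = etrace)
}
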