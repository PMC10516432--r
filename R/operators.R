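#' Sparsity penalty specification
#'
#' Bundles the choice of sparsity-promoting penalty \eqn{c(\cdot)} with its
#' regularization weight \eqn{\lambda} and proximal step size \eqn{\mu}.
#' The four penalties are the absolute value (soft / ISTA), the square root
#' \eqn{|r|^{1/2}} (half thresholding), the counting pseudo-norm (hard
#' thresholding) and the CEL0 continuous exact relaxation of the counting
#' norm, whose per-coefficient cost depends on the norm of the corresponding
#' dictionary column.
#'
#' @param kind one of `"soft"`, `"half"`, `"hard"`, `"cel0"`.
#' @param lambda regularization weight, > 0.
#' @param mu proximal step size, > 0.
#' @param column_norms optional vector of dictionary column norms, used by
#'   the CEL0 penalty only. Defaults to 1 (the learning step renormalizes
#'   columns to unit length, so this is the common case).
#' @return an object of class `penalty_spec`.
#' @examples
#' penalty_spec("soft", lambda = 0.1, mu = 0.5)
#' @export
penalty_spec <- function(kind = c("soft", "half", "hard", "cel0"),
                         lambda, mu, column_norms = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (lambda <= 0) stop("`lambda` must be > 0")
  if (mu <= 0) stop("`mu` must be > 0")
  if (!is.null(column_norms)) {
    if (any(!is.finite(column_norms)) || any(column_norms <= 0))
      stop("`column_norms` must all be finite and > 0")
  }
  structure(list(kind = kind, lambda = lambda, mu = mu,
                 theta = lambda * mu, column_norms = column_norms),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("<penalty_spec> kind=%s lambda=%g mu=%g (theta=%g)\n",
              x$kind, x$lambda, x$mu, x$theta))
  invisible(x)
}

#' Soft thresholding operator
#'
#' The proximal operator of \eqn{\theta |y|}: shrinks the input toward zero
#' by \eqn{\theta} and clips to zero inside \eqn{[-\theta, \theta]}.
#' Continuous in `z`.
#'
#' @param z numeric vector of inputs.
#' @param theta threshold \eqn{\theta = \lambda\mu > 0}.
#' @return numeric vector, same length as `z`.
#' @export
soft_threshold <- function(z, theta) {
  stopifnot(theta > 0)
  sign(z) * pmax(abs(z) - theta, 0)
}

#' Half thresholding operator
#'
#' Exact proximal operator of the square-root penalty,
#' \eqn{\mathrm{argmin}_y \lambda |y|^{1/2} + (y-z)^2/(2\mu)} with
#' \eqn{\theta = \lambda\mu}. Closed form via the trigonometric solution of
#' the stationarity cubic; zero inside the symmetric interval
#' \eqn{|z| \le t_{1/2}(\theta) = (3/2)\,\theta^{2/3}}. Odd in `z`, with a
#' jump of height \eqn{(2/3) t_{1/2}} at the threshold.
#'
#' @inheritParams soft_threshold
#' @return numeric vector, same length as `z`.
#' @export
half_threshold <- function(z, theta) {
  stopifnot(theta > 0)
  out <- numeric(length(z))
  az <- abs(z)
  thr <- 1.5 * theta^(2 / 3)
  up <- which(az > thr)
  if (length(up)) {
    zi <- z[up]
    # clamp guards fp noise just above the threshold
    arg <- pmin(1, pmax(-1, (theta / 4) * (abs(zi) / 3)^(-1.5)))
    psi <- acos(arg)
    out[up] <- (2 / 3) * zi * (1 + cos(2 * pi / 3 - (2 / 3) * psi))
  }
  out
}

#' Hard thresholding operator
#'
#' Keeps the input unchanged when \eqn{|z| > \theta} and sets it to zero
#' otherwise (the boundary \eqn{|z| = \theta} resolves to zero, preferring
#' sparsity). With \eqn{\theta = \lambda\mu} this is the operator used in
#' iterative hard thresholding; it coincides with the exact proximal map of
#' the counting penalty for the effective weight
#' \eqn{\lambda_{\mathrm{eff}} = \theta^2/(2\mu)}.
#'
#' @inheritParams soft_threshold
#' @return numeric vector, same length as `z`.
#' @export
hard_threshold <- function(z, theta) {
  stopifnot(theta > 0)
  ifelse(abs(z) <= theta, 0, z)
}

#' CEL0 thresholding operator
#'
#' Exact proximal operator of the CEL0 penalty (see [penalty_value()]) with
#' step size \eqn{\mu}, for a dictionary column of norm `col_norm`. Writing
#' \eqn{a = \mu\,\|\phi\|^2}: for \eqn{a < 1} the map is
#' \eqn{\mathrm{sign}(z)\min\{|z|, (|z| - \sqrt{2\lambda}\,\mu\,\|\phi\|)_+ /
#' (1 - a)\}} (zero below the knee \eqn{\sqrt{2\lambda}\mu\|\phi\|},
#' identity above \eqn{\sqrt{2\lambda}/\|\phi\|}); for \eqn{a \ge 1} it is a
#' hard threshold at \eqn{\sqrt{2\lambda\mu}}, the tie resolving to zero.
#' Both branches are verified against the brute-force [prox_oracle()].
#'
#' @param z numeric vector of inputs.
#' @param lambda regularization weight, > 0.
#' @param mu step size, > 0.
#' @param col_norm dictionary column norm(s) \eqn{\|\phi_i\|}, > 0; recycled
#'   against `z`.
#' @return numeric vector, same length as `z`.
#' @export
cel0_threshold <- function(z, lambda, mu, col_norm = 1) {
  stopifnot(lambda > 0, mu > 0, all(col_norm > 0))
  n <- rep_len(col_norm, length(z))
  a <- mu * n^2
  out <- numeric(length(z))
  lo <- a < 1
  if (any(lo)) {
    knee <- sqrt(2 * lambda) * mu * n[lo]
    shrunk <- pmax(abs(z[lo]) - knee, 0) / (1 - a[lo])
    out[lo] <- sign(z[lo]) * pmin(abs(z[lo]), shrunk)
  }
  if (any(!lo)) {
    zi <- z[!lo]
    out[!lo] <- ifelse(abs(zi) > sqrt(2 * lambda * mu), zi, 0)
  }
  out
}

#' Penalty value of a coefficient vector
#'
#' Evaluates the (unweighted) separable penalty \eqn{C(r) = \sum_i c(r_i)}:
#' \eqn{|r_i|} for `soft`, \eqn{|r_i|^{1/2}} for `half`, the number of
#' nonzeros for `hard`, and for `cel0` the per-coefficient cost
#' \deqn{c(r_i) = \lambda - \frac{\|\phi_i\|^2}{2}
#'   \left(\left(\frac{\sqrt{2\lambda}}{\|\phi_i\|} - |r_i|\right)_+\right)^2,}
#' which vanishes at zero and saturates at \eqn{\lambda} (the counting cost)
#' once \eqn{|r_i| \ge \sqrt{2\lambda}/\|\phi_i\|}.
#'
#' Note the asymmetry in how the weight enters the energy: for `soft`,
#' `half` and `hard` the energy multiplies this value by \eqn{\lambda},
#' while for `cel0` the weight already lives inside the penalty and the
#' outer weight is 1.
#'
#' @param r numeric coefficient vector.
#' @param spec a [penalty_spec()].
#' @return a single number, \eqn{\sum_i c(r_i)}.
#' @export
penalty_value <- function(r, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  switch(spec$kind,
    soft = sum(abs(r)),
    half = sum(sqrt(abs(r))),
    hard = sum(r != 0),
    cel0 = {
      n <- if (is.null(spec$column_norms)) rep(1, length(r))
           else rep_len(spec$column_norms, length(r))
      lam <- spec$lambda
      sum(lam - (n^2 / 2) * pmax(sqrt(2 * lam) / n - abs(r), 0)^2)
    })
}

# scalar penalty c(y) on a grid, for the oracle; `norm` only used by cel0
penalty_scalar <- function(y, spec, norm = 1) {
  switch(spec$kind,
    soft = abs(y),
    half = sqrt(abs(y)),
    hard = as.numeric(y != 0),
    cel0 = spec$lambda -
      (norm^2 / 2) * pmax(sqrt(2 * spec$lambda) / norm - abs(y), 0)^2)
}

# weight multiplying penalty_scalar/penalty_value inside the prox objective
# and the energy: lambda for soft/half/hard, 1 for cel0 (lambda is inside)
penalty_weight <- function(spec) if (spec$kind == "cel0") 1 else spec$lambda

#' Brute-force scalar proximal operator (test oracle)
#'
#' Minimizes \eqn{w\,c(y) + (y - z)^2 / (2\mu)} over a dense symmetric grid,
#' followed by local refinement, where \eqn{w} is \eqn{\lambda} for the
#' soft, half and hard penalties and 1 for CEL0 (whose weight is internal).
#' Independent of the closed-form operators; used to validate them.
#'
#' @param z scalar input.
#' @param spec a [penalty_spec()]. For `cel0`, the first element of
#'   `column_norms` (default 1) is used.
#' @param grid_halfwidth half-width of the search grid; must exceed `|z|`.
#' @param grid_points number of grid points, at least 1e4.
#' @return the scalar minimizer.
#' @export
prox_oracle <- function(z, spec, grid_halfwidth = max(4, 2 * abs(z)),
                        grid_points = 1e5) {
  stopifnot(inherits(spec, "penalty_spec"), length(z) == 1L,
            grid_points >= 1e4)
  if (grid_halfwidth < abs(z))
    stop("grid too narrow to bracket |z|; increase `grid_halfwidth`")
  norm <- if (is.null(spec$column_norms)) 1 else spec$column_norms[1]
  w <- penalty_weight(spec)
  obj <- function(y) w * penalty_scalar(y, spec, norm) +
    (y - z)^2 / (2 * spec$mu)
  y <- seq(-grid_halfwidth, grid_halfwidth, length.out = grid_points)
  i <- which.min(obj(y))
  best <- y[i]
  # local refinement inside the bracketing cell (objective may be
  # discontinuous at 0 for hard; candidates 0 and z are checked explicitly)
  lo <- y[max(1L, i - 1L)]; hi <- y[min(grid_points, i + 1L)]
  if (hi > lo) {
    ref <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-12)
    if (ref$objective < obj(best)) best <- ref$minimum
  }
  for (cand in c(0, z)) if (obj(cand) < obj(best)) best <- cand
  best
}

# dispatch the component-wise thresholding for a penalty spec
apply_threshold <- function(z, spec) {
  switch(spec$kind,
    soft = soft_threshold(z, spec$theta),
    half = half_threshold(z, spec$theta),
    hard = hard_threshold(z, spec$theta),
    cel0 = cel0_threshold(z, spec$lambda, spec$mu,
                          if (is.null(spec$column_norms)) 1
                          else spec$column_norms))
}
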