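# Receptive-field characterization of learned units: grating-bank
# orientation tuning, circular variance, preferred-orientation statistics,
# and Gabor-shape fitting with a goodness-of-fit filter.
#
# Conventions: patches are flattened row-major; within a patch, x runs
# along columns (rightward) and y upward, both centered on the patch.
# Orientation is the angle of the grating's normal (carrier direction),
# measured counterclockwise from horizontal, reduced to [0, pi).

# centered pixel coordinate grids for a P x P patch, row-major flattening
patch_grid <- function(P) {
  c0 <- (P + 1) / 2
  rows <- rep(seq_len(P), each = P)
  cols <- rep(seq_len(P), times = P)
  list(x = cols - c0, y = c0 - rows)
}

#' Bank of sinusoidal gratings
#'
#' Gratings over a grid of spatial frequencies, orientations and phases,
#' each flattened row-major and normalized to unit Euclidean norm.
#' Defaults: 36 equidistant orientations over \[0, pi), 8 equidistant
#' phases over \[0, 2*pi), and 16 log-spaced spatial frequencies from 0.5
#' to P/4 cycles/patch.
#'
#' @param patch_size patch side P in pixels.
#' @param n_orientations number of orientation steps K (default 36).
#' @param n_phases number of phase steps (default 8).
#' @param spatial_frequencies cycles/patch vector; `NULL` for the default
#'   log-spaced grid.
#' @return an object of class `grating_bank`: list with `gratings`
#'   (P^2 x G matrix), `meta` (data.frame sf/theta/phase), `patch_size`,
#'   `orientations`.
#' @export
grating_bank <- function(patch_size, n_orientations = 36, n_phases = 8,
                         spatial_frequencies = NULL) {
  stopifnot(patch_size >= 4, n_orientations >= 2, n_phases >= 2)
  if (is.null(spatial_frequencies))
    spatial_frequencies <- exp(seq(log(0.5), log(patch_size / 4),
                                   length.out = 16))
  thetas <- seq(0, pi, length.out = n_orientations + 1)[seq_len(n_orientations)]
  phases <- seq(0, 2 * pi, length.out = n_phases + 1)[seq_len(n_phases)]
  g <- patch_grid(patch_size)
  meta <- expand.grid(phase = phases, theta = thetas,
                      sf = spatial_frequencies)[, c("sf", "theta", "phase")]
  gratings <- vapply(seq_len(nrow(meta)), function(i) {
    u <- g$x * cos(meta$theta[i]) + g$y * sin(meta$theta[i])
    gr <- cos(2 * pi * meta$sf[i] * u / patch_size + meta$phase[i])
    gr / sqrt(sum(gr^2))
  }, numeric(patch_size^2))
  structure(list(gratings = gratings, meta = meta,
                 patch_size = as.integer(patch_size),
                 orientations = thetas),
            class = "grating_bank")
}

#' Orientation tuning curve of a unit
#'
#' Stage 1: the inner product of the unit with every grating in the bank;
#' the grating with the highest inner product fixes the optimal spatial
#' frequency. Stage 2: restricted to that frequency, the response at each
#' orientation is the maximum inner product over phases. With phases
#' spanning \[0, 2*pi) the responses are nonnegative (a phase flip negates
#' the product).
#'
#' @param unit length-P^2 numeric vector (a dictionary column).
#' @param bank a [grating_bank()].
#' @return an object of class `tuning_curve`: list with `alpha` (length-K
#'   responses), `theta` (orientations), `optimal_sf` (cycles/patch).
#' @export
tuning_curve <- function(unit, bank) {
  stopifnot(inherits(bank, "grating_bank"))
  if (length(unit) != nrow(bank$gratings))
    stop("unit length does not match the bank patch size")
  if (ncol(bank$gratings) == 0) stop("empty grating bank")
  ip <- as.vector(crossprod(bank$gratings, unit))
  best <- which.max(ip)
  sf_opt <- bank$meta$sf[best]
  sel <- bank$meta$sf == sf_opt
  alpha <- tapply(ip[sel], factor(bank$meta$theta[sel],
                                  levels = bank$orientations), max)
  structure(list(alpha = as.numeric(alpha), theta = bank$orientations,
                 optimal_sf = sf_opt),
            class = "tuning_curve")
}

#' Circular variance of an orientation tuning curve
#'
#' The doubled-angle resultant \eqn{R = \sum_k \alpha_k e^{i 2\theta_k} /
#' \sum_k \alpha_k} and the circular variance \eqn{V = 1 - |R|}: 0 for a
#' unit responding to a single orientation, 1 for a flat tuning curve.
#' The preferred orientation is \eqn{\arg(R)/2} mapped to \[0, pi).
#'
#' @param curve a [tuning_curve()], or any list with numeric `alpha` and
#'   `theta` of equal length.
#' @return an object of class `orientation_stats`: list with
#'   `circular_variance`, `resultant` (complex), `preferred_orientation`.
#' @export
circular_variance <- function(curve) {
  alpha <- curve$alpha; theta <- curve$theta
  stopifnot(length(alpha) == length(theta), all(is.finite(alpha)))
  tot <- sum(alpha)
  if (tot <= 0) stop("all-zero tuning curve: circular variance undefined")
  R <- sum(alpha * exp(2i * theta)) / tot
  pref <- (Arg(R) / 2) %% pi
  structure(list(circular_variance = 1 - Mod(R), resultant = R,
                 preferred_orientation = pref),
            class = "orientation_stats")
}

#' Population histograms of orientation statistics
#'
#' Summarizes a population of units: (a) the circular-variance histogram,
#' normalized to sum to 1; (b) the proportion of units preferring each
#' orientation bin (the polar-profile data); (c) the mean circular
#' variance per preferred-orientation bin.
#'
#' @param stats non-empty list of [circular_variance()] results.
#' @param bins number of bins (for both the \[0, 1\] circular-variance
#'   axis and the \[0, pi) orientation axis).
#' @return a list of three data.frames: `cv_hist` (mid, proportion),
#'   `preferred` (mid, proportion), `cv_by_orientation` (mid, mean_cv, n).
#' @export
orientation_histograms <- function(stats, bins = 18) {
  stopifnot(length(stats) > 0, bins >= 2)
  cv <- vapply(stats, `[[`, numeric(1), "circular_variance")
  po <- vapply(stats, `[[`, numeric(1), "preferred_orientation")
  cv_breaks <- seq(0, 1, length.out = bins + 1)
  cv_bin <- cut(pmin(pmax(cv, 0), 1), cv_breaks, include.lowest = TRUE)
  or_breaks <- seq(0, pi, length.out = bins + 1)
  or_bin <- cut(po %% pi, or_breaks, include.lowest = TRUE)
  mids <- function(b) (b[-1] + b[-length(b)]) / 2
  list(
    cv_hist = data.frame(mid = mids(cv_breaks),
                         proportion = as.vector(table(cv_bin)) / length(cv)),
    preferred = data.frame(mid = mids(or_breaks),
                           proportion = as.vector(table(or_bin)) / length(po)),
    cv_by_orientation = data.frame(
      mid = mids(or_breaks),
      mean_cv = as.vector(tapply(cv, or_bin, mean)),
      n = as.vector(table(or_bin))))
}

#' Evaluate a Gabor function on a patch grid
#'
#' Builds the row-major flattened P x P Gabor surface used by
#' [fit_gabor()]: a sinusoidal carrier of the given period and phase along
#' the orientation direction, under an elliptical Gaussian envelope with
#' sd `sigma_par` along the stripe axis and `sigma_orth` across it.
#' Useful for constructing ground-truth units in recovery experiments.
#'
#' @param P patch side in pixels.
#' @param x0,y0 envelope center in centered pixel coordinates (x rightward
#'   along columns, y upward).
#' @param orientation carrier direction in radians, counterclockwise from
#'   horizontal.
#' @param period carrier period in pixels/cycle.
#' @param phase carrier phase in radians.
#' @param sigma_par,sigma_orth envelope sds (pixels) along / across the
#'   grating axis.
#' @param amplitude peak amplitude.
#' @return a length-P^2 numeric vector (row-major).
#' @export
gabor_surface <- function(P, x0, y0, orientation, period, phase,
                          sigma_par, sigma_orth, amplitude) {
  g <- patch_grid(P)
  dx <- g$x - x0; dy <- g$y - y0
  u <- dx * cos(orientation) + dy * sin(orientation)
  v <- -dx * sin(orientation) + dy * cos(orientation)
  amplitude * exp(-u^2 / (2 * sigma_orth^2) - v^2 / (2 * sigma_par^2)) *
    cos(2 * pi * u / period + phase)
}

# reduce fitted parameters to the canonical ranges: amplitude > 0,
# orientation in [0, pi), phase in [0, 2*pi), sigmas > 0
canonicalize_gabor <- function(p) {
  if (p$amplitude < 0) { p$amplitude <- -p$amplitude; p$phase <- p$phase + pi }
  p$orientation <- p$orientation %% (2 * pi)
  if (p$orientation >= pi) {        # theta -> theta - pi flips the carrier
    p$orientation <- p$orientation - pi
    p$phase <- -p$phase
  }
  p$phase <- p$phase %% (2 * pi)
  p
}

#' Fit a Gabor function to a unit
#'
#' Least-squares (Gaussian-noise maximum-likelihood) fit of the
#' 8-parameter Gabor
#' \deqn{g(x, y) = A \exp\!\left(-\frac{u^2}{2\sigma_\perp^2}
#'   - \frac{v^2}{2\sigma_\parallel^2}\right)
#'   \cos\!\left(\frac{2\pi u}{\mathrm{period}} + \mathrm{phase}\right),}
#' with (u, v) the patch coordinates rotated into the carrier frame:
#' \eqn{\sigma_\perp} is the envelope width across the grating axis and
#' \eqn{\sigma_\parallel} along it. Levenberg-Marquardt optimization with
#' multiple starts over an orientation grid (plus a data-driven start from
#' the unit's own tuning), keeping the best fit by residual sum of
#' squares. Parameters are canonicalized (amplitude > 0, orientation in
#' \[0, pi), phase in \[0, 2*pi)).
#'
#' @param unit length-P^2 numeric vector, row-major.
#' @param restarts number of orientation starts (default 8).
#' @param seed integer seed for start jitter.
#' @return an object of class `gabor_fit`: list with `center` (x0, y0),
#'   `orientation`, `period`, `phase`, `sigma_par`, `sigma_orth`,
#'   `amplitude`, `r2`, and `fitted` (the fitted surface, same layout as
#'   `unit`).
#' @export
fit_gabor <- function(unit, restarts = 8, seed = 1) {
  P <- round(sqrt(length(unit)))
  if (P * P != length(unit)) stop("unit length is not a perfect square")
  unit <- as.numeric(unit)
  ss_tot <- sum((unit - mean(unit))^2)
  if (ss_tot == 0) stop("constant unit: Gabor fit undefined")
  g <- patch_grid(P)

  # data-driven starts: center from the energy centroid, period from the
  # dominant frequency of the unit's power spectrum
  w <- unit^2 / sum(unit^2)
  x0s <- sum(w * g$x); y0s <- sum(w * g$y)
  img <- matrix(unit, P, P, byrow = TRUE)
  spec <- Mod(stats::fft(img))^2
  f <- fft_radial_freq(P, P)
  fpk <- f[which.max(spec * (f > 0))]
  period0 <- P / max(fpk, 0.5)
  amp0 <- max(abs(unit))

  resid_fun <- function(par) {
    gabor_surface(P, par[1], par[2], par[3], exp(par[4]), par[5],
                  exp(par[6]), exp(par[7]), par[8]) - unit
  }
  best <- NULL; best_sse <- Inf
  starts <- with_seed(seed, {
    th <- seq(0, pi, length.out = restarts + 1)[seq_len(restarts)] +
      stats::runif(restarts, 0, pi / (4 * restarts))
    lapply(th, function(t0) {
      list(theta = t0, jitter = stats::runif(2, -0.5, 0.5))
    })
  })
  for (s in starts) {
    for (ph0 in c(0, pi / 2)) {
      par0 <- c(x0s + s$jitter[1], y0s + s$jitter[2], s$theta,
                log(period0), ph0, log(P / 6), log(P / 6), amp0)
      fit <- tryCatch(
        minpack.lm::nls.lm(par0, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ptol = 1e-12, ftol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit) || any(!is.finite(fit$par))) next
      sse <- sum(fit$fvec^2)
      if (sse < best_sse) { best_sse <- sse; best <- fit$par }
    }
  }
  if (is.null(best)) stop("all Gabor fit starts failed")
  p <- canonicalize_gabor(list(
    center = c(x0 = best[1], y0 = best[2]), orientation = best[3],
    period = exp(best[4]), phase = best[5], sigma_par = exp(best[6]),
    sigma_orth = exp(best[7]), amplitude = best[8]))
  p$r2 <- 1 - best_sse / ss_tot
  p$fitted <- gabor_surface(P, p$center[1], p$center[2], p$orientation,
                            p$period, p$phase, p$sigma_par, p$sigma_orth,
                            p$amplitude)
  class(p) <- "gabor_fit"
  p
}

#' @export
print.gabor_fit <- function(x, ...) {
  cat(sprintf(paste0("<gabor_fit> r2=%.3f  theta=%.2f  period=%.2f  ",
                     "sigma_par=%.2f sigma_orth=%.2f\n"),
              x$r2, x$orientation, x$period, x$sigma_par, x$sigma_orth))
  invisible(x)
}

#' Normalized shape table of Gabor fits
#'
#' Filters a list of fits by goodness of fit and tabulates the envelope
#' shapes: both envelope widths normalized by the Gabor's period, and the
#' aspect ratio \eqn{\sigma_\parallel / \sigma_\perp} (1 for an isotropic
#' envelope).
#'
#' @param fits list of [fit_gabor()] results.
#' @param r2_min goodness-of-fit threshold; fits below it are excluded
#'   (default 0.6).
#' @return a data.frame with one row per retained fit: `unit`,
#'   `sigma_par_norm`, `sigma_orth_norm`, `aspect_ratio`, `r2`.
#' @export
shape_table <- function(fits, r2_min = 0.6) {
  keep <- vapply(fits, function(f) f$r2 >= r2_min, logical(1))
  idx <- which(keep)
  data.frame(unit = idx,
             sigma_par_norm = vapply(fits[idx], function(f)
               f$sigma_par / f$period, numeric(1)),
             sigma_orth_norm = vapply(fits[idx], function(f)
               f$sigma_orth / f$period, numeric(1)),
             aspect_ratio = vapply(fits[idx], function(f)
               f$sigma_par / f$sigma_orth, numeric(1)),
             r2 = vapply(fits[idx], `[[`, numeric(1), "r2"))
}

#' Per-unit receptive-field analysis table
#'
#' Runs the full characterization over the columns of a dictionary (or a
#' `sparse_coding` fit): optimal spatial frequency, circular variance,
#' preferred orientation, and Gabor-fit parameters with goodness of fit.
#'
#' @param object a `sparse_coding` fit or an M x N dictionary matrix.
#' @param bank a [grating_bank()]; `NULL` builds the default bank for the
#'   patch size.
#' @param fit_gabors if `TRUE` (default) also fit Gabors per unit.
#' @param restarts,seed passed to [fit_gabor()].
#' @return a data.frame with one row per unit.
#' @export
rf_analysis <- function(object, bank = NULL, fit_gabors = TRUE,
                        restarts = 8, seed = 1) {
  phi <- if (inherits(object, "sparse_coding")) object$phi else object
  stopifnot(is.matrix(phi))
  P <- round(sqrt(nrow(phi)))
  if (is.null(bank)) bank <- grating_bank(P)
  rows <- lapply(seq_len(ncol(phi)), function(j) {
    tc <- tuning_curve(phi[, j], bank)
    os <- circular_variance(tc)
    out <- data.frame(unit = j, optimal_sf = tc$optimal_sf,
                      circular_variance = os$circular_variance,
                      preferred_orientation = os$preferred_orientation)
    if (fit_gabors) {
      gf <- tryCatch(fit_gabor(phi[, j], restarts, seed),
                     error = function(e) NULL)
      out$gabor_r2 <- if (is.null(gf)) NA_real_ else gf$r2
      out$gabor_period <- if (is.null(gf)) NA_real_ else gf$period
      out$sigma_par <- if (is.null(gf)) NA_real_ else gf$sigma_par
      out$sigma_orth <- if (is.null(gf)) NA_real_ else gf$sigma_orth
    }
    out
  })
  do.call(rbind, rows)
}
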