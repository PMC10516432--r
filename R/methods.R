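# S3 methods for fitted sparse_coding models.

#' @export
print.sparse_coding <- function(x, ...) {
  cat("Sparse coding dictionary model\n")
  cat(sprintf("  penalty: %s (lambda=%g, mu=%g)\n", x$penalty$kind,
              x$penalty$lambda, x$penalty$mu))
  cat(sprintf("  dictionary: %d pixels x %d units (%.1fx overcomplete)\n",
              x$M, x$N, x$N / x$M))
  if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  after %d batches: mse=%.4f, mean active=%.1f\n",
                nrow(x$trace), last$mse, last$mean_active))
  } else cat("  untrained (0 batches)\n")
  invisible(x)
}

#' Summarize a sparse-coding fit
#'
#' Reports the final-segment reconstruction error and sparsity: mean and
#' sd of the batch MSE and of the active-unit counts over the last
#' `tail_batches` batches of the training trace.
#'
#' @param object a `sparse_coding` fit.
#' @param tail_batches number of trailing batches to average over
#'   (default 500, clipped to the trace length).
#' @param ... unused.
#' @return an object of class `summary.sparse_coding`.
#' @export
summary.sparse_coding <- function(object, tail_batches = 500, ...) {
  tr <- object$trace
  k <- min(tail_batches, nrow(tr))
  tail_tr <- tr[seq_len(nrow(tr)) > nrow(tr) - k, , drop = FALSE]
  out <- list(penalty = object$penalty, M = object$M, N = object$N,
              n_batches = nrow(tr), tail_batches = k,
              mse_mean = mean(tail_tr$mse), mse_sd = stats::sd(tail_tr$mse),
              active_mean = mean(tail_tr$mean_active),
              active_sd = stats::sd(tail_tr$mean_active),
              baseline_mse = if (!is.null(object$last_batch))
                mean(object$last_batch$patches^2) else NA_real_)
  class(out) <- "summary.sparse_coding"
  out
}

#' @export
print.summary.sparse_coding <- function(x, ...) {
  cat(sprintf("Sparse coding fit (%s penalty), %d x %d dictionary\n",
              x$penalty$kind, x$M, x$N))
  cat(sprintf("  last %d of %d batches:\n", x$tail_batches, x$n_batches))
  cat(sprintf("    MSE          %.4f (sd %.4f)  [zero-code baseline %.4f]\n",
              x$mse_mean, x$mse_sd, x$baseline_mse))
  cat(sprintf("    active units %.2f (sd %.2f) of %d (proportion %.4f)\n",
              x$active_mean, x$active_sd, x$N, x$active_mean / x$N))
  invisible(x)
}

#' @export
coef.sparse_coding <- function(object, ...) object$phi

#' Predict sparse codes or reconstructions for new patches
#'
#' Codes each row of `newdata` against the fitted dictionary with the
#' fitted penalty (proximal-gradient iterations, as during training) and
#' returns either the codes or the reconstructed patches.
#'
#' @param object a `sparse_coding` fit.
#' @param newdata patches-by-pixels matrix (or a `patch_batch`).
#' @param type `"codes"` (default) or `"reconstruction"`.
#' @param max_iters coding iteration budget (defaults to the training
#'   setting).
#' @param ... unused.
#' @return a matrix: B x N codes, or B x M reconstructions.
#' @export
predict.sparse_coding <- function(object, newdata,
                                  type = c("codes", "reconstruction"),
                                  max_iters = object$max_iters, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "patch_batch")) newdata <- newdata$patches
  stopifnot(is.matrix(newdata), ncol(newdata) == object$M)
  coded <- sparse_code_batch(newdata, object$phi, object$penalty,
                             max_iters = max_iters)
  if (type == "codes") coded$codes
  else coded$codes %*% t(object$phi)
}

#' @export
fitted.sparse_coding <- function(object, ...) {
  if (is.null(object$last_batch)) return(NULL)
  object$last_batch$codes %*% t(object$phi)
}

#' @export
residuals.sparse_coding <- function(object, ...) {
  if (is.null(object$last_batch)) return(NULL)
  object$last_batch$patches - fitted(object)
}

#' Plot a sparse-coding fit
#'
#' `type = "dictionary"` draws a mosaic of the learned receptive fields
#' (each unit reshaped to a patch, individually contrast-normalized);
#' `type = "trace"` draws the training curves (batch MSE and mean active
#' units).
#'
#' @param x a `sparse_coding` fit.
#' @param type `"dictionary"` or `"trace"`.
#' @param max_units number of units shown in the mosaic.
#' @param ... passed to [graphics::image()] for the mosaic.
#' @return `x`, invisibly.
#' @export
plot.sparse_coding <- function(x, type = c("dictionary", "trace"),
                               max_units = 100, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    graphics::plot(x$trace$batch, x$trace$mse, type = "l",
                   xlab = "batch", ylab = "MSE", main = "reconstruction")
    graphics::plot(x$trace$batch, x$trace$mean_active, type = "l",
                   xlab = "batch", ylab = "mean active units",
                   main = "sparsity")
    return(invisible(x))
  }
  P <- x$patch_size
  n <- min(max_units, x$N)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  mosaic <- matrix(0, nr * (P + 1) + 1, nc * (P + 1) + 1)
  for (k in seq_len(n)) {
    unit <- matrix(x$phi[, k], P, P, byrow = TRUE)
    m <- max(abs(unit)); if (m > 0) unit <- unit / (2 * m) + 0.5
    i <- (k - 1) %/% nc; j <- (k - 1) %% nc
    mosaic[i * (P + 1) + 1 + seq_len(P), j * (P + 1) + 1 + seq_len(P)] <-
      unit
  }
  graphics::image(t(mosaic)[, nrow(mosaic):1], col = grDevices::gray(
    seq(0, 1, length.out = 256)), axes = FALSE, asp = nr / nc, ...)
  invisible(x)
}

#' Simulate patches from the fitted generative model
#'
#' Draws patches \eqn{I = \Phi r + \nu} from the fitted dictionary with
#' k-sparse Laplace-amplitude codes and Gaussian pixel noise — the same
#' planted-model form used for recovery benchmarks, with the learned
#' \eqn{\Phi} in place of the ground truth.
#'
#' @param object a `sparse_coding` fit.
#' @param nsim number of patches.
#' @param seed integer RNG seed.
#' @param sparsity_k active units per patch.
#' @param amplitude_scale Laplace amplitude scale.
#' @param noise_sigma pixel noise sd.
#' @param ... unused.
#' @return an nsim x M matrix of simulated patches, with the generating
#'   codes in attribute `"codes"`.
#' @export
simulate.sparse_coding <- function(object, nsim = 1, seed = 1,
                                   sparsity_k = 3, amplitude_scale = 1,
                                   noise_sigma = 0, ...) {
  pm <- planted_model(object$phi, sparsity_k, amplitude_scale,
                      noise_sigma, seed = seed)
  s <- sample_planted_patches(pm, nsim)
  structure(s$patches, codes = s$codes)
}
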