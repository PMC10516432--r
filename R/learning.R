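# Learning step: gradient update of the dictionary on batches of patches
# with column renormalization, and the full alternating training loop.

#' Time-based learning-rate decay
#'
#' The schedule \eqn{\eta_t = \eta_0 / (1 + (\eta_0 / d)\, t)}, where the
#' decay rate is the initial value divided by `divisor`. Monotonically
#' decreasing to zero in the batch index t.
#'
#' @param lr0 initial learning rate.
#' @param divisor decay divisor d, > 0 (default 50).
#' @param t batch index, 0-based.
#' @return the learning rate at batch `t`.
#' @export
time_decay_rate <- function(lr0, divisor = 50, t) {
  stopifnot(divisor > 0)
  lr0 / (1 + (lr0 / divisor) * t)
}

#' One dictionary gradient update
#'
#' Moves the dictionary along the batch-averaged residual-code outer
#' product, \eqn{\Phi \leftarrow \Phi + \eta\, \overline{(I - \Phi r)
#' r^\top}}, then rescales every column to unit norm. A column whose norm
#' collapses to (numerical) zero is re-randomized to a fresh unit vector
#' and reported via a message, so the unit count stays meaningful.
#'
#' @param dictionary M x N matrix.
#' @param patches B x M matrix of the batch the codes were computed on.
#' @param codes B x N matrix of codes computed against `dictionary`.
#' @param eta learning rate, > 0.
#' @return the updated M x N dictionary with unit-norm columns.
#' @export
dictionary_update <- function(dictionary, patches, codes, eta) {
  stopifnot(is.matrix(dictionary), nrow(patches) == nrow(codes),
            ncol(patches) == nrow(dictionary),
            ncol(codes) == ncol(dictionary), eta > 0)
  B <- nrow(patches)
  resid <- t(patches) - dictionary %*% t(codes)   # M x B
  phi <- dictionary + eta * (resid %*% codes) / B
  norms <- sqrt(colSums(phi^2))
  dead <- which(norms < 1e-12)
  if (length(dead)) {
    message(length(dead), " degenerate column(s) re-randomized")
    for (j in dead) {
      v <- stats::rnorm(nrow(phi))
      phi[, j] <- v / sqrt(sum(v^2))
    }
    norms <- sqrt(colSums(phi^2))
  }
  sweep(phi, 2, norms, `/`)
}

# resolve per-penalty training defaults (eta / schedule follow the
# published settings: eta = 1e-2 with a constant rate generally, and for
# CEL0 eta = 5e-3 with time-based decay, decay rate eta0/50)
train_defaults <- function(kind) {
  if (kind == "cel0") list(eta = 5e-3, lr_schedule = "time_decay")
  else list(eta = 1e-2, lr_schedule = "constant")
}

# normalize the patch source argument of sparse_coding() into a
# function(count, batch_index) -> count x M matrix
as_patch_sampler <- function(x, patch_size, seed) {
  if (is.function(x)) {
    function(count, b) x(count)
  } else if (is.matrix(x)) {
    M <- ncol(x)
    function(count, b) {
      idx <- sample.int(nrow(x), count, replace = nrow(x) < count)
      x[idx, , drop = FALSE]
    }
  } else if (is.list(x)) {
    function(count, b) {
      extract_patches(x, patch_size, count,
                      seed = (seed + b) %% .Machine$integer.max)$patches
    }
  } else stop("`x` must be a list of images, a patch matrix, ",
              "or a sampler function")
}

#' Fit a sparse-coding dictionary model
#'
#' The central model-fitting routine: alternating minimization of the
#' sparse-coding energy over codes and dictionary. Each batch of patches
#' is coded by proximal-gradient iterations with the chosen thresholding
#' operator (dictionary fixed), then the dictionary takes one gradient
#' step on the batch and its columns are renormalized to unit length.
#'
#' @param x training patch source: a list of (preprocessed) image
#'   matrices, a patches-by-pixels matrix, or a function
#'   `function(count)` returning such a matrix.
#' @param penalty penalty kind, one of `"soft"`, `"half"`, `"hard"`,
#'   `"cel0"`, or a ready [penalty_spec()] (in which case `lambda` / `mu`
#'   are ignored).
#' @param n_units dictionary size N.
#' @param lambda regularization weight (required unless `penalty` is a
#'   `penalty_spec`).
#' @param mu proximal step size; `NULL` (default) uses
#'   \eqn{1/L} recomputed from the current dictionary each batch.
#' @param eta dictionary learning rate; default 1e-2 (5e-3 for CEL0).
#' @param n_batches number of batches (0 returns the initial dictionary).
#' @param batch_size patches per batch (default 250).
#' @param patch_size patch side in pixels when `x` is an image list
#'   (default 16).
#' @param lr_schedule `"constant"` or `"time_decay"`; the default follows
#'   the penalty (`time_decay` for CEL0, constant otherwise).
#' @param decay_divisor divisor of [time_decay_rate()] (default 50).
#' @param max_iters coding iterations per batch (default 200).
#' @param seed integer seed controlling initialization and batch sampling;
#'   the fit is fully deterministic given `seed`.
#' @param rerandomize_every audit window in batches: a unit never active
#'   over a full window is re-randomized to a fresh unit vector (and
#'   reported via a message), so the unit count stays meaningful. `Inf`
#'   disables the audit.
#' @param verbose print per-batch progress every 50 batches.
#' @return an object of class `sparse_coding`: list with `phi` (M x N
#'   dictionary), `penalty` (`penalty_spec`), `trace` (data.frame with one
#'   row per batch: batch, mse, mean_active, sd_active, lambda, eta),
#'   `last_batch` (patches and codes of the final batch, used by
#'   [residuals.sparse_coding()] and [fitted.sparse_coding()]), `M`, `N`,
#'   `patch_size`, `seed`, `call`.
#' @seealso [predict.sparse_coding()], [plot.sparse_coding()],
#'   [simulate.sparse_coding()], [rf_analysis()]
#' @examples
#' imgs <- lapply(generate_pink_noise_images(pink_noise_spec(64, 64), 2),
#'                preprocess_image, whitening_cutoff = 16)
#' fit <- sparse_coding(imgs, "soft", n_units = 32, lambda = 0.05,
#'                      n_batches = 5, batch_size = 20, patch_size = 8,
#'                      max_iters = 30)
#' print(fit)
#' @export
sparse_coding <- function(x, penalty = c("soft", "half", "hard", "cel0"),
                          n_units, lambda = NULL, mu = NULL, eta = NULL,
                          n_batches = 400, batch_size = 250,
                          patch_size = 16, lr_schedule = NULL,
                          decay_divisor = 50, max_iters = 200, seed = 1,
                          rerandomize_every = 50, verbose = FALSE) {
  cl <- match.call()
  if (inherits(penalty, "penalty_spec")) {
    kind <- penalty$kind
    lambda <- penalty$lambda
    if (is.null(mu)) mu <- penalty$mu
  } else {
    kind <- match.arg(penalty)
    if (is.null(lambda)) stop("`lambda` must be supplied")
  }
  defaults <- train_defaults(kind)
  if (is.null(eta)) eta <- defaults$eta
  if (is.null(lr_schedule)) lr_schedule <- defaults$lr_schedule
  lr_schedule <- match.arg(lr_schedule, c("constant", "time_decay"))
  stopifnot(n_units >= 1, batch_size >= 1, n_batches >= 0, eta > 0)

  sampler <- as_patch_sampler(x, patch_size, seed)
  # probe one patch to learn M without consuming training randomness
  M <- ncol(with_seed(seed, sampler(1L, 0L)))
  phi <- random_unit_dictionary(M, n_units, seed = seed)

  trace <- data.frame(batch = integer(0), mse = numeric(0),
                      mean_active = numeric(0), sd_active = numeric(0),
                      lambda = numeric(0), eta = numeric(0))
  last_batch <- NULL
  act_window <- integer(n_units)
  with_seed(seed + 1L, {
    for (b in seq_len(n_batches)) {
      patches <- sampler(batch_size, b)
      mu_b <- if (is.null(mu)) 1 / lipschitz_bound(phi) else mu
      spec <- penalty_spec(kind, lambda, mu_b)
      coded <- sparse_code_batch(patches, phi, spec, max_iters = max_iters)
      eta_b <- if (lr_schedule == "time_decay")
        time_decay_rate(eta, decay_divisor, b - 1L) else eta
      phi <- dictionary_update(phi, patches, coded$codes, eta_b)
      act_window <- act_window + colSums(coded$codes != 0)
      if (is.finite(rerandomize_every) && b %% rerandomize_every == 0L &&
          b < n_batches) {
        dead <- which(act_window == 0L)
        if (length(dead)) {
          message(length(dead), " never-active unit(s) re-randomized ",
                  "at batch ", b)
          for (j in dead) {
            v <- stats::rnorm(M)
            phi[, j] <- v / sqrt(sum(v^2))
          }
        }
        act_window <- integer(n_units)
      }
      sd_act <- if (batch_size > 1) stats::sd(coded$active) else 0
      trace[b, ] <- list(b, mean(coded$mse), mean(coded$active),
                         sd_act, lambda, eta_b)
      if (!all(is.finite(unlist(trace[b, ]))))
        stop("non-finite training trace at batch ", b)
      if (b == n_batches)
        last_batch <- list(patches = patches, codes = coded$codes)
      if (verbose && b %% 50L == 0L)
        cat(sprintf("batch %d/%d  mse=%.4f  active=%.1f\n", b, n_batches,
                    trace$mse[b], trace$mean_active[b]))
    }
  })
  structure(list(phi = phi,
                 penalty = penalty_spec(kind, lambda,
                                        if (is.null(mu))
                                          1 / lipschitz_bound(phi)
                                        else mu),
                 trace = trace, last_batch = last_batch,
                 M = M, N = as.integer(n_units),
                 patch_size = as.integer(round(sqrt(M))),
                 max_iters = max_iters, seed = as.integer(seed),
                 call = cl),
            class = "sparse_coding")
}

#' Match a learned dictionary against a reference
#'
#' Greedy one-to-one matching: repeatedly pairs the reference and learned
#' columns with the largest absolute inner product (both dictionaries have
#' unit-norm columns, so this is the absolute correlation up to centering)
#' and removes them from the pool. Used to score dictionary recovery on
#' planted models.
#'
#' @param learned,reference M x N matrices with unit-norm columns.
#' @return list with `pairs` (data.frame reference/learned/abs_cor) and
#'   `mean_abs_cor`, the mean best-match score over reference columns.
#' @export
dictionary_match <- function(learned, reference) {
  stopifnot(nrow(learned) == nrow(reference))
  C <- abs(crossprod(reference, learned))  # Nref x Nlearn
  nref <- nrow(C)
  pairs <- data.frame(reference = integer(nref), learned = integer(nref),
                      abs_cor = numeric(nref))
  for (k in seq_len(nref)) {
    ij <- arrayInd(which.max(C), dim(C))
    pairs[k, ] <- list(ij[1], ij[2], C[ij[1], ij[2]])
    C[ij[1], ] <- -Inf
    C[, ij[2]] <- -Inf
  }
  list(pairs = pairs[order(pairs$reference), ],
       mean_abs_cor = mean(pairs$abs_cor))
}

#' Write a dictionary to CSV
#'
#' Plain-text serialization of a dictionary matrix (one column per unit),
#' readable back with [read_dictionary_csv()].
#'
#' @param phi M x N matrix or a `sparse_coding` fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary_csv <- function(phi, path) {
  if (inherits(phi, "sparse_coding")) phi <- phi$phi
  utils::write.csv(as.data.frame(phi), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary_csv
#' @export
read_dictionary_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
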