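# Comparative experiment drivers: sparsity-vs-reconstruction trade-off
# across penalties, overcompleteness sweeps at a fixed sparsity window,
# and matched-sparsity method pairs.

# code a patch set with one penalty and summarize error and sparsity
code_summary <- function(patches, dictionary, kind, lambda, mu = NULL,
                         max_iters = 150) {
  if (is.null(mu)) mu <- 1 / lipschitz_bound(dictionary)
  spec <- penalty_spec(kind, lambda, mu)
  coded <- sparse_code_batch(patches, dictionary, spec,
                             max_iters = max_iters)
  data.frame(method = kind, lambda = lambda,
             mse_mean = mean(coded$mse), mse_sd = stats::sd(coded$mse),
             active_mean = mean(coded$active),
             active_sd = stats::sd(coded$active))
}

# stamp an experiment table with its configuration for replay
stamp_config <- function(tab, ...) {
  cfg <- list(...)
  attr(tab, "config") <- cfg
  tab
}

#' Sparsity / reconstruction comparison across penalties
#'
#' For each method and each value of its lambda grid, codes the given
#' patches against a fixed dictionary and records the mean and sd of the
#' per-patch reconstruction MSE and of the active-unit counts. The first
#' row reports the all-zero-code baseline (MSE equal to the mean squared
#' patch, 0.1 for preprocessed images; zero active units).
#'
#' @param patches B x M matrix of (preprocessed) patches.
#' @param dictionary M x N matrix with unit-norm columns.
#' @param methods character vector among soft/half/hard/cel0.
#' @param lambda_grid numeric vector (shared by all methods) or named list
#'   of per-method vectors.
#' @param mu step size; `NULL` uses 1/L of the dictionary.
#' @param max_iters coding iterations per evaluation.
#' @return a data.frame with columns method, lambda, mse_mean, mse_sd,
#'   active_mean, active_sd; the full configuration is attached as
#'   attribute `"config"`.
#' @export
run_sparsity_comparison <- function(patches, dictionary, methods,
                                    lambda_grid, mu = NULL,
                                    max_iters = 150) {
  stopifnot(length(methods) >= 1)
  if (!is.list(lambda_grid))
    lambda_grid <- stats::setNames(rep(list(lambda_grid), length(methods)),
                                   methods)
  base <- data.frame(method = "zero", lambda = NA_real_,
                     mse_mean = mean(rowMeans(patches^2)),
                     mse_sd = stats::sd(rowMeans(patches^2)),
                     active_mean = 0, active_sd = 0)
  rows <- list(base)
  for (m in methods)
    for (lam in lambda_grid[[m]])
      rows[[length(rows) + 1L]] <-
        code_summary(patches, dictionary, m, lam, mu, max_iters)
  stamp_config(do.call(rbind, rows), methods = methods,
               lambda_grid = lambda_grid, mu = mu, max_iters = max_iters,
               n_patches = nrow(patches), n_units = ncol(dictionary))
}

#' Calibrate lambda by bisection
#'
#' Finds the regularization weight at which coding the given patches
#' produces a target mean active-unit count (decreasing in lambda) or a
#' target mean MSE (increasing in lambda), by bisection on log-lambda.
#'
#' @param patches B x M patch matrix.
#' @param dictionary M x N dictionary.
#' @param method penalty kind.
#' @param target target value of the chosen metric.
#' @param metric `"active"` (mean active units) or `"mse"`.
#' @param bracket length-2 positive vector of lambda endpoints that must
#'   straddle the target response.
#' @param tol_rel relative tolerance on the achieved metric (default 2%).
#' @param max_steps bisection budget.
#' @param mu,max_iters coding settings (see [run_sparsity_comparison()]).
#' @return list with `lambda`, `achieved`, `summary` (the final
#'   [run_sparsity_comparison()]-style row), `steps`.
#' @export
calibrate_lambda <- function(patches, dictionary, method, target,
                             metric = c("active", "mse"),
                             bracket = c(1e-4, 10), tol_rel = 0.02,
                             max_steps = 40, mu = NULL, max_iters = 150) {
  metric <- match.arg(metric)
  stopifnot(length(bracket) == 2, all(bracket > 0),
            bracket[1] < bracket[2], target > 0)
  val <- function(lam) {
    s <- code_summary(patches, dictionary, method, lam, mu, max_iters)
    list(v = if (metric == "active") s$active_mean else s$mse_mean, s = s)
  }
  # response direction: active decreases with lambda, mse increases
  sgn <- if (metric == "active") -1 else 1
  lo <- bracket[1]; hi <- bracket[2]
  vlo <- val(lo); vhi <- val(hi)
  if ((vlo$v - target) * (vhi$v - target) > 0)
    stop(sprintf(paste0("bisection bracket [%g, %g] does not straddle the ",
                        "target %s %g (endpoint values %.4g, %.4g)"),
                 lo, hi, metric, target, vlo$v, vhi$v))
  best <- NULL; steps <- 0L
  for (k in seq_len(max_steps)) {
    steps <- k
    mid <- sqrt(lo * hi)
    vm <- val(mid)
    best <- list(lambda = mid, achieved = vm$v, summary = vm$s)
    if (abs(vm$v - target) <= tol_rel * target) break
    if (sgn * (vm$v - target) > 0) hi <- mid else lo <- mid
  }
  best$steps <- steps
  best
}

#' Reconstruction error across dictionary sizes at matched sparsity
#'
#' For each method and dictionary size N, bisects lambda until the trained
#' model's normalized active proportion (mean active units per patch over
#' N, averaged over the trailing segment of the training trace) falls in
#' `sparsity_window`, then reports the trailing-segment MSE. Bisection
#' evaluations may use a shorter training run (`calib_batches`) than the
#' reported one (`n_batches`).
#'
#' @param x training patch source (see [sparse_coding()]).
#' @param sizes integer vector of dictionary sizes, at least 2 values.
#' @param methods character vector of penalty kinds.
#' @param sparsity_window target window for the normalized active
#'   proportion (default the published 0.0105 to 0.0132 band).
#' @param lambda_bracket bisection bracket for lambda.
#' @param n_batches,batch_size,patch_size,max_iters,seed training settings
#'   (see [sparse_coding()]).
#' @param calib_batches batches per bisection evaluation (default
#'   `n_batches`).
#' @param tail_frac fraction of trailing batches summarized (default 0.25).
#' @param max_steps bisection budget per cell.
#' @return a data.frame with one row per (method, N): lambda, mse_mean,
#'   mse_sd, active_mean, active_proportion; configuration in attribute
#'   `"config"`.
#' @export
run_overcompleteness_sweep <- function(x, sizes, methods,
                                       sparsity_window = c(0.0105, 0.0132),
                                       lambda_bracket = c(1e-4, 10),
                                       n_batches = 100, batch_size = 100,
                                       patch_size = 16, max_iters = 150,
                                       seed = 1, calib_batches = n_batches,
                                       tail_frac = 0.25, max_steps = 20) {
  stopifnot(length(sizes) >= 2, length(methods) >= 1,
            length(sparsity_window) == 2,
            sparsity_window[1] < sparsity_window[2])
  target <- mean(sparsity_window)
  tail_stats <- function(fit) {
    tr <- fit$trace
    k <- max(1L, ceiling(tail_frac * nrow(tr)))
    tt <- tr[seq_len(nrow(tr)) > nrow(tr) - k, , drop = FALSE]
    list(mse = mean(tt$mse), mse_sd = stats::sd(tt$mse),
         active = mean(tt$mean_active))
  }
  run <- function(m, N, lam, nb) {
    fit <- sparse_coding(x, m, n_units = N, lambda = lam,
                         n_batches = nb, batch_size = batch_size,
                         patch_size = patch_size, max_iters = max_iters,
                         seed = seed)
    c(tail_stats(fit), list(fit = fit))
  }
  rows <- list()
  for (m in methods) for (N in sizes) {
    lo <- lambda_bracket[1]; hi <- lambda_bracket[2]
    plo <- run(m, N, lo, calib_batches)$active / N
    phi_ <- run(m, N, hi, calib_batches)$active / N
    if ((plo - target) * (phi_ - target) > 0)
      stop(sprintf(paste0("lambda bracket [%g, %g] does not straddle the ",
                          "sparsity window for method %s, N=%d ",
                          "(proportions %.4g, %.4g)"),
                   lo, hi, m, N, plo, phi_))
    lam <- NA; prop <- NA
    for (k in seq_len(max_steps)) {
      lam <- sqrt(lo * hi)
      prop <- run(m, N, lam, calib_batches)$active / N
      if (prop >= sparsity_window[1] && prop <= sparsity_window[2]) break
      if (prop > target) lo <- lam else hi <- lam
    }
    fin <- run(m, N, lam, n_batches)
    rows[[length(rows) + 1L]] <- data.frame(
      method = m, n_units = N, lambda = lam, mse_mean = fin$mse,
      mse_sd = fin$mse_sd, active_mean = fin$active,
      active_proportion = fin$active / N)
  }
  stamp_config(do.call(rbind, rows), sizes = sizes, methods = methods,
               sparsity_window = sparsity_window,
               lambda_bracket = lambda_bracket, n_batches = n_batches,
               batch_size = batch_size, patch_size = patch_size,
               max_iters = max_iters, seed = seed)
}

#' Matched-sparsity comparison of two methods
#'
#' Trains method B at its given lambda, then calibrates method A's lambda
#' (bisection, training each evaluation) until A codes with the same mean
#' number of active units as B within `tol_rel`. Reports both MSEs and,
#' optionally, the Gabor shape tables of both dictionaries.
#'
#' @param x training patch source (see [sparse_coding()]).
#' @param method_a,method_b penalty kinds; A is calibrated to match B.
#' @param lambda_b lambda for method B.
#' @param bracket_a bisection bracket for A's lambda.
#' @param n_units,n_batches,batch_size,patch_size,max_iters,seed training
#'   settings shared by both methods.
#' @param tol_rel relative tolerance on the active-count match (5%).
#' @param max_steps bisection budget.
#' @param tail_frac trailing fraction of the trace summarized.
#' @param shapes if `TRUE`, include `shape_a` / `shape_b` ([shape_table()]
#'   of each dictionary) in the result.
#' @return list with `table` (two-row data.frame: method, lambda,
#'   mse_mean, active_mean, matched within tolerance), `mse_ratio`
#'   (A over B), `fit_a`, `fit_b`, and optionally the shape tables;
#'   configuration attached to `table`.
#' @export
run_matched_instances <- function(x, method_a, method_b, lambda_b,
                                  bracket_a = c(1e-4, 10), n_units = 128,
                                  n_batches = 100, batch_size = 100,
                                  patch_size = 16, max_iters = 150,
                                  seed = 1, tol_rel = 0.05,
                                  max_steps = 20, tail_frac = 0.25,
                                  shapes = FALSE) {
  fit_with <- function(m, lam) {
    sparse_coding(x, m, n_units = n_units, lambda = lam,
                  n_batches = n_batches, batch_size = batch_size,
                  patch_size = patch_size, max_iters = max_iters,
                  seed = seed)
  }
  tail_stats <- function(fit) {
    tr <- fit$trace
    k <- max(1L, ceiling(tail_frac * nrow(tr)))
    tt <- tr[seq_len(nrow(tr)) > nrow(tr) - k, , drop = FALSE]
    list(mse = mean(tt$mse), active = mean(tt$mean_active))
  }
  fit_b <- fit_with(method_b, lambda_b)
  sb <- tail_stats(fit_b)
  target <- sb$active
  if (target <= 0) stop("method B codes with zero active units; ",
                        "lower `lambda_b`")
  lo <- bracket_a[1]; hi <- bracket_a[2]
  alo <- tail_stats(fit_with(method_a, lo))$active
  ahi <- tail_stats(fit_with(method_a, hi))$active
  if ((alo - target) * (ahi - target) > 0)
    stop(sprintf("bracket [%g, %g] does not straddle %.2f active units",
                 lo, hi, target))
  fit_a <- NULL; sa <- NULL; lam_a <- NA
  for (k in seq_len(max_steps)) {
    lam_a <- sqrt(lo * hi)
    fit_a <- fit_with(method_a, lam_a)
    sa <- tail_stats(fit_a)
    if (abs(sa$active - target) <= tol_rel * target) break
    if (sa$active > target) lo <- lam_a else hi <- lam_a
  }
  tab <- data.frame(method = c(method_a, method_b),
                    lambda = c(lam_a, lambda_b),
                    mse_mean = c(sa$mse, sb$mse),
                    active_mean = c(sa$active, sb$active),
                    matched = abs(sa$active - target) <= tol_rel * target)
  tab <- stamp_config(tab, method_a = method_a, method_b = method_b,
                      lambda_b = lambda_b, bracket_a = bracket_a,
                      n_units = n_units, n_batches = n_batches,
                      batch_size = batch_size, patch_size = patch_size,
                      max_iters = max_iters, seed = seed)
  out <- list(table = tab, mse_ratio = sa$mse / sb$mse,
              fit_a = fit_a, fit_b = fit_b)
  if (shapes) {
    fits_of <- function(fit) lapply(seq_len(fit$N), function(j)
      tryCatch(fit_gabor(fit$phi[, j]), error = function(e) NULL))
    drop_null <- function(l) l[!vapply(l, is.null, logical(1))]
    out$shape_a <- shape_table(drop_null(fits_of(fit_a)))
    out$shape_b <- shape_table(drop_null(fits_of(fit_b)))
  }
  out
}

#' Write a training trace or experiment table to CSV
#'
#' @param tab a data.frame (e.g. a `sparse_coding` trace or an experiment
#'   table).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
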