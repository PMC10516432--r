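# Independent oracles and small fixture builders used across the suite.

# cyclic coordinate-descent lasso solver for
# 0.5 * ||I - phi r||^2 + lambda * ||r||_1 (independent of the package's
# proximal-gradient path)
cd_lasso <- function(I, phi, lambda, iters = 5000, tol = 1e-14) {
  N <- ncol(phi)
  r <- numeric(N)
  g2 <- colSums(phi^2)
  resid <- I - as.vector(phi %*% r)
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(N)) {
      rho <- sum(phi[, j] * resid) + g2[j] * r[j]
      new <- sign(rho) * max(abs(rho) - lambda, 0) / g2[j]
      if (new != r[j]) {
        resid <- resid - phi[, j] * (new - r[j])
        delta <- max(delta, abs(new - r[j]))
        r[j] <- new
      }
    }
    if (delta < tol) break
  }
  r
}

lasso_objective <- function(I, phi, r, lambda) {
  0.5 * sum((I - as.vector(phi %*% r))^2) + lambda * sum(abs(r))
}

# slope of log radially-averaged amplitude spectrum vs log frequency,
# averaged over a list of images (direct FFT route, independent of the
# generator's spectral shaping)
radial_amplitude_slope <- function(images, n_bins = 20) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  f <- v1sparse:::fft_radial_freq(h, w)
  amp <- Reduce(`+`, lapply(images, function(im) Mod(stats::fft(im)))) /
    length(images)
  fmax <- min(h, w) / 2
  keep <- f > 0.5 & f <= fmax
  bins <- cut(log(f[keep]), n_bins)
  la <- tapply(log(amp[keep]), bins, mean)
  lf <- tapply(log(f[keep]), bins, mean)
  unname(stats::coef(stats::lm(la ~ lf))[2])
}

# noiseless Gabor patch built directly from the closed form (same
# parameterization the fitter documents; written out here so the fixture
# is constructed independently of the package internals)
make_gabor <- function(P, x0, y0, theta, period, phase, sigma_par,
                       sigma_orth, amplitude) {
  c0 <- (P + 1) / 2
  rows <- rep(seq_len(P), each = P)
  cols <- rep(seq_len(P), times = P)
  x <- cols - c0; y <- c0 - rows
  dx <- x - x0; dy <- y - y0
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  amplitude * exp(-u^2 / (2 * sigma_orth^2) - v^2 / (2 * sigma_par^2)) *
    cos(2 * pi * u / period + phase)
}

# smallest angular distance between two orientations (mod pi)
orientation_dist <- function(a, b) {
  d <- abs(a - b) %% pi
  min(d, pi - d)
}

# shared small preprocessed pink-noise image set (built once per run)
test_images <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      imgs <- generate_pink_noise_images(
        pink_noise_spec(96, 96, 1, seed = 301), 4)
      cache <<- lapply(imgs, preprocess_image, whitening_cutoff = 20)
    }
    cache
  }
})
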