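# Synthetic inputs with the statistical structure the analysis assumes:
# 1/f pink-noise images standing in for natural scenes, and a planted
# k-sparse linear generative model I = Phi r + nu for recovery tests.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pink-noise image specification
#'
#' Describes an ensemble of naturalistic random images whose amplitude
#' spectrum falls off as \eqn{1/f^{\gamma}} with spatial frequency, the
#' characteristic second-order statistic of natural scenes. Exponent 1 is
#' the natural-image convention; exponent 0 gives flat (white) spectra.
#'
#' @param height,width image size in pixels, at least 16.
#' @param spectral_exponent amplitude falloff exponent \eqn{\gamma}
#'   in \[0, 2\].
#' @param seed integer RNG seed; identical spec + seed reproduce identical
#'   images.
#' @return an object of class `pink_noise_spec`.
#' @export
pink_noise_spec <- function(height = 512, width = 512,
                            spectral_exponent = 1, seed = 1) {
  stopifnot(is.numeric(height), is.numeric(width))
  if (height < 16 || width < 16)
    stop("image dimensions must be at least 16 pixels")
  if (spectral_exponent < 0 || spectral_exponent > 2)
    stop("`spectral_exponent` must lie in [0, 2]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 spectral_exponent = spectral_exponent,
                 seed = as.integer(seed)),
            class = "pink_noise_spec")
}

# radial frequency grid in cycles/image for an h x w FFT layout
fft_radial_freq <- function(h, w) {
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Generate pink-noise images
#'
#' Shapes white Gaussian noise in the frequency domain with amplitude
#' \eqn{1/f^{\gamma}} (zero DC component), inverts the transform, and maps
#' each image affinely onto the nonnegative luminance range \[0, 1\].
#'
#' @param spec a [pink_noise_spec()].
#' @param count number of images, at least 1.
#' @return a list of `count` numeric matrices in \[0, 1\].
#' @examples
#' imgs <- generate_pink_noise_images(pink_noise_spec(64, 64, seed = 7), 2)
#' @export
generate_pink_noise_images <- function(spec, count) {
  stopifnot(inherits(spec, "pink_noise_spec"), count >= 1)
  h <- spec$height; w <- spec$width
  f <- fft_radial_freq(h, w)
  gain <- ifelse(f > 0, f^(-spec$spectral_exponent), 0)
  with_seed(spec$seed, {
    lapply(seq_len(count), function(i) {
      white <- matrix(stats::rnorm(h * w), h, w)
      shaped <- Re(stats::fft(stats::fft(white) * gain, inverse = TRUE)) /
        (h * w)
      rng <- range(shaped)
      if (rng[2] > rng[1]) (shaped - rng[1]) / (rng[2] - rng[1])
      else matrix(0.5, h, w)
    })
  })
}

#' Planted sparse generative model
#'
#' Ground-truth instance of the linear generative model
#' \eqn{I = \Phi r + \nu}: a known dictionary with unit-norm columns,
#' exactly `sparsity_k` active coefficients per sample with heavy-tailed
#' (Laplace) amplitudes, and additive white Gaussian pixel noise of
#' standard deviation `noise_sigma`.
#'
#' @param true_dictionary M x N numeric matrix with unit-norm columns
#'   (tolerance 1e-12).
#' @param sparsity_k number of nonzero coefficients per sample, in
#'   \[1, N\].
#' @param amplitude_scale scale of the Laplace amplitude distribution.
#' @param noise_sigma pixel noise standard deviation, >= 0.
#' @param seed integer RNG seed.
#' @return an object of class `planted_model`.
#' @export
planted_model <- function(true_dictionary, sparsity_k, amplitude_scale = 1,
                          noise_sigma = 0, seed = 1) {
  stopifnot(is.matrix(true_dictionary), sparsity_k >= 1,
            amplitude_scale > 0, noise_sigma >= 0)
  N <- ncol(true_dictionary)
  if (sparsity_k > N) stop("`sparsity_k` exceeds the number of columns")
  norms <- sqrt(colSums(true_dictionary^2))
  if (any(abs(norms - 1) > 1e-12))
    stop("`true_dictionary` columns must have unit norm (tol 1e-12)")
  structure(list(true_dictionary = true_dictionary,
                 sparsity_k = as.integer(sparsity_k),
                 amplitude_scale = amplitude_scale,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "planted_model")
}

#' Sample patches from a planted sparse model
#'
#' Draws `count` samples \eqn{I = \Phi r + \nu}: each code r has exactly
#' `sparsity_k` nonzeros at uniformly random positions with Laplace
#' amplitudes (symmetric about zero, scale `amplitude_scale`), and the
#' noise is i.i.d. Gaussian with sd `noise_sigma`. Ground-truth codes are
#' returned alongside the patches.
#'
#' @param model a [planted_model()].
#' @param count number of samples, at least 1.
#' @return a list with `patches` (count x M matrix) and `codes`
#'   (count x N matrix).
#' @export
sample_planted_patches <- function(model, count) {
  stopifnot(inherits(model, "planted_model"), count >= 1)
  phi <- model$true_dictionary
  M <- nrow(phi); N <- ncol(phi); k <- model$sparsity_k
  with_seed(model$seed, {
    codes <- matrix(0, count, N)
    for (b in seq_len(count)) {
      idx <- sample.int(N, k)
      # Laplace(0, scale) = exponential magnitude with random sign
      amp <- model$amplitude_scale * stats::rexp(k) *
        sample(c(-1, 1), k, replace = TRUE)
      codes[b, idx] <- amp
    }
    patches <- codes %*% t(phi)
    if (model$noise_sigma > 0)
      patches <- patches +
        matrix(stats::rnorm(count * M, sd = model$noise_sigma), count, M)
    list(patches = patches, codes = codes)
  })
}

#' Random dictionary with unit-norm Gaussian columns
#'
#' @param M patch dimension (rows).
#' @param N number of units (columns).
#' @param seed integer RNG seed.
#' @return an M x N matrix whose columns have unit Euclidean norm.
#' @export
random_unit_dictionary <- function(M, N, seed = 1) {
  with_seed(seed, {
    phi <- matrix(stats::rnorm(M * N), M, N)
    sweep(phi, 2, sqrt(colSums(phi^2)), `/`)
  })
}
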