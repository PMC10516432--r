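# Image preprocessing: per-image rescale, standardization, frequency-domain
# whitening emulating retinal ganglion-cell filtering, rescale to a target
# variance, and random patch extraction.

#' Radial whitening filter
#'
#' The rotation-invariant frequency-domain filter
#' \eqn{W(f) = f \exp(-(f/f_0)^4)} with \eqn{f} in cycles/image: a ramp
#' flattening the \eqn{1/f} natural-image spectrum, rolled off near the
#' cutoff \eqn{f_0} to suppress the noisiest high frequencies. The DC gain
#' is zero, so filtered images have zero mean.
#'
#' @param height,width image size in pixels.
#' @param cutoff roll-off frequency \eqn{f_0} in cycles/image.
#' @return a height x width matrix of gains in FFT layout.
#' @export
whitening_filter <- function(height, width, cutoff = 200) {
  stopifnot(cutoff > 0)
  f <- fft_radial_freq(height, width)
  f * exp(-(f / cutoff)^4)
}

#' Preprocess a raw image for sparse coding
#'
#' Applies, in order: (1) min-max rescale to \[0, 1\]; (2) standardization
#' (subtract the image mean, divide by the image standard deviation);
#' (3) frequency-domain whitening with [whitening_filter()], which zeroes
#' the DC component; (4) multiplicative rescale so the mean squared pixel
#' value equals `target_variance` exactly (the mean is zero after
#' whitening, so this is the pixel variance). The default target 0.1 fixes
#' the baseline reconstruction error of the all-zero code.
#'
#' @param img numeric matrix of luminance values, at least 16 x 16, finite.
#' @param whitening_cutoff roll-off frequency in cycles/image.
#' @param target_variance final pixel variance, > 0.
#' @return a numeric matrix of class `preprocessed_image` with attribute
#'   `target_variance`.
#' @examples
#' img <- generate_pink_noise_images(pink_noise_spec(64, 64, seed = 1), 1)[[1]]
#' out <- preprocess_image(img, whitening_cutoff = 16)
#' mse_to_zero(out)  # 0.1 by construction
#' @export
preprocess_image <- function(img, whitening_cutoff = 200,
                             target_variance = 0.1) {
  stopifnot(is.matrix(img), all(is.finite(img)), target_variance > 0)
  if (nrow(img) < 16 || ncol(img) < 16)
    stop("image must be at least 16x16 pixels")
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  s <- stats::sd(img)
  if (s == 0)
    stop("constant image: zero standard deviation, cannot standardize")
  img <- (img - mean(img)) / s
  gain <- whitening_filter(nrow(img), ncol(img), whitening_cutoff)
  white <- Re(stats::fft(stats::fft(img) * gain, inverse = TRUE)) /
    length(img)
  ms <- mean(white^2)
  if (ms == 0) stop("whitened image is identically zero")
  out <- white * sqrt(target_variance / ms)
  structure(out, class = c("preprocessed_image", "matrix", "array"),
            target_variance = target_variance)
}

#' Baseline reconstruction error of the all-zero code
#'
#' Mean of squared pixel values: the MSE between the image and the zero
#' image, i.e. the reconstruction error when no unit is active. Equals the
#' target variance (0.1 by default) for preprocessed images.
#'
#' @param img numeric matrix.
#' @return a single number.
#' @export
mse_to_zero <- function(img) mean(unclass(img)^2)

#' Extract random square patches from images
#'
#' Draws `count` patches of size `patch_size` x `patch_size`: for each
#' patch, an image is chosen uniformly at random, then a top-left corner
#' uniformly over all in-bounds positions. Patches are flattened row-major
#' (within a patch, pixels are ordered row by row). Deterministic given
#' `seed`.
#'
#' @param images non-empty list of numeric matrices (typically
#'   [preprocess_image()] outputs).
#' @param patch_size patch side in pixels, at most the smallest image
#'   dimension.
#' @param count number of patches (0 gives an empty batch).
#' @param seed integer RNG seed.
#' @return an object of class `patch_batch`: list with `patches`
#'   (count x patch_size^2 matrix), `coords` (data.frame image/row/col,
#'   0-based top-left corners), `patch_size`, `seed`.
#' @export
extract_patches <- function(images, patch_size, count, seed = 1) {
  if (!is.list(images) || length(images) == 0)
    stop("`images` must be a non-empty list of matrices")
  stopifnot(count >= 0, patch_size >= 1)
  dims <- vapply(images, dim, integer(2))
  if (patch_size > min(dims))
    stop("`patch_size` exceeds the smallest image dimension")
  M <- patch_size^2
  patches <- matrix(0, count, M)
  coords <- data.frame(image = integer(count), row = integer(count),
                       col = integer(count))
  if (count > 0) {
    with_seed(seed, {
      for (b in seq_len(count)) {
        i <- sample.int(length(images), 1)
        r0 <- sample.int(dims[1, i] - patch_size + 1L, 1) - 1L
        c0 <- sample.int(dims[2, i] - patch_size + 1L, 1) - 1L
        win <- unclass(images[[i]])[r0 + seq_len(patch_size),
                                    c0 + seq_len(patch_size), drop = FALSE]
        patches[b, ] <- as.vector(t(win))  # row-major flattening
        coords$image[b] <- i; coords$row[b] <- r0; coords$col[b] <- c0
      }
    })
  }
  structure(list(patches = patches, coords = coords,
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "patch_batch")
}

#' Read a van Hateren raw image
#'
#' Reads the headerless raw dialect of the van Hateren natural image
#' database: 16-bit unsigned big-endian integers, row-major, 1536 columns
#' by 1024 rows (`.iml` linear / `.imc` calibrated files share the layout).
#'
#' @param path file path.
#' @param height,width image dimensions in pixels.
#' @return a height x width numeric matrix of nonnegative luminances.
#' @export
read_iml <- function(path, height = 1024, width = 1536) {
  n <- height * width
  raw <- readBin(path, what = "integer", n = n, size = 2,
                 signed = FALSE, endian = "big")
  if (length(raw) < n) stop("file shorter than expected ", n, " pixels")
  matrix(as.numeric(raw), nrow = height, ncol = width, byrow = TRUE)
}

#' Write an image matrix as a grayscale PNG
#'
#' Rescales the image affinely to \[0, 1\] and writes an 8-bit grayscale
#' PNG (a constant image maps to mid-gray).
#'
#' @param img numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  img <- unclass(img)
  rng <- range(img)
  scaled <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
            else matrix(0.5, nrow(img), ncol(img))
  png::writePNG(scaled, target = path)
  invisible(path)
}
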