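test_that("a bank grating is its own best match", {
  bank <- grating_bank(12)
  idx <- which(abs(bank$meta$sf - 3) < 0.5 &
                 bank$meta$theta == bank$orientations[10] &
                 bank$meta$phase == 0)[1]
  tc <- tuning_curve(bank$gratings[, idx], bank)
  expect_equal(tc$optimal_sf, bank$meta$sf[idx])
  expect_equal(tc$theta[which.max(tc$alpha)], bank$orientations[10])
})

test_that("an isotropic blob is untuned and an oriented pair is bimodal", {
  bank <- grating_bank(12)
  g <- v1sparse:::patch_grid(12)
  blob <- exp(-(g$x^2 + g$y^2) / (2 * 2.5^2))
  tc <- tuning_curve(blob, bank)
  expect_lt((max(tc$alpha) - min(tc$alpha)) / max(tc$alpha), 0.15)
  expect_gt(circular_variance(tc)$circular_variance, 0.95)
  # two orthogonal gratings of equal power: two equal peaks pi/2 apart
  i1 <- which(bank$meta$theta == bank$orientations[1] &
                bank$meta$phase == 0 & abs(bank$meta$sf - 3) < 0.5)[1]
  i2 <- which(bank$meta$theta == bank$orientations[19] &
                bank$meta$phase == 0 & abs(bank$meta$sf - 3) < 0.5)[1]
  tc2 <- tuning_curve(bank$gratings[, i1] + bank$gratings[, i2], bank)
  pk <- order(tc2$alpha, decreasing = TRUE)[1:2]
  expect_equal(orientation_dist(tc2$theta[pk[1]], tc2$theta[pk[2]]),
               pi / 2, tolerance = 1e-9)
  expect_equal(tc2$alpha[pk[1]], tc2$alpha[pk[2]], tolerance = 1e-6)
})

test_that("circular variance hits its limiting values", {
  K <- 36
  theta <- seq(0, pi, length.out = K + 1)[1:K]
  one_hot <- replace(numeric(K), 11, 2.3)
  expect_equal(circular_variance(list(alpha = one_hot, theta = theta))$
                 circular_variance, 0, tolerance = 1e-12)
  flat <- circular_variance(list(alpha = rep(0.7, K), theta = theta))
  expect_equal(flat$circular_variance, 1, tolerance = 1e-12)
  pair <- replace(numeric(K), c(3, 3 + K / 2), 1)  # theta and theta + pi/2
  expect_equal(circular_variance(list(alpha = pair, theta = theta))$
                 circular_variance, 1, tolerance = 1e-12)
  expect_error(circular_variance(list(alpha = numeric(K), theta = theta)),
               "all-zero")
})

test_that("circular variance is scale-invariant and bounded", {
  set.seed(10)
  theta <- seq(0, pi, length.out = 37)[1:36]
  for (i in 1:20) {
    alpha <- runif(36)
    v1 <- circular_variance(list(alpha = alpha, theta = theta))
    v2 <- circular_variance(list(alpha = 7.3 * alpha, theta = theta))
    expect_equal(v1$circular_variance, v2$circular_variance,
                 tolerance = 1e-12)
    expect_gte(v1$circular_variance, 0)
    expect_lte(v1$circular_variance, 1)
  }
})

test_that("preferred orientation is equivariant under rotation", {
  # isotropic-envelope grating units, so the aperture itself does not
  # break rotation symmetry
  P <- 16
  bank <- grating_bank(P)
  g <- v1sparse:::patch_grid(P)
  env <- exp(-(g$x^2 + g$y^2) / (2 * (P / 5)^2))
  unit_at <- function(th)
    env * cos(2 * pi * 3 * (g$x * cos(th) + g$y * sin(th)) / P)
  p0 <- circular_variance(tuning_curve(unit_at(0.3), bank))$
    preferred_orientation
  for (delta in c(0.2, 0.8, 1.5, 2.2)) {
    p <- circular_variance(tuning_curve(unit_at(0.3 + delta), bank))$
      preferred_orientation
    expect_lt(orientation_dist(p - p0, delta), pi / 36)
  }
})

test_that("orientation histograms normalize and degenerate correctly", {
  theta <- seq(0, pi, length.out = 37)[1:36]
  unitstats <- circular_variance(
    list(alpha = replace(numeric(36), 5, 1), theta = theta))
  hist1 <- orientation_histograms(rep(list(unitstats), 12), bins = 10)
  expect_equal(sum(hist1$cv_hist$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(hist1$preferred$proportion), 1, tolerance = 1e-12)
  expect_equal(max(hist1$preferred$proportion), 1)
  # uniform grating population: flat polar profile within binomial error
  bank <- grating_bank(16)
  sel <- which(abs(bank$meta$sf - 3) < 0.6 & bank$meta$phase == 0)
  stats <- lapply(sel, function(i)
    circular_variance(tuning_curve(bank$gratings[, i], bank)))
  h <- orientation_histograms(stats, bins = 6)
  p0 <- 1 / 6
  tol <- 4 * sqrt(p0 * (1 - p0) / length(stats)) + 1e-9
  expect_true(all(abs(h$preferred$proportion - p0) < tol))
})

test_that("gabor fits recover known parameters and flag noise", {
  cfgs <- list(
    list(th = 0.4, per = 5, sp = 3, so = 2),
    list(th = 1.6, per = 6, sp = 2, so = 3.5),
    list(th = 2.8, per = 4.5, sp = 2.5, so = 2.5))
  for (cc in cfgs) {
    u <- make_gabor(16, 0.7, -0.5, cc$th, cc$per, 0.9, cc$sp, cc$so, 1)
    f <- fit_gabor(u, restarts = 8, seed = 3)
    expect_gt(f$r2, 0.999)
    expect_lt(orientation_dist(f$orientation, cc$th), 0.02 * pi)
    expect_lt(abs(f$period - cc$per) / cc$per, 0.02)
    expect_lt(abs(f$sigma_par - cc$sp) / cc$sp, 0.02)
    expect_lt(abs(f$sigma_orth - cc$so) / cc$so, 0.02)
  }
  set.seed(99)
  noise <- rnorm(256)
  fn <- fit_gabor(noise, restarts = 6, seed = 1)
  expect_lt(fn$r2, 0.6)
})

test_that("gabor sigmas are invariant to a pi rotation of the input", {
  u <- make_gabor(16, 0.5, 0.4, 1.1, 5, 0.7, 3, 2, 1)
  img <- matrix(u, 16, 16, byrow = TRUE)
  rot <- as.vector(t(img[16:1, 16:1]))  # 180-degree rotation
  f1 <- fit_gabor(u, restarts = 8, seed = 2)
  f2 <- fit_gabor(rot, restarts = 8, seed = 2)
  expect_equal(f1$sigma_par, f2$sigma_par, tolerance = 1e-3)
  expect_equal(f1$sigma_orth, f2$sigma_orth, tolerance = 1e-3)
  expect_lt(orientation_dist(f1$orientation, f2$orientation), 1e-3)
})

test_that("shape_table filters by fit quality and normalizes by period", {
  clean <- lapply(seq(0.2, 2.9, length.out = 10), function(th)
    fit_gabor(make_gabor(16, 0, 0, th, 5, 0.5, 3, 2, 1), restarts = 6,
              seed = 1))
  set.seed(4)
  noisy <- lapply(1:5, function(i) fit_gabor(rnorm(256), restarts = 4,
                                             seed = i))
  tab <- shape_table(c(clean, noisy), r2_min = 0.6)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$sigma_par_norm, rep(3 / 5, 10), tolerance = 0.01)
  expect_equal(tab$aspect_ratio, rep(1.5, 10), tolerance = 0.01)
  expect_equal(nrow(shape_table(noisy, r2_min = 0.6)), 0)
  iso <- fit_gabor(make_gabor(16, 0, 0, 0.8, 5, 0.5, 2.5, 2.5, 1),
                   restarts = 6, seed = 1)
  expect_equal(shape_table(list(iso))$aspect_ratio, 1, tolerance = 0.01)
})

test_that("rf_analysis tabulates per-unit statistics", {
  phi <- cbind(
    make_gabor(12, 0, 0, 0.5, 4, 0, 2, 1.5, 1),
    make_gabor(12, 1, -1, 2.0, 5, 1, 1.5, 2, 1))
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), `/`)
  tab <- rf_analysis(phi, restarts = 6, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("unit", "optimal_sf", "circular_variance",
                    "preferred_orientation", "gabor_r2") %in% names(tab)))
  expect_true(all(tab$gabor_r2 > 0.99))
  expect_lt(orientation_dist(tab$preferred_orientation[1], 0.5), 0.15)
})
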