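test_that("zero patches and over-regularization give zero codes", {
  phi <- random_unit_dictionary(16, 24, seed = 1)
  spec <- penalty_spec("soft", 0.1, 1 / lipschitz_bound(phi))
  sc <- sparse_code(numeric(16), phi, spec, max_iters = 20)
  expect_equal(sc$r, numeric(24))
  expect_equal(sc$active_count, 0)
  expect_equal(sc$final_mse, 0)
  big <- penalty_spec("soft", 100, 1 / lipschitz_bound(phi))
  sc2 <- sparse_code(rnorm(16), phi, big, max_iters = 5)
  expect_equal(sc2$r, numeric(24))
})

test_that("soft-penalty coding reaches the lasso objective", {
  set.seed(15)
  for (i in 1:10) {
    phi <- random_unit_dictionary(8, 20, seed = 500 + i)
    I <- rnorm(8)
    lam <- runif(1, 0.05, 0.5)
    spec <- penalty_spec("soft", lam, 1 / lipschitz_bound(phi))
    sc <- sparse_code(I, phi, spec, max_iters = 3000)
    r_oracle <- cd_lasso(I, phi, lam)
    expect_lt(abs(lasso_objective(I, phi, sc$r, lam) -
                    lasso_objective(I, phi, r_oracle, lam)), 1e-6)
    # the package energy of the oracle solution equals the oracle objective
    expect_equal(energy(I, phi, r_oracle, spec),
                 lasso_objective(I, phi, r_oracle, lam), tolerance = 1e-12)
  }
})

test_that("soft-penalty coding agrees with glmnet coordinate descent", {
  skip_if_not_installed("glmnet")
  set.seed(16)
  phi <- random_unit_dictionary(12, 30, seed = 77)
  I <- rnorm(12)
  lam <- 0.2
  spec <- penalty_spec("soft", lam, 1 / lipschitz_bound(phi))
  sc <- sparse_code(I, phi, spec, max_iters = 5000)
  # glmnet minimizes RSS/(2n) + lambda_g ||r||_1
  g <- glmnet::glmnet(phi, I, lambda = lam / length(I), intercept = FALSE,
                      standardize = FALSE, thresh = 1e-14)
  r_g <- as.numeric(g$beta)
  expect_lt(abs(lasso_objective(I, phi, sc$r, lam) -
                  lasso_objective(I, phi, r_g, lam)), 1e-6)
})

test_that("energy decomposes into data and penalty terms", {
  phi <- random_unit_dictionary(16, 8, seed = 3)
  I <- rnorm(16)
  for (kind in c("soft", "half", "hard", "cel0")) {
    spec <- penalty_spec(kind, 0.3, 0.5)
    expect_equal(energy(I, phi, numeric(8), spec), 0.5 * sum(I^2))
  }
  # exact code on a noiseless planted patch: hard energy is lambda * k
  s <- sample_planted_patches(planted_model(phi, 3, 1, 0, seed = 9), 5)
  hard <- penalty_spec("hard", 0.3, 0.5)
  for (b in 1:5)
    expect_equal(energy(s$patches[b, ], phi, s$codes[b, ], hard), 0.3 * 3,
                 tolerance = 1e-12)
})

test_that("lipschitz_bound equals the squared spectral norm", {
  expect_equal(lipschitz_bound(diag(8)), 1)
  e <- c(1, rep(0, 9))
  expect_equal(lipschitz_bound(cbind(e, e)), 2, tolerance = 1e-12)
  phi <- random_unit_dictionary(64, 120, seed = 8)
  expect_equal(lipschitz_bound(phi), max(svd(phi)$d)^2, tolerance = 1e-8)
})

test_that("energy traces are non-increasing for mu <= 1/L", {
  set.seed(23)
  phi <- random_unit_dictionary(32, 64, seed = 31)
  mu <- 1 / lipschitz_bound(phi)
  patches <- matrix(rnorm(5 * 32, sd = 0.4), 5, 32)
  for (kind in c("soft", "half", "hard", "cel0")) {
    spec <- penalty_spec(kind, 0.15, mu)
    for (b in 1:5) {
      sc <- sparse_code(patches[b, ], phi, spec, max_iters = 120)
      expect_true(all(diff(sc$energy_trace) <= 1e-10))
      expect_true(all(is.finite(sc$energy_trace)))
    }
  }
})

test_that("all four operators recover a planted 1-sparse patch", {
  phi <- random_unit_dictionary(16, 32, seed = 41)
  mu <- 1 / lipschitz_bound(phi)
  lams <- c(soft = 0.05, half = 0.02, hard = 0.5, cel0 = 0.02)
  for (kind in names(lams)) {
    for (j in c(1L, 7L, 20L)) for (sgn in c(1, -1)) {
      patch <- sgn * 0.9 * phi[, j]
      sc <- sparse_code(patch, phi, penalty_spec(kind, lams[[kind]], mu),
                        max_iters = 300)
      expect_identical(which(sc$r != 0), j)
      expect_equal(sign(sc$r[j]), sgn)
    }
  }
})

test_that("coding is deterministic and batch coding matches single", {
  phi <- random_unit_dictionary(16, 24, seed = 2)
  spec <- penalty_spec("half", 0.1, 1 / lipschitz_bound(phi))
  patches <- matrix(rnorm(3 * 16), 3, 16)
  a <- sparse_code_batch(patches, phi, spec, max_iters = 80)
  b <- sparse_code_batch(patches, phi, spec, max_iters = 80)
  expect_identical(a, b)
  single <- sparse_code(patches[2, ], phi, spec, max_iters = 80)
  expect_equal(single$r, a$codes[2, ], tolerance = 1e-14)
  expect_equal(single$final_mse, a$mse[2], tolerance = 1e-14)
})

test_that("a too-large step size raises the step-size contract error", {
  phi <- random_unit_dictionary(16, 64, seed = 4)
  spec <- penalty_spec("soft", 1e-4, 50 / lipschitz_bound(phi))
  expect_error(sparse_code(rnorm(16), phi, spec, max_iters = 200),
               "mu <= 1/L")
})
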