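test_that("soft thresholding matches its closed form", {
  th <- 0.5
  expect_equal(soft_threshold(2 * th, th), th)
  expect_equal(soft_threshold(th, th), 0)
  expect_equal(soft_threshold(-0.7, 0.5), -0.2)
  expect_equal(soft_threshold(c(-2, 0, 2), 0.5), c(-1.5, 0, 1.5))
})

test_that("half thresholding vanishes inside its region and jumps above", {
  th <- 0.5
  t_half <- 1.5 * th^(2 / 3)
  expect_equal(half_threshold(0, th), 0)
  expect_equal(half_threshold(t_half * 0.999, th), 0)
  expect_gt(half_threshold(t_half * 1.001, th), 0.5 * t_half)
})

test_that("hard thresholding keeps or kills, tie to zero", {
  expect_equal(hard_threshold(1, 1), 0)
  expect_equal(hard_threshold(1.001, 1), 1.001)
  expect_equal(hard_threshold(-5, 1), -5)
})

test_that("cel0 thresholding has the documented knee structure", {
  lam <- 0.3; mu <- 0.5  # a = mu < 1 for unit columns
  expect_equal(cel0_threshold(0, lam, mu), 0)
  low <- sqrt(2 * lam) * mu
  high <- sqrt(2 * lam)
  expect_equal(cel0_threshold(low * 0.99, lam, mu), 0)
  expect_equal(cel0_threshold(high * 1.01, lam, mu), high * 1.01)
  z <- (low + high) / 2
  expect_equal(cel0_threshold(z, lam, mu), (z - low) / (1 - mu))
  # a >= 1 branch: hard threshold at sqrt(2 lambda mu), tie resolves to 0
  mu2 <- 1.5
  knee <- sqrt(2 * lam * mu2)
  expect_equal(cel0_threshold(knee, lam, mu2), 0)
  expect_equal(cel0_threshold(knee * 1.01, lam, mu2), knee * 1.01)
})

test_that("operators are odd, shrinking, and share the zero region width", {
  set.seed(42)
  zs <- runif(400, -6, 6)
  for (kind in c("soft", "half", "hard", "cel0")) {
    lam <- 0.4; mu <- 0.6
    spec <- penalty_spec(kind, lam, mu)
    Tz <- v1sparse:::apply_threshold(zs, spec)
    Tnz <- v1sparse:::apply_threshold(-zs, spec)
    expect_equal(Tnz, -Tz, tolerance = 1e-12)
    expect_true(all(abs(Tz) <= abs(zs) + 1e-12))
    width <- switch(kind,
      soft = spec$theta, hard = spec$theta,
      half = 1.5 * spec$theta^(2 / 3),
      cel0 = sqrt(2 * lam) * mu)
    inside <- abs(zs) <= width * 0.999
    expect_true(all(Tz[inside] == 0))
    outside <- abs(zs) > width * 1.001
    expect_true(all(Tz[outside] != 0))
  }
})

test_that("penalty_value matches the four cost functions", {
  r <- c(0, 1.5, -2, 0, 0.25, 0, 0.5)
  soft <- penalty_spec("soft", 0.3, 0.5)
  half <- penalty_spec("half", 0.3, 0.5)
  hard <- penalty_spec("hard", 0.3, 0.5)
  cel0 <- penalty_spec("cel0", 0.3, 0.5)
  expect_equal(penalty_value(numeric(5), soft), 0)
  expect_equal(penalty_value(numeric(5), half), 0)
  expect_equal(penalty_value(numeric(5), hard), 0)
  expect_equal(penalty_value(numeric(5), cel0), 0)
  expect_equal(penalty_value(r, soft), sum(abs(r)))
  expect_equal(penalty_value(r, half), sum(sqrt(abs(r))))
  expect_equal(penalty_value(rep(1, 7), hard), 7)
  expect_equal(penalty_value(r, hard), 4)
  # cel0 saturates at lambda per coefficient beyond sqrt(2 lambda)
  big <- rep(sqrt(2 * 0.3) + 0.5, 3)
  expect_equal(penalty_value(big, cel0), 3 * 0.3)
})

test_that("closed-form operators agree with the brute-force prox oracle", {
  set.seed(7)
  n_each <- 250
  for (kind in c("soft", "half", "hard", "cel0")) {
    for (i in seq_len(n_each)) {
      z <- runif(1, -4, 4)
      lam <- runif(1, 0.05, 1.5)
      mu <- runif(1, 0.05, 1.5)
      spec <- penalty_spec(kind, lam, mu)
      got <- v1sparse:::apply_threshold(z, spec)
      # the printed hard operator thresholds at theta = lambda mu; it is
      # the exact l0 prox for the effective weight theta^2 / (2 mu)
      ospec <- if (kind == "hard")
        penalty_spec("hard", (lam * mu)^2 / (2 * mu), mu) else spec
      hw <- max(4, 2 * abs(z))
      oracle <- prox_oracle(z, ospec, grid_halfwidth = hw,
                            grid_points = 2e4)
      res <- 2 * (2 * hw / 2e4)
      if (abs(got - oracle) > res) {
        # near a decision boundary the two may land on opposite minima;
        # then their objective values must tie
        w <- v1sparse:::penalty_weight(ospec)
        obj <- function(y) w * v1sparse:::penalty_scalar(y, ospec) +
          (y - z)^2 / (2 * mu)
        expect_lt(abs(obj(got) - obj(oracle)), 1e-6)
      } else {
        expect_lt(abs(got - oracle), res)
      }
    }
  }
})

test_that("prox_oracle validates its grid", {
  spec <- penalty_spec("soft", 0.2, 0.5)
  expect_error(prox_oracle(5, spec, grid_halfwidth = 2), "too narrow")
  expect_error(prox_oracle(0.5, spec, grid_points = 100))
})
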