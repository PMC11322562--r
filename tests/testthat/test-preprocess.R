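test_that("Freeman-Tukey matches direct evaluation and rejects negatives", {
  expect_equal(freeman_tukey(0), 1.0)
  expect_equal(freeman_tukey(3), sqrt(4) + sqrt(3), tolerance = 1e-15)
  x <- c(0, 1, 2, 5, 10, 50, 1000)
  expect_equal(freeman_tukey(x), sqrt(x + 1) + sqrt(x), tolerance = 1e-15)
  expect_error(freeman_tukey(-1), class = "ddgate_domain")
})

test_that("Freeman-Tukey stabilises Poisson variance near 1", {
  withr::with_seed(42, {
    for (lam in c(5, 20, 50, 100)) {
      v <- var(freeman_tukey(rpois(1e5, lam)))
      expect_gt(v, 0.9)
      expect_lt(v, 1.1)
    }
  })
})

test_that("Yeo-Johnson four-branch definition evaluates correctly", {
  expect_equal(yeo_johnson(5, 1), 5)
  expect_equal(yeo_johnson(0, 0), 0)
  expect_equal(yeo_johnson(3, 0.5), (4^0.5 - 1) / 0.5)
  # negative branches
  expect_equal(yeo_johnson(-0.5, 1), -((1.5^1 - 1) / 1))
  expect_equal(yeo_johnson(-3, 2), -log(4))
  # lambda = 0 on positives is log(x + 1)
  expect_equal(yeo_johnson(c(0, 1, 9), 0), log(c(1, 2, 10)))
})

test_that("Yeo-Johnson agrees with an independent implementation", {
  skip_if_not_installed("car")
  x <- seq(-4, 25, by = 0.37)
  for (lam in c(-1, -0.3, 0.5, 1.7)) {
    expect_equal(yeo_johnson(x, lam), unname(car::yjPower(x, lam)),
                 tolerance = 1e-12)
  }
})

test_that("transform chain is monotone so bin ranking is preserved", {
  x <- sort(withr::with_seed(5, rpois(200, 30)))
  y <- yeo_johnson(freeman_tukey(x), 0.3)
  expect_true(all(diff(y) >= 0))
  expect_equal(order(x), order(y))
})

test_that("fit_lambda recovers the Gaussianising power", {
  withr::with_seed(9, {
    # FT-transformed Poisson(50) is near-Gaussian already: lambda ~ 1
    x1 <- freeman_tukey(rpois(2e4, 50))
    expect_lt(abs(fit_lambda(x1)$lam - 1), 0.15)
    # data exactly Gaussian under a known lambda, via the inverse transform
    for (lam in c(0, 0.5, 1)) {
      x <- yeo_johnson_inverse(rnorm(5e4, 1, 0.8), lam)
      expect_lt(abs(fit_lambda(x)$lam - lam), 0.15)
    }
  })
  expect_error(fit_lambda(rep(1, 1000)), class = "ddgate_degenerate")
  expect_error(fit_lambda(1:50), class = "ddgate_degenerate")
})

test_that("yeo_johnson_inverse round-trips through the forward transform", {
  for (lam in c(-1, 0, 0.5, 1, 2)) {
    # stay inside the attainable range of the forward transform
    hi <- if (lam < 0) -1 / lam - 0.01 else 3
    lo <- if (lam > 2) 1 / (2 - lam) + 0.01 else -3
    z <- seq(lo, hi, length.out = 41)
    expect_equal(yeo_johnson(yeo_johnson_inverse(z, lam), lam), z,
                 tolerance = 1e-10)
  }
  expect_true(is.nan(yeo_johnson_inverse(1.5, -1)))
})

test_that("rebin_time conserves counts and validates the frame ratio", {
  s <- tiny_series(nt = 20)
  s$frame_duration_s <- 0.25
  out <- rebin_time(s, 2)
  expect_equal(dim(out$data)[5], 10)
  expect_equal(sum(out$data), sum(s$data))
  expect_equal(out$frame_duration_s, 0.5)
  # ratio 1 is the identity
  s2 <- tiny_series()
  expect_identical(rebin_time(s2, 2)$data, s2$data)
  # non-integer ratio errors
  s3 <- tiny_series()
  s3$frame_duration_s <- 0.3
  expect_error(rebin_time(s3, 2), class = "ddgate_parameter")
})

test_that("mask threshold retains the expected bins", {
  # time-mean values 1..100 exactly: percentile 0.05 keeps 95 bins
  data <- array(rep(1:100, 2), dim = c(10, 5, 2, 1, 2))
  s <- sinogram_series(data)
  msk <- compute_mask(s, 0.05)
  expect_equal(sum(msk$mask), 95)
  # brute-force check of the strict-threshold rule
  expect_equal(sum(msk$mask),
               sum(rowMeans(matrix(data, 100)) > quantile(1:100, 0.05)))
  # percentile 0 keeps everything
  expect_true(all(compute_mask(s, 0)$mask))
  # all-equal series falls back to keeping all bins
  s_eq <- sinogram_series(array(3, dim = c(4, 3, 2, 1, 2)))
  expect_warning(m_eq <- compute_mask(s_eq, 0.05))
  expect_true(all(m_eq$mask))
  expect_error(compute_mask(sinogram_series(array(0, dim = c(2, 2, 2, 1, 2)))),
               class = "ddgate_degenerate")
})

test_that("apply_mask zeroes excluded bins and is idempotent", {
  s <- tiny_series()
  msk <- compute_mask(s, 0.3)
  m1 <- apply_mask(s, msk)
  expect_true(m1$mask_applied)
  nb <- prod(dim(s$data)[1:4])
  dat <- matrix(m1$data, nrow = nb)
  expect_true(all(dat[!as.vector(msk$mask), ] == 0))
  m2 <- apply_mask(m1, msk)
  expect_identical(m2$data, m1$data)
})

test_that("Gaussian smoothing reproduces the discrete kernel on an impulse", {
  data <- array(0, dim = c(21, 1, 1, 1, 1))
  data[11, 1, 1, 1, 1] <- 1
  s <- sinogram_series(data)
  out <- smooth_and_downsample(s, sigmas = c(1, 0, 0),
                               downsample_factor = c(1, 1, 1))
  prof <- out$data[, 1, 1, 1, 1]
  expect_equal(sum(prof), 1, tolerance = 1e-12)
  k <- dnorm(-4:4, sd = 1); k <- k / sum(k)
  expect_equal(prof[7:15], k, tolerance = 1e-12)
  # identity case
  out0 <- smooth_and_downsample(s, sigmas = c(0, 0, 0),
                                downsample_factor = c(1, 1, 1))
  expect_identical(out0$data, s$data)
})

test_that("downsampling is exact on constants and validates factors", {
  data <- array(7, dim = c(8, 6, 4, 1, 3))
  s <- sinogram_series(data)
  out <- smooth_and_downsample(s, sigmas = c(0, 0, 0),
                               downsample_factor = c(2, 1, 2))
  expect_true(all(abs(out$data - 7) < 1e-12))
  expect_equal(dim(out$data)[1:3], c(4, 6, 2))
  expect_error(smooth_and_downsample(s, sigmas = c(0, 0, 0),
                                     downsample_factor = c(20, 1, 1)),
               class = "ddgate_parameter")
})

test_that("preprocess_series runs the full chain and records metadata", {
  s <- tiny_series(nr = 10, na = 8, np = 4, nt = 120, lambda = 20)
  out <- preprocess_series(s, downsample_factor = c(2, 1, 2))
  expect_true(out$transformed)
  expect_true(out$mask_applied)
  expect_true(is.numeric(attr(out, "lambda")))
  expect_equal(dim(out$data)[1:3], c(5, 8, 2))
})
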