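# brute-force oracle: eigendecomposition of the bin covariance matrix
brute_force_pcs <- function(series, k) {
  X <- t(matrix(series$data, nrow = prod(dim(series$data)[1:4])))  # time x bins
  Xc <- scale(X, scale = FALSE)
  e <- eigen(crossprod(Xc), symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE]
}

test_that("pca_decompose matches brute-force covariance eigendecomposition", {
  trace <- sin(2 * pi * 0.25 * (0:15) / 2)
  s <- rank1_series(trace, dims = c(3, 1, 1, 1), noise_sd = 0.3, seed = 2)
  comps <- suppressWarnings(pca_decompose(s, 3))
  V <- brute_force_pcs(s, length(comps))
  for (j in seq_along(comps)) {
    v <- V[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(comps[[j]]$weights, v, tolerance = 1e-8)
  }
})

test_that("rank-1 structure is recovered exactly", {
  trace <- sin(2 * pi * 0.2 * (0:63) / 2)
  s <- rank1_series(trace, dims = c(4, 3, 2, 1))
  comps <- suppressWarnings(pca_decompose(s, 5))
  # single nonzero singular value
  expect_equal(length(comps), 1)
  sig <- apply_component(comps[[1]], s)
  expect_equal(abs(cor(sig$value, trace)), 1, tolerance = 1e-10)
})

test_that("components are orthonormal and the sign convention holds", {
  s <- tiny_series(nt = 32, lambda = 15)
  comps <- pca_decompose(s, 6)
  W <- vapply(comps, function(cp) cp$weights, numeric(length(comps[[1]]$weights)))
  expect_equal(crossprod(W), diag(length(comps)), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (cp in comps) expect_gt(cp$weights[which.max(abs(cp$weights))], 0)
})

test_that("degenerate series and surplus components are handled", {
  const <- sinogram_series(array(5, dim = c(3, 2, 1, 1, 10)), transformed = TRUE)
  expect_error(pca_decompose(const), class = "ddgate_degenerate")
  trace <- rnorm(20)
  s <- rank1_series(trace, dims = c(3, 2, 1, 1))
  expect_warning(pca_decompose(s, 5), "rank")
})

test_that("apply_component computes W = PC x S (hand example and linearity)", {
  # 2-bin toy: PC = (1, -1), frames ((3,1), (0,2)) -> W = (2, -2)
  data <- array(c(3, 1, 0, 2), dim = c(2, 1, 1, 1, 2))
  s <- sinogram_series(data, transformed = TRUE)
  w <- ddgate:::new_component(c(1, -1), 1:2, c(2, 1, 1, 1), "pca", c(1, 2))
  expect_equal(apply_component(w, s)$value, c(2, -2))
  # all-ones PC gives frame sums; zero weights are rejected at construction
  ones <- ddgate:::new_component(c(1, 1), 1:2, c(2, 1, 1, 1), "pca", c(1, 2))
  expect_equal(apply_component(ones, s)$value, c(4, 2))
  expect_error(ddgate:::new_component(c(0, 0), 1:2, c(2, 1, 1, 1), "pca", c(1, 2)),
               class = "ddgate_format")
  # linearity: (a*w1 + b*w2) . S = a*(w1.S) + b*(w2.S)
  s2 <- tiny_series(nt = 24)
  nb <- prod(dim(s2$data)[1:4])
  w1 <- withr::with_seed(1, rnorm(nb)); w2 <- withr::with_seed(2, rnorm(nb))
  lhs <- apply_component(3 * w1 - 2 * w2, s2)$value
  rhs <- 3 * apply_component(w1, s2)$value - 2 * apply_component(w2, s2)$value
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("compute_psd locates pure tones and zeroes constants", {
  psd <- compute_psd(sine_signal(0.25, n = 512))
  expect_equal(psd$freq_hz[which.max(psd$power)], 0.25, tolerance = 1e-9)
  expect_true(all(compute_psd(surrogate_signal(rep(3, 64)))$power < 1e-10))
  # two equal-amplitude on-bin tones give two equal peaks
  t <- (0:399) / 2
  two <- surrogate_signal(sin(2 * pi * 0.05 * t) + sin(2 * pi * 0.25 * t))
  psd2 <- compute_psd(two)
  p05 <- psd2$power[which.min(abs(psd2$freq_hz - 0.05))]
  p25 <- psd2$power[which.min(abs(psd2$freq_hz - 0.25))]
  expect_equal(p05, p25, tolerance = 0.05)
  expect_error(compute_psd(surrogate_signal(rep(NaN, 32))),
               class = "ddgate_degenerate")
})

test_that("conventional score prefers in-band tones and scales linearly", {
  in_band <- sine_signal(0.25, n = 512)
  out_band <- sine_signal(0.02, n = 512)
  expect_gt(conventional_score(in_band), conventional_score(out_band))
  expect_equal(conventional_score(surrogate_signal(rep(0, 64))), 0)
  expect_equal(conventional_score(sig_scale <- sine_signal(0.25, n = 512, amplitude = 10)),
               10 * conventional_score(sine_signal(0.25, n = 512)),
               tolerance = 1e-9)
})

test_that("frequency score is a scale-invariant band-ratio product", {
  w <- frequency_windows()
  sig <- sine_signal(0.25, n = 512)
  noisy <- sig_noise <- surrogate_signal(
    sig$value + withr::with_seed(4, rnorm(512, 0, 0.05)))
  slow <- surrogate_signal(sin(2 * pi * 0.02 * (0:511) / 2) +
                           withr::with_seed(4, rnorm(512, 0, 0.05)))
  expect_gt(frequency_score(noisy, w), 1)
  expect_gt(frequency_score(noisy, w), frequency_score(slow, w))
  # positive rescaling leaves the score unchanged
  expect_equal(frequency_score(noisy, w),
               frequency_score(ddgate:::sig_update(noisy, noisy$value * 10), w),
               tolerance = 1e-9)
})

test_that("estimate_resp_window centres on the dominant frequency", {
  w <- estimate_resp_window(sine_signal(0.25, n = 512))
  centre <- mean(w$respiratory)
  expect_lt(abs(centre - 0.25), 2 / 256)  # within one frequency bin
  # two equal peaks at 0.2 / 0.3 Hz: centre 0.25, and the half-width is half
  # the spectral standard deviation (0.5 * 0.05 for two delta peaks)
  t <- (0:399) / 2
  two <- surrogate_signal(sin(2 * pi * 0.2 * t) + sin(2 * pi * 0.3 * t))
  w2 <- estimate_resp_window(two)
  expect_lt(abs(mean(w2$respiratory) - 0.25), 0.02)
  expect_lt(abs(diff(w2$respiratory) / 2 - 0.025), 0.01)
  # white noise: centroid near mid-band, width near uniform-spectrum moments
  wn <- withr::with_seed(8, surrogate_signal(rnorm(4096)))
  w3 <- estimate_resp_window(wn)
  expect_lt(abs(mean(w3$respiratory) - 0.5), 0.06)
  halfwidth <- diff(w3$respiratory) / 2
  expect_lt(abs(halfwidth - 0.5 / sqrt(12)), 0.05)
})

test_that("sam_signed_mask selects oscillating bins with coherent signs", {
  n <- 128
  t <- (seq_len(n) - 1) / 2
  resp <- sin(2 * pi * 0.25 * t)
  nb <- 24
  m <- matrix(0.05 * withr::with_seed(3, rnorm(nb * n)), nb, n) + 5
  m[3, ] <- 5 + resp          # in-phase bins
  m[7, ] <- 5 + 0.8 * resp
  m[11, ] <- 5 - resp         # anti-phase bin
  s <- sinogram_series(array(m, dim = c(4, 3, 2, 1, n)), transformed = TRUE)
  comp <- sam_signed_mask(s)
  expect_setequal(comp$bins, c(3, 7, 11))
  expect_true(all(comp$weights %in% c(-1, 1)))
  signs <- setNames(comp$weights, comp$bins)
  expect_equal(signs[["3"]], signs[["7"]])
  expect_equal(signs[["11"]], -signs[["3"]])
  # the signal equals the coherent sum up to sign
  sig <- apply_component(comp, s)
  expect_gt(abs(cor(sig$value, resp)), 0.99)
  # all-static series has no qualifying bin
  static <- sinogram_series(array(rep(5, 4 * 3 * 2 * n) +
                                    0.01 * withr::with_seed(5, rnorm(4 * 3 * 2 * n)),
                                  dim = c(4, 3, 2, 1, n)), transformed = TRUE)
  expect_error(sam_signed_mask(static), class = "ddgate_empty_mask")
})

test_that("window_schedule covers the record with half overlaps", {
  sched <- window_schedule(1680, 2)
  expect_equal(sched$start[1], 1)
  expect_true(all(sched$start + sched$size - 1 <= 1680))
  expect_equal(max(sched$start + sched$size - 1), 1680)
  # successive windows overlap by half the previous window
  for (i in 2:nrow(sched)) {
    expect_lte(sched$start[i], sched$start[i - 1] + sched$size[i - 1] / 2 + 1)
  }
  expect_true(all(sched$size >= 8))
})

test_that("moving-window extraction recovers a common trace and fixes signs", {
  trace <- sin(2 * pi * 0.25 * (0:299) / 2)
  s <- rank1_series(trace, dims = c(4, 3, 2, 1), noise_sd = 0.01, seed = 6)
  sched <- window_schedule(300, 2, early_s = 30, late_s = 30)
  out <- moving_window_extract(s, sched)
  expect_gt(abs(cor(out$value, trace)), 0.99)
  # degenerate schedule of one full-length window equals the conventional
  # per-window extraction on the whole record
  one <- tibble::tibble(start = 1L, size = 300L)
  out1 <- moving_window_extract(s, one, normalize = FALSE)
  conv <- conventional_extract(s, 1)
  expect_equal(abs(cor(out1$value, conv$value)), 1, tolerance = 1e-8)
})

test_that("late_time_extract reuses a late component over all frames", {
  trace <- sin(2 * pi * 0.25 * (0:399) / 2)
  s <- rank1_series(trace, dims = c(4, 3, 2, 1), noise_sd = 0.02, seed = 9)
  out <- late_time_extract(s, 0.62)
  expect_equal(nrow(out), 400)
  expect_gt(abs(cor(out$value, trace)), 0.99)
  # cutoff 0 equals conventional extraction up to sign
  out0 <- late_time_extract(s, 0)
  conv <- conventional_extract(s)
  expect_equal(abs(cor(out0$value, conv$value)), 1, tolerance = 1e-8)
  expect_error(late_time_extract(s, 0.99), class = "ddgate_parameter")
})

test_that("score_select filters, sorts and breaks ties stably", {
  s <- tiny_series(nt = 32, lambda = 20)
  comps <- pca_decompose(s, 3)
  fixed <- c(0.2, 0.9, 0.5)
  scorer_env <- new.env()
  scorer_env$i <- 0L
  # scorer keyed to component identity via weights hash
  key <- vapply(comps, function(cp) paste(round(cp$weights[1:3], 6), collapse = ","),
                character(1))
  scorer <- function(sig) NA_real_
  scores <- setNames(fixed, key)
  sel <- score_select(comps, s, function(sig) {
    scorer_env$i <- scorer_env$i + 1L
    fixed[(scorer_env$i - 1L) %% 3L + 1L]
  }, threshold = 0.3)
  expect_equal(vapply(sel, function(cp) cp$score, numeric(1)), c(0.9, 0.5))
  # all below threshold
  expect_error(score_select(comps, s, function(sig) 0.1, threshold = 0.3),
               class = "ddgate_no_candidate")
  # ties keep original component order
  sel_tie <- score_select(comps, s, function(sig) 1, threshold = 0)
  expect_equal(vapply(sel_tie, function(cp) cp$singular_value, numeric(1)),
               vapply(comps, function(cp) cp$singular_value, numeric(1)))
})

test_that("combine keeps the best component when no merge improves the score", {
  # two components with identical signals: a scale-invariant scorer cannot
  # strictly improve, so the first component is returned unchanged
  trace <- sin(2 * pi * 0.25 * (0:127) / 2)
  s <- rank1_series(trace, dims = c(4, 2, 1, 1), noise_sd = 0.01, seed = 13)
  comps <- suppressWarnings(pca_decompose(s, 2))
  c1 <- comps[[1]]
  c2 <- c1; c2$weights <- 2 * c1$weights   # same signal direction
  w <- frequency_windows()
  scorer <- function(sig) frequency_score(sig, w)
  c1$score <- scorer(apply_component(c1, s))
  c2$score <- scorer(apply_component(c2, s))
  out <- combine_components(list(c1, c2), s, scorer)
  expect_equal(out$weights, c1$weights)
})

test_that("combine pools respiratory signal split across components", {
  fx <- two_component_series()
  s <- fx$series
  w <- frequency_windows()
  scorer <- function(sig) frequency_score(sig, w)
  comps <- suppressWarnings(pca_decompose(s, 6))
  r_single <- vapply(comps, function(cp)
    abs(cor(apply_component(cp, s)$value, fx$resp)), numeric(1))
  sel <- score_select(comps, s, scorer, 0)
  comb <- combine_components(sel, s, scorer)
  r_comb <- abs(cor(apply_component(comb, s)$value, fx$resp))
  expect_gt(r_comb, max(r_single))
  # final combined score never falls below the best single score
  expect_gte(comb$score, max(vapply(sel, function(cp) cp$score, numeric(1))) - 1e-9)
})

test_that("extraction output is invariant to component sign flips", {
  trace <- sin(2 * pi * 0.25 * (0:199) / 2)
  s <- rank1_series(trace, dims = c(4, 3, 1, 1), noise_sd = 0.05, seed = 17)
  # negating the data (flips every PC sign relationship) leaves |r| unchanged
  s_neg <- s
  s_neg$data <- -s_neg$data
  r1 <- abs(cor(conventional_extract(s)$value, trace))
  r2 <- abs(cor(conventional_extract(s_neg)$value, trace))
  expect_equal(r1, r2, tolerance = 1e-9)
  # flipping the sign of every component before combining flips the output
  # at most globally
  comps <- suppressWarnings(pca_decompose(s, 3))
  w <- frequency_windows()
  scorer <- function(sig) frequency_score(sig, w)
  sel <- score_select(comps, s, scorer, 0)
  flipped <- lapply(sel, function(cp) { cp$weights <- -cp$weights; cp })
  a <- apply_component(combine_components(sel, s, scorer), s)$value
  b <- apply_component(combine_components(flipped, s, scorer), s)$value
  expect_equal(abs(cor(a, b)), 1, tolerance = 1e-9)
})

test_that("feature scorer maps signals into [0, 1] monotonically", {
  sc <- feature_scorer()
  clean <- sine_signal(0.25, n = 256)
  noise <- withr::with_seed(30, surrogate_signal(rnorm(256)))
  expect_gte(sc(clean), 0); expect_lte(sc(clean), 1)
  expect_gt(sc(clean), sc(noise))
})
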