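# Small in-code fixtures shared across test files.

# a tiny raw-count series: dims (radial, angle, plane, tof, time)
tiny_series <- function(nr = 4, na = 3, np = 2, ntof = 1, nt = 16, seed = 7,
                        lambda = 5) {
  withr::with_seed(seed, {
    data <- array(rpois(nr * na * np * ntof * nt, lambda),
                  dim = c(nr, na, np, ntof, nt))
  })
  sinogram_series(data, frame_duration_s = 0.5)
}

# rank-1 series: one spatial pattern modulated by a temporal trace (plus a
# constant offset), optionally with independent Gaussian noise per bin
rank1_series <- function(trace, pattern = NULL, offset = 10, noise_sd = 0,
                         dims = c(5, 4, 2, 1), seed = 11) {
  nb <- prod(dims)
  if (is.null(pattern)) {
    pattern <- withr::with_seed(seed, rnorm(nb))
  }
  nt <- length(trace)
  m <- offset + outer(pattern, trace)
  if (noise_sd > 0) {
    m <- m + withr::with_seed(seed + 1, matrix(rnorm(nb * nt, 0, noise_sd), nb, nt))
  }
  sinogram_series(array(m, dim = c(dims, nt)), frame_duration_s = 0.5,
                  transformed = TRUE)
}

# pure sinusoid surrogate signal
sine_signal <- function(freq_hz, n = 512, hz = 2, amplitude = 1, phase = 0) {
  t <- (seq_len(n) - 1) / hz
  surrogate_signal(amplitude * sin(2 * pi * freq_hz * t + phase), sampling_hz = hz)
}

# two-respiratory-component fixture: respiration is split across two
# spatial patterns, each entangled with a different kinetic drift, so no
# single principal component carries the whole trace and score-driven
# combination is required to pool it
two_component_series <- function(n = 512, noise_sd = 0.1, seed = 21) {
  t <- (seq_len(n) - 1) / 2
  resp <- sin(2 * pi * 0.25 * t)
  d1 <- sin(2 * pi * 0.015 * t)
  d2 <- exp(-t / 80)
  nb <- 12
  p1 <- c(rep(1, 4), rep(0, 8)); p2 <- c(rep(0, 8), rep(1, 4))
  m <- outer(p1, 1.5 * d1 + 1.0 * resp) + outer(p2, 2 * d2 - 1.2 * resp) + 10
  m <- m + withr::with_seed(seed, matrix(rnorm(nb * n, 0, noise_sd), nb, n))
  list(series = sinogram_series(array(m, dim = c(nb, 1, 1, 1, n)),
                                transformed = TRUE),
       resp = resp)
}

# small fast phantom config for tests; any phantom_config() field can be
# overridden through ...
test_phantom_config <- function(seed = 3, ...) {
  defaults <- list(
    n_frames = 400, image_grid = c(32, 32, 16), n_radial = 16,
    n_angles = 8, n_planes = 8, count_scale = 2000,
    geometry = list(
      list(center = c(16, 16, 8), axes = c(10, 8, 3), label = "body"),
      list(center = c(13, 18, 8), axes = c(4, 3, 2), label = "blood")),
    tacs = list(body = tac_model("uptake", scale = 1, k_uptake = 1 / 200),
                blood = tac_model("bolus_washout", scale = 8,
                                  k_rise = 1 / 3, k_washout = 1 / 40,
                                  delay_s = 3)),
    resp = resp_model(base_freq_hz = 0.25, amplitude_voxels = 1,
                      freq_jitter = 0.03),
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_config, args)
}
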