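#' Parallel compression of a surrogate trace
#'
#' A technique borrowed from audio engineering: the trace is split into two
#' channels, one has its dynamic range reduced by an envelope compressor
#' while the other passes unchanged, and the two are mixed back together.
#' Large amplitude excursions (residual tracer kinetics, drift) are tamed
#' without flattening breath-to-breath variability. The compressor divides
#' the signal by `(envelope / reference)^(1 - 1/ratio)`, where the envelope
#' is a smoothed running maximum of the absolute trace and the reference is
#' its median, pulling loud sections toward the typical amplitude.
#'
#' @param signal a [surrogate_signal()].
#' @param envelope_window_s running-maximum window length, seconds.
#' @param compression_ratio compressor ratio (>= 1; 1 is a no-op).
#' @param mix fraction of the compressed channel in the output average.
#' @return A [surrogate_signal()].
#' @export
parallel_compression <- function(signal, envelope_window_s = 10,
                                 compression_ratio = 4, mix = 0.5) {
  signal <- as_signal(signal)
  if (!nrow(signal)) abort_ddgate("zero-length signal.", "parameter")
  if (compression_ratio < 1) abort_ddgate("`compression_ratio` must be >= 1.", "parameter")
  if (mix < 0 || mix > 1) abort_ddgate("`mix` must be in [0, 1].", "parameter")
  x <- signal$value
  env <- running_envelope(x, max(1L, round(envelope_window_s * sig_hz(signal))))
  ref <- median(env[env > 0])
  if (!is.finite(ref) || ref <= 0) return(signal)   # silent trace: nothing to do
  gain <- (pmax(env, 1e-12 * max(env)) / ref)^(1 / compression_ratio - 1)
  sig_update(signal, mix * (x * gain) + (1 - mix) * x)
}

# smoothed centred running maximum of |x|
running_envelope <- function(x, win) {
  n <- length(x)
  half <- max(1L, win %/% 2L)
  ax <- abs(x)
  ax[!is.finite(ax)] <- 0
  env <- ax
  for (k in seq_len(half)) {
    env <- pmax(env, c(ax[-seq_len(k)], rep(ax[n], k)),
                c(rep(ax[1], k), ax[seq_len(n - k)]))
  }
  # light moving-average smoothing to avoid gain steps
  w <- min(2L * half + 1L, n)
  sm <- stats::filter(env, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- env[is.na(sm)]
  sm
}

#' Quartile-fence outlier repair
#'
#' Samples outside `[Q1 - k*IQR, Q3 + k*IQR]` are treated as momentary
#' spikes and replaced by linear interpolation between the nearest inliers;
#' an outlier at a boundary takes the nearest inlier value. If more than
#' half the samples are flagged the trace is unusable and an error is
#' raised rather than fabricating a signal.
#'
#' @param signal a [surrogate_signal()] with at least 4 samples.
#' @param k fence multiplier (default 1.5).
#' @return A [surrogate_signal()].
#' @export
remove_outliers <- function(signal, k = 1.5) {
  signal <- as_signal(signal)
  x <- signal$value
  if (length(x) < 4) abort_ddgate("need at least 4 samples.", "parameter")
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- which(!is.na(x) & (x < lo | x > hi))
  if (!length(out)) return(signal)
  if (length(out) > 0.5 * sum(!is.na(x)))
    abort_ddgate("more than 50% of samples are outliers; signal unusable.", "degenerate")
  inl <- setdiff(which(!is.na(x)), out)
  x[out] <- approx(inl, x[inl], xout = out, rule = 2)$y
  sig_update(signal, x)
}

#' Truncated windowed-sinc bandpass kernel
#'
#' The ideal bandpass impulse response
#' `h(t) = 2*B_H*sinc(2*B_H*t) - 2*B_L*sinc(2*B_L*t)` sampled at the signal
#' rate, truncated at `+/- kernel_halfwidth_s` and tapered with a Hann
#' window (unity at the centre, so `h(0) = 2*B_H - 2*B_L` exactly). The
#' kernel is symmetric, hence zero-phase.
#'
#' @param B_L,B_H band edges in Hz (`0 < B_L < B_H <= Nyquist`).
#' @param sampling_hz sampling rate in Hz.
#' @param kernel_halfwidth_s truncation half-width in seconds; the default
#'   `8 / B_L` keeps passband ripple around or below 1%.
#' @return A tibble with columns `t_s` and `h`.
#' @export
bandpass_kernel <- function(B_L = 0.1, B_H = 0.4, sampling_hz = 2,
                            kernel_halfwidth_s = 8 / B_L) {
  if (!(B_L > 0 && B_L < B_H)) abort_ddgate("need 0 < B_L < B_H.", "parameter")
  if (B_H > sampling_hz / 2 + 1e-12)
    abort_ddgate("band exceeds the Nyquist frequency.", "parameter")
  nh <- round(kernel_halfwidth_s * sampling_hz)
  t <- (-nh:nh) / sampling_hz
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  h <- 2 * B_H * sinc(2 * B_H * t) - 2 * B_L * sinc(2 * B_L * t)
  taper <- 0.5 * (1 + cos(pi * (-nh:nh) / nh))
  tibble::tibble(t_s = t, h = h * taper)
}

#' Bandpass filter a surrogate trace
#'
#' Convolves the trace with the [bandpass_kernel()] (scaled by the sample
#' spacing so passband gain is ~1), with reflection at the edges. Removes
#' slow kinetic drift below `B_L` and noise above `B_H` while leaving the
#' respiratory band and its phase intact.
#'
#' @inheritParams bandpass_kernel
#' @param signal a [surrogate_signal()].
#' @return A [surrogate_signal()].
#' @export
bandpass <- function(signal, B_L = 0.1, B_H = 0.4,
                     kernel_halfwidth_s = 8 / B_L) {
  signal <- as_signal(signal)
  hz <- sig_hz(signal)
  ker <- bandpass_kernel(B_L, B_H, hz, kernel_halfwidth_s)
  h <- ker$h / hz
  x <- signal$value
  n <- length(x)
  r <- (length(h) - 1L) / 2L
  idx <- reflect_index(n, r)
  padded <- x[idx]
  out <- numeric(n)
  for (j in seq_along(h)) {
    out <- out + h[j] * padded[(j - 1L) + seq_len(n)]
  }
  sig_update(signal, out)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; reproduces polynomials up to
#' the filter order exactly, so respiratory peaks are not flattened the way
#' a moving average would. Defaults: order 3, window 5.
#'
#' @param signal a [surrogate_signal()].
#' @param order polynomial order (< window).
#' @param window window length (odd).
#' @return A [surrogate_signal()].
#' @export
savgol_smooth <- function(signal, order = 3, window = 5) {
  signal <- as_signal(signal)
  if (window %% 2 == 0) abort_ddgate("`window` must be odd.", "parameter")
  if (order >= window) abort_ddgate("`order` must be < `window`.", "parameter")
  if (nrow(signal) < window) abort_ddgate("signal shorter than the window.", "parameter")
  sig_update(signal, signal::sgolayfilt(signal$value, p = order, n = window))
}

#' Full trace post-processing chain
#'
#' Applies, in order: parallel compression, quartile outlier repair,
#' windowed-sinc bandpass, Savitzky-Golay smoothing. Each stage can be
#' toggled. The chain preserves respiratory phase (symmetric zero-phase
#' filters throughout).
#'
#' @param signal a [surrogate_signal()].
#' @param compress,outliers,band,smooth stage toggles.
#' @param B_L,B_H bandpass edges in Hz.
#' @param ... passed through to [parallel_compression()].
#' @return A [surrogate_signal()].
#' @export
postprocess_signal <- function(signal, compress = TRUE, outliers = TRUE,
                               band = TRUE, smooth = TRUE,
                               B_L = 0.1, B_H = 0.4, ...) {
  signal <- as_signal(signal)
  x <- signal
  if (anyNA(x$value)) {
    # moving-window padding: fill leading/trailing NaNs by nearest value
    v <- x$value
    ok <- which(is.finite(v))
    if (!length(ok)) abort_ddgate("all-NaN signal.", "degenerate")
    v <- approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
    x <- sig_update(x, v)
  }
  if (compress) x <- parallel_compression(x, ...)
  if (outliers) x <- remove_outliers(x)
  if (band) x <- bandpass(x, B_L = B_L, B_H = B_H)
  if (smooth) x <- savgol_smooth(x)
  x
}
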