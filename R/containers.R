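#' Sinogram time series container
#'
#' Holds a time series of low-resolution (optionally time-of-flight) PET
#' sinograms as a 5-axis array with axes (radial, angle, plane, tof, time),
#' together with frame timing and processing flags. Raw series contain
#' non-negative Poisson counts; after the variance-stabilising transforms the
#' `transformed` flag is set and negative values are permitted.
#'
#' @param data numeric array with 4 axes (radial, angle, plane, time; a
#'   singleton TOF axis is inserted) or 5 axes (radial, angle, plane, tof,
#'   time).
#' @param frame_duration_s duration of one time frame in seconds.
#' @param start_time_s acquisition time of the first frame start, seconds.
#' @param transformed has the Gaussianising transform chain been applied?
#'   Raw count series (`FALSE`) must be non-negative.
#' @param mask_applied has a low-count mask been applied?
#' @param mask optional logical array over the spatial axes (radial, angle,
#'   plane, tof); `TRUE` marks bins retained for analysis.
#'
#' @return An object of class `sinogram_series`.
#' @export
sinogram_series <- function(data, frame_duration_s = 0.5, start_time_s = 0,
                            transformed = FALSE, mask_applied = FALSE,
                            mask = NULL) {
  if (!is.array(data)) abort_ddgate("`data` must be an array.", "format")
  nd <- length(dim(data))
  if (nd == 4L) {
    # no TOF axis: promote with a singleton tof axis before time
    d <- dim(data)
    dim(data) <- c(d[1:3], 1L, d[4])
  } else if (nd != 5L) {
    abort_ddgate("`data` must have 4 or 5 axes (radial, angle, plane[, tof], time).",
                 "format")
  }
  if (dim(data)[5] < 1L) abort_ddgate("time axis must have length >= 1.", "format")
  if (!is.numeric(frame_duration_s) || frame_duration_s <= 0)
    abort_ddgate("`frame_duration_s` must be > 0.", "parameter")
  if (!transformed && any(data < 0, na.rm = TRUE))
    abort_ddgate("raw count data must be non-negative.", "format")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)[1:4]))
      abort_ddgate("`mask` shape must equal the spatial shape.", "format")
    if (!any(mask)) abort_ddgate("`mask` must retain at least one bin.", "format")
  }
  structure(
    list(data = data,
         frame_duration_s = as.numeric(frame_duration_s),
         start_time_s = as.numeric(start_time_s),
         transformed = isTRUE(transformed),
         mask_applied = isTRUE(mask_applied),
         mask = mask),
    class = "sinogram_series"
  )
}

#' @export
print.sinogram_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sinogram_series> %d x %d x %d x %d bins (radial x angle x plane x tof), %d frames @ %g s\n",
    d[1], d[2], d[3], d[4], d[5], x$frame_duration_s))
  cat(sprintf("  start %g s | transformed: %s | mask applied: %s\n",
              x$start_time_s, x$transformed, x$mask_applied))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[5]

spatial_dim <- function(series) dim(series$data)[1:4]

frame_times <- function(series) {
  # frame mid-times
  series$start_time_s + (seq_len(n_frames(series)) - 0.5) * series$frame_duration_s
}

sampling_rate <- function(series) 1 / series$frame_duration_s

# logical vector over flattened spatial bins of the active analysis support
mask_vector <- function(series) {
  nb <- prod(spatial_dim(series))
  if (!is.null(series$mask)) as.vector(series$mask) else rep(TRUE, nb)
}

# frames as a (time x bins) matrix, restricted to the active mask
frame_matrix <- function(series, bins = NULL) {
  nb <- prod(spatial_dim(series))
  m <- matrix(series$data, nrow = nb, ncol = n_frames(series))
  if (is.null(bins)) bins <- which(mask_vector(series))
  t(m[bins, , drop = FALSE])
}

subset_frames <- function(series, from, to) {
  stopifnot(from >= 1, to <= n_frames(series), from <= to)
  out <- series
  out$data <- series$data[, , , , from:to, drop = FALSE]
  out$start_time_s <- series$start_time_s + (from - 1) * series$frame_duration_s
  out
}

#' Respiratory surrogate signal
#'
#' A surrogate signal is a 1D trace tracking the respiratory cycle, sampled
#' uniformly (2 Hz by default, matching the sinogram rebinning). It is stored
#' as a tibble with columns `time_s` and `value` so it pipes directly into
#' dplyr/ggplot2; sampling metadata travel as attributes. The sign of a
#' data-driven trace is arbitrary (a principal component and its negation are
#' equally valid), which downstream comparison handles via `|r|` or explicit
#' sign alignment.
#'
#' @param values numeric vector of samples (NaN allowed as moving-window
#'   padding).
#' @param sampling_hz sampling rate in Hz.
#' @param start_time_s time of the first sample, seconds.
#' @param sign_arbitrary is the overall sign physically meaningless?
#'
#' @return A tibble of class `surrogate_signal` with columns `time_s`, `value`.
#' @export
surrogate_signal <- function(values, sampling_hz = 2, start_time_s = 0,
                             sign_arbitrary = TRUE) {
  if (!is.numeric(sampling_hz) || sampling_hz <= 0)
    abort_ddgate("`sampling_hz` must be > 0.", "parameter")
  values <- as.numeric(values)
  time_s <- start_time_s + (seq_along(values) - 1) / sampling_hz
  tibble::new_tibble(
    list(time_s = time_s, value = values),
    nrow = length(values),
    class = "surrogate_signal",
    sampling_hz = as.numeric(sampling_hz),
    start_time_s = as.numeric(start_time_s),
    sign_arbitrary = isTRUE(sign_arbitrary)
  )
}

sig_hz <- function(x) {
  hz <- attr(x, "sampling_hz")
  if (is.null(hz)) {
    dt <- diff(x$time_s)
    if (!length(dt)) abort_ddgate("cannot infer sampling rate from one sample.", "parameter")
    hz <- 1 / median(dt)
  }
  hz
}

sig_start <- function(x) {
  s <- attr(x, "start_time_s")
  if (is.null(s)) s <- x$time_s[1]
  s
}

# rebuild a surrogate_signal with new values, keeping timing metadata
sig_update <- function(x, values) {
  surrogate_signal(values, sampling_hz = sig_hz(x), start_time_s = sig_start(x),
                   sign_arbitrary = isTRUE(attr(x, "sign_arbitrary")))
}

as_signal <- function(x, sampling_hz = 2) {
  if (inherits(x, "surrogate_signal")) return(x)
  if (is.numeric(x)) return(surrogate_signal(x, sampling_hz = sampling_hz))
  if (is.data.frame(x) && all(c("time_s", "value") %in% names(x))) {
    dt <- diff(x$time_s)
    if (length(dt) && max(abs(dt - dt[1])) < 1e-9)
      return(surrogate_signal(x$value, sampling_hz = 1 / dt[1],
                              start_time_s = x$time_s[1]))
    return(resample_trace(x, sampling_hz))
  }
  abort_ddgate("cannot interpret input as a surrogate signal.", "format")
}

#' Frequency windows for component scoring
#'
#' Frequency bands on `[0, Nyquist]` partitioning the spectrum into tracer
#' kinetics (slow drift), respiration, and noise. The defaults are the
#' conventional fixed bands: 0-0.1 Hz kinetic, 0.1-0.4 Hz respiratory, and
#' 0.4-1 Hz noise at 2 Hz sampling.
#'
#' @param kinetic,respiratory,noise length-2 numeric `c(lo, hi)` in Hz.
#' @return A list of class `frequency_windows`.
#' @export
frequency_windows <- function(kinetic = c(0, 0.1), respiratory = c(0.1, 0.4),
                              noise = c(0.4, 1.0)) {
  for (w in list(kinetic, respiratory, noise)) {
    if (length(w) != 2 || !all(is.finite(w)) || w[1] < 0 || w[1] >= w[2])
      abort_ddgate("each window must satisfy 0 <= lo < hi.", "parameter")
  }
  structure(list(kinetic = as.numeric(kinetic),
                 respiratory = as.numeric(respiratory),
                 noise = as.numeric(noise)),
            class = "frequency_windows")
}

#' Sinogram-space component
#'
#' A component is a weight map over (masked) sinogram bins: a principal
#' component, or a spectral-analysis signed mask with weights in {-1, 0, +1}.
#' Applying it to a series (element-wise multiply, then sum over bins; see
#' [apply_component()]) yields a candidate surrogate signal per frame.
#'
#' @keywords internal
new_component <- function(weights, bins, spatial_dim, origin,
                          time_support, score = NA_real_, singular_value = NA_real_) {
  if (!all(is.finite(weights))) abort_ddgate("component weights must be finite.", "format")
  if (!any(weights != 0)) abort_ddgate("component must have a nonzero weight.", "format")
  structure(list(weights = as.numeric(weights),
                 bins = as.integer(bins),
                 spatial_dim = as.integer(spatial_dim),
                 origin = origin,
                 time_support = as.integer(time_support),
                 score = score,
                 singular_value = singular_value),
            class = "ddgate_component")
}

#' @export
print.ddgate_component <- function(x, ...) {
  cat(sprintf("<component:%s> %d bins, time support [%d, %d]%s\n",
              x$origin, length(x$weights), x$time_support[1], x$time_support[2],
              if (is.finite(x$score)) sprintf(", score %.4g", x$score) else ""))
  invisible(x)
}
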