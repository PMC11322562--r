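#' Read and write sinogram series containers
#'
#' The on-disk container is a single file holding the 5-axis count array and
#' all timing/processing metadata (R serialisation, version 3), so that
#' write-then-read round-trips are bit-exact. A stored 4-axis array (non-TOF
#' data) is promoted on read by inserting a singleton TOF axis.
#'
#' @param path file path.
#' @param series a [sinogram_series()].
#' @return `read_series()` returns a [sinogram_series()]; `write_series()`
#'   returns `path` invisibly.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) abort_ddgate(paste0("no such file: ", path), "io")
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "ddgate_sinogram_v1"))
    abort_ddgate("not a ddgate sinogram container.", "format")
  for (f in c("data", "frame_duration_s", "start_time_s", "transformed", "mask_applied"))
    if (is.null(obj[[f]])) abort_ddgate(paste0("missing field: ", f), "format")
  sinogram_series(obj$data,
                  frame_duration_s = obj$frame_duration_s,
                  start_time_s = obj$start_time_s,
                  transformed = obj$transformed,
                  mask_applied = obj$mask_applied,
                  mask = obj$mask)
}

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "sinogram_series"))
  obj <- list(format = "ddgate_sinogram_v1",
              data = series$data,
              frame_duration_s = series$frame_duration_s,
              start_time_s = series$start_time_s,
              transformed = series$transformed,
              mask_applied = series$mask_applied,
              mask = series$mask)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Read and write surrogate traces as delimited text
#'
#' Traces are exchanged as two-column delimited text with header
#' `time_s,value` ('.' decimal, UTF-8). On read, a trace already uniform at
#' `sampling_hz` is kept exactly; otherwise it is resampled by linear
#' interpolation onto a uniform grid (a 25 Hz optical-tracker trace becomes a
#' 2 Hz trace of length `floor(duration * 2) + 1`).
#'
#' @param path file path.
#' @param sampling_hz target sampling rate in Hz.
#' @param signal a [surrogate_signal()].
#' @return `read_trace()` returns a [surrogate_signal()]; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path, sampling_hz = 2) {
  if (!file.exists(path)) abort_ddgate(paste0("no such file: ", path), "io")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort_ddgate("trace file needs two columns (time_s, value).", "format")
  names(df)[1:2] <- c("time_s", "value")
  if (nrow(df) < 2) abort_ddgate("cannot resample a single-sample trace.", "format")
  if (any(diff(df$time_s) <= 0)) abort_ddgate("time column must be strictly increasing.", "format")
  dt <- diff(df$time_s)
  target_dt <- 1 / sampling_hz
  if (max(abs(dt - target_dt)) < 1e-9) {
    return(surrogate_signal(df$value, sampling_hz = sampling_hz,
                            start_time_s = df$time_s[1]))
  }
  resample_trace(df, sampling_hz)
}

resample_trace <- function(df, sampling_hz) {
  duration <- df$time_s[nrow(df)] - df$time_s[1]
  n_out <- floor(duration * sampling_hz) + 1
  grid <- df$time_s[1] + (seq_len(n_out) - 1) / sampling_hz
  v <- approx(df$time_s, df$value, xout = grid, rule = 2)$y
  surrogate_signal(v, sampling_hz = sampling_hz, start_time_s = df$time_s[1])
}

#' @rdname read_trace
#' @export
write_trace <- function(signal, path) {
  signal <- as_signal(signal)
  readr::write_csv(tibble::tibble(time_s = signal$time_s, value = signal$value),
                   path, progress = FALSE)
  invisible(path)
}
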