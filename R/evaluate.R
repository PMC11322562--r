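#' Align two traces and correlate over a time span
#'
#' Both traces are linearly resampled to a common 2 Hz grid over their
#' shared support. Because the sign of a data-driven trace is arbitrary,
#' the first trace is globally flipped when the full-record Pearson
#' correlation is negative (unless `align_sign = FALSE`), then the Pearson
#' correlation over `[t0, t1)` is reported. NaN samples are deleted
#' pairwise.
#'
#' @param a,b [surrogate_signal()]s (or two-column `time_s`/`value` data
#'   frames); `a` is the extracted trace, `b` the reference.
#' @param t0,t1 evaluation span in seconds (default 20-840 s, skipping the
#'   pre-injection interval).
#' @param align_sign flip `a` globally if the full-record r is negative.
#' @param sampling_hz common grid rate in Hz.
#' @return The correlation coefficient, with attribute `sign_flipped`.
#' @export
align_and_correlate <- function(a, b, t0 = 20, t1 = 840, align_sign = TRUE,
                                sampling_hz = 2) {
  g <- common_grid(a, b, sampling_hz)
  flip <- FALSE
  if (align_sign) {
    r_all <- pair_cor(g$a, g$b)
    if (!is.na(r_all) && r_all < 0) {
      g$a <- -g$a
      flip <- TRUE
    }
  }
  sel <- g$t >= t0 & g$t < t1
  r <- pair_cor(g$a[sel], g$b[sel])
  if (is.na(r)) abort_ddgate("undefined correlation on the requested span.", "degenerate")
  structure(r, sign_flipped = flip)
}

common_grid <- function(a, b, sampling_hz = 2) {
  a <- as_signal(a); b <- as_signal(b)
  t0 <- max(min(a$time_s), min(b$time_s))
  t1 <- min(max(a$time_s), max(b$time_s))
  n <- floor((t1 - t0) * sampling_hz) + 1
  if (n < 8) abort_ddgate("need >= 8 overlapping samples.", "degenerate")
  t <- t0 + (seq_len(n) - 1) / sampling_hz
  interp <- function(s) {
    ok <- is.finite(s$value)
    if (sum(ok) < 2) return(rep(NA_real_, n))
    v <- approx(s$time_s[ok], s$value[ok], xout = t)$y
    # do not extrapolate across non-finite stretches; keep NA outside support
    v
  }
  list(t = t, a = interp(a), b = interp(b))
}

pair_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 8) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Correlation in contiguous time intervals
#'
#' How early a method starts tracking respiration is visible from the
#' correlation computed in short contiguous bins (20 s by default, i.e. 40
#' samples at 2 Hz) across the early acquisition. The global sign alignment
#' from the full record applies to every bin; a bin with fewer than 8 valid
#' sample pairs reports `NA`.
#'
#' @inheritParams align_and_correlate
#' @param width_s bin width in seconds.
#' @return A tibble with columns `t0`, `t1`, `r`, `n`.
#' @export
windowed_correlation <- function(a, b, width_s = 20, t0 = 20, t1 = 140,
                                 align_sign = TRUE, sampling_hz = 2) {
  g <- common_grid(a, b, sampling_hz)
  if (align_sign) {
    r_all <- pair_cor(g$a, g$b)
    if (!is.na(r_all) && r_all < 0) g$a <- -g$a
  }
  starts <- seq(t0, t1 - width_s, by = width_s)
  purrr::map_dfr(starts, function(s) {
    sel <- g$t >= s & g$t < s + width_s
    ok <- sel & is.finite(g$a) & is.finite(g$b)
    r <- if (sum(ok) < 8) NA_real_ else pair_cor(g$a[sel], g$b[sel])
    tibble::tibble(t0 = s, t1 = s + width_s, r = r, n = sum(ok))
  })
}

#' Evaluation report for one or more methods
#'
#' For every extracted trace, computes the full-record correlation with the
#' reference (20-840 s by default), the early-window correlation
#' (20-140 s), and the 20 s interval correlations, after global sign
#' alignment. `tidy()` returns the per-interval rows, `glance()` the
#' per-method summary.
#'
#' @param method_traces named list of [surrogate_signal()]s.
#' @param reference the reference [surrogate_signal()] (ground truth or an
#'   external device trace).
#' @param t_full,t_early evaluation spans `c(t0, t1)` in seconds.
#' @param width_s interval width for the windowed correlation.
#' @return An object of class `ddgate_eval`.
#' @export
make_report <- function(method_traces, reference,
                        t_full = c(20, 840), t_early = c(20, 140),
                        width_s = 20) {
  if (!length(method_traces)) abort_ddgate("empty method list.", "parameter")
  if (is.null(names(method_traces)) || any(!nzchar(names(method_traces))))
    abort_ddgate("`method_traces` must be a named list.", "parameter")
  summaries <- purrr::imap_dfr(method_traces, function(trace, nm) {
    rf <- align_and_correlate(trace, reference, t_full[1], t_full[2])
    re <- align_and_correlate(trace, reference, t_early[1], t_early[2])
    tibble::tibble(method = nm,
                   r_full = as.numeric(rf),
                   r_early = as.numeric(re),
                   sign_flipped = attr(rf, "sign_flipped"))
  })
  intervals <- purrr::imap_dfr(method_traces, function(trace, nm) {
    dplyr::mutate(
      windowed_correlation(trace, reference, width_s, t_early[1], t_early[2]),
      method = nm, .before = 1)
  })
  structure(list(summary = summaries, intervals = intervals,
                 t_full = t_full, t_early = t_early, width_s = width_s),
            class = "ddgate_eval")
}

#' @export
print.ddgate_eval <- function(x, ...) {
  cat(sprintf("<ddgate_eval> correlation with reference (full %g-%g s, early %g-%g s)\n",
              x$t_full[1], x$t_full[2], x$t_early[1], x$t_early[2]))
  print(x$summary)
  invisible(x)
}

#' @rdname make_report
#' @param x a `ddgate_eval` report.
#' @param ... unused.
#' @export
tidy.ddgate_eval <- function(x, ...) x$intervals

#' @rdname make_report
#' @export
glance.ddgate_eval <- function(x, ...) x$summary

#' Serialise an evaluation report to JSON
#'
#' Deterministic serialisation: fixed field order and 12 significant
#' digits, so identical inputs produce byte-identical files.
#'
#' @param report a `ddgate_eval`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ddgate_eval"))
  obj <- list(
    t_full = report$t_full,
    t_early = report$t_early,
    width_s = report$width_s,
    summary = report$summary,
    intervals = report$intervals
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = 12,
                       na = "null", pretty = TRUE)
  invisible(path)
}
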