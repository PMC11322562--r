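#' Plot a surrogate signal
#'
#' @param object a [surrogate_signal()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.surrogate_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "surrogate amplitude (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot per-interval correlations of an evaluation report
#'
#' Step plot of the 20 s interval correlations per method, mirroring how
#' early-signal quality is usually compared.
#'
#' @param object a `ddgate_eval` report.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ddgate_eval <- function(object, ...) {
  ggplot2::ggplot(object$intervals,
                  ggplot2::aes(x = .data$t0, y = .data$r,
                               colour = .data$method)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "interval start (s)", y = "Pearson r",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Compare extracted traces against a reference
#'
#' Z-normalises each trace for display only (correlation is computed on raw
#' values elsewhere) and overlays them with the reference over a time span.
#'
#' @param traces named list of [surrogate_signal()]s.
#' @param reference the reference [surrogate_signal()].
#' @param t0,t1 display span in seconds.
#' @return A ggplot.
#' @export
plot_trace_comparison <- function(traces, reference, t0 = 20, t1 = 140) {
  znorm <- function(df, nm) {
    sel <- df$time_s >= t0 & df$time_s < t1 & is.finite(df$value)
    v <- df$value[sel]
    tibble::tibble(time_s = df$time_s[sel],
                   value = if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v),
                   trace = nm)
  }
  dat <- dplyr::bind_rows(
    c(purrr::imap(traces, znorm), list(znorm(as_signal(reference), "reference"))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$value,
                                    colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "z-scored amplitude", colour = NULL) +
    ggplot2::theme_minimal()
}
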