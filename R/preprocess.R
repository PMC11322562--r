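#' Freeman-Tukey variance-stabilising transform
#'
#' Applies `X -> sqrt(X + 1) + sqrt(X)` element-wise. For Poisson counts this
#' stabilises the variance near 1 over a wide range of means, the first step
#' in Gaussianising raw sinogram counts before PCA.
#'
#' @param x a [sinogram_series()] of raw counts, or a non-negative numeric
#'   vector/array.
#' @return Same type as the input, transformed element-wise.
#' @export
freeman_tukey <- function(x) {
  if (inherits(x, "sinogram_series")) {
    out <- x
    out$data <- freeman_tukey(x$data)
    return(out)
  }
  if (any(x < 0, na.rm = TRUE))
    abort_ddgate("Freeman-Tukey requires non-negative input.", "domain")
  sqrt(x + 1) + sqrt(x)
}

#' Yeo-Johnson power transform
#'
#' The four-branch power transform
#' \deqn{YJ_\lambda(x) = ((x+1)^\lambda - 1)/\lambda} for \eqn{x \ge 0,
#' \lambda \ne 0}; \eqn{\log(x+1)} for \eqn{x \ge 0, \lambda = 0};
#' \eqn{-((-x+1)^{2-\lambda} - 1)/(2-\lambda)} for \eqn{x < 0, \lambda \ne 2};
#' and \eqn{-\log(-x+1)} for \eqn{x < 0, \lambda = 2}. Applied after
#' Freeman-Tukey it brings the count distribution closer to Gaussian, which
#' PCA implicitly assumes. On a series it sets the `transformed` flag.
#'
#' @param x a [sinogram_series()] or numeric vector/array.
#' @param lambda the power parameter \eqn{\lambda} (finite), or a fitted
#'   [fit_lambda()] result.
#' @return Same type as the input.
#' @export
yeo_johnson <- function(x, lambda) {
  if (is.list(lambda) && !is.null(lambda$lam)) lambda <- lambda$lam
  if (!is.finite(lambda)) abort_ddgate("`lambda` must be finite.", "parameter")
  if (inherits(x, "sinogram_series")) {
    out <- x
    out$data <- yeo_johnson(x$data, lambda)
    out$transformed <- TRUE
    return(out)
  }
  out <- x
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (lambda != 0) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log(x[pos] + 1)
  }
  if (lambda != 2) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log(-x[neg] + 1)
  }
  out
}

#' Fit the Yeo-Johnson power parameter
#'
#' Grid search over \eqn{\lambda \in [-2, 2]} (step 0.05) minimising the
#' Kullback-Leibler divergence from the empirical distribution of the
#' transformed values (histogram with Freedman-Diaconis bins) to the Gaussian
#' with matched mean and variance. A single lambda is fitted from all values,
#' subsampled deterministically for speed on large series.
#'
#' @param x a [sinogram_series()] or numeric vector/array with at least 100
#'   finite values.
#' @param grid candidate lambda values.
#' @param max_values deterministic subsample cap.
#' @return A list of class `yj_params` with `lam`, `fit_grid`,
#'   `fit_objective_value` and the per-lambda objective.
#' @export
fit_lambda <- function(x, grid = seq(-2, 2, by = 0.05), max_values = 2e5) {
  if (inherits(x, "sinogram_series")) x <- x$data
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) < 100) abort_ddgate("need at least 100 finite values.", "degenerate")
  if (length(v) > max_values) {
    v <- v[seq(1, length(v), length.out = max_values)]
  }
  if (max(v) - min(v) < .Machine$double.eps * 100)
    abort_ddgate("constant data: lambda is unidentifiable.", "degenerate")
  obj <- vapply(grid, function(l) kld_to_gaussian(yeo_johnson(v, l)), numeric(1))
  best <- which.min(obj)
  structure(list(lam = grid[best],
                 fit_grid = grid,
                 fit_objective_value = obj[best],
                 objective = obj),
            class = "yj_params")
}

#' Inverse Yeo-Johnson transform
#'
#' Maps a transformed value back through the four-branch transform
#' (`yeo_johnson(yeo_johnson_inverse(z, l), l) == z`). Useful for
#' constructing data that is exactly Gaussian under a known lambda.
#'
#' @param z numeric vector. For `lambda < 0` the forward transform is bounded
#'   above by `-1/lambda` (and for `lambda > 2` bounded below by
#'   `1/(2 - lambda)`); values outside the attainable range return `NaN`.
#' @param lambda the power parameter.
#' @return Numeric vector.
#' @export
yeo_johnson_inverse <- function(z, lambda) {
  out <- z
  pos <- !is.na(z) & z >= 0
  neg <- !is.na(z) & z < 0
  if (lambda != 0) {
    b <- z[pos] * lambda + 1
    out[pos] <- ifelse(b > 0, b^(1 / lambda) - 1, NaN)
  } else {
    out[pos] <- expm1(z[pos])
  }
  if (lambda != 2) {
    b <- 1 - (2 - lambda) * z[neg]
    out[neg] <- ifelse(b > 0, 1 - b^(1 / (2 - lambda)), NaN)
  } else {
    out[neg] <- 1 - exp(-z[neg])
  }
  out
}

# KL divergence from the empirical histogram to the matched Gaussian.
# The data are standardised first (KLD is affine-invariant, and a common
# scale keeps the bin count comparable across lambda values); the
# Freedman-Diaconis width is floored at the typical spacing of distinct
# values so discrete-valued data (transformed counts) do not produce a comb
# histogram with a spuriously large divergence.
kld_to_gaussian <- function(y) {
  n <- length(y)
  iqr <- stats::IQR(y)
  if (iqr <= 0 || sd(y) == 0) return(Inf)
  y <- (y - mean(y)) / sd(y)
  h <- 2 * stats::IQR(y) * n^(-1 / 3)
  u <- sort(unique(round(y, 10)))
  if (length(u) > 1) {
    h <- max(h, 2.5 * median(diff(u)))
  }
  breaks <- seq(min(y) - h / 2, max(y) + h, by = h)
  counts <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  p <- counts / n
  q <- pmax(diff(pnorm(breaks)), 1e-12)
  keep <- p > 0
  # Miller-Madow correction for the plug-in entropy bias
  sum(p[keep] * log(p[keep] / q[keep])) - (sum(keep) - 1) / (2 * n)
}

#' Rebin the time axis by summing consecutive frames
#'
#' Sums groups of consecutive raw frames so the output sampling rate equals
#' `target_hz` (2 Hz by default, fast enough for respiration but suppressing
#' cardiac frequencies). Counts are conserved exactly; the frame ratio must
#' be an integer. A trailing incomplete group is dropped with a warning.
#'
#' @param series a [sinogram_series()].
#' @param target_hz target sampling rate in Hz.
#' @return A [sinogram_series()].
#' @export
rebin_time <- function(series, target_hz = 2) {
  stopifnot(inherits(series, "sinogram_series"))
  if (target_hz > 1 / series$frame_duration_s + 1e-9)
    abort_ddgate("`target_hz` exceeds the native frame rate.", "parameter")
  ratio <- (1 / target_hz) / series$frame_duration_s
  if (abs(ratio - round(ratio)) > 1e-9)
    abort_ddgate("frame ratio must be an integer.", "parameter")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(series)
  nt <- n_frames(series)
  n_out <- nt %/% ratio
  if (n_out * ratio < nt)
    warn(sprintf("dropping %d trailing frame(s) in rebinning.", nt - n_out * ratio))
  nb <- prod(spatial_dim(series))
  m <- matrix(series$data, nrow = nb)[, seq_len(n_out * ratio), drop = FALSE]
  dim(m) <- c(nb * n_out, ratio)
  summed <- rowSums(m)
  out <- series
  out$data <- array(summed, dim = c(spatial_dim(series), n_out))
  out$frame_duration_s <- series$frame_duration_s * ratio
  out
}

#' Low-count sinogram mask
#'
#' The mask removes the bottom fraction of sinogram values, which are mostly
#' background noise. The threshold is the given percentile of the time-mean
#' sinogram (a time-collapsed statistic, so the same mask applies to every
#' frame); bins strictly above it are retained. `percentile = 0` keeps all
#' bins, and a degenerate all-equal sinogram falls back to keeping all bins
#' with a warning.
#'
#' @param series a [sinogram_series()].
#' @param percentile fraction of values to drop (default 0.05).
#' @param mask a mask from `compute_mask()`.
#' @return `compute_mask()` returns a list of class `mask_spec` with
#'   `percentile`, `threshold` and the logical `mask` array;
#'   `apply_mask()` returns the series with excluded bins zeroed and the mask
#'   recorded.
#' @export
compute_mask <- function(series, percentile = 0.05) {
  stopifnot(inherits(series, "sinogram_series"))
  if (percentile < 0 || percentile >= 1)
    abort_ddgate("`percentile` must be in [0, 1).", "parameter")
  nb <- prod(spatial_dim(series))
  mean_sino <- rowMeans(matrix(series$data, nrow = nb))
  if (all(mean_sino == 0))
    abort_ddgate("all-zero series: mask is undefined.", "degenerate")
  if (percentile == 0) {
    mask <- rep(TRUE, nb)
    threshold <- -Inf
  } else {
    threshold <- as.numeric(quantile(mean_sino, percentile))
    mask <- mean_sino > threshold
    if (!any(mask)) {
      warn("mask threshold excludes every bin; keeping all bins.")
      mask <- rep(TRUE, nb)
    }
  }
  structure(list(percentile = percentile,
                 threshold = threshold,
                 mask = array(mask, dim = spatial_dim(series))),
            class = "mask_spec")
}

#' @rdname compute_mask
#' @export
apply_mask <- function(series, mask) {
  stopifnot(inherits(series, "sinogram_series"))
  m <- if (inherits(mask, "mask_spec")) mask$mask else mask
  if (!identical(dim(m), as.integer(spatial_dim(series))) &&
      !identical(dim(m), spatial_dim(series)))
    abort_ddgate("mask shape must equal the spatial shape.", "format")
  out <- series
  nb <- prod(spatial_dim(series))
  dat <- matrix(out$data, nrow = nb)
  dat[!as.vector(m), ] <- 0
  out$data <- array(dat, dim = dim(series$data))
  out$mask <- array(as.logical(m), dim = spatial_dim(series))
  out$mask_applied <- TRUE
  out
}

#' Spatial Gaussian smoothing and linear-interpolation downsampling
#'
#' Per frame, applies a separable Gaussian over the (radial, angle, plane)
#' axes with reflect boundary handling, then resamples each spatial axis by
#' linear interpolation with the given per-axis factor. The TOF axis is never
#' smoothed or resampled. Smoothing reduces noise ahead of PCA/SAM; the
#' downsampling keeps only the resolution needed after smoothing, cutting
#' memory and compute.
#'
#' @param series a [sinogram_series()].
#' @param sigmas Gaussian standard deviations in bins for (radial, angle,
#'   plane); 0 skips an axis.
#' @param downsample_factor per-axis shrink factors (>= 1) for (radial,
#'   angle, plane).
#' @return A [sinogram_series()].
#' @export
smooth_and_downsample <- function(series, sigmas = c(1.0, 0.5, 2.0),
                                  downsample_factor = c(2, 1, 2)) {
  stopifnot(inherits(series, "sinogram_series"))
  if (any(sigmas < 0)) abort_ddgate("`sigmas` must be >= 0.", "parameter")
  if (any(downsample_factor < 1)) abort_ddgate("factors must be >= 1.", "parameter")
  d <- dim(series$data)
  if (any(downsample_factor > d[1:3]))
    abort_ddgate("downsample factor exceeds axis length.", "parameter")
  x <- series$data
  for (ax in 1:3) {
    if (sigmas[ax] > 0) x <- convolve_axis(x, gauss_kernel(sigmas[ax]), ax)
  }
  for (ax in 1:3) {
    if (downsample_factor[ax] > 1) x <- resample_axis(x, downsample_factor[ax], ax)
  }
  out <- series
  out$data <- x
  if (!is.null(series$mask)) {
    m <- series$mask * 1
    dim(m) <- c(dim(series$mask), 1L)
    for (ax in 1:3) {
      if (downsample_factor[ax] > 1) m <- resample_axis(m, downsample_factor[ax], ax)
    }
    out$mask <- array(m >= 0.5, dim = dim(x)[1:4])
    if (!any(out$mask)) out$mask <- array(TRUE, dim = dim(x)[1:4])
  }
  out
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# separable convolution along axis `ax` of a 5-axis array, reflect boundary
convolve_axis <- function(x, kernel, ax) {
  d <- dim(x)
  perm <- c(ax, setdiff(seq_along(d), ax))
  xp <- aperm(x, perm)
  n <- d[ax]
  m <- matrix(xp, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  idx <- reflect_index(n, r)
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# index vector implementing edge-repeating reflection padding
reflect_index <- function(n, r) {
  idx <- seq_len(n)
  left <- pmin(pmax(rev(seq_len(r)), 1L), n)
  right <- pmin(pmax(n - seq_len(r) + 1L, 1L), n)
  c(left, idx, right)
}

# linear-interpolation resampling along axis `ax` by shrink factor `f`
resample_axis <- function(x, f, ax) {
  d <- dim(x)
  n <- d[ax]
  m_out <- max(2L, ceiling(n / f))
  pos <- seq(1, n, length.out = m_out)
  lo <- floor(pos); hi <- pmin(lo + 1L, n); w <- pos - lo
  perm <- c(ax, setdiff(seq_along(d), ax))
  xp <- aperm(x, perm)
  mat <- matrix(xp, nrow = n)
  out <- (1 - w) * mat[lo, , drop = FALSE] + w * mat[hi, , drop = FALSE]
  dim(out) <- c(m_out, d[perm][-1])
  aperm(out, order(perm))
}

#' Full pre-processing chain
#'
#' Rebins the time axis to `target_hz`, Gaussianises the counts
#' (Freeman-Tukey then Yeo-Johnson with a fitted or given lambda), applies
#' the low-count mask, then smooths and downsamples spatially. The default
#' order is transforms, mask, smoothing; the mask is carried through the
#' downsampling by nearest-neighbour resampling.
#'
#' @param series a raw-count [sinogram_series()].
#' @param target_hz temporal sampling rate, Hz.
#' @param lambda `"fit"` to fit the Yeo-Johnson lambda from the data, or a
#'   numeric value.
#' @param mask_percentile bottom fraction of values removed by the mask; `NA`
#'   skips masking.
#' @param sigmas,downsample_factor see [smooth_and_downsample()].
#' @return A preprocessed [sinogram_series()], with attributes `lambda` and
#'   `mask_threshold`.
#' @export
preprocess_series <- function(series, target_hz = 2, lambda = "fit",
                              mask_percentile = 0.05,
                              sigmas = c(1.0, 0.5, 2.0),
                              downsample_factor = c(2, 1, 2)) {
  s <- rebin_time(series, target_hz)
  s <- freeman_tukey(s)
  lam <- if (identical(lambda, "fit")) fit_lambda(s)$lam else as.numeric(lambda)
  s <- yeo_johnson(s, lam)
  thr <- NA_real_
  if (!is.na(mask_percentile) && mask_percentile > 0) {
    msk <- compute_mask(s, mask_percentile)
    thr <- msk$threshold
    s <- apply_mask(s, msk)
  }
  s <- smooth_and_downsample(s, sigmas = sigmas,
                             downsample_factor = downsample_factor)
  attr(s, "lambda") <- lam
  attr(s, "mask_threshold") <- thr
  s
}
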