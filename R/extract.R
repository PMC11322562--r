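#' Principal component decomposition of a sinogram series
#'
#' Frames are flattened over the masked bins, the per-bin time mean is
#' removed, and the (time x bins) matrix is decomposed by SVD. The returned
#' components are the leading right-singular vectors: mutually orthonormal
#' weight maps over sinogram bins, ordered by explained variance. Components
#' beyond the numerical rank are dropped with a warning. The sign convention
#' is deterministic (the largest-magnitude weight is positive); the physical
#' sign of a component remains arbitrary.
#'
#' @param series a preprocessed [sinogram_series()].
#' @param n_components maximum number of components to return.
#' @param time_support optional `c(from, to)` frame range to decompose.
#' @return A list of components.
#' @export
pca_decompose <- function(series, n_components = 10, time_support = NULL) {
  stopifnot(inherits(series, "sinogram_series"))
  sub <- series
  if (!is.null(time_support)) sub <- subset_frames(series, time_support[1], time_support[2])
  if (is.null(time_support)) time_support <- c(1L, n_frames(series))
  if (n_frames(sub) < 2) abort_ddgate("need at least 2 frames for PCA.", "degenerate")
  bins <- which(mask_vector(sub))
  X <- frame_matrix(sub, bins)
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = 0)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > max(tol, 0))
  if (rank == 0) abort_ddgate("constant series: PCA is degenerate.", "degenerate")
  if (n_components > rank) {
    warn(sprintf("requested %d components but rank is %d; returning %d.",
                 n_components, rank, rank))
  }
  k <- min(n_components, rank)
  lapply(seq_len(k), function(j) {
    w <- sv$v[, j]
    if (w[which.max(abs(w))] < 0) w <- -w
    new_component(w, bins, spatial_dim(series), origin = "pca",
                  time_support = time_support, singular_value = sv$d[j])
  })
}

#' Apply a component to a series
#'
#' The surrogate signal of a component is its frame-wise inner product with
#' the data: `W_t = sum_bins PC * S_t` (element-wise multiply, then sum).
#' Linearity in the component carries over to the signal.
#'
#' @param component a component from [pca_decompose()] or
#'   [sam_signed_mask()], or a raw weight array over all spatial bins.
#' @param series a [sinogram_series()].
#' @return A [surrogate_signal()] at the series' sampling rate.
#' @export
apply_component <- function(component, series) {
  stopifnot(inherits(series, "sinogram_series"))
  if (inherits(component, "ddgate_component")) {
    if (!identical(component$spatial_dim, as.integer(spatial_dim(series))))
      abort_ddgate("component and series shapes are incompatible.", "format")
    X <- frame_matrix(series, component$bins)
    w <- component$weights
  } else {
    w <- as.numeric(component)
    nb <- prod(spatial_dim(series))
    if (length(w) != nb) abort_ddgate("weight length must match bin count.", "format")
    X <- frame_matrix(series, seq_len(nb))
  }
  surrogate_signal(drop(X %*% w),
                   sampling_hz = sampling_rate(series),
                   start_time_s = series$start_time_s,
                   sign_arbitrary = TRUE)
}

#' One-sided magnitude spectrum of a surrogate signal
#'
#' Removes the mean, applies the FFT and returns the magnitude on the
#' one-sided frequency grid `[0, Nyquist]`. All component scoring operates
#' on this spectrum.
#'
#' @param signal a [surrogate_signal()] (or numeric vector at 2 Hz).
#' @return A tibble of class `ddgate_psd` with columns `freq_hz`, `power`.
#' @export
compute_psd <- function(signal) {
  signal <- as_signal(signal)
  x <- signal$value
  if (all(!is.finite(x))) abort_ddgate("all-NaN signal.", "degenerate")
  if (sum(is.finite(x)) < 8) abort_ddgate("need at least 8 samples.", "degenerate")
  mu <- mean(x[is.finite(x)])
  x <- ifelse(is.finite(x), x - mu, 0)
  n <- length(x)
  hz <- sig_hz(signal)
  m <- floor(n / 2) + 1
  power <- Mod(fft(x))[seq_len(m)]
  tibble::new_tibble(list(freq_hz = (seq_len(m) - 1) * hz / n, power = power),
                     nrow = m, class = "ddgate_psd")
}

# mean spectral magnitude inside a band; windows are (lo, hi], closed at 0
band_mean <- function(psd, window) {
  sel <- if (window[1] <= 0) psd$freq_hz >= 0 & psd$freq_hz <= window[2]
         else psd$freq_hz > window[1] & psd$freq_hz <= window[2]
  if (!any(sel)) abort_ddgate("empty frequency window.", "parameter")
  mean(psd$power[sel])
}

#' Conventional respiratory score
#'
#' The mean spectral magnitude within the respiratory frequency window.
#' Among candidate components, the one whose signal maximises this score is
#' taken as the surrogate.
#'
#' @param signal a [surrogate_signal()].
#' @param window `c(lo, hi)` respiratory band in Hz.
#' @return A single score (scales linearly with signal amplitude).
#' @export
conventional_score <- function(signal, window = c(0.1, 0.4)) {
  band_mean(compute_psd(signal), window)
}

#' Frequency-ratio respiratory score
#'
#' Extends the conventional score with the kinetic and noise bands:
#' `(resp / kinetic) * (resp / noise)` of the mean spectral magnitudes. The
#' ratios make the score invariant to positive rescaling of the signal; a
#' zero kinetic or noise band returns `+Inf` as a documented sentinel.
#'
#' @param signal a [surrogate_signal()].
#' @param windows a [frequency_windows()].
#' @return A single non-negative score (possibly `+Inf`).
#' @export
frequency_score <- function(signal, windows = frequency_windows()) {
  psd <- compute_psd(signal)
  r <- band_mean(psd, windows$respiratory)
  k <- band_mean(psd, windows$kinetic)
  nz <- band_mean(psd, windows$noise)
  if (k == 0 || nz == 0) return(Inf)
  (r / k) * (r / nz)
}

#' Estimate the respiratory frequency window from an initial signal
#'
#' Fixed 0.1-0.4 Hz bands are too wide for slow breathers and can mislabel
#' noise, so the respiratory window is adapted to the data: the centre is
#' the power-weighted mean frequency (spectral centroid) of the initial
#' signal's spectrum, and each bound sits half a power-weighted standard
#' deviation away (a full standard deviation between the bounds). The
#' kinetic window is everything below, the noise window everything above.
#'
#' @param initial a [surrogate_signal()] with at least 64 samples, typically
#'   from [late_time_extract()].
#' @param min_width_hz floor on the half-width to keep the window non-empty.
#' @return A [frequency_windows()].
#' @export
estimate_resp_window <- function(initial, min_width_hz = 0.02) {
  initial <- as_signal(initial)
  if (sum(is.finite(initial$value)) < 64)
    abort_ddgate("need at least 64 samples to estimate the window.", "degenerate")
  psd <- compute_psd(initial)
  nyq <- max(psd$freq_hz)
  # moments on the noise-floor-subtracted spectrum: the broadband floor of a
  # low-count signal would otherwise drag the centroid toward Nyquist/2.
  # White-noise magnitudes are Rayleigh distributed, so the floor is set at
  # the Rayleigh 95% quantile with sigma estimated robustly from the median;
  # the subtraction is frequency-symmetric, leaving flat-spectrum moments
  # unchanged in expectation.
  sigma <- median(psd$power) / sqrt(2 * log(2))
  p <- pmax(psd$power - sigma * sqrt(-2 * log(0.05)), 0)
  tot <- sum(p)
  if (tot <= 0 || nrow(psd) < 3) {
    warn("degenerate spectrum; falling back to default windows.")
    return(frequency_windows())
  }
  centre <- sum(psd$freq_hz * p) / tot
  spread <- sqrt(sum(p * (psd$freq_hz - centre)^2) / tot)
  hw <- max(0.5 * spread, min_width_hz)
  # keep non-trivial kinetic and noise bands on either side
  lo <- max(centre - hw, 0.02)
  hi <- min(centre + hw, nyq - 0.02)
  if (lo >= hi) {
    warn("degenerate spectrum; falling back to default windows.")
    return(frequency_windows())
  }
  frequency_windows(kinetic = c(0, lo), respiratory = c(lo, hi),
                    noise = c(hi, nyq))
}

#' Conventional PCA extraction
#'
#' PCA on the whole series in one go, as for a static acquisition: the top
#' `n_components` components are scored by [conventional_score()] on their
#' signals and the best-scoring signal is returned. On dynamic data the
#' early tracer kinetics dominate the variance, which is what the other
#' extractors address.
#'
#' @param series a preprocessed [sinogram_series()].
#' @param n_components number of candidate components.
#' @param resp_window respiratory band for scoring, Hz.
#' @return A [surrogate_signal()]; the winning component and score are
#'   attached as attributes `component` and `score`.
#' @export
conventional_extract <- function(series, n_components = 10,
                                 resp_window = c(0.1, 0.4)) {
  comps <- pca_decompose(series, n_components)
  sigs <- lapply(comps, apply_component, series = series)
  scores <- vapply(sigs, conventional_score, numeric(1), window = resp_window)
  best <- which.max(scores)
  out <- sigs[[best]]
  comps[[best]]$score <- scores[best]
  attr(out, "component") <- comps[[best]]
  attr(out, "score") <- scores[best]
  out
}

#' Spectral-analysis signed mask
#'
#' Per-bin spectral analysis: a bin experiencing respiratory motion shows a
#' peak in its TAC spectrum at the breathing frequency. Bins whose mean
#' in-band spectral power exceeds `alpha` times their mean out-of-band power
#' are included. Because opposite edges of a moving structure oscillate in
#' antiphase, each included bin gets sign +1 or -1 by correlating its TAC
#' with the running signed-mean TAC of already-included bins (seeded by the
#' strongest bin). The result is a component with weights in {-1, 0, +1}.
#'
#' @param series a preprocessed [sinogram_series()] with >= 64 frames.
#' @param resp_window `c(lo, hi)` respiratory band in Hz.
#' @param alpha inclusion threshold on the in/out band power ratio.
#' @return A component with origin `"sam"`.
#' @export
sam_signed_mask <- function(series, resp_window = c(0.1, 0.4), alpha = 2) {
  stopifnot(inherits(series, "sinogram_series"))
  if (n_frames(series) < 64) abort_ddgate("need at least 64 frames for SAM.", "degenerate")
  bins <- which(mask_vector(series))
  X <- frame_matrix(series, bins)              # time x bins
  Xc <- sweep(X, 2, colMeans(X))
  n <- nrow(Xc)
  hz <- sampling_rate(series)
  m <- floor(n / 2) + 1
  freqs <- (seq_len(m) - 1) * hz / n
  P <- Mod(stats::mvfft(Xc))[seq_len(m), , drop = FALSE]
  in_band <- freqs > resp_window[1] & freqs <= resp_window[2]
  out_band <- !in_band & freqs > 0
  if (!any(in_band) || !any(out_band))
    abort_ddgate("respiratory band is empty at this record length.", "parameter")
  p_in <- colMeans(P[in_band, , drop = FALSE])
  p_out <- colMeans(P[out_band, , drop = FALSE])
  include <- p_in > alpha * p_out
  if (!any(include)) abort_ddgate("no bin passes the spectral criterion.", "empty_mask")
  ord <- order(p_in, decreasing = TRUE)
  ord <- ord[include[ord]]
  signs <- numeric(ncol(Xc))
  signs[ord[1]] <- 1
  ref <- Xc[, ord[1]]
  for (b in ord[-1]) {
    s <- suppressWarnings(cor(Xc[, b], ref))
    s <- if (is.na(s) || s >= 0) 1 else -1
    signs[b] <- s
    ref <- ref + s * Xc[, b]
  }
  keep <- signs != 0
  new_component(signs[keep], bins[keep], spatial_dim(series), origin = "sam",
                time_support = c(1L, n_frames(series)))
}

#' Moving-window schedule
#'
#' Start indices and window lengths for the moving-window extractor: each
#' window overlaps the previous by half its length, small windows early in
#' the acquisition (where kinetics are most severe) and longer ones later
#' (for noise reduction). Window sizes are `early_s` seconds before the
#' late-time cutoff and grow linearly to `late_s` at the end of the record;
#' the final window is re-anchored to end exactly at the last frame.
#'
#' @param n_frames number of frames in the series.
#' @param sampling_hz series sampling rate, Hz.
#' @param early_s,late_s window lengths in seconds.
#' @param cutoff_fraction fraction of the record where windows start growing.
#' @return A tibble with columns `start`, `size` (frames, 1-based).
#' @export
window_schedule <- function(n_frames, sampling_hz = 2, early_s = 60,
                            late_s = 120, cutoff_fraction = 0.62) {
  size_at <- function(i) {
    cut <- cutoff_fraction * n_frames
    s <- if (i <= cut || n_frames <= cut) early_s
         else early_s + (late_s - early_s) * (i - cut) / (n_frames - cut)
    max(8L, 2L * round(s * sampling_hz / 2))  # even, >= 8 frames
  }
  starts <- integer(0); sizes <- integer(0)
  i <- 1L
  repeat {
    size <- size_at(i)
    if (i + size - 1L > n_frames) {
      i <- max(1L, n_frames - size + 1L)   # tail clamp
      starts <- c(starts, i); sizes <- c(sizes, min(size, n_frames))
      break
    }
    starts <- c(starts, i); sizes <- c(sizes, size)
    i <- i + size %/% 2L
  }
  tibble::tibble(start = starts, size = sizes)
}

#' Moving-window extraction
#'
#' Applies the extraction independently in each window of the schedule (for
#' the PCA engine, the window's components are scored by
#' [conventional_score()] and the best is kept, as in the whole-record
#' method; the SAM engine uses the window's signed mask), NaN-pads each
#' window signal to the full record, flips a window's sign when its
#' correlation with the previous window's signal over their overlap is
#' negative (the sign of each window is arbitrary), and averages the padded
#' signals ignoring NaNs.
#'
#' @param series a preprocessed [sinogram_series()].
#' @param schedule a tibble from [window_schedule()]; `NULL` for the default.
#' @param engine `"pca"` or `"sam"`.
#' @param resp_window respiratory band (Hz) for per-window scoring (PCA) or
#'   bin selection (SAM).
#' @param n_components candidate components per window (PCA engine).
#' @param normalize z-score each window signal before averaging. Window
#'   signal amplitudes scale with the window's data variance, so raw
#'   averaging lets high-variance (early, kinetic-dominated) windows swamp
#'   their neighbours in the overlap mean; normalisation weights windows
#'   equally.
#' @return A [surrogate_signal()].
#' @export
moving_window_extract <- function(series, schedule = NULL,
                                  engine = c("pca", "sam"),
                                  resp_window = c(0.1, 0.4),
                                  n_components = 10,
                                  normalize = TRUE) {
  engine <- match.arg(engine)
  nt <- n_frames(series)
  if (is.null(schedule))
    schedule <- window_schedule(nt, sampling_rate(series))
  if (any(schedule$size < 8)) abort_ddgate("each window needs >= 8 frames.", "parameter")
  signals <- list()
  last <- NULL
  for (w in seq_len(nrow(schedule))) {
    from <- schedule$start[w]
    to <- min(from + schedule$size[w] - 1L, nt)
    seg <- subset_frames(series, from, to)
    sig <- tryCatch({
      if (engine == "pca") {
        comps <- suppressWarnings(pca_decompose(seg, n_components))
        cand <- lapply(comps, function(cp) apply_component(cp, seg)$value)
        sc <- vapply(cand, function(v)
          conventional_score(surrogate_signal(v, sampling_rate(seg)),
                             resp_window), numeric(1))
        cand[[which.max(sc)]]
      } else {
        comp <- sam_signed_mask(seg, resp_window)
        apply_component(comp, seg)$value
      }
    }, ddgate_error = function(e) {
      warn(sprintf("window %d (frames %d-%d) skipped: %s", w, from, to,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(sig)) next
    if (normalize && sd(sig) > 0) sig <- (sig - mean(sig)) / sd(sig)
    padded <- rep(NA_real_, nt)
    padded[from:to] <- sig
    if (!is.null(last)) {
      both <- which(is.finite(padded) & is.finite(last))
      if (length(both) >= 2) {
        r <- suppressWarnings(cor(padded[both], last[both]))
        if (!is.na(r) && r < 0) padded <- -padded
      }
    }
    signals[[length(signals) + 1L]] <- padded
    last <- padded
  }
  if (!length(signals)) abort_ddgate("no usable window.", "degenerate")
  mat <- do.call(cbind, signals)
  out <- rowMeans(mat, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  surrogate_signal(out, sampling_hz = sampling_rate(series),
                   start_time_s = series$start_time_s)
}

#' Late-time-interval component extraction
#'
#' Tracer kinetics dominate early frames, but by late times the activity
#' distribution is near-stationary and respiration is the main source of
#' variance. This extractor runs PCA on the late segment only (frames after
#' `cutoff_fraction` of the record; the reference operating point is 62%,
#' about 520 s into a 840 s acquisition), selects the best-scoring late
#' component, and applies it to all frames — respiration being
#' semi-consistent throughout, a component capturing it late captures it
#' early too.
#'
#' @param series a preprocessed [sinogram_series()].
#' @param cutoff_fraction fraction of the record to skip (in `[0, 1)`).
#' @param n_components candidate components in the late segment.
#' @param resp_window respiratory band for scoring, Hz.
#' @return A [surrogate_signal()] over all frames, with attributes
#'   `component` and `score`.
#' @export
late_time_extract <- function(series, cutoff_fraction = 0.62,
                              n_components = 10, resp_window = c(0.1, 0.4)) {
  if (cutoff_fraction < 0 || cutoff_fraction >= 1)
    abort_ddgate("`cutoff_fraction` must be in [0, 1).", "parameter")
  nt <- n_frames(series)
  from <- floor(cutoff_fraction * nt) + 1L
  if (nt - from + 1L < 64) abort_ddgate("late segment has fewer than 64 frames.", "parameter")
  comps <- pca_decompose(series, n_components, time_support = c(from, nt))
  late <- subset_frames(series, from, nt)
  sigs <- lapply(comps, apply_component, series = late)
  scores <- vapply(sigs, conventional_score, numeric(1), window = resp_window)
  best <- which.max(scores)
  comp <- comps[[best]]
  comp$score <- scores[best]
  out <- apply_component(comp, series)
  attr(out, "component") <- comp
  attr(out, "score") <- scores[best]
  out
}

#' Score and select components
#'
#' Scores every component's signal with `scorer`, drops components whose
#' score is not strictly above `threshold` (erroring if none survive), and
#' returns the rest sorted by descending score; ties keep the original
#' component order.
#'
#' @param components list of components sharing one decomposition.
#' @param series the [sinogram_series()] the components came from.
#' @param scorer function mapping a [surrogate_signal()] to a scalar score.
#' @param threshold minimum score (strict).
#' @return The selected components, each with its `score` field set.
#' @export
score_select <- function(components, series, scorer, threshold = 0) {
  if (!length(components)) abort_ddgate("no components supplied.", "no_candidate")
  scores <- vapply(components, function(cp)
    scorer(apply_component(cp, series)), numeric(1))
  keep <- which(scores > threshold)
  if (!length(keep)) abort_ddgate("no component scores above the threshold.", "no_candidate")
  ord <- keep[order(-scores[keep], keep)]
  purrr::map2(components[ord], scores[ord], function(cp, s) {
    cp$score <- s
    cp
  })
}

#' Greedily combine components to maximise the respiratory score
#'
#' Starting from the best-scoring component, each further component is both
#' added and subtracted (each side weighted by its score — the two signs
#' handle the arbitrary component sign), the two candidates are rescored,
#' and the better one replaces the current best only if it strictly improves
#' the score (the summed candidate is preferred when both improve equally).
#' Combining components pools respiratory information that PCA split across
#' several components, improving the signal-to-noise ratio.
#'
#' @param components components sorted by [score_select()].
#' @param series the [sinogram_series()] the components came from.
#' @param scorer function mapping a [surrogate_signal()] to a scalar score.
#' @return The combined component (with its final `score`).
#' @export
combine_components <- function(components, series, scorer) {
  if (!length(components)) abort_ddgate("no components to combine.", "no_candidate")
  best <- components[[1]]
  best_score <- if (is.finite(best$score)) best$score
                else scorer(apply_component(best, series))
  merge_weights <- function(a, wa, b, wb) {
    bins <- union(a$bins, b$bins)
    w <- numeric(length(bins))
    w[match(a$bins, bins)] <- w[match(a$bins, bins)] + wa * a$weights
    w[match(b$bins, bins)] <- w[match(b$bins, bins)] + wb * b$weights
    nz <- w != 0
    if (!any(nz)) return(NULL)
    new_component(w[nz], bins[nz], a$spatial_dim, origin = a$origin,
                  time_support = a$time_support)
  }
  for (cp in components[-1]) {
    cur_score <- if (is.finite(cp$score)) cp$score
                 else scorer(apply_component(cp, series))
    # a +Inf score sentinel cannot be used as a combination weight; fall
    # back to equal weighting for the merge while scores still decide
    # acceptance
    wb <- if (is.finite(best_score)) best_score else 1
    wc <- if (is.finite(cur_score)) cur_score else 1
    cand_sum <- merge_weights(best, wb, cp, wc)
    cand_sub <- merge_weights(best, wb, cp, -wc)
    s_sum <- if (is.null(cand_sum)) -Inf else scorer(apply_component(cand_sum, series))
    s_sub <- if (is.null(cand_sub)) -Inf else scorer(apply_component(cand_sub, series))
    # strict improvement up to floating-point jitter (a proportional signal
    # must not count as an improvement)
    improves <- function(s) is.finite(s) && s > best_score + abs(best_score) * 1e-9
    if (improves(s_sum)) {
      best <- cand_sum; best_score <- s_sum
    } else if (improves(s_sub)) {
      best <- cand_sub; best_score <- s_sub
    }
  }
  best$score <- best_score
  best
}

#' Transparent stand-in for a learned signal scorer
#'
#' The score-select-combine search accepts any callable mapping a signal to
#' `[0, 1]` (for example a pretrained network scoring how respiratory-like a
#' trace is). This constructor builds a transparent feature-based stand-in:
#' a logistic squash of the log frequency-ratio score, so the ordering of
#' candidates matches the frequency scorer while the range contract holds.
#'
#' @param windows a [frequency_windows()] supplying the feature bands.
#' @param steepness logistic slope on the log-score.
#' @return A function `signal -> score in [0, 1]`.
#' @export
feature_scorer <- function(windows = frequency_windows(), steepness = 0.5) {
  force(windows); force(steepness)
  function(signal) {
    fs <- frequency_score(signal, windows)
    if (!is.finite(fs)) return(1)
    if (fs <= 0) return(0)
    stats::plogis(steepness * log(fs))
  }
}

#' Score-select-combine extraction
#'
#' The full pipeline: (1) a late-time-interval extraction provides an
#' initial signal; (2) the respiratory frequency window is estimated from
#' its spectrum; (3) PCA decomposes all frames at once; (4) components are
#' scored (frequency-ratio scorer with the estimated windows, or a pluggable
#' `[0, 1]` scorer), thresholded and sorted; (5) the greedy combine search
#' merges them; (6) the combined component is applied to all frames.
#'
#' @param series a preprocessed [sinogram_series()].
#' @param n_components candidate components.
#' @param cutoff_fraction late-time cutoff for the initial estimate.
#' @param scorer `"frequency"` for the frequency-ratio score, or a function
#'   mapping a [surrogate_signal()] to `[0, 1]`.
#' @param threshold minimum score for selection; defaults to 0 for the
#'   scale-free frequency scorer and 0.5 for a pluggable `[0, 1]` scorer.
#' @return A [surrogate_signal()] with attributes `component`, `score`,
#'   and `windows` (the estimated respiratory bands).
#' @export
ssc_extract <- function(series, n_components = 10, cutoff_fraction = 0.62,
                        scorer = "frequency", threshold = NULL) {
  init <- late_time_extract(series, cutoff_fraction, n_components)
  # estimate the respiratory band from the late segment only: the early part
  # of the initial signal still carries kinetic leakage, which would drag
  # the spectral centroid below the breathing peak
  ts <- attr(init, "component")$time_support
  init_late <- surrogate_signal(init$value[ts[1]:ts[2]],
                                sampling_hz = sig_hz(init),
                                start_time_s = init$time_s[ts[1]])
  windows <- estimate_resp_window(init_late)
  comps <- pca_decompose(series, n_components)
  if (identical(scorer, "frequency")) {
    fn <- function(sig) frequency_score(sig, windows)
    if (is.null(threshold)) threshold <- 0
  } else if (is.function(scorer)) {
    fn <- scorer
    if (is.null(threshold)) threshold <- 0.5
  } else {
    abort_ddgate("`scorer` must be \"frequency\" or a function.", "parameter")
  }
  sel <- score_select(comps, series, fn, threshold)
  comb <- combine_components(sel, series, fn)
  out <- apply_component(comb, series)
  attr(out, "component") <- comb
  attr(out, "score") <- comb$score
  attr(out, "windows") <- windows
  out
}

#' Dispatch extraction by method name
#'
#' @param series a preprocessed [sinogram_series()].
#' @param method one of `"conventional"`, `"moving_window_pca"`,
#'   `"moving_window_sam"`, `"late_time"`, `"ssc_freq"`, `"ssc_pluggable"`.
#' @param ... passed to the specific extractor.
#' @return A [surrogate_signal()].
#' @export
extract_signal <- function(series,
                           method = c("conventional", "moving_window_pca",
                                      "moving_window_sam", "late_time",
                                      "ssc_freq", "ssc_pluggable"),
                           ...) {
  method <- match.arg(method)
  switch(method,
    conventional = conventional_extract(series, ...),
    moving_window_pca = moving_window_extract(series, engine = "pca", ...),
    moving_window_sam = moving_window_extract(series, engine = "sam", ...),
    late_time = late_time_extract(series, ...),
    ssc_freq = ssc_extract(series, scorer = "frequency", ...),
    ssc_pluggable = ssc_extract(series, scorer = feature_scorer(), ...)
  )
}
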