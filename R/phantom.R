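#' Respiratory motion model
#'
#' Quasi-periodic breathing: each cycle is a sine whose period and amplitude
#' are drawn per cycle (relative Gaussian jitter), with optional linear
#' baseline drift and breath holds during which the trace freezes at its
#' hold-onset value. This emulates the variability seen in patient traces —
#' varying rates, pauses, irregular depth — while keeping the trace known
#' exactly.
#'
#' @param base_freq_hz mean breathing frequency in Hz (must be below the
#'   Nyquist rate of the 2 Hz sinogram sampling).
#' @param amplitude_voxels displacement amplitude in image voxels (default
#'   0.8, a shallow-breathing excursion typical of the fibrotic-lung
#'   population these methods target).
#' @param freq_jitter relative standard deviation of the cycle-to-cycle period.
#' @param amplitude_jitter relative standard deviation of per-cycle amplitude.
#' @param drift baseline drift, voxels per minute.
#' @param breath_holds list of `c(start_s, duration_s)` pairs.
#' @return A list of class `resp_model`.
#' @export
resp_model <- function(base_freq_hz = 0.25, amplitude_voxels = 0.8,
                       freq_jitter = 0.05, amplitude_jitter = 0.1,
                       drift = 0, breath_holds = list()) {
  if (!(base_freq_hz > 0 && base_freq_hz < 1))
    abort_ddgate("`base_freq_hz` must be in (0, 1) Hz.", "parameter")
  if (amplitude_voxels < 0) abort_ddgate("`amplitude_voxels` must be >= 0.", "parameter")
  if (freq_jitter < 0 || amplitude_jitter < 0)
    abort_ddgate("jitter parameters must be >= 0.", "parameter")
  structure(list(base_freq_hz = base_freq_hz,
                 amplitude_voxels = amplitude_voxels,
                 freq_jitter = freq_jitter,
                 amplitude_jitter = amplitude_jitter,
                 drift = drift,
                 breath_holds = breath_holds),
            class = "resp_model")
}

#' Time-activity curve model
#'
#' Regional tracer kinetics. Activity is zero before the injection time, then
#' follows the chosen form: `constant` (step to `scale`), `bolus_washout`
#' (`scale * (exp(-k_washout t') - exp(-k_rise t'))`, a fast rise and slower
#' washout, emulating a blood-pool bolus), or `uptake`
#' (`scale * (1 - exp(-k_uptake t'))`, monotone tissue accumulation), with
#' `t'` the time since injection.
#'
#' @param form one of `"constant"`, `"bolus_washout"`, `"uptake"`.
#' @param scale activity scale (arbitrary units, >= 0).
#' @param k_rise,k_washout,k_uptake rate constants in 1/s.
#' @param delay_s transit delay after injection before activity reaches the
#'   region, seconds (the bolus arrives in the right heart, lungs, arterial
#'   pool and tissue at successively later times).
#' @return A list of class `tac_model`.
#' @export
tac_model <- function(form = c("constant", "bolus_washout", "uptake"),
                      scale = 1, k_rise = 0.1, k_washout = 1 / 80,
                      k_uptake = 1 / 200, delay_s = 0) {
  form <- match.arg(form)
  if (scale < 0) abort_ddgate("`scale` must be >= 0.", "parameter")
  if (any(c(k_rise, k_washout, k_uptake) <= 0))
    abort_ddgate("rate constants must be > 0.", "parameter")
  if (delay_s < 0) abort_ddgate("`delay_s` must be >= 0.", "parameter")
  structure(list(form = form, scale = scale, k_rise = k_rise,
                 k_washout = k_washout, k_uptake = k_uptake,
                 delay_s = delay_s),
            class = "tac_model")
}

tac_eval <- function(model, t, injection_time_s) {
  t_on <- injection_time_s + (model$delay_s %||% 0)
  tp <- pmax(t - t_on, 0)
  on <- as.numeric(t >= t_on)
  v <- switch(model$form,
    constant = model$scale * on,
    bolus_washout = {
      # normalise so the peak equals `scale`
      kp <- model$k_rise; kw <- model$k_washout
      tpk <- log(kp / kw) / (kp - kw)
      peak <- exp(-kw * tpk) - exp(-kp * tpk)
      model$scale * on * (exp(-kw * tp) - exp(-kp * tp)) / peak
    },
    uptake = model$scale * on * (1 - exp(-model$k_uptake * tp))
  )
  pmax(v, 0)
}

#' Phantom configuration
#'
#' Describes a synthetic dynamic PET acquisition: an image grid of ellipsoidal
#' regions with per-region tracer kinetics, rigid axial respiratory
#' displacement, a discrete line-integral projector into (radial, angle,
#' plane, TOF) sinogram bins, and Poisson counting noise. Defaults emulate a
#' 14-minute dynamic acquisition at 500 ms frames with injection 20 s after
#' the scan start (so the first 20 s hold essentially no counts).
#'
#' @param n_frames number of time frames.
#' @param frame_duration_s frame duration, seconds.
#' @param image_grid `c(nx, ny, nz)` voxel counts.
#' @param n_radial,n_angles,n_planes,n_tof_bins sinogram dimensions
#'   (`n_planes` must divide `nz`; `n_tof_bins = 1` means non-TOF).
#' @param geometry list of ellipsoid specs: each a list with `center` (3
#'   voxel coordinates), `axes` (3 semi-axes in voxels) and `label`.
#' @param tacs named list of [tac_model()]s, one per geometry label.
#' @param resp a [resp_model()].
#' @param count_scale expected total counts per frame at the late-time
#'   plateau.
#' @param injection_time_s tracer injection time, seconds.
#' @param poisson draw Poisson counts (`TRUE`) or return noise-free expected
#'   counts (`FALSE`).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_frames = 1680, frame_duration_s = 0.5,
                           image_grid = c(64, 64, 16),
                           n_radial = 24, n_angles = 16, n_planes = 8,
                           n_tof_bins = 1,
                           geometry = default_geometry(image_grid),
                           tacs = default_tacs(),
                           resp = resp_model(),
                           count_scale = 250,
                           injection_time_s = 20,
                           poisson = TRUE,
                           seed = 1L) {
  if (n_frames < 1) abort_ddgate("`n_frames` must be >= 1.", "parameter")
  if (frame_duration_s <= 0) abort_ddgate("`frame_duration_s` must be > 0.", "parameter")
  if (count_scale < 0) abort_ddgate("`count_scale` must be >= 0.", "parameter")
  if (image_grid[3] %% n_planes != 0)
    abort_ddgate("`n_planes` must divide the axial grid size.", "parameter")
  labels <- vapply(geometry, function(g) g$label, character(1))
  if (!all(labels %in% names(tacs)))
    abort_ddgate("every geometry label needs a TAC model.", "parameter")
  for (g in geometry) {
    if (any(g$axes <= 0)) abort_ddgate("ellipsoid axes must be > 0.", "parameter")
  }
  structure(list(n_frames = as.integer(n_frames),
                 frame_duration_s = frame_duration_s,
                 image_grid = as.integer(image_grid),
                 n_radial = as.integer(n_radial),
                 n_angles = as.integer(n_angles),
                 n_planes = as.integer(n_planes),
                 n_tof_bins = as.integer(n_tof_bins),
                 geometry = geometry, tacs = tacs, resp = resp,
                 count_scale = count_scale,
                 injection_time_s = injection_time_s,
                 poisson = isTRUE(poisson),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_geometry <- function(image_grid = c(64, 64, 16)) {
  # positions and axes scale with the grid (reference proportions set on a
  # 64 x 64 x 16 grid)
  sx <- image_grid[1] / 64; sy <- image_grid[2] / 64; sz <- image_grid[3] / 16
  cx <- image_grid[1] / 2; cy <- image_grid[2] / 2; cz <- image_grid[3] / 2
  ell <- function(dx, dy, dz, ax, ay, az, label)
    list(center = c(cx + dx * sx, cy + dy * sy, cz + dz * sz),
         axes = c(ax * sx, ay * sy, az * sz), label = label)
  list(
    ell(0, 0, 0, 22, 18, 4, "body"),
    ell(-5, 5, -1, 6, 5, 2.5, "rheart"),
    ell(9, 7, 0, 10, 7, 3, "lungfield"),
    ell(-8, -6, 1, 7, 5, 2.5, "aorta"),
    ell(8, -5, 1, 5, 4, 2, "lesion")
  )
}

#' @rdname phantom_config
#' @export
default_tacs <- function() {
  # first-pass redistribution chain: the bolus reaches the right heart,
  # then the lung field, then the arterial pool, before tissue uptake
  list(body = tac_model("uptake", scale = 1, k_uptake = 1 / 400),
       rheart = tac_model("bolus_washout", scale = 25, k_rise = 1 / 2,
                          k_washout = 1 / 15, delay_s = 5),
       lungfield = tac_model("bolus_washout", scale = 8, k_rise = 1 / 4,
                             k_washout = 1 / 30, delay_s = 10),
       aorta = tac_model("bolus_washout", scale = 15, k_rise = 1 / 5,
                         k_washout = 1 / 60, delay_s = 16),
       lesion = tac_model("uptake", scale = 2.5, k_uptake = 1 / 200))
}

#' Simulate a ground-truth respiratory trace
#'
#' Draws per-cycle periods and amplitudes under the jitter model, evaluates a
#' per-cycle sine, adds baseline drift, then freezes the trace during breath
#' holds at the hold-onset value. Deterministic for a fixed seed; the global
#' RNG state is left untouched.
#'
#' @param model a [resp_model()].
#' @param n_frames number of samples.
#' @param dt sample spacing in seconds.
#' @param seed integer RNG seed.
#' @return A [surrogate_signal()] at `1/dt` Hz with `sign_arbitrary = FALSE`.
#' @export
simulate_resp_trace <- function(model, n_frames, dt = 0.5, seed = 1L) {
  stopifnot(inherits(model, "resp_model"))
  if (n_frames < 1) abort_ddgate("`n_frames` must be >= 1.", "parameter")
  if (dt <= 0) abort_ddgate("`dt` must be > 0.", "parameter")
  total_t <- n_frames * dt
  t0_base <- 1 / model$base_freq_hz
  v <- withr::with_seed(seed, {
    # draw enough cycles to cover the record
    n_cyc <- ceiling(total_t / t0_base * 2) + 10
    eps <- rnorm(n_cyc, 0, model$freq_jitter)
    eps <- pmin(pmax(eps, -3 * model$freq_jitter), 3 * model$freq_jitter)
    periods <- pmax(t0_base * (1 + eps), 0.2 * t0_base)
    amps <- model$amplitude_voxels *
      pmax(1 + rnorm(n_cyc, 0, model$amplitude_jitter), 0)
    starts <- c(0, cumsum(periods))
    t <- (seq_len(n_frames) - 0.5) * dt
    cyc <- findInterval(t, starts)
    phase <- 2 * pi * (t - starts[cyc]) / periods[cyc]
    amps[cyc] * sin(phase) + model$drift * t / 60
  })
  t <- (seq_len(n_frames) - 0.5) * dt
  for (h in model$breath_holds) {
    idx <- which(t >= h[1] & t < h[1] + h[2])
    if (length(idx)) {
      onset <- if (idx[1] > 1) v[idx[1] - 1] else v[1]
      v[idx] <- onset
    }
  }
  surrogate_signal(v, sampling_hz = 1 / dt, start_time_s = 0, sign_arbitrary = FALSE)
}

# soft-edged ellipsoid on the grid: a linear ramp of `edge_width` voxels at
# the boundary emulates the scanner point-spread blur
ellipsoid_image <- function(grid, center, axes, edge_width = 1.5) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  x <- ((1:nx) - center[1]) / axes[1]
  y <- ((1:ny) - center[2]) / axes[2]
  z <- ((1:nz) - center[3]) / axes[3]
  rho <- sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
  # signed distance from the boundary in voxel units (approximate)
  s <- (1 - rho) * min(axes)
  array(pmin(1, pmax(0, 0.5 + s / edge_width)), dim = grid)
}

# per-angle nearest-neighbour radial bin index for every (x, y) pixel
projector_indices <- function(grid, n_radial, n_angles) {
  nx <- grid[1]; ny <- grid[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r_scale <- nx / n_radial
  xs <- rep(seq_len(nx) - cx, times = ny)
  ys <- rep(seq_len(ny) - cy, each = nx)
  lapply(seq_len(n_angles), function(a) {
    th <- (a - 1) * pi / n_angles
    r <- round((xs * cos(th) + ys * sin(th)) / r_scale + (n_radial + 1) / 2)
    r[r < 1 | r > n_radial] <- NA_integer_
    as.integer(r)
  })
}

# project a 3D image (already shifted) into a (radial x angle x plane) array
project_image <- function(img, idx_by_angle, n_radial, n_planes) {
  grid <- dim(img)
  nz <- grid[3]
  zgroup <- rep(seq_len(n_planes), each = nz / n_planes)
  slab <- matrix(img, nrow = grid[1] * grid[2], ncol = nz)
  planes <- slab %*% outer(zgroup, seq_len(n_planes), `==`)
  out <- array(0, dim = c(n_radial, length(idx_by_angle), n_planes))
  for (a in seq_along(idx_by_angle)) {
    idx <- idx_by_angle[[a]]
    keep <- !is.na(idx)
    for (p in seq_len(n_planes)) {
      s <- rowsum(planes[keep, p], idx[keep])
      out[as.integer(rownames(s)), a, p] <- s
    }
  }
  out
}

# integer axial shift with zero fill
shift_z <- function(img, k) {
  if (k == 0) return(img)
  nz <- dim(img)[3]
  out <- array(0, dim = dim(img))
  if (k > 0) out[, , (1 + k):nz] <- img[, , 1:(nz - k)]
  else out[, , 1:(nz + k)] <- img[, , (1 - k):nz]
  out
}

#' Generate a synthetic dynamic PET sinogram series
#'
#' Per frame, every region is rigidly displaced along the axial direction by
#' the respiratory trace (sub-voxel displacement by linear interpolation),
#' scaled by its time-activity value, and forward-projected by a
#' nearest-neighbour ray-summation projector into (radial, angle, plane)
#' bins; TOF bins split counts with a fixed Gaussian along-ray profile.
#' Counts are Poisson with the projection as mean, scaled so the late-time
#' plateau has `count_scale` expected counts per frame. The injected
#' respiratory trace is returned exactly as ground truth.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `series` (a [sinogram_series()]) and `truth`
#'   (list: `resp_trace`, `tacs` tibble, `first_counts_time_s`,
#'   `displacement_voxels`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$image_grid
  trace <- simulate_resp_trace(config$resp, config$n_frames,
                               config$frame_duration_s, seed = config$seed)
  d <- trace$value
  k_lo <- floor(min(d)); k_hi <- ceiling(max(d))
  shifts <- k_lo:k_hi
  # geometry must stay inside the grid for every shift (mass conservation)
  for (g in config$geometry) {
    zmin <- g$center[3] - g$axes[3] - 1 + k_lo
    zmax <- g$center[3] + g$axes[3] + 1 + k_hi
    if (zmin < 1 || zmax > grid[3])
      abort_ddgate("grid too small for the axial displacement.", "geometry")
  }
  idx <- projector_indices(grid, config$n_radial, config$n_angles)
  nb <- config$n_radial * config$n_angles * config$n_planes
  labels <- vapply(config$geometry, function(g) g$label, character(1))
  nreg <- length(labels)
  nK <- length(shifts)
  # noise-free projections of each region at each integer axial shift
  P <- matrix(0, nrow = nb, ncol = nreg * nK)
  for (r in seq_len(nreg)) {
    img <- ellipsoid_image(grid, config$geometry[[r]]$center, config$geometry[[r]]$axes)
    for (j in seq_len(nK)) {
      P[, (r - 1) * nK + j] <-
        as.vector(project_image(shift_z(img, shifts[j]), idx,
                                config$n_radial, config$n_planes))
    }
  }
  t <- frame_times_raw(config)
  tac_mat <- vapply(labels, function(lb)
    tac_eval(config$tacs[[lb]], t, config$injection_time_s),
    numeric(config$n_frames))
  # frame weights: fractional shift = convex combination of two integer shifts
  k0 <- floor(d); fr <- d - k0
  W <- matrix(0, nrow = nreg * nK, ncol = config$n_frames)
  j0 <- match(k0, shifts)
  for (r in seq_len(nreg)) {
    base <- (r - 1) * nK
    i_lo <- cbind(base + j0, seq_len(config$n_frames))
    W[i_lo] <- W[i_lo] + (1 - fr) * tac_mat[, r]
    up <- fr > 0
    if (any(up)) {
      i_hi <- cbind(base + j0[up] + 1L, seq_len(config$n_frames)[up])
      W[i_hi] <- W[i_hi] + fr[up] * tac_mat[up, r]
    }
  }
  Q <- P %*% W  # noise-free projections, bins x frames
  totals <- colSums(Q)
  plateau <- median(tail(totals, max(1, round(0.1 * config$n_frames))))
  scale <- if (plateau > 0) config$count_scale / plateau else 0
  M <- Q * scale
  # TOF: fixed Gaussian along-ray profile
  ntof <- config$n_tof_bins
  if (ntof > 1) {
    gw <- dnorm(seq_len(ntof), mean = (ntof + 1) / 2, sd = ntof / 4)
    gw <- gw / sum(gw)
    M <- M[rep(seq_len(nb), times = ntof), ] *
      rep(gw, each = nb)
    dim(M) <- c(nb * ntof, config$n_frames)
  }
  counts <- if (config$poisson) {
    withr::with_seed(config$seed + 1L,
                     matrix(rpois(length(M), M), nrow = nrow(M)))
  } else M
  data <- array(counts, dim = c(config$n_radial, config$n_angles,
                                config$n_planes, ntof, config$n_frames))
  series <- sinogram_series(data, frame_duration_s = config$frame_duration_s,
                            start_time_s = 0)
  ft <- colSums(counts)
  first_counts <- if (any(ft > 0)) t[which(ft > 0)[1]] else NA_real_
  tac_tbl <- tibble::tibble(
    time_s = rep(t, times = nreg),
    region = rep(labels, each = config$n_frames),
    activity = as.vector(tac_mat))
  list(series = series,
       truth = list(resp_trace = trace,
                    tacs = tac_tbl,
                    first_counts_time_s = first_counts,
                    displacement_voxels = d))
}

frame_times_raw <- function(config) {
  (seq_len(config$n_frames) - 0.5) * config$frame_duration_s
}
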