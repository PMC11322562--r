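# ddgate

Data-driven respiratory surrogate signal extraction for **dynamic** PET.

## The problem

Respiratory motion blurs PET images and biases quantification. Most
correction schemes need a 1D *surrogate signal* (SS) — a trace that follows
the breathing cycle — to gate or deform the data. Data-driven methods read
the SS straight out of the acquisition: a time series of low-resolution
sinograms is decomposed (classically by PCA at 2 Hz sampling), and the
component whose per-frame weights

    W_t = Σ_bins PC · S_t

look most respiratory (largest mean spectral magnitude in the breathing
band) supplies the trace. That works well for static acquisitions, but in a
*dynamic* scan — tracer injected after the scan starts — the rapid early
redistribution of activity dominates the variance, and whole-record PCA
loses the breathing signal exactly where gating is needed most.

`ddgate` implements the family of extractors designed for this regime,
together with the full processing chain around them:

- **Conventional PCA** — whole-record decomposition, respiratory-band PSD
  scoring (the static-acquisition baseline).
- **Moving window** (PCA or spectral-analysis signed masks) — extraction in
  half-overlapping windows with overlap-correlation sign correction and
  NaN-aware averaging.
- **Late-time-interval component** — PCA on the late, kinetically quiet part
  of the record (62 % cutoff by default); the winning component is applied
  to *all* frames.
- **Score–Select–Combine (SSC)** — components are scored by the ratio
  product (respiratory/kinetic) × (respiratory/noise) over an adaptive
  respiratory band estimated from a late-time initial signal, thresholded,
  sorted, and greedily summed/subtracted (score-weighted) whenever the
  combination strictly improves the score. A pluggable `[0, 1]` scorer slot
  accepts learned scorers; a transparent feature-based stand-in ships with
  the package.

Around the extractors:

- **Pre-processing**: Freeman–Tukey (`√(X+1)+√X`) then Yeo–Johnson
  Gaussianisation with the power fitted by KL-divergence minimisation,
  bottom-5 % low-count masking, separable Gaussian smoothing and
  linear-interpolation downsampling, 2 Hz temporal rebinning.
- **Post-processing**: parallel compression (audio-style two-channel
  dynamic-range taming), quartile-fence outlier repair, truncated
  windowed-sinc bandpass `h(t) = 2B_H sinc(2B_H t) − 2B_L sinc(2B_L t)`,
  Savitzky–Golay smoothing (order 3, window 5).
- **Evaluation**: Pearson correlation against a reference trace over the
  usable record (20–840 s), the early window (20–140 s), and 20 s intervals,
  with global sign alignment (a PCA trace's sign is arbitrary).
- **Phantom simulator**: a dynamic-PET phantom with ellipsoidal regions, a
  first-pass bolus redistribution chain (right heart → lung field → arterial
  pool → tissue uptake), rigid axial respiratory displacement with per-cycle
  frequency/amplitude jitter and breath holds, a nearest-neighbour
  ray-summation projector (optional TOF bins), and Poisson counting noise —
  so every stage is testable against known ground truth.

Intended users: researchers in PET motion correction and data-driven gating
who want a reference implementation of these extractors, a ground-truth
phantom to benchmark against, or building blocks for their own pipelines.

## Worked example

Simulate a 5-minute dynamic acquisition, extract a surrogate with three
methods, post-process, and compare with the injected ground truth:

```r
library(ddgate)

cfg <- pipeline_config(
  methods = c("conventional", "late_time", "ssc_freq"),
  seed    = 42,
  phantom = list(n_frames = 600, image_grid = c(32, 32, 16), n_radial = 16,
                 n_angles = 8, n_planes = 8, count_scale = 4000,
                 resp = resp_model(base_freq_hz = 0.25, amplitude_voxels = 1.2,
                                   freq_jitter = 0.03)),
  cutoff_fraction = 0.5, t_full = c(20, 290), t_early = c(20, 140))

res <- run_pipeline(cfg)
glance(res$report)
#> # A tibble: 3 × 4
#>   method       r_full r_early sign_flipped
#>   <chr>         <dbl>   <dbl> <lgl>
#> 1 conventional  0.934   0.933 FALSE
#> 2 late_time     0.939   0.917 TRUE
#> 3 ssc_freq      0.757   0.615 FALSE

head(tidy(res$report), 4)
#> # A tibble: 4 × 5
#>   method          t0    t1     r     n
#>   <chr>        <dbl> <dbl> <dbl> <int>
#> 1 conventional    20    40 0.810    40
#> 2 conventional    40    60 0.985    40
#> 3 conventional    60    80 0.995    40
#> 4 conventional    80   100 0.997    40
```

`r_full` / `r_early` are the Pearson correlations between each extracted
trace and the ground-truth breathing trace over the whole usable record and
over the first usable 120 s; `tidy()` gives the same correlation in 20 s
intervals (40 samples each at 2 Hz); `sign_flipped` records whether the
arbitrary trace sign was inverted for reporting. On this short, well-counted
phantom all methods track breathing; the methods separate sharply on the
14-minute sparse-count phantom bank (see below), where early tracer kinetics
swamp whole-record PCA. `autoplot(res$report)` and
`plot_trace_comparison(res$traces, res$reference)` draw the standard
figures.

A thin command-line front end mirrors the pipeline
(`Rscript inst/cli/ddgate.R run-all --seed 1 --out outdir`; subcommands
`simulate`, `preprocess`, `extract`, `postprocess`, `evaluate`).

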