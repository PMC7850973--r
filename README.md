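# transmitscope

Quantitative analysis of wide-field fluorescence movies acquired with
genetically encoded neurotransmitter sensors (iAChSnFR, the GRAB family,
dLight, iGluSnFR and related probes).  These sensors report local
transmitter concentration as a fractional fluorescence change ΔF/F; combined
with point-spread-function (PSF) based deconvolution, single movies resolve
synaptic parameters of neuromodulatory transmission that electrophysiology
cannot reach.  The package is aimed at imaging labs that want a tested,
scriptable path from raw TIFF stacks to two kinds of estimates:

1. **Spatial transmitter spread.** Around an isolated release site the
   pixel-wise maximal ΔF/F decays with distance *d* as a single exponential

   ΔF/F(d) = A · exp(−d/λ),

   and the length constant λ (µm) quantifies how far released transmitter
   acts — the quantity that discriminates point-to-point from volume
   transmission.

2. **Vesicle-pool parameters from prolonged stimulus trains.** With
   per-stimulus release amplitudes aₖ (ΔF/F units) and their cumulative sum
   plotted against stimulus number, the late, refill-dominated phase is
   linear; back-extrapolating the fitted line f(x) = slope · x + intercept
   to x = 0 gives the readily releasable pool (intercept, ΔF/F) and the
   vesicle refill rate (slope, ΔF/F per stimulus).  Release probability
   (mean early release / pool) and quantal size (unitary ΔF/F per vesicle,
   from the amplitude distribution) follow.

Supporting these headline estimators, the package provides

* a **forward simulator** with complete ground truth — binomial quantal
  release with pool depletion and refill, exponential spatial spread,
  difference-of-exponentials sensor kinetics, expression texture, PSF blur,
  Poisson photon noise, Gaussian read noise, mono-exponential
  photobleaching, rigid drift, and fluorescent-bead calibration stacks;
* **preprocessing**: rigid sub-pixel drift registration (normalized
  cross-correlation with parabolic refinement), photobleaching /
  autofluorescence correction, Gaussian/median denoising and ΔF/F
  computation;
* **optics**: the Abbe limit λ/2NA, the photon-scaling laws for
  superresolution (N^−1/2) and deconvolution (N^−1/4) imaging, theoretical
  Gaussian PSFs, and empirical PSF estimation from bead images;
* **Richardson–Lucy deconvolution** with flux-conservation and convergence
  diagnostics;
* TIFF + JSON-sidecar I/O, a validated pipeline configuration, and a thin
  command-line wrapper (`inst/cli/transmitscope.R`).

## Worked example

Simulate a noisy movie of one isolated release site (λ = 0.75 µm, 0.2 µm
pixels, PSF FWHM 0.5 µm, 500 baseline photons/pixel), then recover λ through
the full pipeline:

```r
library(transmitscope)

psf <- theoretical_psf(optical_config(1000, numerical_aperture = 1),
                       pixel_size_um = 0.2)
cfg <- sim_config(field_size_px = c(64, 64), pixel_size_um = 0.2,
                  frame_rate_hz = 10, n_frames = 30, stimulus_times_s = 1,
                  site_positions_um = matrix(c(6.45, 6.35), 1),
                  spread_length_um = 0.75, quantal_dff = 0.125,
                  pool_size_vesicles = 8, release_prob = 1,
                  baseline_photons = 500, seed = 1)
sim  <- simulate_movie(cfg, psf)
coll <- collapse_event_window(sim$movie)      # baseline + event average
dec  <- deconvolve_movie(coll, psf, max_iterations = 30)
analyze_spread(compute_dff(dec), smooth_sigma_px = 2, frames = 2,
               min_peak_dff = 0.2, n_boot = 99)
```

```
  site_id y_um x_um peak_dff amplitude lambda_um ci_low_um ci_high_um r_squared n_pixels
1       1 6.43 6.37    0.715     0.799     0.748     0.729      0.765     0.853      707
```

`lambda_um = 0.748` recovers the generating λ = 0.75 µm within 0.3%;
`amplitude` is the fitted ΔF/F at the site centre after the event-window
average (scaled below the instantaneous peak by the window mean of the
sensor kernel), and the bootstrap CI comes from resampling profile pixels.

For a prolonged train (1920 pulses at 16 Hz, pool 100 vesicles, release
probability 0.08, refill 0.5 vesicles/stimulus, quantal size 0.01 ΔF/F):

```r
run <- run_pipeline(list(
  seed = 1,
  input = list(simulate = list(
    field_size_px = c(16, 16), pixel_size_um = 0.2, frame_rate_hz = 16,
    n_frames = 1992, stimulus_times_s = 2 + (0:1919) / 16,
    site_positions_um = matrix(c(1.4, 1.4), 1), quantal_dff = 0.01,
    pool_size_vesicles = 100, release_prob = 0.08,
    refill_per_stimulus = 0.5, baseline_photons = 500)),
  preprocess = list(register = FALSE, bleach = "none"),
  pool = list(enabled = TRUE, roi_radius_um = 1.4)))
run$pool
```

```
<pool_fit> pool = 0.9703 dF/F, refill = 0.004971 dF/F per stimulus (R2 0.9995, 640 late pts)
  release probability 0.07599, quantal size 0.01555 dF/F, pool ~ 62.38 vesicles
```

The back-extrapolated pool (0.97 ΔF/F) and refill rate (0.0050 ΔF/F per
stimulus) recover the generating values q·N₀ = 1.0 and q·R = 0.005; the
release probability estimate 0.076 sits near the generating p = 0.08.  The
quantal-size estimate is the least certain output at this photon budget
(see the methods vignette).

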