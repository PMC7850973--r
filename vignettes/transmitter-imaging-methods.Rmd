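---
title: "Methods: sensor-movie simulation, deconvolution and synaptic parameter estimation"
author: "transmitscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-movie simulation, deconvolution and synaptic parameter estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`transmitscope`, in the spirit of a methods section: what is assumed, what
the defaults mean, and where the boundaries of validity lie.  It states no
empirical result that the package's test suite and `scripts/acceptance.R`
do not themselves compute.

## The measurement problem

Intensity-based genetically encoded transmitter sensors (cpGFP fused to a
GPCR or periplasmic binding protein) convert local transmitter
concentration into a fractional fluorescence change
$\Delta F/F = (F - F_0)/F_0$.  Imaged wide-field, a single release event
appears as a blurred, noisy bump rising and decaying with the sensor's
kinetics.  Two synaptic quantities are recoverable from such movies:

* the **spread length constant** $\lambda$: around an isolated release
  site, the pixel-wise maximal $\Delta F/F$ decays as
  $A\,e^{-d/\lambda}$ with distance $d$ from the site.  Sub-micrometre
  $\lambda$ values indicate spatially restricted, point-to-point
  transmission rather than volume transmission;
* the **vesicle-pool parameters** $(N_0, p, R, q)$ — readily releasable
  pool, per-vesicle release probability per stimulus, refill per stimulus,
  and quantal size (the $\Delta F/F$ contributed by one vesicle) — from
  responses to prolonged stimulus trains.

Both estimates are photon-limited.  The diffraction bound is the Abbe
limit $\Delta x = \lambda_{\mathrm{em}}/2\mathrm{NA}$; collecting $N$
photons improves the effective resolution as $N^{-1/2}$ for hardware
superresolution and $N^{-1/4}$ for computational deconvolution
(`abbe_limit()`, `effective_resolution()`, `photons_required()`).  The
$N^{-1/4}$ law is why deconvolution imaging of bright sensors is viable at
all — and why each further factor of two costs sixteen-fold more light.

## The forward simulator

`sim_config()` + `simulate_movie()` implement the generative model used by
every test.  It matters that this model is explicit, because parameter
recovery can only be demonstrated against known truth.

**Release.** On stimulus $k$ each site releases
$r_k \sim \mathrm{Binomial}(\lfloor o_k \rfloor, p)$ vesicles from its
current occupancy $o_k$, then refills:
$o_{k+1} = \min(N_0,\, o_k - r_k + R)$.  Fractional refill accumulates
deterministically (a `stochastic_refill` flag converts the fractional part
into a Bernoulli vesicle); the floor in the binomial keeps
$r_k \le o_k$ always.  At steady state the mean release balances the
refill $R$ regardless of the floor, which the test suite verifies on a
$10^4$-pulse train.

**Signal.** A release of $r_k$ vesicles contributes
$r_k\, q\, e^{-d/\lambda}$ spatially and a causal, peak-normalized
difference of exponentials
$k(t) \propto e^{-t/\tau_{off}} - e^{-t/\tau_{on}}$ temporally
(`sensor_kernel()`); contributions sum linearly.  The defaults
$\tau_{on} = 250$ ms, $\tau_{off} = 700$ ms are the published kinetics of
the GRAB-class acetylcholine sensor generation this pipeline targets.
The exponential spatial family is a modeling decision, not an empirical
claim about transmitter diffusion: it is the same family the estimator
fits, chosen precisely so that estimator recovery is testable under a
model-true generator.  The spatial field is evaluated analytically at
pixel centres (exact for a continuous profile); bilinear splatting is used
only for rendering point-like objects (beads), where, notably, splatting a
delta would convolve the rendered PSF with the pixel transfer triangle and
inflate its apparent width by several percent — point beads are therefore
placed by exact Fourier shift of the PSF.

**Acquisition.** Expected photons are
$F_0(x)\,(1 + \Delta F/F)$, blurred by the PSF, scaled by the bleach curve
$e^{-t/\tau_{bleach}}$, rigidly shifted by per-frame drift (bilinear
interpolation, replicated edges), Poisson-sampled, and optionally given
Gaussian read noise.  $F_0(x)$ is `baseline_photons` modulated by a
static two-scale random texture (cell-scale plus punctate,
`texture_rel_sd` default 0.3, floor 10%) emulating heterogeneous sensor
expression.  The texture is essential realism: a spatially uniform field
carries no registration information, whereas $\Delta F/F$ cancels the
texture exactly, so downstream estimators are unaffected by it.
Simulations are bit-reproducible from `seed`.

**What the simulator does not emulate** — and hence what passing tests do
not certify on real data: reaction–diffusion transmitter kinetics (the
true spatial family may not be exponential), out-of-focus light and 3D
PSFs, sensor saturation and Hill-type dose response, non-rigid tissue
motion, dark/blinking sensor states, and correlated camera noise.

## Preprocessing

**Registration** (`register_stack()`).  Rigid translation per frame
against the mean of the first ten frames.  The integer lag is found by
normalized cross-correlation over the *valid* (non-circular) overlap —
computed with a zero-padded FFT cross term and integral-image
normalization — and refined by parabolic interpolation of the NCC surface.
Classical whitened phase correlation was rejected after direct comparison:
for smooth, band-limited scenes it amplifies empty-band noise, and
circular unnormalized correlation is biased toward zero lag when content
does not wrap.  The correction applies the inverse shift via the Fourier
shift theorem.  Contract (verified in tests): RMSE $< 0.25$ px against
ground-truth drift at 500 photons/pixel; in practice $\approx 0.1$ px.
Estimated drift is relative to the reference, so a common offset equal to
the mean drift of the reference frames is removed before comparing with
truth.

**Bleaching** (`correct_bleaching()`).  A mono-exponential with offset,
$A e^{-t/\tau} + C$, is fitted (Levenberg–Marquardt) to the mean trace of
background pixels; the correction is $(F - C)/e^{-t/\hat\tau}$, so the
offset term absorbs non-bleaching autofluorescence.  Background pixels are
selected by low temporal max/mean ratio, which separates release sites
from static expression texture.  A trace whose first- and last-quarter
means differ by under 1% is declared bleach-free and left untouched
(fitting an exponential to noise is the alternative); a non-convergent fit
on a genuinely decaying trace falls back to frame-median normalization,
flagged in the returned parameters.

**$\Delta F/F$** (`compute_dff()`).  $F_0$ is the per-pixel mean over the
pre-stimulus window (all frames before the first stimulus by default).
Non-positive baselines are masked, not patched.

**Event-window collapse** (`collapse_event_window()`).  The ideal response
is separable — spatial profile times temporal kernel — so *any* temporal
average preserves the spatial profile, and hence $\lambda$, exactly, while
reducing photon noise by roughly the square root of the number of averaged
frames.  The collapse averages pre-stimulus frames into a baseline image
and the frames where the expected kernel exceeds half its peak into an
event image.  This is the recommended preprocessing for spread analysis of
single events: deconvolving individual 500-photon frames amplifies shot
noise into speckle that fragments site detection, whereas deconvolving the
collapsed pair is both more accurate and ~15x cheaper.  Amplitudes are
scaled by the window mean of the kernel; length constants are not.

## PSF calibration

`theoretical_psf()` provides an isotropic Gaussian with FWHM equal to the
Abbe limit — adequate for simulation and for seeding deconvolution, but
real aberrated systems should be measured.  `estimate_psf_from_beads()`
implements the empirical route: detect bead spots (local maxima above a
robust threshold with a 5%-of-peak floor), reject beads closer than
4 FWHM, subtract the median of the window border ring, refine centres by
twice-iterated intensity-weighted centroid, align spots to a common
sub-pixel centre by Fourier shift, average across beads and trials, and
optionally average over circular axes (`radial_symmetrize()`).  All
peak-shape measurements (FWHM via `psf_fwhm()`, symmetrization) operate on
a 4x sinc-upsampled copy: linear interpolation of a kernel sampled near
Nyquist systematically broadens it by enough to violate a 2% FWHM
tolerance.  Bead diameter is reported but not deconvolved out of the
estimate; beads smaller than half the resolution perturb the FWHM
negligibly.

## Deconvolution

`richardson_lucy()` is the classical multiplicative
maximum-likelihood update for Poisson noise,
$u \leftarrow u \cdot [\,(d / (u \ast h)) \ast \tilde h\,]$, with
replicate-boundary FFT convolutions.  It preserves non-negativity by
construction and total flux up to boundary leakage (tests enforce
$\le 1\%$ drift at every iteration).  Iteration stops at `max_iterations`
(default 50) or when the reconvolution RMS residual changes by less than
`stop_tol` ($10^{-4}$); the full residual history is returned because a
non-decreasing residual on noisy data is the practical overfitting signal.
An optional relaxation factor (`damping`) attenuates the multiplicative
correction for very noisy data.  On noiseless input the residual is
non-increasing and two points separated by $0.8\times$ the Abbe limit,
unresolved in the observed image, acquire a $\ge 20\%$ intensity dip after
50 iterations — both asserted numerically in the test suite.

## Spread analysis

`detect_release_sites()` finds local maxima of the temporal-max
$\Delta F/F$ image above
$\max(\texttt{min\_peak\_dff},\ \texttt{threshold\_sd}\times\sigma_{baseline})$,
with optional Gaussian smoothing of the detection image
(`smooth_sigma_px`, recommended 1–2 px on deconvolved data) to merge
sub-PSF noise speckle; reported positions are centroid-refined and peak
amplitudes always come from the unsmoothed image.
`select_isolated_sites()` keeps sites whose nearest neighbour is at least
3 µm away (about four length constants, cross-talk $< e^{-4}$).
`spatial_profile()` collects, for every pixel within the profile radius,
its distance to the sub-pixel centre and its temporal-max $\Delta F/F$;
pixels, not annuli, are the fit units.  `fit_spread_length()` fits
$A e^{-d/\lambda}$ by Levenberg–Marquardt with multi-start initialization
(the $A/e$ crossing, then a third and a tenth of the profile radius), an
optional additive offset for noisy baselines (off by default — the plain
single-exponential decay), optional weights (unweighted by default), and a
pixel-resampling bootstrap for the 95% CI.  Exactness on model-true
profiles is at the $10^{-6}$ relative level; scale equivariance and
amplitude invariance are property-tested.

Without deconvolution, PSF blur biases $\hat\lambda$ upward (a
FWHM-0.5 µm PSF inflates a 0.75 µm constant by ~7%); deconvolution
reduces that bias more than twofold (tests measure ~35x on noiseless
input).  The end-to-end study — 0.2 µm pixels, 500 baseline photons,
Poisson noise, collapse + 30 RL iterations — recovers
$\lambda = 0.75\,\mu m$ within 15% in at least 16 of 20 seeds
(`scripts/acceptance.R` recomputes this; observed: 20 of 20, median
within ~1.5%).

## Pool analysis

`extract_stimulus_responses()` turns a $\Delta F/F$ trace into
per-stimulus release amplitudes.  For widely spaced pulses the increment
method suffices (trace at the kernel peak time minus trace just before
the pulse).  For trains faster than the sensor decay — 16 Hz against
$\tau_{off} = 700$ ms leaves ~11 responses overlapping — the trace is
temporally deconvolved by least squares against the kernel placed at every
stimulus time, with **non-negativity enforced in the solver**
(`nnls_banded`, cyclic coordinate descent on the sparse banded normal
equations, warm-started at the clipped unconstrained solution).  The
constraint matters doubly: it regularizes an ill-conditioned system (at
stimulus-rate sampling the per-amplitude noise exceeds the quantal size),
and it makes the downstream clip-at-zero of `cumulative_release()` a
no-op, avoiding the rectification bias that clipping independent noisy
estimates would inject into the cumulative slope (roughly
$\sigma/\sqrt{2\pi}$ per stimulus, several times the true refill signal at
500 photons).

`fit_pool_model()` runs OLS on the final third of the cumulative curve
(the `late_fraction` default; the choice is reported and a quadratic
curvature check flags a late phase that is not yet linear).  The intercept
estimates the initially available pool in $\Delta F/F$ units and the slope
the refill rate per stimulus; vesicle units are derived only when a
quantal size is available.  Note the estimand subtlety: the intercept's
expectation is $q(N_0 - o^\ast)$ with steady-state occupancy
$o^\ast \approx R/p$, i.e. ~6% below $qN_0$ at the default parameters —
inherent to back-extrapolation, not an estimator defect.
`release_probability()` divides the mean of the first five releases by the
pool estimate (the raw running average of individual releases is returned
alongside, since its normalization is a matter of convention).
`estimate_quantal_size()` offers the first kernel-density mode of the
suprathreshold amplitudes and a trimmed-minimum variant; the noise floor
is the larger of a mirrored-negative robust SD and 30% of the 90th
percentile of positive amplitudes (a non-negative solver leaves no
negatives to measure noise from, but piles small spurious amplitudes near
zero).  Quantal estimation is the least robust output: at 16 Hz and 500
photons the per-stimulus noise is of the order of the quantum itself, and
the estimate is biased toward the noise scale; a slower train or brighter
baseline resolves it (property-tested at 2 Hz).

The acceptance study (20 seeds of the 1920-pulse, 16 Hz train with
$N_0 = 100$, $p = 0.08$, $R = 0.5$, $q = 0.01$) recovers the pool
($qN_0 = 1.0$) and refill ($qR = 0.005$) within 20% as medians; an exact
linear cumulative input returns its own slope and intercept to machine
precision.

## Problem sizes and runtime

The simulation studies are sized to be definitive yet fast on a single
CPU: spread recovery uses 64x64 px movies of 30 frames (20 seeds,
~1.5 s each); pool recovery uses 16x16 px movies of ~2000 frames
(20 seeds, ~3.5 s each); bead studies use 96x96 px fields.  These sizes
were chosen once, as the smallest at which the contracts are comfortably
testable, and are shared between the test suite and the acceptance
script.

## Interfaces and conventions

Pixel indices are 1-based in R; physical positions are micrometres from
the centre of pixel (1, 1); time is seconds from the first frame; stimulus
frames are assigned by `floor(t * frame_rate)`.  Movies travel as
multi-page TIFF (16-bit unsigned for integer data, 32-bit float otherwise,
values scaled into [0, 1] with the scale recorded) plus a JSON sidecar
carrying pixel size, frame rate, stimulus times and the provenance chain;
every processing step appends to that chain.  `run_pipeline()` executes
simulate/ingest → register → bleach-correct → (denoise) → (collapse) →
(deconvolve) → $\Delta F/F$ → spread and pool analyses from a validated
configuration (unknown keys are rejected before any compute, and
deconvolution without a configured PSF fails fast).  The thin CLI at
`inst/cli/transmitscope.R` maps subcommands onto these functions.

## Known limitations

Single 2D PSF (no depth dependence), rigid-translation-only registration,
mono-exponential bleaching, a single-pool depletion/refill model (no
reserve pool, facilitation or frequency-dependent refill), exponential
spatial spread as both generator and fit family, and quantal-size
estimates that degrade at photon budgets where the quantum is below the
per-stimulus noise.  Very large BigTIFF (>4 GB) inputs are untested in
this build and should be split or down-sampled upstream.
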