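# Shared fixtures: all synthetic, built in code at test time.

gaussian_kernel <- transmitscope:::gaussian_kernel
conv2_same <- transmitscope:::conv2_same
fourier_shift <- transmitscope:::fourier_shift
bilinear_shift <- transmitscope:::bilinear_shift
phase_correlate <- transmitscope:::phase_correlate
baseline_texture <- transmitscope:::baseline_texture
rms <- transmitscope:::rms

# Gaussian PSF with sigma = 1.5 px on a 0.2 um grid (FWHM ~ 0.706 um)
gauss_psf <- function(sigma_px = 1.5, support = 15, pixel_size_um = 0.2) {
  psf_model(gaussian_kernel(sigma_px, support), pixel_size_um)
}

# Theoretical PSF with FWHM 0.5 um sampled at 0.2 um (Abbe limit of
# 1000 nm emission at NA 1)
psf_fwhm05 <- function(pixel_size_um = 0.2) {
  theoretical_psf(optical_config(1000, numerical_aperture = 1),
                  pixel_size_um)
}

# Single isolated release site, full release on one stimulus: the
# configuration behind the spread-recovery studies (lambda 0.75 um,
# 0.2 um pixels, 500 baseline photons, peak dF/F 1).
single_site_config <- function(seed, ...) {
  defaults <- list(field_size_px = c(64L, 64L), pixel_size_um = 0.2,
                   frame_rate_hz = 10, n_frames = 30L,
                   stimulus_times_s = 1.0,
                   site_positions_um = matrix(c(6.45, 6.35), 1),
                   spread_length_um = 0.75, quantal_dff = 0.125,
                   pool_size_vesicles = 8L, release_prob = 1,
                   baseline_photons = 500, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Full spread pipeline on a simulated single-site movie: preprocess
# (event-window collapse) -> Richardson-Lucy -> dF/F -> detection ->
# exponential fit.  Returns the fitted lambda (um) or NA.
run_spread_pipeline <- function(seed, psf, deconvolve = TRUE,
                                max_iterations = 30) {
  sim <- simulate_movie(single_site_config(seed), psf)
  coll <- collapse_event_window(sim$movie)
  m <- if (deconvolve)
    deconvolve_movie(coll, psf, max_iterations = max_iterations)
  else coll
  dff <- compute_dff(m)
  res <- analyze_spread(dff, n_boot = 0, smooth_sigma_px = 2, frames = 2,
                        expected_lambda_um = 0.75, min_peak_dff = 0.2)
  if (nrow(res)) res$lambda_um[1] else NA_real_
}

# Prolonged-train simulation (1920 pulses at 16 Hz; N0 = 100, p = 0.08,
# R = 0.5, q = 0.01) and its pool analysis.
pool_train_config <- function(seed, n_stim = 1920L, rate = 16) {
  stim <- 2 + (seq_len(n_stim) - 1) / rate
  sim_config(field_size_px = c(16L, 16L), pixel_size_um = 0.2,
             frame_rate_hz = rate,
             n_frames = as.integer(ceiling((2 + n_stim / rate + 2.5) * rate)),
             stimulus_times_s = stim,
             site_positions_um = matrix(c(1.4, 1.4), 1),
             spread_length_um = 0.75, quantal_dff = 0.01,
             pool_size_vesicles = 100L, release_prob = 0.08,
             refill_per_stimulus = 0.5, baseline_photons = 500,
             seed = seed)
}

run_pool_pipeline <- function(seed, n_stim = 1920L, rate = 16) {
  cfg <- pool_train_config(seed, n_stim, rate)
  sim <- simulate_movie(cfg)
  dff <- compute_dff(sim$movie)
  # spread length for the matched-filter ROI, fitted on the time-average
  # response image (high SNR after averaging ~2000 frames)
  avg <- apply(dff$dff, c(2, 3), mean)
  arr <- array(0, c(2, dim(avg))); arr[2, , ] <- avg
  davg <- dff_stack(arr, dff$baseline_f0, c(1, 1), cfg$pixel_size_um, rate)
  lam <- tryCatch(
    fit_spread_length(spatial_profile(davg, list(y_px = 8, x_px = 8), 1.4,
                                      frames = 2),
                      n_boot = 0)$length_constant_um,
    error = function(e) NA_real_)
  tr <- roi_trace(dff, c(8, 8), radius_um = 1.4,
                  lambda_um = if (is.finite(lam)) lam else NULL)
  pf <- suppressWarnings(
    analyze_pool(tr, cfg$stimulus_times_s, rate, method = "kernel"))
  list(fit = pf, truth = sim$truth, config = cfg)
}

# Well-separated bead grid positions (separation 16 px >= 4 x FWHM for the
# sigma = 1.5 px PSF), jittered sub-pixel.
bead_grid <- function(n_beads, seed, jitter = 0.5) {
  set.seed(seed)
  full <- as.matrix(expand.grid(y = seq(16, 80, by = 16),
                                x = seq(16, 80, by = 16)))
  full[seq_len(n_beads), , drop = FALSE] +
    matrix(runif(2 * n_beads, -jitter, jitter), n_beads)
}

# RMS error between an estimated and a true PSF kernel (cropped to the
# smaller support, renormalized)
kernel_rms_error <- function(est, truth) {
  k1 <- est$kernel; k0 <- truth$kernel
  h <- (nrow(k1) - nrow(k0)) %/% 2
  if (h > 0) {
    k1 <- k1[(1 + h):(nrow(k1) - h), (1 + h):(ncol(k1) - h)]
    k1 <- k1 / sum(k1)
  } else if (h < 0) {
    h <- -h
    k0 <- k0[(1 + h):(nrow(k0) - h), (1 + h):(ncol(k0) - h)]
    k0 <- k0 / sum(k0)
  }
  sqrt(mean((k1 - k0)^2))
}
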