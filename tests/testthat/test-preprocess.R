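test_that("registration recovers stationary, integer and noisy drift", {
  cfg <- sim_config(field_size_px = c(48L, 48L), n_frames = 8L,
                    stimulus_times_s = 0.5, release_prob = 0,
                    baseline_photons = 500, shot_noise = FALSE, seed = 4)
  tex <- baseline_texture(cfg)
  # stationary movie: all shifts zero
  still <- movie_stack(aperm(array(tex, c(48, 48, 6)), c(3, 1, 2)),
                       0.2, 10)
  reg0 <- register_stack(still)
  expect_true(all(reg0$shifts == 0))

  # known integer shift (3, -2) on one frame is recovered exactly
  arr <- aperm(array(tex, c(48, 48, 6)), c(3, 1, 2))
  arr[4, , ] <- bilinear_shift(tex, 3, -2)
  m <- movie_stack(arr, 0.2, 10)
  reg <- register_stack(m, reference = "first")
  expect_equal(unname(reg$shifts[4, ]), c(3, -2), tolerance = 0.02)
  expect_equal(unname(reg$shifts[2, ]), c(0, 0))

  # sinusoidal drift at 500 photons: RMSE < 0.25 px against ground truth
  cfg_d <- single_site_config(seed = 7, field_size_px = c(48L, 48L),
                              n_sites = 3L, site_positions_um = NULL,
                              drift_px = list(amplitude_px = 3,
                                              period_s = 4))
  sim <- simulate_movie(cfg_d, psf_fwhm05())
  regd <- register_stack(sim$movie)
  err <- regd$shifts - sim$truth$drift_px
  err <- sweep(err, 2, colMeans(err))   # reference-frame offset is arbitrary
  expect_lt(rms(err), 0.25)
})

test_that("registration followed by the inverse shift is near-identity", {
  img <- outer(1:48, 1:48, function(y, x)
    200 + 150 * exp(-((y - 20)^2 + (x - 30)^2) / 80) +
      80 * sin(x / 3) * cos(y / 4))
  sh <- fourier_shift(img, 1.7, -2.4)
  est <- phase_correlate(img, sh)
  back <- fourier_shift(sh, -est[1], -est[2])
  expect_lt(rms((back - img)[5:44, 5:44]) / diff(range(img)), 0.01)
})

test_that("all-zero frames are skipped with a warning", {
  arr <- array(100, c(4, 16, 16)); arr[3, , ] <- 0
  m <- movie_stack(arr, 0.2, 10)
  expect_warning(reg <- register_stack(m), "all zero")
  expect_equal(unname(reg$shifts[3, ]), c(0, 0))
})

test_that("bleach correction recovers tau, offsets, and leaves clean movies", {
  # no bleach: movie unchanged within 0.1%, rate ~ 0
  cfg <- sim_config(field_size_px = c(32L, 32L), frame_rate_hz = 5,
                    n_frames = 50L, stimulus_times_s = 9,
                    release_prob = 0, baseline_photons = 500, seed = 3)
  sim <- simulate_movie(cfg)
  bl <- correct_bleaching(sim$movie)
  expect_equal(bl$params$tau_s, Inf)
  expect_equal(bl$movie$data, sim$movie$data, tolerance = 1e-3)

  # simulated tau = 60 s recovered within 10%
  cfg_b <- sim_config(field_size_px = c(32L, 32L), frame_rate_hz = 5,
                      n_frames = 300L, stimulus_times_s = 50,
                      quantal_dff = 0.01, pool_size_vesicles = 1L,
                      release_prob = 1, baseline_photons = 500,
                      bleach_tau_s = 60, seed = 3)
  sim_b <- simulate_movie(cfg_b)
  bl_b <- correct_bleaching(sim_b$movie)
  expect_lt(abs(bl_b$params$tau_s - 60) / 60, 0.1)
  # corrected background is flat: |relative slope| < 0.5% over the movie
  msk <- apply(bl_b$movie$data, c(2, 3), max) <=
    quantile(apply(bl_b$movie$data, c(2, 3), max), 0.5)
  trend <- vapply(seq_len(300), function(j)
    mean(bl_b$movie$data[j, , ][msk]), numeric(1))
  sl <- coef(lm(trend ~ seq_along(trend)))[2] * 300 / mean(trend)
  expect_lt(abs(sl), 0.005)

  # constant autofluorescence offset is recovered by the offset term
  tt <- (0:599) / 5
  offset_true <- 120
  arr <- array(0, c(600, 32, 32))
  set.seed(9)
  for (j in 1:600)
    arr[j, , ] <- rpois(1024, 400 * exp(-tt[j] / 60) + offset_true)
  m_o <- movie_stack(arr, 0.2, 5)
  bl_o <- correct_bleaching(m_o)
  expect_lt(abs(bl_o$params$offset - offset_true) / offset_true, 0.02)
})

test_that("denoising filters behave as contracted", {
  arr <- array(100, c(3, 32, 32))
  m <- movie_stack(arr, 0.2, 10)
  expect_equal(denoise(m, "none")$data, arr)

  # single impulse is removed by a median filter
  arr_i <- arr; arr_i[2, 16, 16] <- 5000
  m_i <- movie_stack(arr_i, 0.2, 10)
  md <- denoise(m_i, "median", width = 1)
  expect_lt(md$data[2, 16, 16], 200)

  # Gaussian filtering reduces Poisson pixel variance >= 3x
  set.seed(5)
  arr_p <- array(rpois(50 * 32 * 32, 100), c(50, 32, 32))
  m_p <- movie_stack(arr_p, 0.2, 10)
  g <- denoise(m_p, "gaussian", width = 1)
  v_raw <- mean(apply(arr_p[, 8:25, 8:25], c(2, 3), var))
  v_g <- mean(apply(g$data[, 8:25, 8:25], c(2, 3), var))
  expect_gt(v_raw / v_g, 3)

  expect_error(denoise(m, "wavelet"), "arg")
  expect_error(denoise(m, "gaussian", width = 40), "width")
})

test_that("dF/F computation is exact and masks bad baselines", {
  arr <- array(200, c(5, 8, 8))
  m <- movie_stack(arr, 0.2, 10, stimulus_times_s = 0.25)
  dff <- compute_dff(m)
  expect_true(all(dff$dff == 0))

  arr2 <- arr; arr2[4, , ] <- 400
  dff2 <- compute_dff(movie_stack(arr2, 0.2, 10), baseline_window = 1:2)
  expect_true(all(dff2$dff[4, , ] == 1))

  # noiseless simulated event of true peak dF/F 0.3 is recovered exactly
  cfg <- sim_config(field_size_px = c(32L, 32L), pixel_size_um = 0.2,
                    frame_rate_hz = 10, n_frames = 30L,
                    stimulus_times_s = 1.0,
                    site_positions_um = matrix(c(3.0, 3.0), 1),
                    spread_length_um = 0.75, quantal_dff = 0.3,
                    pool_size_vesicles = 1L, release_prob = 1,
                    baseline_photons = 500, shot_noise = FALSE, seed = 1)
  sim <- simulate_movie(cfg)
  dff3 <- compute_dff(sim$movie)
  true_peak <- max(sim$truth$ideal_dff[, 16, 16])
  expect_equal(max(dff3$dff[, 16, 16]), true_peak, tolerance = 1e-6)

  # zero-baseline pixels are masked with a warning
  arr3 <- array(10, c(5, 8, 8)); arr3[, 2, 2] <- 0
  expect_warning(dffm <- compute_dff(movie_stack(arr3, 0.2, 10),
                                     baseline_window = 1:2), "masked")
  expect_true(all(is.na(dffm$dff[, 2, 2])))
})

test_that("event-window collapse preserves the spatial profile exactly", {
  cfg <- sim_config(field_size_px = c(48L, 48L), pixel_size_um = 0.2,
                    frame_rate_hz = 10, n_frames = 30L,
                    stimulus_times_s = 1.0,
                    site_positions_um = matrix(c(4.7, 4.7), 1),
                    spread_length_um = 0.75, quantal_dff = 0.2,
                    pool_size_vesicles = 2L, release_prob = 1,
                    baseline_photons = 500, texture_rel_sd = 0,
                    shot_noise = FALSE, seed = 1)
  sim <- simulate_movie(cfg)
  coll <- collapse_event_window(sim$movie)
  expect_equal(dim(coll$data)[1], 2L)
  dff <- compute_dff(coll)
  prof <- spatial_profile(dff, list(y_px = 24.5, x_px = 24.5), 2.5,
                          frames = 2)
  fit <- fit_spread_length(prof, n_boot = 0)
  expect_equal(fit$length_constant_um, 0.75, tolerance = 1e-4)
})

test_that("preprocessing preserves acquisition metadata", {
  cfg <- single_site_config(seed = 2, field_size_px = c(32L, 32L),
                            site_positions_um = matrix(c(3.1, 3.1), 1))
  sim <- simulate_movie(cfg)
  out <- register_stack(sim$movie)$movie
  out <- correct_bleaching(out)$movie
  out <- denoise(out, "gaussian", width = 1)
  expect_equal(out$pixel_size_um, 0.2)
  expect_equal(out$frame_rate_hz, 10)
  expect_equal(out$stimulus_times_s, 1.0)
  expect_gt(length(out$provenance), 2)
})
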