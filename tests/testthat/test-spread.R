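test_that("release sites are detected with sub-pixel accuracy", {
  cfg <- single_site_config(seed = 4, shot_noise = FALSE,
                            texture_rel_sd = 0)
  sim <- simulate_movie(cfg)
  dff <- compute_dff(sim$movie)
  sites <- detect_release_sites(dff)
  expect_equal(nrow(sites), 1L)
  true_px <- cfg$site_positions_um / 0.2 + 1
  expect_lt(sqrt((sites$y_px - true_px[1])^2 + (sites$x_px - true_px[2])^2),
            0.5)

  # blank movie: no detections
  blank <- dff_stack(array(0, c(10, 32, 32)), matrix(500, 32, 32),
                     c(1, 5), 0.2, 10)
  expect_equal(nrow(detect_release_sites(blank, threshold_sd = 5)), 0L)

  # five well-separated sites, all found within 0.5 px
  pos <- rbind(c(3, 3), c(3, 9), c(9, 3), c(9, 9), c(6.2, 6.2))
  cfg5 <- single_site_config(seed = 9, site_positions_um = pos,
                             shot_noise = FALSE, texture_rel_sd = 0)
  sim5 <- simulate_movie(cfg5)
  dff5 <- compute_dff(sim5$movie)
  s5 <- detect_release_sites(dff5)
  expect_equal(nrow(s5), 5L)
  for (i in seq_len(5)) {
    d <- sqrt((s5$y_um - pos[i, 1])^2 + (s5$x_um - pos[i, 2])^2)
    expect_lt(min(d) / 0.2, 0.5)
  }
})

test_that("isolation filtering matches a brute-force oracle", {
  mk_sites <- function(pos_um) {
    df <- data.frame(site_id = seq_len(nrow(pos_um)),
                     y_px = pos_um[, 1] / 0.2 + 1,
                     x_px = pos_um[, 2] / 0.2 + 1,
                     y_um = pos_um[, 1], x_um = pos_um[, 2],
                     peak_dff = 1, peak_frame = 1L,
                     isolation_distance_um = NA_real_, isolated = NA)
    class(df) <- c("release_sites", "data.frame")
    df
  }
  # two sites 1 um apart at 3 um minimum: both excluded
  both <- select_isolated_sites(mk_sites(rbind(c(5, 5), c(5, 6))), 3)
  expect_equal(nrow(both), 0L)
  # a lone site is kept with infinite isolation
  lone <- select_isolated_sites(mk_sites(matrix(c(5, 5), 1)), 3)
  expect_equal(nrow(lone), 1L)
  expect_equal(lone$isolation_distance_um, Inf)
  # mixed random field equals the O(n^2) pairwise filter
  set.seed(21)
  pos <- cbind(runif(12, 0, 12), runif(12, 0, 12))
  got <- select_isolated_sites(mk_sites(pos), 3)$site_id
  dmat <- as.matrix(dist(pos)); diag(dmat) <- Inf
  want <- unname(which(apply(dmat, 1, min) >= 3))
  expect_equal(got, want)
})

test_that("spatial profiles report exact distances, counts and values", {
  cfg <- sim_config(field_size_px = c(64L, 64L), pixel_size_um = 0.2,
                    frame_rate_hz = 10, n_frames = 30L,
                    stimulus_times_s = 1.0,
                    site_positions_um = matrix(c(6.4, 6.4), 1),
                    spread_length_um = 0.75, quantal_dff = 0.5,
                    pool_size_vesicles = 2L, release_prob = 1,
                    baseline_photons = 500, texture_rel_sd = 0,
                    shot_noise = FALSE, seed = 2)
  sim <- simulate_movie(cfg)
  dff <- compute_dff(sim$movie)
  site <- list(y_px = 33, x_px = 33)   # 6.4 um on the 0.2 um grid
  prof <- spatial_profile(dff, site, max_radius_um = 2.0)
  # pixel count equals the counting oracle |{pixels: d <= r}|
  d <- sqrt(outer(((1:64) - 33)^2, ((1:64) - 33)^2, "+")) * 0.2
  expect_equal(nrow(prof), sum(d <= 2.0))
  # centre pixel: distance 0, value = peak dF/F
  i0 <- which.min(prof$distance_um)
  expect_equal(prof$distance_um[i0], 0)
  expect_equal(prof$max_dff[i0], max(dff$dff[, 33, 33]))
  # noiseless values follow A exp(-d / lambda) within 1%
  A <- prof$max_dff[i0]
  expect_lt(max(abs(prof$max_dff - A * exp(-prof$distance_um / 0.75)) / A),
            0.01)
  # radius past the field edge warns and crops
  expect_warning(spatial_profile(dff, list(y_px = 3, x_px = 3), 2), "crop")
})

test_that("exponential fits recover generating length constants exactly", {
  d <- as.vector(sqrt(outer((-15:15)^2, (-15:15)^2, "+"))) * 0.1
  for (lam in c(0.65, 0.91, 0.88)) {
    prof <- data.frame(distance_um = d, max_dff = 1.2 * exp(-d / lam))
    fit <- fit_spread_length(prof, n_boot = 0)
    expect_lt(abs(fit$length_constant_um / lam - 1), 1e-6)
    expect_lt(abs(fit$amplitude / 1.2 - 1), 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-9)
  }
})

test_that("spread fits are amplitude-invariant and scale-equivariant", {
  d <- seq(0, 3, by = 0.06)
  prof <- data.frame(distance_um = d, max_dff = exp(-d / 0.7))
  f1 <- fit_spread_length(prof, n_boot = 0)
  prof_big <- transform(prof, max_dff = 37 * max_dff)
  f2 <- fit_spread_length(prof_big, n_boot = 0)
  expect_equal(f1$length_constant_um, f2$length_constant_um,
               tolerance = 1e-9)
  # rescaling all distances by c rescales lambda by c exactly
  prof_scaled <- transform(prof, distance_um = 2.5 * distance_um)
  f3 <- fit_spread_length(prof_scaled, n_boot = 0)
  expect_equal(f3$length_constant_um, 2.5 * f1$length_constant_um,
               tolerance = 1e-9)
})

test_that("bootstrap CI brackets the point estimate on noisy profiles", {
  set.seed(14)
  d <- seq(0, 3, by = 0.05)
  prof <- data.frame(distance_um = d,
                     max_dff = exp(-d / 0.75) + rnorm(length(d), 0, 0.03))
  fit <- fit_spread_length(prof, n_boot = 99)
  expect_true(fit$ci95_length_um[1] <= fit$length_constant_um)
  expect_true(fit$ci95_length_um[2] >= fit$length_constant_um)
  expect_lt(abs(fit$length_constant_um - 0.75), 0.1)
})

test_that("PSF blur biases lambda upward; deconvolution removes the bias", {
  psf <- psf_fwhm05()
  cfg <- single_site_config(seed = 5, baseline_photons = 50000,
                            texture_rel_sd = 0)
  sim <- simulate_movie(cfg, psf)
  coll <- collapse_event_window(sim$movie)
  lam_of <- function(m) {
    res <- analyze_spread(compute_dff(m), n_boot = 0, smooth_sigma_px = 2,
                          frames = 2)
    res$lambda_um[1]
  }
  l_raw <- lam_of(coll)
  l_dec <- lam_of(deconvolve_movie(coll, psf, max_iterations = 50))
  expect_gt(l_raw, 0.75)                    # blur inflates lambda
  expect_gt(abs(l_raw - 0.75) / abs(l_dec - 0.75), 2)  # bias shrinks >= 2x
})
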