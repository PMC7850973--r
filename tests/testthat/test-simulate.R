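test_that("pool dynamics deplete, stay silent, and reach refill balance", {
  # full depletion in one pulse
  cfg <- sim_config(stimulus_times_s = seq(1, 2.8, by = 0.2),
                    pool_size_vesicles = 5L, release_prob = 1,
                    refill_per_stimulus = 0, n_frames = 40L, seed = 1)
  ev <- simulate_pool_dynamics(cfg)
  expect_equal(ev$released, c(5L, rep(0L, 9)))
  expect_equal(sum(ev$released), 5L)

  # silent site at p = 0
  cfg0 <- sim_config(stimulus_times_s = seq(1, 2.8, by = 0.2),
                     pool_size_vesicles = 5L, release_prob = 0,
                     n_frames = 40L, seed = 1)
  ev0 <- simulate_pool_dynamics(cfg0)
  expect_true(all(ev0$released == 0))
  expect_true(all(ev0$occupancy == 5))

  # long-run balance: mean release approaches the refill rate
  n_stim <- 10000L
  cfg_ss <- sim_config(frame_rate_hz = 16, n_frames = n_stim + 64L,
                       stimulus_times_s = 2 + (seq_len(n_stim) - 1) / 16,
                       pool_size_vesicles = 100L, release_prob = 0.08,
                       refill_per_stimulus = 0.5, seed = 42)
  ev_ss <- simulate_pool_dynamics(cfg_ss)
  late <- ev_ss$released[-(1:500)]
  expect_lt(abs(mean(late) - 0.5) / 0.5, 0.05)

  # invariants: bounded occupancy, release never exceeds it
  expect_true(all(ev_ss$occupancy >= 0 & ev_ss$occupancy <= 100))
  expect_true(all(ev_ss$released <= ev_ss$occupancy))
})

test_that("ideal dF/F rendering follows the exponential-spread model", {
  cfg <- sim_config(field_size_px = c(33L, 33L), pixel_size_um = 0.2,
                    frame_rate_hz = 10, n_frames = 40L,
                    stimulus_times_s = 1.0,
                    site_positions_um = matrix(c(3.2, 3.2), 1),
                    spread_length_um = 0.75, quantal_dff = 0.1,
                    pool_size_vesicles = 1L, release_prob = 1, seed = 1)
  ev <- list(simulate_pool_dynamics(cfg))
  expect_equal(ev[[1]]$released[1], 1L)
  dff <- render_ideal_dff(cfg, ev)
  site_px <- c(17L, 17L)   # 3.2 um / 0.2 um + 1
  peak <- max(dff[, site_px[1], site_px[2]])
  # one vesicle of q = 0.1 at distance 0: peak dF/F = q at the kernel peak
  tt <- (seq_len(40L) - 1) / 10
  kmax <- max(sensor_kernel(tt - 1, 250, 700))
  expect_equal(peak, 0.1 * kmax, tolerance = 1e-12)
  # pixel at d = lambda: peak is q / e
  px_lambda <- site_px + c(0L, round(0.75 / 0.2))  # 3.75 px away... use exact
  d_px <- round(0.75 / 0.2)  # 3.75 rounds to 4 px = 0.8 um; use the formula
  v <- max(dff[, site_px[1], site_px[2] + d_px])
  expect_equal(v, 0.1 * kmax * exp(-(d_px * 0.2) / 0.75), tolerance = 1e-12)

  # linearity: two simultaneous vesicles double the profile, lambda unchanged
  cfg2 <- sim_config(field_size_px = c(33L, 33L), pixel_size_um = 0.2,
                     frame_rate_hz = 10, n_frames = 40L,
                     stimulus_times_s = 1.0,
                     site_positions_um = matrix(c(3.2, 3.2), 1),
                     spread_length_um = 0.75, quantal_dff = 0.1,
                     pool_size_vesicles = 2L, release_prob = 1, seed = 1)
  ev2 <- list(simulate_pool_dynamics(cfg2))
  expect_equal(ev2[[1]]$released[1], 2L)
  dff2 <- render_ideal_dff(cfg2, ev2)
  expect_equal(dff2, 2 * dff, tolerance = 1e-12)
})

test_that("total rendered dF/F matches the closed-form spatial sum", {
  cfg <- sim_config(field_size_px = c(64L, 64L), pixel_size_um = 0.2,
                    frame_rate_hz = 10, n_frames = 30L,
                    stimulus_times_s = 1.0,
                    site_positions_um = matrix(c(6.4, 6.4), 1),
                    spread_length_um = 0.5, quantal_dff = 0.1,
                    pool_size_vesicles = 3L, release_prob = 1, seed = 2)
  ev <- list(simulate_pool_dynamics(cfg))
  dff <- render_ideal_dff(cfg, ev)
  # closed form: sum_x exp(-d(x)/lambda) * released * q * k(t)
  y <- (0:63) * 0.2; x <- (0:63) * 0.2
  d <- sqrt(outer((y - 6.4)^2, (x - 6.4)^2, "+"))
  spatial_sum <- sum(exp(-d / 0.5))
  tt <- (0:29) / 10
  expected <- 0.1 * ev[[1]]$released[1] * sensor_kernel(tt - 1, 250, 700) *
    spatial_sum
  rendered <- apply(dff, 1, sum)
  expect_equal(rendered, expected, tolerance = 1e-3)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- single_site_config(seed = 11)
  s1 <- simulate_movie(cfg)
  s2 <- simulate_movie(cfg)
  expect_identical(s1$movie$data, s2$movie$data)
  expect_identical(s1$truth$events, s2$truth$events)
})

test_that("acquisition effects: noiseless identity, bleach decay, Poisson", {
  # zero noise, no PSF/drift/bleach: output is exactly F0 x (1 + dF/F)
  cfg <- single_site_config(seed = 1, texture_rel_sd = 0, shot_noise = FALSE)
  ev <- list(simulate_pool_dynamics(cfg))
  ideal <- render_ideal_dff(cfg, ev)
  movie <- apply_acquisition_effects(ideal, cfg)
  expect_equal(movie$data, 500 * (1 + ideal), tolerance = 1e-12)

  # uniform field, bleach tau = movie span: last-frame mean ~ F0 / e
  n <- 20L
  cfg_b <- sim_config(field_size_px = c(128L, 128L), pixel_size_um = 0.2,
                      frame_rate_hz = 1, n_frames = n,
                      stimulus_times_s = 1, release_prob = 0,
                      baseline_photons = 500, texture_rel_sd = 0,
                      bleach_tau_s = (n - 1) / 1, seed = 3)
  ev_b <- list(simulate_pool_dynamics(cfg_b))
  m_b <- apply_acquisition_effects(render_ideal_dff(cfg_b, ev_b), cfg_b)
  expect_lt(abs(mean(m_b$data[n, , ]) / (500 * exp(-1)) - 1), 0.01)

  # Poisson statistics: per-pixel variance ~ mean across repeats
  reps <- sapply(1:100, function(s) {
    cfg_p <- sim_config(field_size_px = c(16L, 16L), pixel_size_um = 0.2,
                        frame_rate_hz = 10, n_frames = 2L,
                        stimulus_times_s = 0.15, release_prob = 0,
                        baseline_photons = 200, texture_rel_sd = 0, seed = s)
    ev_p <- list(simulate_pool_dynamics(cfg_p))
    as.vector(apply_acquisition_effects(render_ideal_dff(cfg_p, ev_p),
                                        cfg_p)$data[1, , ])
  })
  ratio <- mean(apply(reps, 1, var) / rowMeans(reps))
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)

  # impossible photon counts are rejected
  expect_error(apply_acquisition_effects(ideal - 2, cfg), "negative")
})

test_that("bead stacks render the PSF with sub-pixel fidelity", {
  psf <- gauss_psf()
  # one centered bead, no noise: the frame equals the PSF up to scale
  bs <- simulate_bead_stack(matrix(c(33, 33), 1), psf, photons = 1000,
                            n_trials = 1, seed = NA,
                            field_size_px = c(65L, 65L))
  fr <- bs$data[1, , ]
  sub <- fr[26:40, 26:40]
  expect_equal(sub / sum(sub), psf$kernel, tolerance = 1e-6)

  # off-grid bead: intensity-weighted centroid within 0.1 px of truth
  pos <- matrix(c(30.37, 41.81), 1)
  bs2 <- simulate_bead_stack(pos, psf, photons = 1000, n_trials = 1,
                             seed = NA, field_size_px = c(65L, 65L))
  fr2 <- pmax(bs2$data[1, , ], 0)
  cy <- sum(row(fr2) * fr2) / sum(fr2)
  cx <- sum(col(fr2) * fr2) / sum(fr2)
  expect_lt(abs(cy - 30.37), 0.1)
  expect_lt(abs(cx - 41.81), 0.1)

  # 10 beads x 20 trials = 200 extractable spots
  pos10 <- bead_grid(10, seed = 5)
  bs3 <- simulate_bead_stack(pos10, psf, photons = 20000, n_trials = 20,
                             seed = 2, field_size_px = c(96L, 96L))
  est <- estimate_psf_from_beads(bs3, nominal_fwhm_um = 0.7)
  expect_equal(est$n_beads_averaged, 200L)

  # overlapping beads are flagged
  expect_warning(
    bs4 <- simulate_bead_stack(rbind(c(30, 30), c(33, 31)), psf,
                               photons = 1000, n_trials = 1, seed = 1,
                               field_size_px = c(64L, 64L)),
    "overlap")
  expect_true(attr(bs4, "overlapping_beads"))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(release_prob = 1.5), "release_prob")
  expect_error(sim_config(pool_size_vesicles = 0), "pool_size")
  expect_error(sim_config(stimulus_times_s = 100, n_frames = 30), "duration")
  expect_error(sim_config(spread_length_um = -1), "spread_length")
  expect_warning(
    sim_config(site_positions_um = rbind(c(3, 3), c(3.5, 3)),
               min_separation_um = 3),
    "separation")
})
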