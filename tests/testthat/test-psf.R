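test_that("Abbe limit arithmetic is exact", {
  expect_equal(abbe_limit(optical_config(500, numerical_aperture = 1)), 250)
  # water-immersion at the full collection angle: NA = n sin(90 deg) = 1.33
  expect_equal(
    abbe_limit(optical_config(488, refractive_index = 1.33,
                              half_angle_deg = 90)),
    488 / (2 * 1.33), tolerance = 1e-12)
  # homogeneity: doubling NA halves the limit
  a1 <- abbe_limit(optical_config(500, numerical_aperture = 0.7))
  a2 <- abbe_limit(optical_config(500, numerical_aperture = 1.4))
  expect_equal(a1, 2 * a2)
})

test_that("photon-scaling laws and their inversion are exact", {
  o1 <- optical_config(500, numerical_aperture = 1, photon_count = 1)
  expect_equal(effective_resolution(o1, "superresolution"), 250)
  expect_equal(effective_resolution(o1, "deconvolution"), 250)
  o16 <- optical_config(500, numerical_aperture = 1, photon_count = 16)
  expect_equal(effective_resolution(o16, "superresolution"), 250 / 4)
  expect_equal(effective_resolution(o16, "deconvolution"), 250 / 2)
  expect_error(effective_resolution(o16, "magic"), "arg")

  # inversion: 2x improvement costs 4 photons (hardware) vs 16 (software)
  expect_equal(photons_required(o1, 125, "superresolution"), 4)
  expect_equal(photons_required(o1, 125, "deconvolution"), 16)
  expect_equal(photons_required(o1, 25, "deconvolution"), 1e4)
  at_limit <- photons_required(o1, 300, "deconvolution")
  expect_equal(as.numeric(at_limit), 1)
  expect_match(attr(at_limit, "note"), "Abbe")

  # monotonicity; deconvolution never beats superresolution for N > 1
  Ns <- c(2, 5, 10, 100, 1e4)
  for (mode in c("superresolution", "deconvolution")) {
    res <- sapply(Ns, function(N)
      effective_resolution(optical_config(500, numerical_aperture = 1,
                                          photon_count = N), mode))
    expect_true(all(diff(res) < 0))
  }
  expect_true(all(sapply(Ns, function(N) {
    o <- optical_config(500, numerical_aperture = 1, photon_count = N)
    effective_resolution(o, "deconvolution") >=
      effective_resolution(o, "superresolution")
  })))
})

test_that("optical configuration validation", {
  expect_error(optical_config(500), "supply")
  expect_error(optical_config(500, numerical_aperture = 1.2,
                              refractive_index = 1.33,
                              half_angle_deg = 60), "not both")
  expect_error(optical_config(500, refractive_index = 0.8,
                              half_angle_deg = 60), "refractive_index")
  expect_error(optical_config(-1, numerical_aperture = 1), "wavelength")
})

test_that("theoretical PSF is normalized, well-sampled and correctly sized", {
  psf <- theoretical_psf(optical_config(500, numerical_aperture = 1), 0.1)
  expect_equal(sum(psf$kernel), 1, tolerance = 1e-12)
  expect_equal(psf$fwhm_um, 0.25, tolerance = 0.01)   # 2.5 px
  expect_equal(psf$provenance, "theoretical")
  # truncation: support spanning > 4 FWHM leaves < 1e-6 mass at the border
  border <- c(psf$kernel[1, ], psf$kernel[nrow(psf$kernel), ],
              psf$kernel[, 1], psf$kernel[, ncol(psf$kernel)])
  expect_lt(sum(border), 1e-6)
  # undersampled grid is rejected
  expect_error(theoretical_psf(optical_config(500, numerical_aperture = 1),
                               0.2), "undersamples")
  expect_error(theoretical_psf(optical_config(1000,
                                              numerical_aperture = 1),
                               0.2, support = 14), "odd")
})

test_that("bead-based PSF estimation recovers FWHM and the exact kernel", {
  psf <- gauss_psf(sigma_px = 1.5)
  true_fwhm <- 2 * sqrt(2 * log(2)) * 1.5 * 0.2
  # noiseless multi-bead stack: FWHM within 2%
  bs <- simulate_bead_stack(bead_grid(5, seed = 3), psf, photons = 2e4,
                            n_trials = 1, seed = NA,
                            field_size_px = c(96L, 96L))
  est <- estimate_psf_from_beads(bs, nominal_fwhm_um = 0.7)
  expect_lt(abs(est$fwhm_um / true_fwhm - 1), 0.02)
  expect_equal(sum(est$kernel), 1, tolerance = 1e-9)
  expect_equal(est$provenance, "empirical")

  # single noiseless centered bead: kernel equals the rendered PSF
  bs1 <- simulate_bead_stack(matrix(c(48, 48), 1), psf, photons = 1e4,
                             n_trials = 1, seed = NA,
                             field_size_px = c(96L, 96L))
  est1 <- estimate_psf_from_beads(bs1, nominal_fwhm_um = 0.7,
                                  symmetrize = FALSE)
  expect_lt(kernel_rms_error(est1, psf), 1e-6)

  # empty stack errors
  blank <- movie_stack(array(0, c(2, 32, 32)), 0.2, 1)
  expect_error(estimate_psf_from_beads(blank, nominal_fwhm_um = 0.7),
               "no beads")
})

test_that("multi-bead averaging suppresses noise in the estimated kernel", {
  psf <- gauss_psf(sigma_px = 1.5)
  err_for <- function(n_beads, seed) {
    bs <- simulate_bead_stack(bead_grid(n_beads, seed), psf,
                              photons = 2000, n_trials = 1, seed = seed,
                              field_size_px = c(96L, 96L))
    est <- suppressWarnings(
      estimate_psf_from_beads(bs, nominal_fwhm_um = 0.7,
                              symmetrize = FALSE))
    kernel_rms_error(est, psf)
  }
  e1 <- median(sapply(1:8, function(s) err_for(1, s)))
  e20 <- median(sapply(1:8, function(s) err_for(20, s + 100)))
  expect_gt(e1 / e20, 3)
})

test_that("radial symmetrization preserves mass and centre", {
  set.seed(2)
  k <- gaussian_kernel(2, 17)
  k <- k * (1 + 0.2 * matrix(runif(289), 17, 17))  # break symmetry
  k <- k / sum(k)
  ks <- radial_symmetrize(k)
  expect_equal(sum(ks), sum(k), tolerance = 1e-9)
  com_k <- transmitscope:::kernel_com(k)
  com_s <- transmitscope:::kernel_com(ks)
  expect_lt(max(abs(com_k - com_s)), 0.05)
})
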