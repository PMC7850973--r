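#' Simulation configuration for synthetic sensor movies
#'
#' Defines the full generative model for a synthetic transmitter-sensor
#' movie: release-site geometry, vesicle-pool dynamics, spatial transmitter
#' spread, sensor kinetics, optics and noise.  Defaults are typical of
#' wide-field imaging with GPCR/PBP-based sensors: quantal responses of a
#' few percent \eqn{\Delta F/F}, sensor rise/decay of 250/700 ms, hundreds
#' of baseline photons per pixel, and sub-micrometre transmitter spread.
#'
#' @param field_size_px integer pair `c(ny, nx)`.
#' @param pixel_size_um pixel pitch, micrometres.
#' @param frame_rate_hz acquisition rate, Hz.
#' @param n_frames number of frames.
#' @param stimulus_times_s stimulus onset times, seconds; all must fall
#'   within the movie duration.
#' @param site_positions_um release-site positions, n x 2 matrix of
#'   `(y_um, x_um)`; alternatively `NULL` with `n_sites` set for random
#'   placement respecting `min_separation_um`.
#' @param n_sites,min_separation_um random-placement alternative to
#'   `site_positions_um`.
#' @param spread_length_um ground-truth spatial spread length constant
#'   \eqn{\lambda} (µm): peak \eqn{\Delta F/F} decays as
#'   \eqn{e^{-d/\lambda}} with distance from the site.
#' @param quantal_dff peak \eqn{\Delta F/F} contributed by one vesicle (q).
#' @param pool_size_vesicles readily releasable pool size N0.
#' @param release_prob per-vesicle release probability per stimulus, p in
#'   [0, 1] (0 gives a silent site).
#' @param refill_per_stimulus vesicles replenished per stimulus (R >= 0);
#'   fractional amounts accumulate deterministically by default.
#' @param stochastic_refill if `TRUE`, the fractional part of the refill is
#'   realized as a Bernoulli vesicle instead of carrying over.
#' @param sensor_tau_on_ms,sensor_tau_off_ms sensor rise/decay time
#'   constants, ms.
#' @param baseline_photons expected baseline photons per pixel per frame F0.
#' @param texture_rel_sd relative SD of the static multiplicative baseline
#'   texture emulating heterogeneous sensor expression across the field
#'   (0 gives a spatially uniform baseline).  Registration of real movies
#'   relies on such static structure; \eqn{\Delta F/F} cancels it exactly.
#' @param texture_scale_um correlation length of the baseline texture.
#' @param bleach_tau_s mono-exponential photobleaching time constant,
#'   seconds; `Inf` for none.
#' @param drift_px per-frame rigid drift: an `n_frames x 2` matrix of
#'   `(dy, dx)` pixel shifts, or `list(amplitude_px =, period_s =)` for a
#'   sinusoidal trajectory, or `NULL` for none.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @param shot_noise apply Poisson photon sampling (`FALSE` returns the
#'   noiseless expected image, useful for oracle tests).
#' @param seed integer RNG seed; everything stochastic derives from it.
#'
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(field_size_px = c(64L, 64L),
                       pixel_size_um = 0.2,
                       frame_rate_hz = 10,
                       n_frames = 40L,
                       stimulus_times_s = 1.0,
                       site_positions_um = NULL,
                       n_sites = 1L,
                       min_separation_um = 3.0,
                       spread_length_um = 0.75,
                       quantal_dff = 0.125,
                       pool_size_vesicles = 8L,
                       release_prob = 1.0,
                       refill_per_stimulus = 0,
                       stochastic_refill = FALSE,
                       sensor_tau_on_ms = 250,
                       sensor_tau_off_ms = 700,
                       baseline_photons = 500,
                       texture_rel_sd = 0.3,
                       texture_scale_um = 2,
                       bleach_tau_s = Inf,
                       drift_px = NULL,
                       read_noise_sd = 0,
                       shot_noise = TRUE,
                       seed = 1L) {
  cfg <- list(field_size_px = as.integer(field_size_px),
              pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
              n_frames = as.integer(n_frames),
              stimulus_times_s = sort(stimulus_times_s),
              site_positions_um = site_positions_um,
              n_sites = as.integer(n_sites),
              min_separation_um = min_separation_um,
              spread_length_um = spread_length_um, quantal_dff = quantal_dff,
              pool_size_vesicles = as.integer(pool_size_vesicles),
              release_prob = release_prob,
              refill_per_stimulus = refill_per_stimulus,
              stochastic_refill = isTRUE(stochastic_refill),
              sensor_tau_on_ms = sensor_tau_on_ms,
              sensor_tau_off_ms = sensor_tau_off_ms,
              baseline_photons = baseline_photons,
              texture_rel_sd = texture_rel_sd,
              texture_scale_um = texture_scale_um,
              bleach_tau_s = bleach_tau_s, drift_px = drift_px,
              read_noise_sd = read_noise_sd,
              shot_noise = isTRUE(shot_noise), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(field_size_px) != 2L || any(field_size_px < 4L))
      stop("`field_size_px` must be two integers >= 4", call. = FALSE)
    if (pixel_size_um <= 0 || frame_rate_hz <= 0 || n_frames < 1)
      stop("pixel size, frame rate and frame count must be positive",
           call. = FALSE)
    dur <- n_frames / frame_rate_hz
    if (length(stimulus_times_s) < 1)
      stop("at least one stimulus time is required", call. = FALSE)
    if (any(stimulus_times_s < 0 | stimulus_times_s >= dur))
      stop("stimulus times must lie within the movie duration", call. = FALSE)
    if (spread_length_um <= 0)
      stop("`spread_length_um` must be > 0", call. = FALSE)
    if (quantal_dff <= 0) stop("`quantal_dff` must be > 0", call. = FALSE)
    if (pool_size_vesicles < 1)
      stop("`pool_size_vesicles` must be a positive integer", call. = FALSE)
    if (release_prob < 0 || release_prob > 1)
      stop("`release_prob` must lie in [0, 1]", call. = FALSE)
    if (refill_per_stimulus < 0)
      stop("`refill_per_stimulus` must be >= 0", call. = FALSE)
    if (sensor_tau_on_ms <= 0 || sensor_tau_off_ms <= 0)
      stop("sensor time constants must be > 0", call. = FALSE)
    if (baseline_photons <= 0)
      stop("`baseline_photons` must be > 0", call. = FALSE)
    if (texture_rel_sd < 0 || texture_scale_um <= 0)
      stop("texture parameters must be non-negative / positive", call. = FALSE)
    if (read_noise_sd < 0) stop("`read_noise_sd` must be >= 0", call. = FALSE)
  })
  if (!is.null(cfg$site_positions_um)) {
    pos <- as.matrix(cfg$site_positions_um)
    if (ncol(pos) != 2) stop("`site_positions_um` must be n x 2", call. = FALSE)
    ext <- (cfg$field_size_px - 1L) * cfg$pixel_size_um
    if (any(pos[, 1] < 0 | pos[, 1] > ext[1] | pos[, 2] < 0 | pos[, 2] > ext[2]))
      stop("site positions must lie within the field", call. = FALSE)
    if (nrow(pos) > 1) {
      dmin <- min(dist(pos))
      if (dmin < cfg$min_separation_um)
        warning(sprintf(
          "site separation %.3g um below stated minimum %.3g um",
          dmin, cfg$min_separation_um))
    }
    cfg$site_positions_um <- pos
    cfg$n_sites <- nrow(pos)
  } else {
    cfg$site_positions_um <- place_sites(cfg)
  }
  cfg
}

# Rejection-sample site positions with the requested minimum separation,
# keeping a 2*lambda margin from the field edge.
place_sites <- function(cfg) {
  ext <- (cfg$field_size_px - 1L) * cfg$pixel_size_um
  margin <- min(2 * cfg$spread_length_um, min(ext) / 4)
  set.seed(cfg$seed + 77L)
  pos <- matrix(NA_real_, cfg$n_sites, 2)
  n_placed <- 0L
  for (attempt in seq_len(2000L * cfg$n_sites)) {
    cand <- c(runif(1, margin, ext[1] - margin),
              runif(1, margin, ext[2] - margin))
    if (n_placed == 0L ||
        min(sqrt(colSums((t(pos[seq_len(n_placed), , drop = FALSE]) - cand)^2))) >=
        cfg$min_separation_um) {
      n_placed <- n_placed + 1L
      pos[n_placed, ] <- cand
      if (n_placed == cfg$n_sites) break
    }
  }
  if (n_placed < cfg$n_sites)
    stop("could not place ", cfg$n_sites, " sites at min separation ",
         cfg$min_separation_um, " um; enlarge the field", call. = FALSE)
  pos
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %dx%d px @ %.3g um, %d frames @ %.3g Hz, %d stimuli\n",
    x$field_size_px[1], x$field_size_px[2], x$pixel_size_um, x$n_frames,
    x$frame_rate_hz, length(x$stimulus_times_s)))
  cat(sprintf(
    "  %d site(s); lambda %.3g um, q %.3g dF/F, N0 %d, p %.3g, R %.3g/stim\n",
    nrow(x$site_positions_um), x$spread_length_um, x$quantal_dff,
    x$pool_size_vesicles, x$release_prob, x$refill_per_stimulus))
  invisible(x)
}

#' Simulate vesicle-pool dynamics at one release site
#'
#' Binomial release from the available pool on every stimulus, with
#' depletion and per-stimulus refill: released_k ~ Binomial(occupancy_k, p)
#' and occupancy_(k+1) = min(N0, occupancy_k - released_k + R).  Fractional
#' occupancy (accumulated from fractional refill R) carries over but only
#' whole vesicles can be released, so released_k <= occupancy_k always; at
#' steady state the mean release per stimulus balances the refill R.
#'
#' @param config a [sim_config()].
#' @param site_index which site (seeds are decorrelated across sites).
#' @return data frame with one row per stimulus: `stimulus_index`,
#'   `occupancy` (before release), `released`, `occupancy_after`.
#' @export
simulate_pool_dynamics <- function(config, site_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  K <- length(config$stimulus_times_s)
  p <- config$release_prob
  N0 <- config$pool_size_vesicles
  R <- config$refill_per_stimulus
  set.seed(config$seed + 1000L * site_index)
  occ <- numeric(K); rel <- integer(K); occ_after <- numeric(K)
  o <- as.numeric(N0)
  for (k in seq_len(K)) {
    occ[k] <- o
    r <- rbinom(1L, floor(o), p)
    rel[k] <- r
    refill <- if (config$stochastic_refill) {
      floor(R) + rbinom(1L, 1L, R - floor(R))
    } else R
    o <- min(N0, o - r + refill)
    occ_after[k] <- o
  }
  data.frame(stimulus_index = seq_len(K), occupancy = occ,
             released = rel, occupancy_after = occ_after)
}

#' Render the noiseless delta F over F stack
#'
#' Each release event of `n` vesicles at site `s` on stimulus `k`
#' contributes `n * quantal_dff * exp(-d / lambda)` spatially (distance `d`
#' in micrometres from the sub-pixel site position, evaluated at pixel
#' centres) and the peak-normalized [sensor_kernel()] temporally;
#' contributions of all events sum linearly.
#'
#' @param config a [sim_config()].
#' @param events list of per-site event tables from
#'   [simulate_pool_dynamics()] (one element per site, in site order).
#' @return 3D array `[frame, row, col]` of noiseless \eqn{\Delta F/F}.
#' @export
render_ideal_dff <- function(config, events) {
  stopifnot(inherits(config, "sim_config"))
  if (config$spread_length_um <= 0) stop("spread length must be > 0")
  ny <- config$field_size_px[1]; nx <- config$field_size_px[2]
  tt <- (seq_len(config$n_frames) - 1) / config$frame_rate_hz
  dff <- array(0, c(config$n_frames, ny, nx))
  y_um <- (seq_len(ny) - 1) * config$pixel_size_um
  x_um <- (seq_len(nx) - 1) * config$pixel_size_um
  for (s in seq_along(events)) {
    pos <- config$site_positions_um[s, ]
    d <- sqrt(outer((y_um - pos[1])^2, (x_um - pos[2])^2, "+"))
    spatial <- exp(-d / config$spread_length_um)
    temporal <- numeric(config$n_frames)
    ev <- events[[s]]
    for (k in seq_len(nrow(ev))) {
      if (ev$released[k] == 0) next
      amp <- ev$released[k] * config$quantal_dff
      temporal <- temporal + amp *
        sensor_kernel(tt - config$stimulus_times_s[k],
                      config$sensor_tau_on_ms, config$sensor_tau_off_ms)
    }
    dff <- dff + outer(temporal, spatial)
  }
  dff
}

# Resolve the drift specification to an n_frames x 2 matrix of (dy, dx).
drift_trajectory <- function(config) {
  d <- config$drift_px
  n <- config$n_frames
  if (is.null(d)) return(matrix(0, n, 2))
  if (is.matrix(d)) {
    if (nrow(d) != n || ncol(d) != 2)
      stop("`drift_px` matrix must be n_frames x 2")
    return(d)
  }
  if (is.list(d)) {
    tt <- (seq_len(n) - 1) / config$frame_rate_hz
    w <- 2 * pi / d$period_s
    return(cbind(d$amplitude_px * sin(w * tt),
                 d$amplitude_px * (1 - cos(w * tt)) / 2))
  }
  stop("unsupported `drift_px` specification")
}

#' Apply optics, photobleaching, drift and noise to an ideal movie
#'
#' Converts a noiseless \eqn{\Delta F/F} stack into simulated camera data:
#' `F = baseline_photons * (1 + dff)`, blurred by the PSF per frame,
#' multiplied by the mono-exponential bleach curve `exp(-t / bleach_tau_s)`,
#' rigidly shifted by the per-frame drift (bilinear interpolation), then
#' Poisson-sampled with additive Gaussian read noise.
#'
#' @param ideal_dff 3D array from [render_ideal_dff()].
#' @param config a [sim_config()].
#' @param psf optional [psf_model()]; `NULL` means no blur.  Its pixel size
#'   must match the movie's.
#' @return a [movie_stack()] of photon counts; the applied drift and bleach
#'   curves are attached as attributes `drift_px` and `bleach_curve`.
#' @export
apply_acquisition_effects <- function(ideal_dff, config, psf = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(psf)) {
    stopifnot(inherits(psf, "psf_model"))
    if (abs(psf$pixel_size_um - config$pixel_size_um) >
        1e-9 * config$pixel_size_um)
      stop("PSF pixel size does not match the simulation's")
    if (abs(sum(psf$kernel) - 1) > 1e-8)
      stop("PSF must be normalized to unit sum")
  }
  n <- config$n_frames
  tt <- (seq_len(n) - 1) / config$frame_rate_hz
  bleach <- if (is.finite(config$bleach_tau_s)) {
    if (config$bleach_tau_s <= 0) stop("`bleach_tau_s` must be > 0")
    exp(-tt / config$bleach_tau_s)
  } else rep(1, n)
  drift <- drift_trajectory(config)
  base_map <- baseline_texture(config)
  expected <- array(0, dim(ideal_dff))
  for (j in seq_len(n)) expected[j, , ] <- base_map * (1 + ideal_dff[j, , ])
  if (any(expected < 0))
    stop("negative expected photon count; check quantal_dff/baseline")
  set.seed(config$seed + 500000L)
  out <- array(0, dim(ideal_dff))
  for (j in seq_len(n)) {
    fr <- expected[j, , ]
    if (!is.null(psf)) fr <- conv2_same(fr, psf$kernel)
    fr <- fr * bleach[j]
    if (any(drift[j, ] != 0)) fr <- bilinear_shift(fr, drift[j, 1], drift[j, 2])
    fr <- pmax(fr, 0)
    counts <- if (config$shot_noise) rpois(length(fr), fr) else fr
    if (config$read_noise_sd > 0)
      counts <- counts + rnorm(length(fr), 0, config$read_noise_sd)
    out[j, , ] <- pmax(matrix(counts, nrow(fr), ncol(fr)), 0)
  }
  movie <- movie_stack(out, config$pixel_size_um, config$frame_rate_hz,
                       config$stimulus_times_s,
                       provenance = "simulated")
  attr(movie, "drift_px") <- drift
  attr(movie, "bleach_curve") <- bleach
  attr(movie, "baseline_map") <- base_map
  movie
}

# Static multiplicative expression texture emulating heterogeneous sensor
# expression: a two-scale Gaussian random field (cell-scale structure at
# `texture_scale_um` plus punctate structure at a quarter of that),
# normalized to unit mean and the configured relative SD, floored at 10%.
baseline_texture <- function(config) {
  ny <- config$field_size_px[1]; nx <- config$field_size_px[2]
  if (config$texture_rel_sd == 0)
    return(matrix(config$baseline_photons, ny, nx))
  set.seed(config$seed + 8888L)
  smooth_field <- function(sigma_px) {
    g <- matrix(rnorm(ny * nx), ny, nx)
    supp <- min(2 * ceiling(3 * sigma_px) + 1,
                min(ny, nx) - 1 - (min(ny, nx) %% 2))
    g <- conv2_same(g, gaussian_kernel(sigma_px, supp))
    (g - mean(g)) / max(sd(g), 1e-12)
  }
  sigma <- config$texture_scale_um / config$pixel_size_um
  g <- (smooth_field(sigma) + smooth_field(max(sigma / 4, 0.6))) / sqrt(2)
  config$baseline_photons * pmax(1 + config$texture_rel_sd * g, 0.1)
}

#' Simulate a complete sensor movie with ground truth
#'
#' Convenience wrapper chaining [simulate_pool_dynamics()] (per site),
#' [render_ideal_dff()] and [apply_acquisition_effects()].
#'
#' @inheritParams apply_acquisition_effects
#' @return list with `movie` (a [movie_stack()]) and `truth`: the per-site
#'   event table (`site_id`, `stimulus_index`, `vesicles_released`,
#'   `occupancy`), site positions, ideal \eqn{\Delta F/F} stack, drift and
#'   bleach curves, and the config.
#' @export
simulate_movie <- function(config, psf = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_sites <- nrow(config$site_positions_um)
  events <- lapply(seq_len(n_sites), function(s)
    simulate_pool_dynamics(config, s))
  ideal <- render_ideal_dff(config, events)
  movie <- apply_acquisition_effects(ideal, config, psf)
  ev_table <- do.call(rbind, lapply(seq_len(n_sites), function(s)
    data.frame(site_id = s,
               stimulus_index = events[[s]]$stimulus_index,
               vesicles_released = events[[s]]$released,
               occupancy = events[[s]]$occupancy)))
  list(movie = movie,
       truth = list(events = ev_table,
                    site_positions_um = config$site_positions_um,
                    ideal_dff = ideal,
                    drift_px = attr(movie, "drift_px"),
                    bleach_curve = attr(movie, "bleach_curve"),
                    config = config))
}

#' Simulate a fluorescent bead calibration stack
#'
#' Renders sub-resolution fluorescent microspheres as points (or small
#' disks) placed with bilinear sub-pixel spreading, convolved with the true
#' PSF and Poisson-sampled; one frame per trial.
#'
#' @param bead_positions_px n x 2 matrix of fractional `(y, x)` bead
#'   positions, pixels (1-based grid).
#' @param psf_truth a [psf_model()]: the PSF to be recovered.
#' @param photons expected total photons per bead spot per trial.
#' @param n_trials frames to simulate.
#' @param seed RNG seed; `NA` disables noise (noiseless expected image).
#' @param field_size_px field dimensions `c(ny, nx)`.
#' @param bead_diameter_um bead diameter; 0 renders ideal points.  Beads
#'   wider than about half the PSF FWHM inflate the apparent PSF.
#' @param background_photons uniform background level per pixel.
#' @return a [movie_stack()]; beads closer than 4 x FWHM are flagged in
#'   attribute `overlapping_beads` with a warning.
#' @export
simulate_bead_stack <- function(bead_positions_px, psf_truth, photons,
                                n_trials = 1L, seed = 1L,
                                field_size_px = c(64L, 64L),
                                bead_diameter_um = 0,
                                background_photons = 0) {
  stopifnot(inherits(psf_truth, "psf_model"))
  pos <- as.matrix(bead_positions_px)
  ny <- field_size_px[1]; nx <- field_size_px[2]
  if (any(pos[, 1] < 1 | pos[, 1] > ny | pos[, 2] < 1 | pos[, 2] > nx))
    stop("bead positions must lie within the field")
  overlapping <- FALSE
  if (nrow(pos) > 1) {
    min_sep_px <- 4 * psf_truth$fwhm_um / psf_truth$pixel_size_um
    if (min(dist(pos)) < min_sep_px) {
      warning("beads closer than 4 x PSF FWHM; spots may overlap")
      overlapping <- TRUE
    }
  }
  base <- matrix(0, ny, nx)
  obj <- matrix(0, ny, nx)   # extended (disk) objects, blurred at the end
  k <- psf_truth$kernel
  hw <- (nrow(k) - 1L) %/% 2L
  for (b in seq_len(nrow(pos))) {
    if (bead_diameter_um > 0) {
      # render the bead as a uniform disk, sub-pixel sampled and splatted
      r_px <- bead_diameter_um / 2 / psf_truth$pixel_size_um
      off <- seq(-r_px, r_px, length.out = 11)
      pts <- expand.grid(dy = off, dx = off)
      pts <- pts[pts$dy^2 + pts$dx^2 <= r_px^2, ]
      for (i in seq_len(nrow(pts)))
        obj <- obj + bilinear_splat(ny, nx, pos[b, 1] + pts$dy[i],
                                    pos[b, 2] + pts$dx[i],
                                    photons / nrow(pts))
    } else {
      # ideal point: place the PSF itself at the bead position, with the
      # fractional offset applied by exact Fourier shift (bilinear
      # splatting of a delta would blur the rendered PSF by the pixel
      # transfer function)
      i0 <- round(pos[b, ])
      tmp <- matrix(0, ny, nx)
      ys <- (i0[1] - hw):(i0[1] + hw); xs <- (i0[2] - hw):(i0[2] + hw)
      ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
      tmp[ys[ok_y], xs[ok_x]] <- k[ok_y, ok_x] * photons
      fr <- pos[b, ] - i0
      if (any(fr != 0)) tmp <- fourier_shift(tmp, fr[1], fr[2])
      base <- base + tmp
    }
  }
  if (any(obj > 0)) base <- base + conv2_same(obj, k)
  base <- pmax(base, 0) + background_photons
  out <- array(0, c(n_trials, ny, nx))
  noiseless <- is.na(seed)
  if (!noiseless) set.seed(as.integer(seed))
  for (j in seq_len(n_trials)) {
    out[j, , ] <- if (noiseless) base else
      matrix(rpois(length(base), pmax(base, 0)), ny, nx)
  }
  movie <- movie_stack(out, psf_truth$pixel_size_um, frame_rate_hz = 1,
                       provenance = "simulated beads")
  attr(movie, "overlapping_beads") <- overlapping
  attr(movie, "bead_positions_px") <- pos
  movie
}
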