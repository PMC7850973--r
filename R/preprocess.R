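#' Rigid drift registration
#'
#' Estimates a rigid sub-pixel translation for every frame against a
#' reference (by default the mean of the first 10 frames) by normalized
#' cross-correlation over the valid overlap with parabolic sub-pixel
#' refinement, and corrects each frame by the inverse translation via the
#' Fourier shift theorem.
#'
#' @param movie a [movie_stack()].
#' @param reference `"mean10"` (mean of the first up-to-10 frames),
#'   `"first"`, a frame index, or a reference matrix.
#' @param max_shift_px integer search radius for the drift, pixels
#'   (default a quarter of the field).
#' @return list with `movie` (registered [movie_stack()]) and `shifts`
#'   (`n_frames x 2` matrix of estimated `(dy, dx)` drift per frame; the
#'   applied correction is its negative).
#' @export
register_stack <- function(movie, reference = "mean10",
                           max_shift_px = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  if (d[1] < 2) stop("registration needs at least 2 frames")
  ref <- if (is.matrix(reference)) reference
  else if (identical(reference, "first")) movie$data[1, , ]
  else if (is.numeric(reference)) movie$data[reference, , ]
  else if (identical(reference, "mean10")) {
    n <- min(10L, d[1])
    apply(movie$data[seq_len(n), , , drop = FALSE], c(2, 3), mean)
  } else stop("unknown `reference` specification")
  if (all(ref == 0)) stop("reference frame has no image content")
  if (is.null(max_shift_px)) max_shift_px <- min(d[2], d[3]) / 4
  shifts <- matrix(0, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  out <- movie$data
  for (j in seq_len(d[1])) {
    fr <- movie$data[j, , ]
    if (all(fr == 0)) {
      warning("frame ", j, " is all zero; skipped in registration")
      next
    }
    s <- phase_correlate(ref, fr, max_shift = ceiling(max_shift_px))
    shifts[j, ] <- s
    if (any(s != 0)) out[j, , ] <- pmax(fourier_shift(fr, -s[1], -s[2]), 0)
  }
  reg <- movie_stack(out, movie$pixel_size_um, movie$frame_rate_hz,
                     movie$stimulus_times_s, movie$provenance)
  reg <- log_step(reg, sprintf("registered (rigid NCC, max_shift=%g px)",
                               max_shift_px))
  list(movie = reg, shifts = shifts)
}

#' Photobleaching / autofluorescence correction
#'
#' Fits a mono-exponential trend `A * exp(-t / tau) + C` to the mean
#' fluorescence of background pixels (below the 50th percentile of the
#' temporal-max image, which excludes release sites) and divides the decay
#' out: corrected `F' = (F - C) / exp(-t / tau_hat)`.  The offset C absorbs
#' non-bleaching autofluorescence.  If the fitted decay over the movie is
#' below `min_decay` the movie is returned unchanged (rate ~ 0, tau = Inf).
#'
#' @param movie a [movie_stack()] with at least 10 frames.
#' @param model `"mono_exp"` or `"none"`.
#' @param mask optional logical matrix selecting background pixels;
#'   computed from the intensity percentile rule when `NULL`.
#' @param min_decay smallest fractional decay over the movie treated as
#'   real bleaching (default 1%).
#' @return list with `movie` (corrected) and `params`: `tau_s`, `amplitude`,
#'   `offset`, `converged`, `method`.
#' @export
correct_bleaching <- function(movie, model = c("mono_exp", "none"),
                              mask = NULL, min_decay = 0.01) {
  stopifnot(inherits(movie, "movie_stack"))
  model <- match.arg(model)
  d <- dim(movie$data)
  if (model == "none")
    return(list(movie = log_step(movie, "bleach correction: none"),
                params = list(tau_s = Inf, amplitude = 0, offset = 0,
                              converged = TRUE, method = "none")))
  if (d[1] < 10) stop("bleach correction needs at least 10 frames")
  if (is.null(mask)) {
    # release sites show strong temporal modulation (max >> mean); the
    # max/mean ratio separates them from static expression texture
    tmax <- apply(movie$data, c(2, 3), max)
    tmean <- apply(movie$data, c(2, 3), mean)
    ratio <- tmax / pmax(tmean, 1e-12)
    mask <- ratio <= quantile(ratio, 0.5)
  }
  if (!any(mask)) stop("background mask is empty")
  tt <- (seq_len(d[1]) - 1) / movie$frame_rate_hz
  trace <- vapply(seq_len(d[1]),
                  function(j) mean(movie$data[j, , ][mask]), numeric(1))
  f1 <- mean(head(trace, max(3, d[1] %/% 4)))
  fend <- mean(tail(trace, max(3, d[1] %/% 4)))
  # flat background: no bleaching to correct (rate ~ 0, movie unchanged)
  if (abs(f1 - fend) / max(f1, 1e-12) < min_decay) {
    corrected <- log_step(movie, "bleach correction: no significant bleach")
    return(list(movie = corrected,
                params = list(tau_s = Inf, amplitude = 0, offset = 0,
                              converged = TRUE, method = "mono_exp")))
  }
  method <- "mono_exp"; converged <- TRUE
  fit <- tryCatch(
    minpack.lm::nlsLM(
      trace ~ A * exp(-tt / tau) + C,
      start = list(A = max(f1 - fend, 0.05 * f1), tau = max(tt) / 2,
                   C = max(fend - max(f1 - fend, 0.05 * f1) * 0.05, 0)),
      lower = c(A = 0, tau = max(tt) * 1e-3, C = 0),
      upper = c(A = Inf, tau = max(tt) * 1e3, C = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) && abs(f1 - fend) / max(f1, 1e-12) < 5 * min_decay) {
    # near-flat trace the exponential could not latch onto: leave it alone
    corrected <- log_step(movie, "bleach correction: no significant bleach")
    return(list(movie = corrected,
                params = list(tau_s = Inf, amplitude = 0, offset = 0,
                              converged = TRUE, method = "mono_exp")))
  }
  if (is.null(fit)) {
    # fall back to frame-median normalization
    warning("bleach fit did not converge; falling back to frame-median ",
            "normalization")
    med <- vapply(seq_len(d[1]),
                  function(j) median(movie$data[j, , ][mask]), numeric(1))
    scale <- med[1] / pmax(med, 1e-12)
    out <- movie$data
    for (j in seq_len(d[1])) out[j, , ] <- out[j, , ] * scale[j]
    corrected <- movie_stack(out, movie$pixel_size_um, movie$frame_rate_hz,
                             movie$stimulus_times_s, movie$provenance)
    corrected <- log_step(corrected, "bleach correction: median fallback")
    return(list(movie = corrected,
                params = list(tau_s = NA_real_, amplitude = NA_real_,
                              offset = NA_real_, converged = FALSE,
                              method = "median_fallback")))
  }
  cf <- coef(fit)
  decay_frac <- cf[["A"]] * (1 - exp(-max(tt) / cf[["tau"]])) /
    max(cf[["A"]] + cf[["C"]], 1e-12)
  if (!is.finite(decay_frac) || decay_frac < min_decay) {
    corrected <- log_step(movie, "bleach correction: no significant bleach")
    return(list(movie = corrected,
                params = list(tau_s = Inf, amplitude = 0, offset = 0,
                              converged = TRUE, method = "mono_exp")))
  }
  decay <- exp(-tt / cf[["tau"]])
  out <- movie$data
  for (j in seq_len(d[1]))
    out[j, , ] <- pmax((out[j, , ] - cf[["C"]]) / decay[j], 0)
  corrected <- movie_stack(out, movie$pixel_size_um, movie$frame_rate_hz,
                           movie$stimulus_times_s, movie$provenance)
  corrected <- log_step(corrected, sprintf(
    "bleach corrected (mono_exp tau=%.4g s, offset=%.4g)",
    cf[["tau"]], cf[["C"]]))
  list(movie = corrected,
       params = list(tau_s = unname(cf[["tau"]]),
                     amplitude = unname(cf[["A"]]),
                     offset = unname(cf[["C"]]),
                     converged = converged, method = method))
}

#' Spatial denoising
#'
#' Applies a per-frame Gaussian or median filter.  Denoising before or
#' between deconvolution stages suppresses the noise amplification inherent
#' to iterative deblurring.
#'
#' @param movie a [movie_stack()].
#' @param method `"none"`, `"gaussian"` (sigma = `width` px) or `"median"`
#'   (window radius `width` px).
#' @param width filter width parameter, pixels; must be smaller than the
#'   image.
#' @return the filtered [movie_stack()].
#' @export
denoise <- function(movie, method = c("none", "gaussian", "median"),
                    width = 1) {
  stopifnot(inherits(movie, "movie_stack"))
  method <- match.arg(method)
  d <- dim(movie$data)
  if (width >= min(d[2], d[3])) stop("`width` must be below the image size")
  if (method == "none")
    return(log_step(movie, "denoise: none"))
  out <- movie$data
  if (method == "gaussian") {
    for (j in seq_len(d[1]))
      out[j, , ] <- EBImage::gblur(movie$data[j, , ], sigma = width)
  } else {
    hi <- max(movie$data) + 1e-12  # medianFilter needs [0, 1]
    for (j in seq_len(d[1]))
      out[j, , ] <- EBImage::medianFilter(movie$data[j, , ] / hi,
                                          size = width) * hi
  }
  out <- pmax(out, 0)
  res <- movie_stack(out, movie$pixel_size_um, movie$frame_rate_hz,
                     movie$stimulus_times_s, movie$provenance)
  log_step(res, sprintf("denoised (%s, width=%g)", method, width))
}

#' Collapse a movie onto its baseline and event windows
#'
#' Averages the pre-stimulus frames into a baseline image and the
#' event-window frames (those where the expected sensor response, the
#' summed [sensor_kernel()] over all stimuli, exceeds half its maximum)
#' into a single event image, returning a two-frame movie.  Because the
#' ideal response is separable into a spatial profile times a temporal
#' kernel, any such temporal average preserves the spatial profile -- and
#' hence the spread length constant -- exactly, while reducing photon
#' noise by roughly the square root of the number of averaged frames.
#' Peak \eqn{\Delta F/F} amplitudes are scaled down by the window-mean of
#' the temporal kernel; distances and length constants are unaffected.
#'
#' @param movie a [movie_stack()] with stimulus times in its metadata.
#' @param tau_on_ms,tau_off_ms sensor kinetics defining the expected
#'   response time course.
#' @return a two-frame [movie_stack()] (frame 1 baseline mean, frame 2
#'   event mean) whose stimulus time points at frame 2, so that
#'   [compute_dff()] uses frame 1 as baseline.
#' @export
collapse_event_window <- function(movie, tau_on_ms = 250,
                                  tau_off_ms = 700) {
  stopifnot(inherits(movie, "movie_stack"))
  if (is.null(movie$stimulus_times_s))
    stop("`collapse_event_window` needs stimulus times in the metadata")
  d <- dim(movie$data)
  tt <- (seq_len(d[1]) - 1) / movie$frame_rate_hz
  resp <- rowSums(vapply(movie$stimulus_times_s, function(t0)
    sensor_kernel(tt - t0, tau_on_ms, tau_off_ms), numeric(d[1])))
  base_idx <- which(tt < min(movie$stimulus_times_s))
  if (!length(base_idx)) stop("no pre-stimulus frames for the baseline")
  ev_idx <- which(resp >= max(resp) / 2)
  ev_idx <- setdiff(ev_idx, base_idx)
  if (!length(ev_idx)) stop("no event-window frames found")
  arr <- array(0, c(2L, d[2], d[3]))
  arr[1, , ] <- apply(movie$data[base_idx, , , drop = FALSE], c(2, 3), mean)
  arr[2, , ] <- apply(movie$data[ev_idx, , , drop = FALSE], c(2, 3), mean)
  # synthetic two-frame time base: the "stimulus" sits at frame 2 so that
  # compute_dff() defaults to frame 1 as baseline
  out <- movie_stack(arr, movie$pixel_size_um, movie$frame_rate_hz,
                     stimulus_times_s = 1 / movie$frame_rate_hz,
                     provenance = movie$provenance)
  log_step(out, sprintf(
    "collapsed to baseline (%d frames) + event window (%d frames)",
    length(base_idx), length(ev_idx)))
}

#' Compute delta F over F
#'
#' Pixel-wise \eqn{\Delta F/F = (F - F_0)/F_0} with \eqn{F_0} the per-pixel
#' mean over a baseline window, by default every frame before the first
#' stimulus.
#'
#' @param movie a [movie_stack()].
#' @param baseline_window integer vector of baseline frame indices; default
#'   all frames strictly before the first stimulus.
#' @return a [dff_stack()]. Pixels with non-positive baseline are set to
#'   `NA` with a warning.
#' @export
compute_dff <- function(movie, baseline_window = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  if (is.null(baseline_window)) {
    if (is.null(movie$stimulus_times_s))
      stop("supply `baseline_window` or stimulus times in the movie metadata")
    first_stim_frame <- floor(min(movie$stimulus_times_s) *
                                movie$frame_rate_hz) + 1L
    if (first_stim_frame < 2)
      stop("no pre-stimulus frames available for the baseline")
    baseline_window <- seq_len(first_stim_frame - 1L)
  }
  if (any(baseline_window < 1 | baseline_window > d[1]))
    stop("`baseline_window` out of range")
  f0 <- apply(movie$data[baseline_window, , , drop = FALSE], c(2, 3), mean)
  bad <- f0 <= 0
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with non-positive baseline masked")
    f0[bad] <- NA_real_
  }
  dff <- array(0, d)
  for (j in seq_len(d[1])) dff[j, , ] <- movie$data[j, , ] / f0 - 1
  dff_stack(dff, f0, range(baseline_window), movie$pixel_size_um,
            movie$frame_rate_hz, movie$stimulus_times_s)
}
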