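#' Movie stack container
#'
#' A `movie_stack` holds a fluorescence movie as a 3D array indexed
#' `[frame, row, col]` together with the acquisition metadata every
#' downstream stage needs, plus an append-only provenance log.
#'
#' @param data numeric 3D array, `[frame, row, col]`, non-negative
#'   intensities (photon counts or camera units).
#' @param pixel_size_um pixel pitch in micrometres (> 0).
#' @param frame_rate_hz acquisition rate in Hz (> 0).
#' @param stimulus_times_s optional numeric vector of stimulus onset times,
#'   seconds from the first frame.
#' @param provenance character vector describing processing applied so far.
#'
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, pixel_size_um, frame_rate_hz,
                        stimulus_times_s = NULL, provenance = character()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array [frame, row, col]")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be > 0")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be > 0")
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values")
  structure(
    list(data = data,
         pixel_size_um = pixel_size_um,
         frame_rate_hz = frame_rate_hz,
         stimulus_times_s = stimulus_times_s,
         provenance = as.character(provenance)),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames of %d x %d px\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel %.4g um, %.4g Hz, duration %.3g s\n",
              x$pixel_size_um, x$frame_rate_hz, d[1] / x$frame_rate_hz))
  if (length(x$stimulus_times_s))
    cat(sprintf("  %d stimuli (first at %.3g s)\n",
                length(x$stimulus_times_s), min(x$stimulus_times_s)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

# append a provenance entry without touching earlier ones
log_step <- function(movie, entry) {
  movie$provenance <- c(movie$provenance, entry)
  movie
}

#' Delta F over F stack
#'
#' Result of [compute_dff()]: unitless fractional fluorescence change per
#' pixel and frame, with the per-pixel baseline it was referenced to.
#'
#' @param dff 3D array `[frame, row, col]` of \eqn{\Delta F/F} values.
#' @param baseline_f0 matrix of per-pixel baseline fluorescence F0.
#' @param baseline_window integer frame interval used for F0.
#' @param pixel_size_um,frame_rate_hz,stimulus_times_s acquisition metadata
#'   carried over from the source movie.
#'
#' @return an object of class `dff_stack`.
#' @export
dff_stack <- function(dff, baseline_f0, baseline_window, pixel_size_um,
                      frame_rate_hz, stimulus_times_s = NULL) {
  if (length(dim(dff)) != 3L)
    stop("`dff` must be a 3D array [frame, row, col]")
  structure(
    list(dff = dff, baseline_f0 = baseline_f0,
         baseline_window = baseline_window,
         pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
         stimulus_times_s = stimulus_times_s),
    class = "dff_stack")
}

#' @export
print.dff_stack <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("<dff_stack> %d frames of %d x %d px (baseline frames %d..%d)\n",
              d[1], d[2], d[3], x$baseline_window[1],
              x$baseline_window[length(x$baseline_window)]))
  invisible(x)
}

#' Point-spread-function model
#'
#' A normalized 2D blur kernel with its provenance (empirical bead
#' measurement or theoretical model) and measured full width at half maximum.
#'
#' @param kernel square, odd-sized, non-negative matrix summing to 1.
#' @param pixel_size_um pixel pitch of the kernel grid, micrometres.
#' @param fwhm_um full width at half maximum of the kernel, micrometres
#'   (measured with [psf_fwhm()] when `NULL`).
#' @param provenance `"empirical"` or `"theoretical"`.
#' @param n_beads_averaged number of bead spots averaged (0 for theoretical).
#'
#' @return an object of class `psf_model`.
#' @export
psf_model <- function(kernel, pixel_size_um, fwhm_um = NULL,
                      provenance = c("empirical", "theoretical"),
                      n_beads_averaged = 0L) {
  provenance <- match.arg(provenance)
  kernel <- as.matrix(kernel)
  if (any(kernel < 0)) stop("PSF kernel must be non-negative")
  s <- sum(kernel)
  if (s <= 0) stop("PSF kernel must have positive mass")
  kernel <- kernel / s
  if (any(dim(kernel) %% 2L == 0L))
    stop("PSF kernel must be odd-sized in both dimensions")
  if (is.null(fwhm_um)) fwhm_um <- psf_fwhm(kernel, pixel_size_um)
  structure(
    list(kernel = kernel, pixel_size_um = pixel_size_um, fwhm_um = fwhm_um,
         provenance = provenance, n_beads_averaged = as.integer(n_beads_averaged)),
    class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> %s, %d x %d px @ %.4g um, FWHM %.4g um",
              x$provenance, nrow(x$kernel), ncol(x$kernel),
              x$pixel_size_um, x$fwhm_um))
  if (x$n_beads_averaged > 0)
    cat(sprintf(" (%d bead spots averaged)", x$n_beads_averaged))
  cat("\n")
  invisible(x)
}
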