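#' Optical configuration
#'
#' Holds the parameters of the diffraction-limit arithmetic: emission
#' wavelength, numerical aperture (either directly or as refractive index
#' plus collection half-angle, NA = n sin(alpha)), and the photon count
#' available for computational or hardware resolution improvement.
#'
#' @param wavelength_nm emission wavelength, nm.
#' @param numerical_aperture numerical aperture; supply either this or the
#'   `(refractive_index, half_angle_deg)` pair, not both.
#' @param refractive_index index of refraction n of the imaging medium
#'   (>= 1).
#' @param half_angle_deg maximum half-angle alpha of collected rays,
#'   degrees in (0, 90].
#' @param photon_count number of photons detected (N >= 1).
#' @return object of class `optical_config` with a resolved `na` field.
#' @export
optical_config <- function(wavelength_nm, numerical_aperture = NULL,
                           refractive_index = NULL, half_angle_deg = NULL,
                           photon_count = 1) {
  if (wavelength_nm <= 0) stop("`wavelength_nm` must be > 0")
  pair <- !is.null(refractive_index) || !is.null(half_angle_deg)
  if (!is.null(numerical_aperture) && pair)
    stop("supply either `numerical_aperture` or (n, alpha), not both")
  if (is.null(numerical_aperture)) {
    if (is.null(refractive_index) || is.null(half_angle_deg))
      stop("supply `numerical_aperture` or both `refractive_index` and ",
           "`half_angle_deg`")
    if (refractive_index < 1) stop("`refractive_index` must be >= 1")
    if (half_angle_deg <= 0 || half_angle_deg > 90)
      stop("`half_angle_deg` must lie in (0, 90]")
    numerical_aperture <- refractive_index * sin(half_angle_deg * pi / 180)
  }
  if (numerical_aperture <= 0) stop("numerical aperture must be > 0")
  if (!is.null(refractive_index) && numerical_aperture > refractive_index + 1e-12)
    stop("numerical aperture cannot exceed the refractive index")
  if (photon_count < 1) stop("`photon_count` must be >= 1")
  structure(list(wavelength_nm = wavelength_nm, na = numerical_aperture,
                 refractive_index = refractive_index,
                 half_angle_deg = half_angle_deg,
                 photon_count = photon_count),
            class = "optical_config")
}

#' Abbe diffraction limit
#'
#' Minimum resolvable distance of a diffraction-limited microscope:
#' \eqn{\Delta x = \lambda / (2 n \sin\alpha) = \lambda / (2\,NA)}.
#'
#' @param optics an [optical_config()].
#' @return resolution limit in nm.
#' @export
abbe_limit <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  optics$wavelength_nm / (2 * optics$na)
}

#' Photon-limited effective resolution
#'
#' Resolution attainable with N detected photons: the Abbe limit scaled by
#' \eqn{N^{-1/2}} for hardware superresolution (localization-type) imaging
#' and by \eqn{N^{-1/4}} for computational deconvolution imaging -- the
#' less favorable scaling that makes each factor-of-two gain cost 16x more
#' photons instead of 4x.
#'
#' @param optics an [optical_config()] (its `photon_count` is N).
#' @param mode `"superresolution"` or `"deconvolution"`.
#' @return effective resolution in nm.
#' @export
effective_resolution <- function(optics,
                                 mode = c("superresolution", "deconvolution")) {
  mode <- match.arg(mode)
  N <- optics$photon_count
  if (N < 1) stop("photon count must be >= 1")
  expo <- if (mode == "superresolution") -1 / 2 else -1 / 4
  abbe_limit(optics) * N^expo
}

#' Photons required for a target resolution
#'
#' Inverts the photon-scaling laws of [effective_resolution()]: the
#' smallest photon count N whose effective resolution reaches
#' `target_resolution_nm`.
#'
#' @inheritParams effective_resolution
#' @param target_resolution_nm desired resolution, nm; must be below the
#'   Abbe limit for the answer to exceed 1.
#' @return photon count (numeric, >= 1); if the target is already at or
#'   above the Abbe limit, 1 is returned with attribute
#'   `note = "target at or above the Abbe limit"`.
#' @export
photons_required <- function(optics, target_resolution_nm,
                             mode = c("superresolution", "deconvolution")) {
  mode <- match.arg(mode)
  ab <- abbe_limit(optics)
  if (target_resolution_nm >= ab) {
    out <- 1
    attr(out, "note") <- "target at or above the Abbe limit"
    return(out)
  }
  expo <- if (mode == "superresolution") 2 else 4
  (ab / target_resolution_nm)^expo
}

#' Theoretical point-spread function
#'
#' Isotropic Gaussian approximation to the diffraction-limited PSF with
#' FWHM equal to the Abbe limit of the supplied optics.  Adequate for
#' simulation and for seeding deconvolution when no bead calibration is
#' available; real, aberrated systems should prefer
#' [estimate_psf_from_beads()].
#'
#' @param optics an [optical_config()].
#' @param pixel_size_um kernel grid pitch, micrometres; must sample the
#'   FWHM with at least two pixels (Nyquist), else an error is raised.
#' @param support odd kernel side length in pixels; defaults to the
#'   smallest odd size spanning 6 FWHM.
#' @return a [psf_model()] with `provenance = "theoretical"`.
#' @export
theoretical_psf <- function(optics, pixel_size_um, support = NULL) {
  fwhm_um <- abbe_limit(optics) / 1000
  if (pixel_size_um >= fwhm_um / 2)
    stop(sprintf(
      "pixel size %.3g um undersamples the %.3g um FWHM (need < FWHM/2)",
      pixel_size_um, fwhm_um))
  sigma_px <- fwhm_um / (2 * sqrt(2 * log(2))) / pixel_size_um
  if (is.null(support)) {
    support <- ceiling(6 * fwhm_um / pixel_size_um)
    if (support %% 2 == 0) support <- support + 1
  }
  if (support %% 2 != 1) stop("`support` must be odd")
  psf_model(gaussian_kernel(sigma_px, support), pixel_size_um,
            provenance = "theoretical")
}

#' Estimate the PSF from a fluorescent bead stack
#'
#' Detects bead spots in every frame, rejects overlapping beads, subtracts
#' the local background (median of the window border ring), refines each
#' spot centre by iterated intensity-weighted centroid, aligns the spots to
#' a common sub-pixel centre, averages across beads and trials, optionally
#' averages over circular axes (radial symmetrization), and normalizes to
#' unit sum.
#'
#' @param bead_stack a [movie_stack()] of bead images (one frame per trial).
#' @param nominal_fwhm_um rough prior on the PSF FWHM used to size the
#'   extraction window (6 x FWHM) and the overlap criterion.
#' @param threshold_sd detection threshold in robust (MAD) noise SDs above
#'   the frame median.
#' @param symmetrize average the kernel over circular axes.
#' @return a [psf_model()] with `provenance = "empirical"` and
#'   `n_beads_averaged` set to the number of spots averaged.
#' @export
estimate_psf_from_beads <- function(bead_stack, nominal_fwhm_um,
                                    threshold_sd = 5, symmetrize = TRUE) {
  stopifnot(inherits(bead_stack, "movie_stack"))
  px <- bead_stack$pixel_size_um
  win <- ceiling(6 * nominal_fwhm_um / px)
  if (win %% 2 == 0) win <- win + 1
  hw <- (win - 1) %/% 2
  n_frames <- dim(bead_stack$data)[1]
  spots <- list(); n_excluded <- 0L
  for (j in seq_len(n_frames)) {
    fr <- bead_stack$data[j, , ]
    bg <- median(fr)
    noise <- mad(fr)
    # relative floor keeps numerical ripple out of noiseless images
    thr <- bg + max(threshold_sd * noise, 0.05 * (max(fr) - bg), 1e-12)
    peaks <- local_maxima(fr, threshold = thr)
    if (!nrow(peaks)) next
    # exclude peaks whose window leaves the field or touches a neighbour
    keep <- rep(TRUE, nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      p <- peaks[i, ]
      if (p[1] <= hw + 1 || p[1] > nrow(fr) - hw - 1 ||
          p[2] <= hw + 1 || p[2] > ncol(fr) - hw - 1) {
        keep[i] <- FALSE; next
      }
      if (nrow(peaks) > 1) {
        d <- sqrt(rowSums((peaks[-i, , drop = FALSE] -
                             matrix(p, nrow(peaks) - 1, 2, byrow = TRUE))^2))
        # the bead-separation precondition: 4 x FWHM
        if (min(d) < 4 * nominal_fwhm_um / px) {
          keep[i] <- FALSE; n_excluded <- n_excluded + 1L
        }
      }
    }
    peaks <- peaks[keep, , drop = FALSE]
    for (i in seq_len(nrow(peaks))) {
      ctr <- centroid_refine(fr, peaks[i, 1], peaks[i, 2], hw = hw)
      i0 <- round(ctr)
      patch <- fr[(i0[1] - hw - 1):(i0[1] + hw + 1),
                  (i0[2] - hw - 1):(i0[2] + hw + 1)]
      ring <- c(patch[1, ], patch[nrow(patch), ],
                patch[, 1], patch[, ncol(patch)])
      patch <- patch - median(ring)
      # sub-pixel align: shift the fractional centroid offset out
      frac <- ctr - i0
      patch <- fourier_shift(patch, -frac[1], -frac[2])
      patch <- pmax(patch[2:(nrow(patch) - 1), 2:(ncol(patch) - 1)], 0)
      spots[[length(spots) + 1L]] <- patch
    }
  }
  if (n_excluded > 0)
    warning(n_excluded, " bead spot(s) excluded as overlapping")
  if (!length(spots)) stop("no beads found in the stack")
  kernel <- Reduce(`+`, spots) / length(spots)
  if (symmetrize) kernel <- radial_symmetrize(kernel)
  psf_model(kernel, px, provenance = "empirical",
            n_beads_averaged = length(spots))
}

#' Radially symmetrize a kernel
#'
#' Replaces the kernel by its angular average about its centre of mass
#' (averaging over "multiple circular axes"), renormalized to the original
#' total mass.  Preserves unit sum and the centre of mass.
#'
#' @param kernel non-negative 2D kernel.
#' @return symmetrized kernel of the same dimensions and total mass.
#' @export
radial_symmetrize <- function(kernel) {
  # angular averaging on a sinc-upsampled copy: linear interpolation of a
  # peaked kernel near Nyquist broadens it measurably
  up <- 4L
  ku <- pmax(fft_upsample(kernel, up), 0)
  com_u <- kernel_com(ku)
  dr_u <- 0.25
  prof <- radial_profile(ku, com_u, dr = dr_u, n_theta = 180,
                         max_r = max(dim(ku)))
  ny <- nrow(kernel); nx <- ncol(kernel)
  com <- (com_u - 1) / up + 1
  d <- sqrt(outer((seq_len(ny) - com[1])^2, (seq_len(nx) - com[2])^2, "+"))
  idx <- pmin(pmax(d * up / dr_u, 0), nrow(prof) - 1)
  lo <- floor(idx); f <- idx - lo
  vals <- prof$value[lo + 1] * (1 - f) +
    prof$value[pmin(lo + 2, nrow(prof))] * f
  out <- matrix(pmax(vals, 0) / up^2, ny, nx)
  out * (sum(kernel) / sum(out))
}
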