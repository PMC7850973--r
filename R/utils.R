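# Internal numerics shared across modules: convolution, sub-pixel shifts,
# phase correlation, interpolation, kernel geometry.

# 2D convolution, 'same' output, replicate boundary.  Kernel must be
# odd-sized; EBImage does the FFT work.
conv2_same <- function(x, kernel) {
  EBImage::filter2(x, kernel, boundary = "replicate")
}

# FFT frequency index vector for length n (cycles per array, integer bins)
fft_freq <- function(n) {
  c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
}

# Shift an image by (dy, dx) pixels via the Fourier shift theorem
# (exact for band-limited content, circular boundary).
fourier_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- fft_freq(ny) / ny
  kx <- fft_freq(nx) / nx
  ph <- exp(-2i * pi * outer(ky * dy, kx * dx, "+"))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (ny * nx)
}

# Bilinear interpolation of img at (y, x) (1-based, fractional), edge
# coordinates clamped to the field.
bilinear_interp <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 1), ny); x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# Shift an image by (dy, dx) with bilinear interpolation and replicated
# edges (used when wrap-around from a Fourier shift would be harmful).
bilinear_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  yy <- matrix(seq_len(ny), ny, nx) - dy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - dx
  matrix(bilinear_interp(img, as.vector(yy), as.vector(xx)), ny, nx)
}

# Spread a unit point at fractional position (y, x) onto the pixel grid by
# bilinear weights; returns a sparse-ish dense matrix.
bilinear_splat <- function(ny, nx, y, x, mass = 1) {
  out <- matrix(0, ny, nx)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  put <- function(r, c, w) {
    if (r >= 1 && r <= ny && c >= 1 && c <= nx && w > 0)
      out[r, c] <<- out[r, c] + w * mass
  }
  put(y0,     x0,     (1 - fy) * (1 - fx))
  put(y0 + 1, x0,     fy       * (1 - fx))
  put(y0,     x0 + 1, (1 - fy) * fx)
  put(y0 + 1, x0 + 1, fy       * fx)
  out
}

# Estimate the rigid translation s such that img(x) ~= ref(x - s).
# Integer lag by normalized cross-correlation over the VALID (non-circular)
# overlap -- circular FFT correlation is badly biased toward zero lag for
# smooth scenes whose content does not wrap -- followed by parabolic
# sub-pixel interpolation of the NCC surface.  The cross term is computed
# with a zero-padded FFT and the per-lag means/energies with integral
# images, so the whole lag search is O(n^2 log n).
# Returns c(dy, dx); applying the inverse shift (-dy, -dx) aligns img to ref.
phase_correlate <- function(ref, img, max_shift = NULL, min_overlap = 0.5) {
  ny <- nrow(ref); nx <- ncol(ref)
  if (is.null(max_shift)) max_shift <- floor(min(ny, nx) / 4)
  NY <- nextn(ny + max_shift + 1, 2); NX <- nextn(nx + max_shift + 1, 2)
  pad <- function(m) { out <- matrix(0, NY, NX); out[1:ny, 1:nx] <- m; out }
  cross <- Re(fft(fft(pad(ref)) * Conj(fft(pad(img))), inverse = TRUE)) /
    (NY * NX)
  # integral images for per-lag overlap sums
  ii <- function(m) {
    out <- matrix(0, ny + 1, nx + 1)
    out[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    out
  }
  Sr <- ii(ref); Sr2 <- ii(ref^2); Si <- ii(img); Si2 <- ii(img^2)
  boxsum <- function(S, y1, y2, x1, x2)
    S[y2 + 1, x2 + 1] - S[y1, x2 + 1] - S[y2 + 1, x1] + S[y1, x1]
  lags <- -max_shift:max_shift
  ncc <- matrix(-Inf, length(lags), length(lags))
  n_min <- min_overlap * ny * nx
  for (a in seq_along(lags)) for (b in seq_along(lags)) {
    ly <- lags[a]; lx <- lags[b]   # hypothesis: img(x) = ref(x - (ly, lx))
    # overlap in img coordinates
    y1 <- max(1, 1 + ly); y2 <- min(ny, ny + ly)
    x1 <- max(1, 1 + lx); x2 <- min(nx, nx + lx)
    npx <- (y2 - y1 + 1) * (x2 - x1 + 1)
    if (npx < n_min) next
    sr <- boxsum(Sr, y1 - ly, y2 - ly, x1 - lx, x2 - lx)
    sr2 <- boxsum(Sr2, y1 - ly, y2 - ly, x1 - lx, x2 - lx)
    si <- boxsum(Si, y1, y2, x1, x2)
    si2 <- boxsum(Si2, y1, y2, x1, x2)
    # cross(u) = sum_x ref(x + u) img(x): lag u = -(ly, lx) (mod padded dims)
    uy <- (-ly) %% NY; ux <- (-lx) %% NX
    sc <- cross[uy + 1, ux + 1]
    num <- sc - sr * si / npx
    den <- sqrt(max(sr2 - sr^2 / npx, 0) * max(si2 - si^2 / npx, 0))
    if (den > 0) ncc[a, b] <- num / den
  }
  pk <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
  sy <- lags[pk[1]]; sx <- lags[pk[2]]
  # parabolic sub-pixel refinement along each axis
  refine <- function(cm, c0, cp) {
    d <- cm - 2 * c0 + cp
    if (!is.finite(d) || d >= 0) return(0)
    delta <- 0.5 * (cm - cp) / d
    max(min(delta, 0.5), -0.5)
  }
  dy <- if (pk[1] > 1 && pk[1] < length(lags))
    refine(ncc[pk[1] - 1, pk[2]], ncc[pk[1], pk[2]], ncc[pk[1] + 1, pk[2]])
  else 0
  dx <- if (pk[2] > 1 && pk[2] < length(lags))
    refine(ncc[pk[1], pk[2] - 1], ncc[pk[1], pk[2]], ncc[pk[1], pk[2] + 1])
  else 0
  c(dy = sy + dy, dx = sx + dx)
}

# Peak-normalized causal difference-of-exponentials sensor response kernel.
# Rise time constant tau_on, decay tau_off (seconds); k(t) = 0 for t < 0.

#' Sensor temporal response kernel
#'
#' Causal, peak-normalized difference-of-exponentials impulse response of an
#' intensity-based transmitter sensor:
#' \eqn{k(t) \propto e^{-t/\tau_{off}} - e^{-t/\tau_{on}}} for \eqn{t \ge 0},
#' scaled so its maximum is 1.  A release of amplitude \eqn{a} (peak
#' \eqn{\Delta F/F}) contributes \eqn{a\,k(t - t_{stim})} to the trace.
#'
#' @param t_s numeric vector of times in seconds (values < 0 give 0).
#' @param tau_on_ms,tau_off_ms sensor rise and decay time constants, ms.
#' @return numeric vector of kernel values, peak 1.
#' @export
sensor_kernel <- function(t_s, tau_on_ms, tau_off_ms) {
  stopifnot(tau_on_ms > 0, tau_off_ms > 0)
  ton <- tau_on_ms / 1000; toff <- tau_off_ms / 1000
  if (abs(ton - toff) < 1e-12) {
    k <- ifelse(t_s < 0, 0, t_s / ton * exp(1 - t_s / ton))
    return(k)
  }
  if (ton > toff) { tmp <- ton; ton <- toff; toff <- tmp }
  k <- ifelse(t_s < 0, 0, exp(-t_s / toff) - exp(-t_s / ton))
  tp <- ton * toff / (toff - ton) * log(toff / ton)
  k / (exp(-tp / toff) - exp(-tp / ton))
}

# Positions (row, col) of strict local maxima of img over a 3x3
# neighbourhood, above `threshold`.
local_maxima <- function(img, threshold = -Inf) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3 || nx < 3) return(matrix(numeric(0), 0, 2))
  ok <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    shifted[ys, xs] <- img[ys - dy, xs - dx]
    ok <- ok & (img > shifted | (img == shifted & (dy < 0 | (dy == 0 & dx < 0))))
  }
  ok[img < threshold] <- FALSE
  ok[c(1, ny), ] <- FALSE; ok[, c(1, nx)] <- FALSE
  which(ok, arr.ind = TRUE)
}

# Intensity-weighted centroid of img restricted to a square window of
# half-width `hw` around (y0, x0); returns c(y, x) in pixels.
centroid_refine <- function(img, y0, x0, hw, n_iter = 2) {
  ny <- nrow(img); nx <- ncol(img)
  y <- y0; x <- x0
  for (i in seq_len(n_iter)) {
    ys <- max(1, round(y) - hw):min(ny, round(y) + hw)
    xs <- max(1, round(x) - hw):min(nx, round(x) + hw)
    w <- img[ys, xs, drop = FALSE]
    w <- pmax(w - min(w), 0)
    if (sum(w) <= 0) break
    y <- sum(outer(ys, rep(1, length(xs))) * w) / sum(w)
    x <- sum(outer(rep(1, length(ys)), xs) * w) / sum(w)
  }
  c(y = y, x = x)
}

# Angle-averaged radial profile of a kernel about `center` (c(y, x), pixels),
# sampled every `dr` pixels by bilinear interpolation.
radial_profile <- function(kernel, center, dr = 0.1, n_theta = 90,
                           max_r = NULL) {
  if (is.null(max_r))
    max_r <- min(nrow(kernel), ncol(kernel)) / 2 - 1
  r <- seq(0, max_r, by = dr)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  vals <- vapply(r, function(ri) {
    mean(bilinear_interp(kernel,
                         center[1] + ri * sin(th),
                         center[2] + ri * cos(th)))
  }, numeric(1))
  data.frame(r_px = r, value = vals)
}

#' Full width at half maximum of a PSF kernel
#'
#' Measured on the angle-averaged radial profile about the kernel's centre
#' of mass, with linear interpolation of the half-maximum crossing.
#'
#' @param kernel non-negative 2D kernel matrix.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return FWHM in micrometres.
#' @export
psf_fwhm <- function(kernel, pixel_size_um) {
  # sinc-interpolate onto a finer grid first: linear interpolation of a
  # peaked kernel sampled near Nyquist biases the half-max crossing
  up <- 4L
  kernel <- pmax(fft_upsample(kernel, up), 0)
  pixel_size_um <- pixel_size_um / up
  com <- kernel_com(kernel)
  prof <- radial_profile(kernel, com, dr = 0.05,
                         max_r = min(dim(kernel)) / 2 - 1)
  half <- prof$value[1] / 2
  below <- which(prof$value <= half)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(0)
  # linear interpolation between the bracketing radii
  r_half <- prof$r_px[i - 1] +
    (prof$value[i - 1] - half) / (prof$value[i - 1] - prof$value[i]) *
    (prof$r_px[i] - prof$r_px[i - 1])
  2 * r_half * pixel_size_um
}

# Band-limited (zero-padded FFT) upsampling of an image by integer factor.
fft_upsample <- function(img, factor) {
  ny <- nrow(img); nx <- ncol(img)
  F0 <- fft(img)
  NY <- ny * factor; NX <- nx * factor
  F1 <- matrix(0 + 0i, NY, NX)
  iy <- fft_freq(ny); ix <- fft_freq(nx)
  F1[ifelse(iy >= 0, iy + 1, NY + iy + 1),
     ifelse(ix >= 0, ix + 1, NX + ix + 1)] <- F0
  Re(fft(F1, inverse = TRUE)) * factor^2 / (NY * NX)
}

# Centre of mass of a non-negative kernel, c(y, x) in pixels.
kernel_com <- function(kernel) {
  w <- pmax(kernel, 0); s <- sum(w)
  c(y = sum(row(kernel) * w) / s, x = sum(col(kernel) * w) / s)
}

# Discrete isotropic Gaussian kernel, odd support, unit sum.
gaussian_kernel <- function(sigma_px, support) {
  stopifnot(support %% 2 == 1)
  h <- (support - 1) / 2
  g1 <- exp(-(-h:h)^2 / (2 * sigma_px^2))
  k <- outer(g1, g1)
  k / sum(k)
}

rms <- function(x) sqrt(mean(x^2))
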