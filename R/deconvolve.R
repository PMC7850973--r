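#' Richardson-Lucy deconvolution
#'
#' Iterative maximum-likelihood deblurring under the Poisson photon-noise
#' model: each iteration multiplies the current estimate by the
#' back-projected ratio of observed to re-blurred image,
#' \deqn{u_{k+1} = u_k \cdot \left[\frac{d}{u_k \ast h} \ast \tilde h\right],}
#' where \eqn{h} is the PSF and \eqn{\tilde h} its mirror.  The update
#' preserves non-negativity and (up to boundary effects, handled with
#' replicated edges) total flux.  Iteration stops at `max_iterations` or
#' when the relative change of the reconvolution residual falls below
#' `stop_tol`.
#'
#' @param x observed image (matrix) or stack (3D array `[frame, y, x]`),
#'   non-negative.
#' @param psf a [psf_model()] (unit-sum kernel).
#' @param max_iterations iteration cap.
#' @param stop_tol relative residual-change stopping tolerance.
#' @param damping relaxation coefficient in `[0, 1)`: the multiplicative
#'   correction `c` is replaced by `1 + (1 - damping) (c - 1)`; 0 (default)
#'   is the plain RL update.
#' @return a `deconvolution_result`: `estimate` (same shape as `x`),
#'   `iterations_run`, `residual_history` (reconvolution RMS per
#'   iteration), `converged`.  For stacks these fields are per-frame lists
#'   or vectors.
#' @export
richardson_lucy <- function(x, psf, max_iterations = 50, stop_tol = 1e-4,
                            damping = 0) {
  stopifnot(inherits(psf, "psf_model"))
  if (any(is.na(x))) stop("input contains NaN/NA")
  if (any(x < -1e-9 * max(abs(x)))) stop("input must be non-negative")
  x <- pmax(x, 0)
  if (length(dim(x)) == 3L) {
    frames <- lapply(seq_len(dim(x)[1]), function(j)
      richardson_lucy(x[j, , ], psf, max_iterations, stop_tol, damping))
    est <- array(0, dim(x))
    for (j in seq_along(frames)) est[j, , ] <- frames[[j]]$estimate
    return(structure(list(
      estimate = est,
      iterations_run = vapply(frames, `[[`, integer(1), "iterations_run"),
      residual_history = lapply(frames, `[[`, "residual_history"),
      converged = vapply(frames, `[[`, logical(1), "converged")),
      class = "deconvolution_result"))
  }
  h <- psf$kernel
  ht <- h[rev(seq_len(nrow(h))), rev(seq_len(ncol(h))), drop = FALSE]
  if (sum(x) == 0) {
    return(structure(list(estimate = x, iterations_run = 0L,
                          residual_history = numeric(0), converged = TRUE),
                     class = "deconvolution_result"))
  }
  u <- x
  res_hist <- numeric(0)
  converged <- FALSE
  iters <- 0L
  eps <- 1e-12 * max(x)
  for (k in seq_len(max_iterations)) {
    reblur <- conv2_same(u, h)
    res <- rms(reblur - x)
    ratio <- x / pmax(reblur, eps)
    corr <- conv2_same(ratio, ht)
    if (damping > 0) corr <- 1 + (1 - damping) * (corr - 1)
    u <- pmax(u * corr, 0)
    iters <- k
    res_hist <- c(res_hist, res)
    if (k > 1) {
      rel <- abs(res_hist[k - 1] - res) / max(res_hist[k - 1], 1e-300)
      if (rel < stop_tol) { converged <- TRUE; break }
    }
  }
  structure(list(estimate = u, iterations_run = iters,
                 residual_history = res_hist, converged = converged),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  it <- sum(x$iterations_run)
  cat(sprintf("<deconvolution_result> %d iteration(s), %s\n", it,
              if (all(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Reconvolution residual
#'
#' RMS of `estimate (x) psf - observed`; the standard convergence/quality
#' diagnostic for deconvolution: a good estimate re-blurs to the data.
#'
#' @param estimate deconvolved image (matrix).
#' @param psf a [psf_model()].
#' @param observed observed image, same shape as `estimate`.
#' @return RMS residual (scalar).
#' @export
reconvolution_residual <- function(estimate, psf, observed) {
  stopifnot(inherits(psf, "psf_model"))
  if (!all(dim(estimate) == dim(observed)))
    stop("`estimate` and `observed` shapes differ")
  rms(conv2_same(estimate, psf$kernel) - observed)
}

#' Deconvolve a movie frame by frame
#'
#' Applies [richardson_lucy()] with a shared PSF to every frame.  The PSF
#' pixel size must match the movie's (no implicit resampling).
#'
#' @param movie a [movie_stack()] (typically registered and bleach
#'   corrected).
#' @param psf a [psf_model()].
#' @param max_iterations,stop_tol,damping passed to [richardson_lucy()].
#' @param verbose print per-frame progress to stderr.
#' @return a [movie_stack()] of deconvolved frames; per-frame iteration
#'   counts and final residuals are attached as attribute `diagnostics`.
#' @export
deconvolve_movie <- function(movie, psf, max_iterations = 50,
                             stop_tol = 1e-4, damping = 0, verbose = FALSE) {
  stopifnot(inherits(movie, "movie_stack"), inherits(psf, "psf_model"))
  if (abs(psf$pixel_size_um - movie$pixel_size_um) >
      1e-9 * movie$pixel_size_um)
    stop(sprintf(
      "PSF pixel size (%.4g um) does not match the movie (%.4g um)",
      psf$pixel_size_um, movie$pixel_size_um))
  d <- dim(movie$data)
  out <- array(0, d)
  iters <- integer(d[1]); resid <- numeric(d[1])
  for (j in seq_len(d[1])) {
    r <- richardson_lucy(movie$data[j, , ], psf, max_iterations, stop_tol,
                         damping)
    out[j, , ] <- r$estimate
    iters[j] <- r$iterations_run
    resid[j] <- if (length(r$residual_history))
      tail(r$residual_history, 1) else 0
    if (verbose)
      message(sprintf("frame %d/%d: %d iterations, residual %.4g",
                      j, d[1], iters[j], resid[j]))
  }
  res <- movie_stack(out, movie$pixel_size_um, movie$frame_rate_hz,
                     movie$stimulus_times_s, movie$provenance)
  res <- log_step(res, sprintf(
    "deconvolved (Richardson-Lucy, max_iter=%d, tol=%g, psf=%s)",
    max_iterations, stop_tol, psf$provenance))
  attr(res, "diagnostics") <- data.frame(frame = seq_len(d[1]),
                                         iterations = iters,
                                         residual = resid)
  res
}
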