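#' Extract a region-of-interest trace from a delta F over F stack
#'
#' Returns one \eqn{\Delta F/F} value per frame for a release site, either
#' as the plain mean within a radius or as a matched-filter estimate of the
#' site-centre amplitude using exponential-spread weights
#' \eqn{w_i = e^{-d_i/\lambda}}: \eqn{\hat a_j = \sum_i w_i y_{ij} /
#' \sum_i w_i^2}, which is unbiased for the centre amplitude when the
#' spatial profile is \eqn{a\,e^{-d/\lambda}} and has much lower variance
#' than a single pixel.
#'
#' @param dff a [dff_stack()].
#' @param center_px `c(y_px, x_px)` sub-pixel site centre (1-based).
#' @param radius_um pixels within this radius enter the estimate.
#' @param lambda_um spread length constant for matched-filter weights;
#'   `NULL` gives the unweighted ROI mean.
#' @return numeric vector, one \eqn{\Delta F/F} value per frame.
#' @export
roi_trace <- function(dff, center_px, radius_um, lambda_um = NULL) {
  stopifnot(inherits(dff, "dff_stack"))
  d <- dim(dff$dff)
  px <- dff$pixel_size_um
  yy <- (seq_len(d[2]) - center_px[1]) * px
  xx <- (seq_len(d[3]) - center_px[2]) * px
  dd <- sqrt(outer(yy^2, xx^2, "+"))
  keep <- which(dd <= radius_um)
  if (!length(keep)) stop("no pixels within `radius_um`")
  flat <- matrix(dff$dff, d[1], d[2] * d[3])[, keep, drop = FALSE]
  if (is.null(lambda_um)) return(rowMeans(flat, na.rm = TRUE))
  w <- exp(-dd[keep] / lambda_um)
  ok <- colSums(is.na(flat)) == 0
  as.vector(flat[, ok, drop = FALSE] %*% w[ok]) / sum(w[ok]^2)
}

#' Per-stimulus release amplitudes from a train response
#'
#' Decomposes a \eqn{\Delta F/F} trace evoked by a stimulus train into one
#' release amplitude per pulse.  With `method = "none"` each amplitude is
#' the baseline-referenced increment around its pulse (trace at the sensor
#' peak time after the pulse minus trace just before it) -- adequate when
#' the inter-stimulus interval well exceeds the sensor decay
#' \eqn{\tau_{off}}.  With `method = "kernel"` the trace is temporally
#' deconvolved by linear least squares against the peak-normalized
#' [sensor_kernel()] placed at every stimulus time, which remains unbiased
#' when responses overlap heavily (interval < \eqn{\tau_{off}}).
#'
#' @param trace numeric \eqn{\Delta F/F} trace, one value per frame.
#' @param stimulus_times_s stimulus onset times, seconds from frame 1.
#' @param frame_rate_hz acquisition rate, Hz.
#' @param method `"kernel"` or `"none"`.
#' @param tau_on_ms,tau_off_ms sensor kinetics used for the kernel and the
#'   peak-time lookup.
#' @return numeric vector of per-stimulus release amplitudes
#'   (\eqn{\Delta F/F} units, can be slightly negative from noise).
#' @export
extract_stimulus_responses <- function(trace, stimulus_times_s,
                                       frame_rate_hz,
                                       method = c("kernel", "none"),
                                       tau_on_ms = 250, tau_off_ms = 700) {
  method <- match.arg(method)
  n <- length(trace)
  tt <- (seq_len(n) - 1) / frame_rate_hz
  st <- sort(stimulus_times_s)
  if (any(st < 0 | st > max(tt)))
    stop("stimulus times must lie within the trace")
  K <- length(st)
  # reference the trace to its pre-stimulus baseline
  pre <- which(tt < st[1])
  if (length(pre)) trace <- trace - mean(trace[pre])
  iv <- if (K > 1) min(diff(st)) else Inf
  if (method == "none") {
    if (iv < tau_off_ms / 1000)
      warning("inter-stimulus interval below sensor tau_off; responses ",
              "overlap -- consider method = \"kernel\"")
    tp <- kernel_peak_time(tau_on_ms, tau_off_ms)
    amp <- vapply(st, function(t0) {
      i_pre <- max(1L, floor(t0 * frame_rate_hz))      # frame before onset
      i_pk <- min(n, floor((t0 + tp) * frame_rate_hz) + 1L)
      trace[i_pk] - trace[i_pre]
    }, numeric(1))
    return(amp)
  }
  # kernel mode: sparse banded non-negative least squares on the full train.
  # Release amplitudes are physically non-negative; enforcing that in the
  # solver (rather than clipping noisy unconstrained estimates afterwards)
  # keeps the cumulative release unbiased even when the per-stimulus noise
  # exceeds the quantal size.
  span_s <- 6 * tau_off_ms / 1000
  ii <- list(); jj <- list(); vv <- list()
  for (k in seq_len(K)) {
    rel <- tt - st[k]
    idx <- which(rel > 0 & rel <= span_s)
    if (!length(idx)) next
    ii[[k]] <- idx
    jj[[k]] <- rep(k, length(idx))
    vv[[k]] <- sensor_kernel(rel[idx], tau_on_ms, tau_off_ms)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, K))
  AtA <- Matrix::crossprod(A)
  Atb <- as.numeric(Matrix::crossprod(A, trace))
  a0 <- as.numeric(Matrix::solve(AtA, Atb))
  nnls_banded(AtA, Atb, a0)
}

# Non-negative least squares for a sparse (banded) normal-equation system,
# by cyclic coordinate descent with clamping, warm-started at the clipped
# unconstrained solution.  Converges to the global NNLS optimum (convex QP,
# positive-definite AtA).
nnls_banded <- function(AtA, Atb, a0 = NULL, max_sweeps = 500, tol = 1e-10) {
  K <- length(Atb)
  # general (not symmetric-triangular) storage so each column is complete
  AtA <- as(as(AtA, "generalMatrix"), "CsparseMatrix")
  p <- AtA@p; i <- AtA@i; xv <- AtA@x
  a <- if (is.null(a0)) numeric(K) else pmax(a0, 0)
  g <- Atb - as.numeric(AtA %*% a)        # negative gradient
  dg <- Matrix::diag(AtA)
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (k in seq_len(K)) {
      a_new <- max(0, a[k] + g[k] / dg[k])
      d <- a_new - a[k]
      if (d != 0) {
        idx <- (p[k] + 1L):p[k + 1L]
        a[k] <- a_new
        g[i[idx] + 1L] <- g[i[idx] + 1L] - xv[idx] * d
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol * max(max(a), 1e-12)) break
  }
  a
}

# time at which the difference-of-exponentials kernel peaks (seconds)
kernel_peak_time <- function(tau_on_ms, tau_off_ms) {
  ton <- min(tau_on_ms, tau_off_ms) / 1000
  toff <- max(tau_on_ms, tau_off_ms) / 1000
  if (abs(ton - toff) < 1e-12) return(ton)
  ton * toff / (toff - ton) * log(toff / ton)
}

#' Cumulative release series
#'
#' Prefix sums of the per-stimulus amplitudes with negative values
#' (noise artefacts -- release is non-negative) clipped to zero first; the
#' number of clipped entries is reported in attribute `n_clipped`.
#'
#' @param amplitudes per-stimulus release amplitudes.
#' @return cumulative series of the same length, non-decreasing.
#' @export
cumulative_release <- function(amplitudes) {
  clipped <- pmax(amplitudes, 0)
  out <- cumsum(clipped)
  attr(out, "n_clipped") <- sum(amplitudes < 0)
  out
}

#' Back-extrapolation fit of the cumulative release curve
#'
#' Ordinary least squares on the late, refill-dominated phase of the
#' cumulative release versus stimulus number.  Early in a prolonged train
#' the readily releasable pool depletes; once release balances refill the
#' cumulative curve grows linearly.  Extrapolating that line back to
#' stimulus zero, the y-intercept estimates the initially available pool
#' (in \eqn{\Delta F/F} units) and the slope the vesicle refill rate per
#' stimulus.
#'
#' @param cumulative cumulative release series from [cumulative_release()].
#' @param late_fraction fraction of final stimuli taken as the linear
#'   phase (default the final third).
#' @param min_late_points minimum number of late points required.
#' @return object of class `pool_fit`: `pool_estimate_dff` (intercept),
#'   `refill_rate_dff_per_stimulus` (slope), `late_fraction`,
#'   `fit_r_squared`, `n_late_points`, `slope_nonnegative`,
#'   `late_phase_linear` (curvature check), plus slots for
#'   `release_probability`, `quantal_size_dff` and `pool_vesicles` filled
#'   by the downstream estimators.
#' @export
fit_pool_model <- function(cumulative, late_fraction = 1 / 3,
                           min_late_points = 20) {
  K <- length(cumulative)
  n_late <- max(min_late_points, ceiling(K * late_fraction))
  if (K < n_late)
    stop("need at least ", n_late, " stimuli for the late-phase fit")
  idx <- (K - n_late + 1L):K
  df <- data.frame(x = idx, y = as.numeric(cumulative[idx]))
  fit <- lm(y ~ x, data = df)
  cf <- coef(fit)
  ss_tot <- sum((df$y - mean(df$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  # curvature check: a quadratic term that changes the fitted span by > 5%
  # flags a late phase that is not yet linear
  qfit <- lm(y ~ x + I(x^2), data = df)
  qc <- coef(qfit)[["I(x^2)"]]
  span <- diff(range(df$y))
  linear_ok <- !is.finite(qc) || span == 0 ||
    abs(qc) * (n_late / 2)^2 <= 0.05 * span
  slope <- unname(cf[["x"]])
  if (slope < 0)
    warning("negative refill slope; late phase may be dominated by noise")
  if (!linear_ok)
    warning("late phase fails the curvature (linearity) check; consider ",
            "a smaller `late_fraction` or a longer train")
  structure(list(pool_estimate_dff = unname(cf[["(Intercept)"]]),
                 refill_rate_dff_per_stimulus = slope,
                 late_fraction = late_fraction,
                 fit_r_squared = r2,
                 n_late_points = n_late,
                 slope_nonnegative = slope >= 0,
                 late_phase_linear = linear_ok,
                 release_probability = NA_real_,
                 quantal_size_dff = NA_real_,
                 pool_vesicles = NA_real_,
                 fit = fit),
            class = "pool_fit")
}

#' @export
print.pool_fit <- function(x, ...) {
  cat(sprintf(
    "<pool_fit> pool = %.4g dF/F, refill = %.4g dF/F per stimulus (R2 %.4g, %d late pts)\n",
    x$pool_estimate_dff, x$refill_rate_dff_per_stimulus, x$fit_r_squared,
    x$n_late_points))
  if (is.finite(x$release_probability))
    cat(sprintf("  release probability %.4g", x$release_probability))
  if (is.finite(x$quantal_size_dff))
    cat(sprintf(", quantal size %.4g dF/F, pool ~ %.4g vesicles",
                x$quantal_size_dff, x$pool_vesicles))
  cat("\n")
  invisible(x)
}

#' Release probability
#'
#' Fraction of the available pool released per stimulus, defined against
#' the back-extrapolated pool estimate: the mean of the first `n_first`
#' individual release amplitudes (before appreciable depletion) divided by
#' the pool.  The raw running average of the individual releases is
#' returned as attribute `running_average`.
#'
#' @param amplitudes per-stimulus release amplitudes.
#' @param pool_fit a [fit_pool_model()] result with positive pool estimate.
#' @param n_first number of initial stimuli averaged (default 5).
#' @return release probability (scalar in `[0, 1]` for well-behaved data).
#' @export
release_probability <- function(amplitudes, pool_fit, n_first = 5) {
  stopifnot(inherits(pool_fit, "pool_fit"))
  if (!is.finite(pool_fit$pool_estimate_dff) ||
      pool_fit$pool_estimate_dff <= 0)
    stop("release probability undefined: pool estimate is not positive")
  a <- pmax(amplitudes, 0)
  pr <- mean(head(a, n_first)) / pool_fit$pool_estimate_dff
  attr(pr, "running_average") <- cumsum(a) / seq_along(a)
  pr
}

#' Estimate the quantal size
#'
#' The \eqn{\Delta F/F} contributed by a single vesicle, estimated from
#' the distribution of per-stimulus release amplitudes.
#' `"histogram_mode"` takes the first local maximum of a kernel-density
#' estimate of the positive amplitudes (the one-vesicle peak);
#' `"min_positive"` takes a trimmed minimum (the 5th percentile of positive
#' amplitudes).  Amplitudes below the noise floor (estimated by mirroring
#' the negative amplitudes, which can only be noise) are excluded first.
#'
#' @param amplitudes per-stimulus release amplitudes.
#' @param method `"histogram_mode"` or `"min_positive"`.
#' @param min_amplitude noise floor below which amplitudes are treated as
#'   failures-plus-noise rather than release events.  `NULL` estimates it
#'   as the larger of 2 robust SDs of the mirrored negative amplitudes and
#'   30% of the 90th percentile of the positive ones; the second term
#'   matters when a non-negative extraction leaves no negatives to measure
#'   the noise from but piles small spurious amplitudes near zero.
#' @param min_events minimum number of retained events for histogram mode.
#' @return quantal size in \eqn{\Delta F/F} units.
#' @export
estimate_quantal_size <- function(amplitudes,
                                  method = c("histogram_mode",
                                             "min_positive"),
                                  min_amplitude = NULL, min_events = 50) {
  method <- match.arg(method)
  if (is.null(min_amplitude)) {
    neg <- amplitudes[amplitudes < 0]
    from_neg <- if (length(neg) >= 10)
      2 * mad(c(neg, -neg), center = 0) else 0
    posq <- amplitudes[amplitudes > 0]
    from_scale <- if (length(posq))
      0.3 * unname(quantile(posq, 0.9)) else 0
    min_amplitude <- max(from_neg, from_scale)
  }
  pos <- amplitudes[amplitudes > min_amplitude]
  if (method == "min_positive") {
    if (length(pos) < 5) stop("too few positive amplitudes")
    return(unname(quantile(pos, 0.05)))
  }
  if (length(pos) < min_events)
    stop("histogram mode needs at least ", min_events, " events above the ",
         "noise floor")
  den <- density(pos)
  y <- den$y
  # first local maximum of the density
  i <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(i)) i <- which.max(y)
  den$x[i[1]]
}

#' Full pool analysis of a train response
#'
#' Chains [extract_stimulus_responses()], [cumulative_release()],
#' [fit_pool_model()], [release_probability()] and
#' [estimate_quantal_size()] and reports everything in one `pool_fit`.
#'
#' @inheritParams extract_stimulus_responses
#' @inheritParams fit_pool_model
#' @param n_first stimuli averaged for the release probability.
#' @param quantal_method method for [estimate_quantal_size()]; `NULL`
#'   skips the quantal estimate.
#' @return a `pool_fit` with `release_probability`, `quantal_size_dff` and
#'   `pool_vesicles` (pool / quantal size) filled in; the per-stimulus
#'   amplitudes and cumulative series are attached as attributes
#'   `amplitudes` and `cumulative`.
#' @export
analyze_pool <- function(trace, stimulus_times_s, frame_rate_hz,
                         method = c("kernel", "none"), tau_on_ms = 250,
                         tau_off_ms = 700, late_fraction = 1 / 3,
                         n_first = 5, quantal_method = "histogram_mode") {
  amp <- extract_stimulus_responses(trace, stimulus_times_s, frame_rate_hz,
                                    method, tau_on_ms, tau_off_ms)
  cum <- cumulative_release(amp)
  pf <- fit_pool_model(cum, late_fraction)
  pf$release_probability <- as.numeric(release_probability(amp, pf, n_first))
  if (!is.null(quantal_method)) {
    q <- tryCatch(estimate_quantal_size(amp, quantal_method),
                  error = function(e) NA_real_)
    pf$quantal_size_dff <- q
    pf$pool_vesicles <- if (is.finite(q) && q > 0)
      pf$pool_estimate_dff / q else NA_real_
  }
  attr(pf, "amplitudes") <- amp
  attr(pf, "cumulative") <- cum
  pf
}
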