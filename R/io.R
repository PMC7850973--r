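#' Read a movie from a multi-page TIFF
#'
#' Grayscale 8/16-bit unsigned or 32-bit float TIFFs are supported, one
#' frame per page.  Acquisition metadata comes from a JSON sidecar
#' (`<path>.json`, written by [write_movie()]) or from the arguments;
#' having neither is an error, since every downstream stage needs the
#' pixel size and frame rate.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_rate_hz,stimulus_times_s metadata overrides
#'   (take precedence over the sidecar).
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, pixel_size_um = NULL, frame_rate_hz = NULL,
                       stimulus_times_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop("RGB / multi-channel TIFF is not supported; supply a grayscale ",
         "stack with one frame per page")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  else list()
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  frame_rate_hz <- frame_rate_hz %||% meta$frame_rate_hz
  stimulus_times_s <- stimulus_times_s %||% meta$stimulus_times_s
  if (is.null(pixel_size_um) || is.null(frame_rate_hz))
    stop("pixel size and frame rate are required: pass them as arguments ",
         "or provide the JSON sidecar ", side)
  scale <- meta$scale %||% 1
  d <- dim(pages[[1]])
  data <- array(0, c(length(pages), d[1], d[2]))
  for (j in seq_along(pages)) data[j, , ] <- pages[[j]] * scale
  if (!is.null(meta$integer_counts) && isTRUE(meta$integer_counts))
    data <- round(data)
  movie_stack(data, pixel_size_um, frame_rate_hz, stimulus_times_s,
              provenance = meta$provenance %||% sprintf("read %s", path))
}

#' Write a movie to a multi-page TIFF with JSON sidecar
#'
#' Integer stacks with values up to 65535 are written as 16-bit unsigned
#' (lossless); anything else as 32-bit float.  Metadata (pixel size, frame
#' rate, stimulus times, intensity scale, provenance) goes to
#' `<path>.json` so that [read_movie()] round-trips exactly.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  mx <- max(movie$data)
  is_int <- all(movie$data == round(movie$data))
  if (is_int && mx <= 65535) {
    scale <- 65535
    pages <- lapply(seq_len(d[1]), function(j) movie$data[j, , ] / scale)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 16))
  } else {
    # 32-bit float path; values are stored in [0, 1] (the storage of
    # values outside that range is undefined in the TIFF writer) with the
    # scale recorded in the sidecar
    scale <- max(mx, 1)
    pages <- lapply(seq_len(d[1]), function(j) movie$data[j, , ] / scale)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32))
  }
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size_um,
         frame_rate_hz = movie$frame_rate_hz,
         stimulus_times_s = movie$stimulus_times_s,
         scale = scale, integer_counts = is_int,
         provenance = movie$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Save / load a PSF model (TIFF kernel + JSON sidecar)
#'
#' @param psf a [psf_model()].
#' @param path output TIFF path; metadata goes to `<path>.json`.
#' @return `path` (write) or a [psf_model()] (read).
#' @export
write_psf <- function(psf, path) {
  stopifnot(inherits(psf, "psf_model"))
  suppressWarnings(tiff::writeTIFF(psf$kernel, path, bits.per.sample = 32))
  jsonlite::write_json(
    list(pixel_size_um = psf$pixel_size_um, fwhm_um = psf$fwhm_um,
         provenance = psf$provenance,
         n_beads_averaged = psf$n_beads_averaged),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  kernel <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  psf_model(kernel, meta$pixel_size_um, fwhm_um = meta$fwhm_um,
            provenance = meta$provenance,
            n_beads_averaged = meta$n_beads_averaged %||% 0L)
}

#' Write simulation ground truth (JSON + CSV event table)
#'
#' @param sim result of [simulate_movie()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `movie.tif`(+sidecar),
#'   `events.csv` (site_id, stimulus_index, vesicles_released, occupancy)
#'   and `truth.json`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_movie(sim$movie, file.path(dir, "movie.tif"))
  write.csv(sim$truth$events, file.path(dir, "events.csv"),
            row.names = FALSE)
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(site_positions_um = sim$truth$site_positions_um,
         drift_px = sim$truth$drift_px,
         bleach_curve = sim$truth$bleach_curve,
         config = cfg[setdiff(names(cfg), "site_positions_um")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
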