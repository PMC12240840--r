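#' Fluorescence movie container
#'
#' A lightweight wrapper around an `H x W x T` numeric array with the
#' geometry and timing metadata needed by the analysis: um per pixel,
#' frames per second, clock origin and stimulus times. Frame `k` (1-based)
#' is timestamped `t0 + (k - 1) / fps` (frame start).
#'
#' @param frames Numeric `H x W x T` array.
#' @param pixel_size um per pixel.
#' @param fps Frames per second.
#' @param t0 Time of the first frame in seconds.
#' @param stimulus_times Stimulus onset times in seconds.
#' @param units Character description of the pixel values.
#' @return A `vq_movie` object.
#' @export
new_movie <- function(frames, pixel_size, fps, t0 = 0,
                      stimulus_times = numeric(), units = "fluorescence") {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be an H x W x T array")
  }
  if (any(!is.finite(frames))) abort("movie frames must be finite")
  assert_scalar_pos(pixel_size, "pixel_size")
  assert_scalar_pos(fps, "fps")
  structure(
    list(frames = frames, pixel_size = pixel_size, fps = fps, t0 = t0,
         stimulus_times = stimulus_times, units = units),
    class = "vq_movie"
  )
}

#' @export
print.vq_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<vq_movie> %d x %d px (%g um/px), %d frames at %g fps [%s]\n",
    d[1], d[2], x$pixel_size, d[3], x$fps, x$units
  ))
  if (length(x$stimulus_times)) {
    cat("  stimuli at", paste(signif(utils::head(x$stimulus_times, 5), 4),
                              collapse = ", "),
        if (length(x$stimulus_times) > 5) "..." else "", "s\n")
  }
  invisible(x)
}

# Frame timestamps (frame starts).
frame_times <- function(movie) {
  movie$t0 + (seq_len(dim(movie$frames)[3]) - 1) / movie$fps
}

#' Wrap dF/F0 frames (percent) and a baseline map as a `vq_dff` movie
#'
#' Used to promote sensor-model output (which is already dF/F0) to the
#' container the analysis functions expect, bypassing the camera.
#'
#' @param frames `H x W x T` array of percent dF/F0.
#' @param f0_map `H x W` baseline fluorescence map.
#' @inheritParams new_movie
#' @return A `vq_dff` movie.
#' @export
new_dff_movie <- function(frames, f0_map, pixel_size, fps, t0 = 0,
                          stimulus_times = numeric()) {
  m <- new_movie(frames, pixel_size, fps, t0, stimulus_times,
                 units = "% dF/F0")
  m$f0_map <- f0_map
  class(m) <- c("vq_dff", class(m))
  m
}

#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit TIFF pages after an affine normalisation
#' `stored = (value - value_offset) / value_scale` recorded in the sidecar,
#' which preserves the data to better than single-float precision
#' (relative quantisation ~2e-10 of the dynamic range). The sidecar
#' `<path>.json` carries `pixel_size_um`, `fps`, `t0_s`,
#' `stimulus_times_s`, `units`, the normalisation, and an optional `seed`.
#' External integer TIFF stacks (e.g. 16-bit camera output) are promoted
#' to float on read; the integer scale is recorded in the returned movie's
#' `promotion_scale` field.
#'
#' @param movie A `vq_movie`.
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @param seed Optional integer recorded in the sidecar.
#' @return `write_movie()` returns `path` invisibly; `read_movie()` a
#'   `vq_movie`.
#' @export
write_movie <- function(movie, path, seed = NULL) {
  stopifnot(inherits(movie, "vq_movie"))
  lo <- min(movie$frames)
  hi <- max(movie$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(k) (movie$frames[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    pixel_size_um = movie$pixel_size, fps = movie$fps, t0_s = movie$t0,
    stimulus_times_s = movie$stimulus_times, units = movie$units,
    value_offset = lo, value_scale = scale
  )
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    abort(sprintf("missing sidecar metadata %s", side))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (req in c("pixel_size_um", "fps")) {
    if (is.null(meta[[req]])) {
      abort(sprintf("sidecar metadata lacks required field `%s`", req))
    }
  }
  promotion_scale <- 1
  if (!is.null(meta$value_scale)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      p * meta$value_scale + (meta$value_offset %||% 0)
    })
  } else {
    # External stack: read raw sample values, promote integers to float.
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      p + 0
    })
    promotion_scale <- 1
  }
  fr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) fr[, , k] <- pages[[k]]
  m <- new_movie(fr, meta$pixel_size_um, meta$fps,
                 t0 = meta$t0_s %||% 0,
                 stimulus_times = meta$stimulus_times_s %||% numeric(),
                 units = meta$units %||% "fluorescence")
  m$promotion_scale <- promotion_scale
  m
}
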