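#' Compute dF/F0 from a fluorescence movie
#'
#' `F0` is the per-pixel mean over the baseline window (which must contain
#' at least 3 frames and precede the first stimulus);
#' `dF/F0 = 100 (F - F0) / F0`. Pixels with non-positive baseline are
#' masked (set `NA` in `f0_map`, zero response) with a warning.
#'
#' @param movie A fluorescence `vq_movie`.
#' @param baseline_window `(start, end)` seconds; defaults to everything
#'   before the first stimulus.
#' @return A `vq_dff` movie (percent dF/F0) with `f0_map` attached.
#' @export
compute_dff <- function(movie, baseline_window = NULL) {
  stopifnot(inherits(movie, "vq_movie"))
  tt <- frame_times(movie)
  if (is.null(baseline_window)) {
    if (!length(movie$stimulus_times)) {
      abort("no stimulus times: pass `baseline_window` explicitly")
    }
    baseline_window <- c(tt[1], min(movie$stimulus_times))
  }
  idx <- which(tt >= baseline_window[1] & tt < baseline_window[2])
  if (length(idx) < 3L) {
    abort("baseline window must contain at least 3 frames")
  }
  if (length(movie$stimulus_times) &&
      baseline_window[2] > min(movie$stimulus_times) + 1e-9) {
    abort("baseline window must precede the first stimulus")
  }
  d <- dim(movie$frames)
  f0 <- apply(movie$frames[, , idx, drop = FALSE], c(1, 2), mean)
  bad <- f0 <= 0
  if (any(bad)) {
    warn(sprintf("%d pixel(s) with non-positive baseline masked", sum(bad)))
    f0[bad] <- NA_real_
  }
  dff <- array(0, dim = d)
  safe_f0 <- f0
  safe_f0[bad] <- 1
  for (k in seq_len(d[3])) {
    fr <- 100 * (movie$frames[, , k] - f0) / safe_f0
    fr[bad] <- 0
    dff[, , k] <- fr
  }
  dff[is.na(dff)] <- 0
  m <- new_dff_movie(dff, f0, movie$pixel_size, movie$fps, movie$t0,
                     movie$stimulus_times)
  m$truth <- movie$truth
  m
}

#' Pixel-wise maximal dF/F0 map
#'
#' Builds the 3-D spatial profile of a releasing synapse: per pixel the
#' maximum of the boxcar-smoothed trace over a response window. Background
#' statistics (median and MAD) are computed from the pixels below the
#' 50th percentile of map values, on the premise that release sites occupy
#' a small area fraction.
#'
#' @param dff A `vq_dff` movie.
#' @param response_window `(start, end)` seconds; default: first stimulus
#'   to end of movie (whole movie when no stimuli are recorded).
#' @param smooth_frames Temporal boxcar width in frames applied before the
#'   max (suppresses shot-noise max bias); 1 disables smoothing.
#' @return A `vq_maxmap` object: `values` (H x W), `window`,
#'   `background_median`, `background_mad`, `pixel_size`.
#' @export
compute_pixel_max_map <- function(dff, response_window = NULL,
                                  smooth_frames = 3L) {
  stopifnot(inherits(dff, "vq_dff"))
  tt <- frame_times(dff)
  if (is.null(response_window)) {
    start <- if (length(dff$stimulus_times)) min(dff$stimulus_times) else tt[1]
    response_window <- c(start, tt[length(tt)] + 1 / dff$fps)
  }
  idx <- which(tt >= response_window[1] & tt < response_window[2])
  if (!length(idx)) abort("response window contains no frames")
  d <- dim(dff$frames)
  fr <- dff$frames
  if (smooth_frames > 1L) {
    w <- as.integer(smooth_frames)
    mat <- matrix(fr, d[1] * d[2], d[3])
    cs <- cbind(0, t(apply(mat, 1, cumsum)))
    sm <- matrix(0, d[1] * d[2], d[3])
    for (k in seq_len(d[3])) {
      k0 <- max(0L, k - w)
      sm[, k] <- (cs[, k + 1L] - cs[, k0 + 1L]) / (k - k0)
    }
    fr <- array(sm, dim = d)
  }
  vals <- apply(fr[, , idx, drop = FALSE], c(1, 2), max)
  new_maxmap(vals, dff$pixel_size, window = response_window,
             truth = dff$truth)
}

# Assemble a pixel-max map with background statistics from the pixels
# below the 50th percentile of map values.
new_maxmap <- function(values, pixel_size, window = c(0, 0), truth = NULL) {
  lower <- values[values <= stats::quantile(values, 0.5)]
  structure(
    list(
      values = values,
      window = window,
      background_median = median(lower),
      background_mad = mad(lower, constant = 1),
      pixel_size = pixel_size,
      truth = truth
    ),
    class = "vq_maxmap"
  )
}

#' @export
print.vq_maxmap <- function(x, ...) {
  cat(sprintf(
    "<vq_maxmap> %d x %d px (%g um/px), window [%.3g, %.3g] s, peak %.3g%%\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$window[1], x$window[2],
    max(x$values)
  ))
  cat(sprintf("  background median %.3g%%, MAD %.3g%%\n",
              x$background_median, x$background_mad))
  invisible(x)
}

#' Detect isolated release sites on a pixel-max map
#'
#' Local maxima exceeding
#' `background_median + snr_threshold * 1.4826 * background_mad` are
#' candidate release centres; peaks closer than `min_separation` are merged
#' keeping the larger. A site is `isolated` when no other detected site
#' lies within `isolation_radius`.
#'
#' @param map A `vq_maxmap`.
#' @param min_separation Minimum peak separation in um (>= 2 pixels).
#' @param snr_threshold Detection threshold in robust SDs above background.
#' @param isolation_radius Isolation radius in um.
#' @return A tibble: `site_id`, `row`, `col` (0-based), `x_um`, `y_um`,
#'   `peak_pct`, `snr`, `isolated`. Empty tibble when nothing is detected.
#' @export
detect_release_sites <- function(map, min_separation = 1.5,
                                 snr_threshold = 4, isolation_radius = 3) {
  stopifnot(inherits(map, "vq_maxmap"))
  ps <- map$pixel_size
  if (min_separation < 2 * ps) {
    abort("`min_separation` must be at least 2 pixels")
  }
  v <- map$values
  H <- nrow(v); W <- ncol(v)
  # numerical floor: on noiseless maps the background MAD collapses to 0
  # and floating-point dust would otherwise register as peaks
  sigma <- max(MAD_TO_SD * map$background_mad,
               1e-9 * (max(v) - map$background_median), 1e-300)
  thr <- map$background_median + snr_threshold * sigma
  # 8-neighbourhood local maxima (ties kept; duplicates resolved by merge).
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- v
  is_max <- v > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & v >= pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  empty <- tibble::tibble(
    site_id = integer(), row = integer(), col = integer(),
    x_um = numeric(), y_um = numeric(), peak_pct = numeric(),
    snr = numeric(), isolated = logical()
  )
  if (!nrow(idx)) return(empty)
  peaks <- v[idx]
  ord <- order(peaks, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  peaks <- peaks[ord]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    kept <- which(keep)
    dist <- sqrt((idx[kept, 1] - idx[i, 1])^2 +
                   (idx[kept, 2] - idx[i, 2])^2) * ps
    keep[i] <- all(dist >= min_separation)
  }
  idx <- idx[keep, , drop = FALSE]
  peaks <- unname(peaks[keep])
  x_um <- unname((idx[, 2] - 1) * ps)
  y_um <- unname((idx[, 1] - 1) * ps)
  iso <- vapply(seq_along(peaks), function(i) {
    if (length(peaks) == 1L) return(TRUE)
    dd <- sqrt((x_um[-i] - x_um[i])^2 + (y_um[-i] - y_um[i])^2)
    all(dd >= isolation_radius)
  }, logical(1))
  tibble::tibble(
    site_id = seq_along(peaks),
    row = as.integer(idx[, 1] - 1L),
    col = as.integer(idx[, 2] - 1L),
    x_um = x_um, y_um = y_um,
    peak_pct = peaks,
    snr = (peaks - map$background_median) / sigma,
    isolated = iso
  )
}
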