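#' Radial profile of a pixel-max map around a release centre
#'
#' Annulus means of map values at radii `[k dr, (k+1) dr)`; empty annuli
#' are filled by linear interpolation between neighbours.
#'
#' @param map A `vq_maxmap`.
#' @param center `(x, y)` in um.
#' @param dr Annulus width in um.
#' @param r_max Outer radius in um (>= 3 dr).
#' @return A tibble (`r_um`, `dff_pct`) with attributes `dr`, `r_max` and
#'   `background` (the map's background median).
#' @export
radial_profile <- function(map, center, dr = 0.1, r_max = 8) {
  stopifnot(inherits(map, "vq_maxmap"))
  assert_scalar_pos(dr, "dr")
  if (r_max < 3 * dr) abort("`r_max` must be at least 3 * dr")
  px_of_um(center, map$pixel_size, dim(map$values))  # bounds check
  r <- radius_map(nrow(map$values), ncol(map$values), center,
                  map$pixel_size)
  sel <- r < r_max
  bin <- floor(r[sel] / dr)
  mv <- tapply(map$values[sel], bin, mean)
  mr <- tapply(r[sel], bin, mean)  # mean pixel radius, not the bin middle
  all_bins <- seq(0, floor((r_max - 1e-9) / dr))
  vals <- rep(NA_real_, length(all_bins))
  vals[match(as.numeric(names(mv)), all_bins)] <- as.numeric(mv)
  rads <- (all_bins + 0.5) * dr
  rads[match(as.numeric(names(mr)), all_bins)] <- as.numeric(mr)
  if (anyNA(vals)) {
    filled <- which(!is.na(vals))
    vals <- approx(rads[filled], vals[filled], xout = rads, rule = 2)$y
  }
  out <- tibble::tibble(r_um = rads, dff_pct = vals)
  attr(out, "dr") <- dr
  attr(out, "r_max") <- r_max
  attr(out, "background") <- map$background_median
  class(out) <- c("radial_profile", class(out))
  out
}

#' Fit the single-exponential spatial spread
#'
#' Least-squares fit of `p(r) = p0 exp(-r / lambda) + offset` to a radial
#' profile, with the offset fixed to the map background (a free offset is
#' degenerate with lambda on short profiles). The decay constant `lambda`
#' is the spatial spread length constant.
#'
#' @param profile A [radial_profile()] tibble.
#' @param fit_range `(min, max)` radius in um.
#' @param offset Fixed offset; defaults to the profile's background
#'   attribute (0 if absent).
#' @return A `spatial_fit` object: `lambda`, `p0`, `offset`, `r_squared`,
#'   `converged`, `at_bound`.
#' @export
fit_length_constant <- function(profile, fit_range = c(0, 8),
                                offset = NULL) {
  r <- profile$r_um
  v <- profile$dff_pct
  sel <- r >= fit_range[1] & r <= fit_range[2]
  if (sum(sel) < 5L) abort("need at least 5 profile points in the fit range")
  r <- r[sel]
  v <- v[sel] - (offset %||% attr(profile, "background") %||% 0)
  off <- offset %||% attr(profile, "background") %||% 0
  # log-linear start values on the positive part
  pos <- v > max(v) * 1e-3
  start_lam <- if (sum(pos) >= 2L) {
    sl <- coef(lm(log(v[pos]) ~ r[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else 1
  } else 1
  lam_lo <- 1e-3
  lam_hi <- 50
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ p0 * exp(-r / lambda),
      start = list(p0 = max(v), lambda = min(max(start_lam, 0.05), 10)),
      lower = c(0, lam_lo), upper = c(Inf, lam_hi),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    res <- list(lambda = NA_real_, p0 = NA_real_, offset = off,
                r_squared = NA_real_, converged = FALSE, at_bound = FALSE)
  } else {
    cf <- coef(fit)
    rsq <- 1 - sum(residuals(fit)^2) / sum((v - mean(v))^2)
    res <- list(
      lambda = unname(cf["lambda"]), p0 = unname(cf["p0"]), offset = off,
      r_squared = max(0, min(1, rsq)), converged = TRUE,
      at_bound = cf["lambda"] <= lam_lo * 1.01 || cf["lambda"] >= lam_hi * 0.99
    )
    if (res$at_bound) {
      warn(sprintf("lambda fit at bound (%.3g um): flagged", res$lambda))
    }
  }
  structure(res, class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf(
    "<spatial_fit> lambda = %.3f um, p0 = %.3g%%, offset = %.3g%%, R2 = %.3f%s\n",
    x$lambda, x$p0, x$offset, x$r_squared,
    if (!x$converged) " (NOT CONVERGED)" else if (x$at_bound) " (AT BOUND)" else ""
  ))
  invisible(x)
}

# Connected component (8-neighbourhood) of a logical mask containing a
# pixel; iterative flood fill.
flood_component <- function(mask, start_rc) {
  H <- nrow(mask); W <- ncol(mask)
  comp <- matrix(FALSE, H, W)
  if (!mask[start_rc[1], start_rc[2]]) return(comp)
  stack <- matrix(start_rc, ncol = 2)
  comp[start_rc[1], start_rc[2]] <- TRUE
  while (nrow(stack)) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      rr <- cur[1] + dr; cc <- cur[2] + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
          mask[rr, cc] && !comp[rr, cc]) {
        comp[rr, cc] <- TRUE
        stack <- rbind(stack, c(rr, cc))
      }
    }
  }
  comp
}

#' Half-maximum shape metrics of a diffusion profile
#'
#' The half-max mask is the connected component containing the centre
#' where `map >= background + 0.5 (peak - background)`. Full widths at
#' half maximum come from the second-moment ellipse of the mask
#' (`4 sqrt(eigenvalue)`, exact for filled discs and ellipses);
#' `roundness = 4 area / (pi fwhm_major^2)` so a circle scores 1.
#'
#' @param map A `vq_maxmap`.
#' @param center `(x, y)` in um.
#' @param count_outlets_annulus Annulus passed to [count_outlets()] for the
#'   outlet count included in the result (NULL skips it).
#' @return A one-row tibble: `fwhm_minor_um`, `fwhm_major_um`,
#'   `aspect_ratio`, `roundness`, `half_max_area_um2`, `n_outlets`,
#'   `truncated` (mask touches the image border).
#' @export
shape_metrics <- function(map, center, count_outlets_annulus = c(0.75, 3)) {
  stopifnot(inherits(map, "vq_maxmap"))
  rc <- px_of_um(center, map$pixel_size, dim(map$values))
  v <- map$values
  bg <- map$background_median
  peak <- v[rc[1], rc[2]]
  if (peak <= bg) abort("peak at centre does not exceed background")
  mask <- flood_component(v >= bg + 0.5 * (peak - bg), rc)
  idx <- which(mask, arr.ind = TRUE)
  truncated <- any(idx[, 1] %in% c(1L, nrow(v))) ||
    any(idx[, 2] %in% c(1L, ncol(v)))
  if (truncated) warn("half-max mask touches the image border (truncated)")
  ps <- map$pixel_size
  xy <- cbind(idx[, 2], idx[, 1]) * ps
  ctr <- colMeans(xy)
  S <- crossprod(sweep(xy, 2, ctr)) / nrow(xy) + diag(2) * ps^2 / 12
  ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  fwhm_major <- 4 * sqrt(ev[1])
  fwhm_minor <- 4 * sqrt(ev[2])
  area <- nrow(idx) * ps^2
  n_out <- if (is.null(count_outlets_annulus)) {
    NA_integer_
  } else {
    tryCatch(count_outlets(map, center, annulus = count_outlets_annulus),
             error = function(e) NA_integer_)
  }
  tibble::tibble(
    fwhm_minor_um = fwhm_minor,
    fwhm_major_um = fwhm_major,
    aspect_ratio = fwhm_major / fwhm_minor,
    roundness = 4 * area / (pi * fwhm_major^2),
    half_max_area_um2 = area,
    n_outlets = n_out,
    truncated = truncated
  )
}

#' Count egress outlets around a release centre
#'
#' Builds a 10-degree-binned angular profile over an annulus and counts
#' circular local maxima exceeding `median + 2 * 1.4826 * MAD`, with a
#' minimum angular separation of 45 degrees. To make angular bins
#' comparable, each background-subtracted pixel is first normalised by
#' the radial mean profile at its radius (outlet channels are
#' multiplicative excursions above the isotropic decay, and raw angular
#' means otherwise inherit grid-dependent radial weighting). An isotropic
#' profile yields 0.
#'
#' @param map A `vq_maxmap`.
#' @param center `(x, y)` in um.
#' @param annulus `(inner, outer)` radii in um.
#' @param bin_deg Angular bin width in degrees.
#' @param min_contrast Minimum peak elevation relative to the angular
#'   median (guards against residual grid ripple on noiseless maps,
#'   whose MAD is otherwise vanishingly small).
#' @return Integer outlet count.
#' @export
count_outlets <- function(map, center, annulus = c(0.75, 3), bin_deg = 10,
                          min_contrast = 0.05) {
  stopifnot(inherits(map, "vq_maxmap"))
  ps <- map$pixel_size
  r <- radius_map(nrow(map$values), ncol(map$values), center, ps)
  if (annulus[2] > max(r)) abort("annulus extends outside the map")
  sel <- r >= annulus[1] & r <= annulus[2]
  if (!any(sel)) abort("annulus contains no pixels")
  x <- (col(map$values) - 1) * ps - center[1]
  y <- (row(map$values) - 1) * ps - center[2]
  theta <- (atan2(y, x) * 180 / pi) %% 360
  bin <- floor(theta[sel] / bin_deg)
  # radius-normalised contrast: value relative to the radial mean profile
  rp <- radial_profile(map, center, dr = ps,
                       r_max = min(annulus[2] + 2 * ps, max(r)))
  v_sub <- map$values[sel] - map$background_median
  rad_ref <- approx(rp$r_um, rp$dff_pct - map$background_median,
                    xout = r[sel], rule = 2)$y
  rad_ref <- pmax(rad_ref, 1e-12)
  A <- tapply(v_sub / rad_ref, bin, mean)
  n_bins <- as.integer(360 / bin_deg)
  prof <- rep(NA_real_, n_bins)
  prof[as.numeric(names(A)) + 1L] <- as.numeric(A)
  if (anyNA(prof)) {
    filled <- which(!is.na(prof))
    prof[is.na(prof)] <- mean(prof, na.rm = TRUE)
  }
  med <- median(prof)
  # spread from sub-median bins so broad outlets do not inflate their own
  # detection threshold
  mad_low <- mad(prof[prof <= med], constant = 1)
  thr <- med + max(2 * MAD_TO_SD * mad_low, min_contrast * abs(med))
  nb <- length(prof)
  is_pk <- vapply(seq_len(nb), function(i) {
    lft <- prof[(i - 2) %% nb + 1L]
    rgt <- prof[i %% nb + 1L]
    prof[i] > thr && prof[i] >= lft && prof[i] >= rgt
  }, logical(1))
  pk <- which(is_pk)
  if (!length(pk)) return(0L)
  ang <- (pk - 0.5) * bin_deg
  ord <- order(prof[pk], decreasing = TRUE)
  kept <- numeric()
  for (i in ord) {
    a <- ang[i]
    if (!length(kept) ||
        all(pmin(abs(a - kept), 360 - abs(a - kept)) >= 45)) {
      kept <- c(kept, a)
    }
  }
  length(kept)
}

#' Radial band integrals of a diffusion profile
#'
#' Background-subtracted map values (clipped at zero) are summed per
#' radial band; fractions are relative to the total over
#' `[0, max(edges)]`. With the default edges this quantifies synaptic
#' (0-0.5 um), perisynaptic (0.5-3 um) and proximate extrasynaptic
#' (3-8 um) accumulation. Fractions sum to 1 by construction.
#'
#' @param map A `vq_maxmap`.
#' @param center `(x, y)` in um.
#' @param edges Increasing band edges in um (at least 3 values).
#' @return A tibble: `band`, `r_lo_um`, `r_hi_um`, `fraction`.
#' @export
band_integrals <- function(map, center, edges = c(0, 0.5, 3, 8)) {
  stopifnot(inherits(map, "vq_maxmap"))
  if (length(edges) < 3L || any(diff(edges) <= 0)) {
    abort("`edges` must be increasing with at least 2 bands")
  }
  r <- radius_map(nrow(map$values), ncol(map$values), center,
                  map$pixel_size)
  v <- pmax(map$values - map$background_median, 0)
  total <- sum(v[r < max(edges)])
  if (total <= 0) abort("map is all background: zero total integral")
  n_band <- length(edges) - 1L
  fr <- numeric(n_band)
  for (b in seq_len(n_band)) {
    fr[b] <- sum(v[r >= edges[b] & r < edges[b + 1L]]) / total
  }
  tibble::tibble(
    band = paste0(edges[-length(edges)], "-", edges[-1], " um"),
    r_lo_um = edges[-length(edges)],
    r_hi_um = edges[-1],
    fraction = fr
  )
}
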