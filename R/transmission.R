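#' Distal point detector (voltammetric-electrode analogue)
#'
#' Emulates an extracellular electrochemical probe placed tens of microns
#' from the imaged neuron: the local transmitter concentration is low-pass
#' filtered with time constant `tau_filter` and compared against a limit
#' of detection. Defaults: 25 um from the site centroid, 0.3 s filter,
#' 0.6 nM limit of detection. The default limit is set so that the
#' detector separates synchronous multi-axon high-frequency release from
#' single-axon or low-frequency release under the volume preset; it is
#' far below a real electrode's sensitivity because first-order
#' (non-saturable) perisynaptic clearance lets only ~1% of released
#' transmitter escape the neuropil, so absolute far-field concentrations
#' are not comparable to printed voltammetric values.
#'
#' @param position `(x, y)` in um, or NULL to auto-place `distance_um`
#'   from the site centroid (along +x) when the trace is simulated.
#' @param tau_filter Filter time constant in s.
#' @param lod Limit of detection in nM.
#' @param distance_um Distance used for auto-placement.
#' @return A `distal_detector` object.
#' @export
distal_detector <- function(position = NULL, tau_filter = 0.3, lod = 0.6,
                            distance_um = 25) {
  assert_scalar_pos(tau_filter, "tau_filter")
  assert_scalar_pos(lod, "lod")
  structure(
    list(position = position, tau_filter = tau_filter, lod = lod,
         distance_um = distance_um),
    class = "distal_detector"
  )
}

#' Simulate the distal detector on a concentration movie
#'
#' Samples the concentration at the detector pixel, applies the
#' first-order low-pass filter, and flags detection when the filtered
#' peak reaches the limit of detection.
#'
#' @param conc A concentration `vq_movie` (nM).
#' @param detector A [distal_detector()].
#' @return A `distal_trace`: tibble (`time_s`, `concentration_nM`) with
#'   attributes `peak`, `detected`, `position`, `lod`.
#' @export
simulate_distal_detector <- function(conc, detector = distal_detector()) {
  stopifnot(inherits(conc, "vq_movie"), inherits(detector, "distal_detector"))
  pos <- detector$position
  if (is.null(pos)) {
    if (is.null(conc$truth)) {
      abort("detector has no position and the movie carries no site truth")
    }
    ctr <- c(mean(conc$truth$sites$x_um), mean(conc$truth$sites$y_um))
    # place along the first cardinal direction that stays inside the domain
    lim <- (dim(conc$frames)[1:2] - 1) * conc$pixel_size
    for (dir in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      cand <- ctr + detector$distance_um * dir
      if (all(cand >= 0) && cand[1] <= lim[2] && cand[2] <= lim[1]) {
        pos <- cand
        break
      }
    }
    if (is.null(pos)) abort("detector placement falls outside the domain")
  }
  rc <- px_of_um(pos, conc$pixel_size, dim(conc$frames)[1:2])
  raw <- conc$frames[rc[1], rc[2], ]
  dt <- 1 / conc$fps
  alpha <- exp(-dt / detector$tau_filter)
  filt <- numeric(length(raw))
  state <- 0
  for (k in seq_along(raw)) {
    state <- raw[k] + (state - raw[k]) * alpha
    filt[k] <- state
  }
  out <- tibble::tibble(time_s = frame_times(conc), concentration_nM = filt)
  attr(out, "peak") <- max(filt)
  attr(out, "detected") <- max(filt) >= detector$lod
  attr(out, "position") <- pos
  attr(out, "lod") <- detector$lod
  class(out) <- c("distal_trace", class(out))
  out
}

#' Classify an episode as synaptic or volume transmission
#'
#' Volume transmission means transmitter escaped far enough from the
#' releasing synapses to be detected at the distal probe; otherwise the
#' episode is synaptic.
#'
#' @param distal A `distal_trace` from [simulate_distal_detector()].
#' @return `"volume"` or `"synaptic"`.
#' @export
classify_transmission <- function(distal) {
  stopifnot(inherits(distal, "distal_trace"))
  if (isTRUE(attr(distal, "detected"))) "volume" else "synaptic"
}

#' Ordinary least squares of responses on log2(frequency)
#'
#' Encoding fit `y = a + b log2(x)` with the F statistic
#' `(r^2 / (1 - r^2)) (n - 2)` on `(1, n - 2)` degrees of freedom. A
#' constant response is reported with slope 0 and `r_squared = 0` (with a
#' warning) so encoding sweeps always return a total fit.
#'
#' @param x Stimulus frequencies in Hz (> 0).
#' @param y Responses (e.g. percent dF/F0).
#' @return An `encode_fit`: `intercept`, `slope`, `r_squared`,
#'   `f_statistic`, `p_value`, `n`.
#' @export
fit_log2_linear <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("need n >= 3 paired observations")
  }
  if (any(x <= 0)) abort("frequencies must be positive")
  if (max(x) == min(x)) abort("constant x: regression undefined")
  if (var(y) == 0) {
    warn("zero-variance response: slope 0, r_squared reported as 0")
    return(structure(
      list(intercept = y[1], slope = 0, r_squared = 0,
           f_statistic = 0, p_value = 1, n = length(x)),
      class = "encode_fit"
    ))
  }
  lx <- log2(x)
  fit <- lm(y ~ lx)
  rsq <- summary(fit)$r.squared
  n <- length(x)
  Fst <- (rsq / (1 - rsq)) * (n - 2)
  structure(
    list(
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      r_squared = rsq,
      f_statistic = Fst,
      p_value = pf(Fst, 1, n - 2, lower.tail = FALSE),
      n = n
    ),
    class = "encode_fit"
  )
}

#' @export
print.encode_fit <- function(x, ...) {
  cat(sprintf(
    "<encode_fit> y = %.4g + %.4g log2(x); r2 = %.3f, F = %.3g, p = %.3g (n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$f_statistic, x$p_value, x$n
  ))
  invisible(x)
}

#' Through-origin linear fit
#'
#' `slope = sum(x y) / sum(x^2)`; `r_squared` is computed against the
#' through-origin model (`1 - RSS / sum(y^2)`).
#'
#' @param x,y Paired observations (n >= 1; x not all zero).
#' @return A list: `slope`, `r_squared`, `n`.
#' @export
fit_linear_origin <- function(x, y) {
  if (length(x) != length(y) || !length(x)) abort("need paired observations")
  if (all(x == 0)) abort("all-zero x: slope undefined")
  b <- sum(x * y) / sum(x^2)
  ss <- sum(y^2)
  rsq <- if (ss > 0) 1 - sum((y - b * x)^2) / ss else 1
  list(slope = b, r_squared = rsq, n = length(x))
}

#' Encoding sweep over stimulation protocols
#'
#' Runs the movie-level pipeline once per protocol (seeded) and tabulates
#' how responses encode pulse frequency, count and axon synchrony:
#' whole-cell and single-site maximal dF/F0, detected site count, the
#' fraction of sites with an expanded diffusion profile (fitted lambda
#' above `expanded_lambda_factor` times the control reference), and the
#' volume-transmission flag from the distal detector.
#'
#' Sites are placed per axon (`sites_per_axon` each, uniform in a disc of
#' `scatter_radius` around the domain centre, stream `"sites"`).
#'
#' @param grid Data frame with columns `n_pulses`, `frequency`, `n_axons`.
#' @param preset_name `"control"` or `"ssri"`.
#' @param geometry Simulation geometry (see [preset()]).
#' @param seed Integer root seed; row `i` uses `seed + i - 1`.
#' @param sites_per_axon Released sites recruited per activated axon.
#' @param scatter_radius Site scatter radius in um.
#' @param detector A [distal_detector()] (NULL skips classification).
#' @param expanded_lambda_factor Threshold multiplier on the control
#'   reference spread length.
#' @param snr_threshold,min_separation Passed to [detect_release_sites()].
#' @param ... Overrides forwarded to [preset()].
#' @return A tibble with one row per protocol: the grid columns plus
#'   `whole_cell_max`, `site_max`, `n_sites`, `expanded_fraction`,
#'   `volume`.
#' @export
encode_sweep <- function(grid, preset_name = "control",
                         geometry = "volume", seed = 1L,
                         sites_per_axon = 3.68, scatter_radius = 12,
                         detector = distal_detector(),
                         expanded_lambda_factor = 1.1,
                         snr_threshold = 4, min_separation = 1.5, ...) {
  stopifnot(all(c("n_pulses", "frequency", "n_axons") %in% names(grid)))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    run_seed <- seed + i - 1L
    ps <- preset(preset_name, geometry = geometry, seed = run_seed, ...)
    cfg <- ps$config
    protocol <- make_protocol(g$n_pulses, g$frequency,
                              t_start = max(0.2, 3 / cfg$output_fps),
                              n_axons = g$n_axons)
    n_sites_true <- max(1L, round(sites_per_axon * g$n_axons))
    ctr <- cfg$domain_size / 2
    pos <- with_stream(run_seed, "sites", {
      rad <- scatter_radius * sqrt(runif(n_sites_true))
      ang <- runif(n_sites_true, 0, 2 * pi)
      cbind(ctr + rad * cos(ang), ctr + rad * sin(ang))
    })
    sites <- purrr::map(seq_len(n_sites_true), function(j) {
      release_site(pos[j, 1], pos[j, 2], quanta = ps$quanta,
                   q_true = ps$q_true, axon_id = (j - 1L) %% g$n_axons + 1L)
    })
    dur <- max(protocol$pulse_times) + 2
    cfg <- sim_config(
      domain_size = cfg$domain_size, dx = cfg$dx, duration = dur,
      D_eff = cfg$D_eff, r_syn = cfg$r_syn, r_peri = cfg$r_peri,
      k_syn = cfg$k_syn, k_peri = cfg$k_peri, k_extra = cfg$k_extra,
      ssri_factor = cfg$ssri_factor, outlets = cfg$outlets,
      boundary = cfg$boundary, amount_per_vesicle = cfg$amount_per_vesicle,
      source_sigma = cfg$source_sigma, output_fps = cfg$output_fps,
      seed = run_seed
    )
    conc <- simulate_concentration(cfg, sites, protocol)
    dffm <- apply_sensor(conc, ps$sensor)
    dff <- new_dff_movie(dffm$frames,
                         matrix(1, dim(dffm$frames)[1], dim(dffm$frames)[2]),
                         dffm$pixel_size, dffm$fps, dffm$t0,
                         dffm$stimulus_times)
    dff$truth <- dffm$truth
    map <- compute_pixel_max_map(dff)
    det <- detect_release_sites(map, min_separation = max(min_separation, 2 * cfg$dx),
                                snr_threshold = snr_threshold)
    cell_r <- radius_map(nrow(map$values), ncol(map$values),
                         c(ctr, ctr), map$pixel_size) <= scatter_radius + 2
    cell_trace <- vapply(seq_len(dim(dff$frames)[3]),
                         function(k) mean(dff$frames[, , k][cell_r]),
                         numeric(1))
    lam <- if (nrow(det)) {
      vapply(seq_len(nrow(det)), function(j) {
        tryCatch({
          prof <- radial_profile(map, c(det$x_um[j], det$y_um[j]),
                                 dr = map$pixel_size,
                                 r_max = min(8, scatter_radius))
          fit_length_constant(prof, fit_range = c(0, attr(prof, "r_max")))$lambda
        }, error = function(e) NA_real_)
      }, numeric(1))
    } else {
      numeric()
    }
    vol <- if (is.null(detector)) {
      NA
    } else {
      classify_transmission(simulate_distal_detector(conc, detector)) == "volume"
    }
    tibble::tibble(
      n_pulses = g$n_pulses, frequency = g$frequency, n_axons = g$n_axons,
      whole_cell_max = max(cell_trace),
      site_max = if (nrow(det)) max(det$peak_pct) else 0,
      n_sites = nrow(det),
      expanded_fraction = if (length(lam)) {
        mean(lam > expanded_lambda_factor * CONTROL_LAMBDA_REF,
             na.rm = TRUE)
      } else 0,
      volume = vol
    )
  })
  dplyr::bind_rows(rows)
}
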