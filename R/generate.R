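#' Sample per-trial vesicular quanta counts
#'
#' I.i.d. categorical draws from a [quanta_dist()]; `0` is a release
#' failure. Reproducible for a fixed seed (drawn from the `"quanta"`
#' stream of the root seed).
#'
#' @param dist A [quanta_dist()].
#' @param n_trials Number of trials.
#' @param seed Integer root seed.
#' @return Integer vector of quanta counts.
#' @export
sample_trial_quanta <- function(dist, n_trials, seed = 1L) {
  stopifnot(inherits(dist, "quanta_dist"))
  if (n_trials < 1) abort("`n_trials` must be >= 1")
  with_stream(seed, "quanta", {
    sample(seq_along(dist$probs) - 1L, n_trials, replace = TRUE,
           prob = dist$probs)
  })
}

#' Generate per-trial quantal amplitudes for one release site
#'
#' Amplitude-level generative mode: each trial's dF/F0 amplitude is
#' `k_i * q_true + noise`, with `k_i` the sampled quanta count and
#' Gaussian measurement noise. This is the fast counterpart of rendering
#' and re-analysing a full movie, and is the mode quantal-analysis tests
#' default to.
#'
#' @param site A [release_site()] (its `quanta` and `q_true` are used).
#' @param protocol A [make_protocol()]; one trial per pulse.
#' @param noise_sd Gaussian amplitude noise SD in percent dF/F0.
#' @param seed Integer root seed (streams `"quanta"` and `"amp_noise"`).
#' @return A tibble with columns `trial`, `amplitude_pct`, `true_quanta`.
#' @export
generate_amplitude_series <- function(site, protocol, noise_sd = 0.045,
                                      seed = 1L) {
  stopifnot(inherits(site, "release_site_truth"),
            inherits(protocol, "stim_protocol"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  n <- protocol$n_pulses
  k <- sample_trial_quanta(site$quanta, n, seed = seed)
  eps <- if (noise_sd > 0) {
    with_stream(seed, "amp_noise", rnorm(n, 0, noise_sd))
  } else {
    numeric(n)
  }
  tibble::tibble(
    trial = seq_len(n),
    amplitude_pct = k * site$q_true + eps,
    true_quanta = as.integer(k)
  )
}

# Zone clearance map for a set of sites: each pixel takes the zone of its
# nearest site; outlet wedges multiply clearance by k_factor beyond r_syn.
clearance_map <- function(config, sites, xs, ys) {
  n_r <- length(ys)
  n_c <- length(xs)
  rmin <- matrix(Inf, n_r, n_c)
  theta_near <- matrix(0, n_r, n_c)
  for (s in sites) {
    dxm <- outer(rep(1, n_r), xs - s$x_um)
    dym <- outer(ys - s$y_um, rep(1, n_c))
    r <- sqrt(dxm^2 + dym^2)
    upd <- r < rmin
    rmin[upd] <- r[upd]
    theta_near[upd] <- (atan2(dym, dxm) * 180 / pi)[upd]
  }
  k <- matrix(config$k_extra, n_r, n_c)
  k[rmin <= config$r_peri] <- config$k_peri
  k[rmin <= config$r_syn] <- config$k_syn
  k <- k * config$ssri_factor
  for (ol in config$outlets) {
    dang <- abs(((theta_near - ol$angle + 180) %% 360) - 180)
    wedge <- dang <= ol$half_width & rmin > config$r_syn
    k[wedge] <- k[wedge] * ol$k_factor
  }
  k
}

#' Simulate the transmitter concentration field
#'
#' Explicit-Euler finite-difference solution of the reaction-diffusion
#' equation `dC/dt = D_eff lap(C) - k(x, y) C + S(x, y, t)` on the square
#' grid of `config`. Each stimulus pulse injects
#' `amount_per_vesicle * quanta` as a sub-pixel Gaussian source of width
#' `source_sigma` at every release site; zone-dependent clearance follows
#' [clearance_map()] around the nearest site. Output frames at
#' `config$output_fps` are sub-step averages, so time integrals of the
#' field are preserved.
#'
#' @param config A [sim_config()]. The time step is validated against the
#'   stability bound `dx^2 / (4 D_eff)` before integration.
#' @param sites List of [release_site()] objects (a single site may be
#'   passed bare).
#' @param protocol A [make_protocol()].
#' @param quanta Optional integer matrix (`length(sites)` x `n_pulses`) of
#'   vesicles released per site and pulse; sampled from each site's quanta
#'   distribution (stream `"quanta"`) when omitted.
#' @return A `vq_movie` in nM with a `truth` field holding the per-site,
#'   per-pulse quanta matrix, site positions and the analytic spread
#'   length `sqrt(D_eff / (k_peri * ssri_factor))`.
#' @export
simulate_concentration <- function(config, sites, protocol, quanta = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(protocol, "stim_protocol"))
  if (inherits(sites, "release_site_truth")) sites <- list(sites)
  if (!length(sites)) abort("need at least one release site")
  n <- round(config$domain_size / config$dx)
  xs <- (seq_len(n) - 1) * config$dx
  ys <- xs
  for (s in sites) {
    if (s$x_um < 0 || s$x_um > config$domain_size ||
        s$y_um < 0 || s$y_um > config$domain_size) {
      abort("release site outside the simulation domain")
    }
  }
  if (is.null(quanta)) {
    quanta <- matrix(0L, length(sites), protocol$n_pulses)
    for (i in seq_along(sites)) {
      quanta[i, ] <- with_stream(config$seed + i - 1L, "quanta", {
        sample(seq_along(sites[[i]]$quanta$probs) - 1L, protocol$n_pulses,
               replace = TRUE, prob = sites[[i]]$quanta$probs)
      })
    }
  }
  stopifnot(nrow(quanta) == length(sites), ncol(quanta) == protocol$n_pulses)

  k_map <- clearance_map(config, sites, xs, ys)
  # operator splitting: explicit Euler for diffusion, exact exponential
  # decay for clearance (unconditionally stable in k)
  decay <- exp(-k_map * config$dt)
  # Per-site normalised source kernels (sum * dx^2 = 1).
  src <- lapply(sites, function(s) {
    g <- exp(-radius_map(n, n, c(s$x_um, s$y_um), config$dx)^2 /
               (2 * config$source_sigma^2))
    g / (sum(g) * config$dx^2)
  })

  dt <- config$dt
  dx <- config$dx
  D <- config$D_eff
  reflect <- config$boundary == "reflecting"
  n_steps <- ceiling(config$duration / dt)
  pulse_step <- round((protocol$pulse_times) / dt) + 1L
  if (any(pulse_step > n_steps)) {
    abort("protocol pulses extend beyond the configured duration")
  }
  fps <- config$output_fps
  steps_per_frame <- max(1L, round(1 / (fps * dt)))
  n_frames <- ceiling(n_steps / steps_per_frame)

  C <- matrix(0, n, n)
  acc <- matrix(0, n, n)
  frames <- array(0, dim = c(n, n, n_frames))
  fi <- 1L
  in_frame <- 0L
  idx_up <- c(1L, seq_len(n - 1L))
  idx_dn <- c(seq_len(n)[-1L], n)
  for (s in seq_len(n_steps)) {
    hit <- which(pulse_step == s)
    if (length(hit)) {
      for (p in hit) {
        for (i in seq_along(sites)) {
          if (quanta[i, p] > 0) {
            C <- C + config$amount_per_vesicle * quanta[i, p] * src[[i]]
          }
        }
      }
    }
    up <- C[idx_up, ]; dn <- C[idx_dn, ]
    lf <- C[, idx_up]; rt <- C[, idx_dn]
    if (!reflect) {
      up[1L, ] <- 0; dn[n, ] <- 0; lf[, 1L] <- 0; rt[, n] <- 0
    }
    C <- (C + dt * D * (up + dn + lf + rt - 4 * C) / dx^2) * decay
    if (anyNA(C) || any(!is.finite(C))) {
      abort(sprintf(
        "non-finite concentration at step %d (t = %.4g s): integration aborted",
        s, s * dt
      ))
    }
    acc <- acc + C
    in_frame <- in_frame + 1L
    if (in_frame == steps_per_frame || s == n_steps) {
      frames[, , fi] <- acc / in_frame
      acc[] <- 0
      in_frame <- 0L
      fi <- fi + 1L
    }
  }

  m <- new_movie(frames, pixel_size = dx, fps = 1 / (steps_per_frame * dt),
                 t0 = 0, stimulus_times = protocol$pulse_times,
                 units = "nM")
  m$truth <- list(
    quanta = quanta,
    sites = tibble::tibble(
      site_id = seq_along(sites),
      x_um = vapply(sites, `[[`, 0, "x_um"),
      y_um = vapply(sites, `[[`, 0, "y_um"),
      axon_id = vapply(sites, `[[`, 0L, "axon_id")
    ),
    lambda_true = sqrt(D / (config$k_peri * config$ssri_factor)),
    config = config
  )
  class(m) <- c("vq_conc", class(m))
  m
}

#' Convert a concentration movie to sensor dF/F0
#'
#' Integrates the per-pixel bound-sensor fraction
#' `dB/dt = k_on C (1 - B) - k_off B` with an exact exponential update per
#' frame (frame-mean concentration), and returns `dF/F0 = f_max B` in
#' percent. For `hill != 1` the quasi-steady Hill mapping
#' `f_max C^h / (C^h + Kd^h)` is applied instead (kinetics of cooperative
#' binding are not modelled).
#'
#' @param conc A concentration `vq_movie` (nM, non-negative).
#' @param sensor A [sensor_model()].
#' @return A `vq_movie` of percent dF/F0 (sensor response; no camera yet).
#' @export
apply_sensor <- function(conc, sensor) {
  stopifnot(inherits(conc, "vq_movie"), inherits(sensor, "sensor_model"))
  if (min(conc$frames) < 0) abort("concentrations must be non-negative")
  d <- dim(conc$frames)
  out <- array(0, dim = d)
  if (sensor$hill != 1) {
    ch <- conc$frames^sensor$hill
    out <- sensor$f_max * ch / (ch + sensor$kd^sensor$hill)
  } else {
    dt <- 1 / conc$fps
    B <- matrix(0, d[1], d[2])
    for (k in seq_len(d[3])) {
      Ck <- conc$frames[, , k]
      a <- sensor$k_on * Ck + sensor$k_off
      Binf <- sensor$k_on * Ck / a
      B <- Binf + (B - Binf) * exp(-a * dt)
      out[, , k] <- sensor$f_max * B
    }
  }
  m <- new_movie(out, conc$pixel_size, conc$fps, conc$t0,
                 conc$stimulus_times, units = "% dF/F0")
  m$truth <- conc$truth
  class(m) <- c("vq_sensor", class(m))
  m
}

#' Render a dF/F0 movie through the camera model
#'
#' Applies `F = F0(x, y) * (1 + dFF / 100)`, Gaussian PSF blurring,
#' Poisson shot noise at `photon_gain` photons per fluorescence unit and
#' Gaussian read noise. The baseline field `F0` is lognormal with mean
#' `f0_mean` and CV `f0_cv` (stream `"f0"`); shot and read noise use
#' streams `"shot"` and `"read"`. `photon_gain = Inf` and
#' `read_noise_sd = 0` give a noise-free rendering.
#'
#' @param dff A dF/F0 `vq_movie` (percent).
#' @param camera A [camera_model()].
#' @param seed Integer root seed.
#' @return A fluorescence `vq_movie` with the generated `f0_map` attached.
#' @export
render_camera <- function(dff, camera, seed = 1L) {
  stopifnot(inherits(dff, "vq_movie"), inherits(camera, "camera_model"))
  d <- dim(dff$frames)
  f0 <- if (camera$f0_cv > 0) {
    sdlog <- sqrt(log(1 + camera$f0_cv^2))
    mulog <- log(camera$f0_mean) - sdlog^2 / 2
    with_stream(seed, "f0", matrix(rlnorm(d[1] * d[2], mulog, sdlog), d[1], d[2]))
  } else {
    matrix(camera$f0_mean, d[1], d[2])
  }
  sig_px <- camera$psf_sigma / camera$pixel_size
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    Fk <- f0 * (1 + dff$frames[, , k] / 100)
    if (sig_px > 0) Fk <- gaussian_blur2d(Fk, sig_px)
    out[, , k] <- Fk
  }
  if (is.finite(camera$photon_gain)) {
    out <- with_stream(seed, "shot", {
      array(rpois(length(out), out * camera$photon_gain) / camera$photon_gain,
            dim = d)
    })
  }
  if (camera$read_noise_sd > 0) {
    out <- out + with_stream(seed, "read", {
      array(rnorm(length(out), 0, camera$read_noise_sd), dim = d)
    })
  }
  m <- new_movie(out, dff$pixel_size, dff$fps, dff$t0, dff$stimulus_times,
                 units = "fluorescence")
  m$f0_map <- f0
  m$truth <- dff$truth
  m
}
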