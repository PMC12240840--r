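#' Configure the reaction-diffusion simulation
#'
#' The generator solves \deqn{\partial C/\partial t = \nabla\cdot(D\nabla C)
#' - k(x,y)\,C + S(x,y,t)} on a square 2-D domain by explicit Euler finite
#' differences. Clearance `k(x, y)` is zone-dependent around each release
#' site: `k_syn` within the synaptic radius `r_syn`, `k_peri` in the
#' perisynaptic annulus out to `r_peri`, `k_extra` beyond. `ssri_factor`
#' multiplies all clearance rates (reuptake inhibition weakens clearance);
#' outlet wedges further multiply clearance by `k_factor` within an angular
#' sector beyond `r_syn`, modelling egress channels.
#'
#' The quasi-steady spread length around an isolated site is
#' `sqrt(D_eff / (k_peri * ssri_factor))`.
#'
#' @param domain_size Side of the square domain in um.
#' @param dx Grid spacing in um.
#' @param dt Time step in s; defaults to 80% of the explicit-scheme
#'   stability bound `dx^2 / (4 D_eff)`.
#' @param duration Simulated time in s.
#' @param D_eff Effective diffusion coefficient in um^2/s.
#' @param r_syn,r_peri Synaptic and outer perisynaptic radii in um.
#' @param k_syn,k_peri,k_extra First-order clearance rates (1/s).
#' @param ssri_factor Multiplier (0, 1] on all clearance rates.
#' @param outlets List of outlet wedges, each
#'   `list(angle = degrees, half_width = degrees, k_factor <= 1)`.
#' @param boundary `"reflecting"` or `"absorbing"`.
#' @param amount_per_vesicle Transmitter injected per vesicle, nM um^2.
#' @param source_sigma Sub-pixel Gaussian width of the release source, um;
#'   defaults to `r_syn / 2`.
#' @param output_fps Frame rate of the returned concentration movie; each
#'   frame is the mean field over its sub-steps.
#' @param seed Integer root seed for the named random streams.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(domain_size = 16, dx = 0.1, dt = NULL, duration = 2,
                       D_eff = 5, r_syn = 0.25, r_peri = 3,
                       k_syn = 0, k_peri = 8.889, k_extra = k_peri / 4,
                       ssri_factor = 1, outlets = list(),
                       boundary = c("reflecting", "absorbing"),
                       amount_per_vesicle = 1,
                       source_sigma = r_syn / 2,
                       output_fps = 25, seed = 1L) {
  boundary <- match.arg(boundary)
  for (nm in c("domain_size", "dx", "duration", "D_eff", "r_syn", "r_peri",
               "amount_per_vesicle", "source_sigma", "output_fps")) {
    assert_scalar_pos(get(nm), nm)
  }
  if (!(r_syn < r_peri)) abort("need 0 < r_syn < r_peri")
  if (any(c(k_syn, k_peri, k_extra) < 0)) abort("clearance rates must be >= 0")
  if (ssri_factor <= 0 || ssri_factor > 1) abort("need 0 < ssri_factor <= 1")
  dt_max <- dx^2 / (4 * D_eff)
  if (is.null(dt)) dt <- 0.8 * dt_max
  if (dt > dt_max + 1e-12) {
    abort(sprintf(
      "dt = %g violates the explicit-scheme stability bound dx^2/(4 D) = %g",
      dt, dt_max
    ))
  }
  for (ol in outlets) {
    if (!all(c("angle", "half_width", "k_factor") %in% names(ol))) {
      abort("each outlet needs fields angle, half_width, k_factor")
    }
    if (ol$k_factor > 1 || ol$k_factor < 0) abort("outlet k_factor must be in [0, 1]")
  }
  structure(
    list(
      domain_size = domain_size, dx = dx, dt = dt, duration = duration,
      D_eff = D_eff, r_syn = r_syn, r_peri = r_peri,
      k_syn = k_syn, k_peri = k_peri, k_extra = k_extra,
      ssri_factor = ssri_factor, outlets = outlets, boundary = boundary,
      amount_per_vesicle = amount_per_vesicle, source_sigma = source_sigma,
      output_fps = output_fps, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> %g x %g um, dx %g um, dt %.2g s, %g s\n",
      "  D_eff %g um^2/s; k(syn, peri, extra) = (%g, %g, %g) 1/s; ssri %g\n",
      "  lambda = sqrt(D/(k_peri*ssri)) = %.3f um; %d outlet(s); %s boundary\n"
    ),
    x$domain_size, x$domain_size, x$dx, x$dt, x$duration,
    x$D_eff, x$k_syn, x$k_peri, x$k_extra, x$ssri_factor,
    sqrt(x$D_eff / (x$k_peri * x$ssri_factor)),
    length(x$outlets), x$boundary
  ))
  invisible(x)
}

#' First-order fluorescent-sensor model
#'
#' Per pixel the bound-sensor fraction `B` obeys
#' `dB/dt = k_on C (1 - B) - k_off B` and the reported signal is
#' `dF/F0 = f_max * B` (percent). At steady state this is the Hill sigmoid
#' `f_max C^h / (C^h + Kd^h)` with `Kd = k_off / k_on`. For `hill != 1` the
#' quasi-steady mapping is used.
#'
#' @param k_on Binding rate, 1/(nM s).
#' @param k_off Unbinding rate, 1/s.
#' @param f_max Percent dF/F0 at saturation.
#' @param hill Hill coefficient.
#' @return A `sensor_model` object.
#' @export
sensor_model <- function(k_on = 0.125 / 1010, k_off = 0.125, f_max = 5,
                         hill = 1) {
  for (nm in c("k_on", "k_off", "f_max", "hill")) assert_scalar_pos(get(nm), nm)
  structure(
    list(k_on = k_on, k_off = k_off, f_max = f_max, hill = hill,
         kd = k_off / k_on),
    class = "sensor_model"
  )
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf(
    "<sensor_model> k_on %.3g /(nM s), k_off %.3g /s (Kd %.0f nM), f_max %g%%, hill %g\n",
    x$k_on, x$k_off, x$kd, x$f_max, x$hill
  ))
  invisible(x)
}

#' Camera and baseline-fluorescence model
#'
#' Renders a dF/F0 movie to fluorescence counts:
#' `F = F0(x, y) * (1 + dFF/100)` blurred by a Gaussian point-spread
#' function, Poisson shot noise applied at `photon_gain` photons per
#' fluorescence unit, plus Gaussian read noise. The baseline field `F0` is
#' lognormal with mean `f0_mean` and coefficient of variation `f0_cv`
#' (responses are heterogeneous in F0 but dF/F0 is not).
#'
#' @param pixel_size um per pixel.
#' @param fps Frames per second (typically 10-50).
#' @param psf_sigma Gaussian PSF sigma in um (0 disables blurring).
#' @param photon_gain Photons per fluorescence unit (Inf disables shot
#'   noise).
#' @param f0_mean,f0_cv Mean and CV of the baseline fluorescence field.
#' @param read_noise_sd Gaussian read noise SD in fluorescence units.
#' @return A `camera_model` object.
#' @export
camera_model <- function(pixel_size = 0.1, fps = 25, psf_sigma = 0.1,
                         photon_gain = 200, f0_mean = 100, f0_cv = 0.3,
                         read_noise_sd = 0.5) {
  assert_scalar_pos(pixel_size, "pixel_size")
  assert_scalar_pos(fps, "fps")
  assert_scalar_pos(f0_mean, "f0_mean")
  if (photon_gain <= 0) abort("`photon_gain` must be positive (may be Inf)")
  if (psf_sigma < 0 || f0_cv < 0 || read_noise_sd < 0) {
    abort("psf_sigma, f0_cv and read_noise_sd must be >= 0")
  }
  structure(
    list(pixel_size = pixel_size, fps = fps, psf_sigma = psf_sigma,
         photon_gain = photon_gain, f0_mean = f0_mean, f0_cv = f0_cv,
         read_noise_sd = read_noise_sd),
    class = "camera_model"
  )
}

#' Ground-truth description of one release site
#'
#' @param x_um,y_um Position in um.
#' @param quanta QuantaDistribution of vesicles per pulse.
#' @param q_true Percent dF/F0 per vesicle (amplitude-level mode).
#' @param axon_id Integer axon label.
#' @return A `release_site_truth` object.
#' @export
release_site <- function(x_um, y_um, quanta = quanta_dist(c(0.2, 0.6, 0.15, 0.04, 0.01)),
                         q_true = 0.45, axon_id = 1L) {
  assert_scalar_pos(q_true, "q_true")
  stopifnot(inherits(quanta, "quanta_dist"))
  structure(
    list(x_um = x_um, y_um = y_um, quanta = quanta, q_true = q_true,
         axon_id = as.integer(axon_id)),
    class = "release_site_truth"
  )
}
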