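# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# Noise-free dF/F0 movie wrapper around a sensor movie.
as_dff <- function(sensed) {
  d <- dim(sensed$frames)
  m <- new_dff_movie(sensed$frames, matrix(1, d[1], d[2]), sensed$pixel_size,
                     sensed$fps, sensed$t0, sensed$stimulus_times)
  m$truth <- sensed$truth
  m
}

# Control-preset profile-geometry pixel-max map (16 x 16 um, dx 0.1 um,
# 10 pulses at 16 Hz). ~6 s; used by the spatial acceptance checks.
profile_map <- function(preset_name = "control", seed = 7, ...) {
  ps <- preset(preset_name, seed = seed, ...)
  cfg <- ps$config
  cfg$duration <- 10 / 16 + 1.5
  site <- release_site(8, 8, quanta = ps$quanta, q_true = ps$q_true)
  prot <- make_protocol(10, 16, t_start = 0.2)
  conc <- simulate_concentration(cfg, site, prot)
  map <- compute_pixel_max_map(as_dff(apply_sensor(conc, ps$sensor)))
  map
}

# Coarser, faster single-site map (8.2 x 8.2 um so the 41-px grid has a
# central pixel, dx 0.2 um) for property tests that only need
# qualitative structure.
mini_map <- function(ssri_factor = 1, outlets = list(), seed = 3,
                     n_pulses = 6) {
  ps <- preset("control", seed = seed)
  cfg <- sim_config(domain_size = 8.2, dx = 0.2, duration = n_pulses / 16 + 1.2,
                    D_eff = 5, k_peri = 8.889, k_syn = 0, k_extra = 8.889 / 4,
                    r_syn = 0.25, r_peri = 3, ssri_factor = ssri_factor,
                    outlets = outlets, boundary = "reflecting",
                    amount_per_vesicle = cfg_amount(), output_fps = 25,
                    seed = seed)
  site <- release_site(4, 4, quanta = ps$quanta)
  prot <- make_protocol(n_pulses, 16, t_start = 0.2)
  conc <- simulate_concentration(cfg, site, prot)
  compute_pixel_max_map(as_dff(apply_sensor(conc, preset("control")$sensor)))
}

cfg_amount <- function() preset("control")$config$amount_per_vesicle

# Analytic exponential-cone pixel-max map: v(r) = p0 exp(-r / lambda).
exp_cone_map <- function(lambda = 0.75, p0 = 2, H = 161, ps = 0.1,
                         center = NULL) {
  center <- center %||% c((H - 1) / 2 * ps, (H - 1) / 2 * ps)
  r <- vesiq:::radius_map(H, H, center, ps)
  vesiq:::new_maxmap(p0 * exp(-r / lambda), ps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free camera scene: n sites (pairwise separation >= min_sep),
# rendered through lognormal F0 + PSF with shot noise off. Returns the
# max map plus the ground-truth positions.
scene_map <- function(seed, n_sites = 3, peak = 3, H = 80, ps = 0.2,
                      min_sep = 2, shot_noise = FALSE, gain = 200) {
  set.seed(seed)
  repeat {
    xy <- matrix(runif(n_sites * 2, 2, (H - 1) * ps - 2), ncol = 2)
    if (n_sites == 1 || min(dist(xy)) >= min_sep) break
  }
  x <- (seq_len(H) - 1) * ps
  bump <- matrix(0, H, H)
  for (i in seq_len(n_sites)) {
    bump <- bump + peak * exp(-outer((x - xy[i, 2])^2, (x - xy[i, 1])^2, "+") /
                                (2 * 0.3^2))
  }
  tc <- c(rep(0, 5), 1 - exp(-(1:15) / 3))
  fr <- array(0, c(H, H, length(tc)))
  for (k in seq_along(tc)) fr[, , k] <- bump * tc[k]
  dff <- new_movie(fr, ps, 10, 0, stimulus_times = 0.5, units = "% dF/F0")
  cam <- camera_model(pixel_size = ps, fps = 10, psf_sigma = 0.15,
                      photon_gain = if (shot_noise) gain else Inf,
                      f0_mean = 150, f0_cv = 0.3, read_noise_sd = 0)
  mov <- render_camera(dff, cam, seed = seed)
  map <- compute_pixel_max_map(compute_dff(mov, baseline_window = c(0, 0.5)))
  list(map = map, xy = xy)
}

# Match detections to truth within tol um; returns recall and precision.
match_sites <- function(det, xy, tol = 0.5) {
  if (!nrow(det)) return(c(recall = 0, precision = 1))
  n <- nrow(xy)
  dd <- as.matrix(dist(rbind(xy, cbind(det$x_um, det$y_um))))
  dmat <- dd[seq_len(n), n + seq_len(nrow(det)), drop = FALSE]
  tp <- sum(apply(dmat, 1, min) <= tol)
  c(recall = tp / n, precision = tp / nrow(det))
}
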