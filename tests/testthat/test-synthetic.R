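test_that("trial quanta sampling matches the categorical distribution", {
  all_fail <- quanta_dist(c(1, 0, 0, 0, 0))
  expect_true(all(sample_trial_quanta(all_fail, 50, seed = 1) == 0))

  all_one <- quanta_dist(c(0, 1, 0, 0, 0))
  k <- sample_trial_quanta(all_one, 50, seed = 1)
  expect_true(all(k == 1))

  ctl <- quanta_dist(c(0.20, 0.60, 0.15, 0.04, 0.01))
  k <- sample_trial_quanta(ctl, 1e5, seed = 42)
  # law of large numbers on the stated categorical: Pr = 0.800 +/- 0.005
  expect_lt(abs(mean(k > 0) - 0.800), 0.005)
  # mean quanta within 3 SE of the analytic 1.06 (over all trials)
  mu <- sum((0:4) * ctl$probs)
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - mu), 3 * se)
  # reproducibility
  expect_identical(k, sample_trial_quanta(ctl, 1e5, seed = 42))
})

test_that("amplitude series are a noisy quantal lattice with recorded truth", {
  site <- release_site(8, 8, quanta = quanta_dist(c(0, 1, 0, 0, 0)),
                       q_true = 0.45)
  a <- generate_amplitude_series(site, make_protocol(5, 0.1), noise_sd = 0,
                                 seed = 1)
  expect_equal(a$amplitude_pct, a$true_quanta * 0.45)

  # linearity: scaling q scales amplitudes exactly (noise free)
  site2 <- release_site(8, 8, quanta = quanta_dist(c(0, 1, 0, 0, 0)),
                        q_true = 0.9)
  a2 <- generate_amplitude_series(site2, make_protocol(5, 0.1), noise_sd = 0,
                                  seed = 1)
  expect_equal(a2$amplitude_pct, 2 * a$amplitude_pct)

  # control preset, 40 trials: mean over successes / q_true in [1.1, 1.6]
  ctl <- release_site(8, 8, q_true = 0.45)
  a3 <- generate_amplitude_series(ctl, make_protocol(40, 0.1),
                                  noise_sd = 0.045, seed = 7)
  succ <- a3$amplitude_pct[a3$true_quanta > 0]
  expect_gt(mean(succ) / 0.45, 1.1)
  expect_lt(mean(succ) / 0.45, 1.6)
})

test_that("concentration simulation conserves mass and is reproducible", {
  cfg <- sim_config(domain_size = 6, dx = 0.2, duration = 0.8,
                    k_syn = 0, k_peri = 0, k_extra = 0,
                    boundary = "reflecting", amount_per_vesicle = 100,
                    output_fps = 20, seed = 1)
  site <- release_site(3, 3)
  prot <- make_protocol(2, 10, t_start = 0.1)
  conc <- simulate_concentration(cfg, site, prot,
                                 quanta = matrix(c(1L, 2L), 1))
  tot <- apply(conc$frames, 3, sum) * cfg$dx^2
  after <- tot[frame_times(conc) > 0.25]
  expect_lt(max(abs(after - 300)) / 300, 0.001)  # 3 vesicles x 100
  # no pulses -> identically zero
  z <- simulate_concentration(cfg, site, prot, quanta = matrix(0L, 1, 2))
  expect_true(all(z$frames == 0))
  # determinism: same config and seed give bit-identical frames
  conc2 <- simulate_concentration(cfg, site, prot,
                                  quanta = matrix(c(1L, 2L), 1))
  expect_identical(conc$frames, conc2$frames)
})

test_that("unstable time steps are rejected before integration", {
  expect_error(
    sim_config(domain_size = 4, dx = 0.1, dt = 0.01, D_eff = 5),
    "stability"
  )
})

test_that("sites outside the domain are rejected", {
  cfg <- sim_config(domain_size = 4, dx = 0.2, duration = 0.2)
  expect_error(
    simulate_concentration(cfg, release_site(10, 2), make_protocol(1, 10)),
    "outside"
  )
})

test_that("sensor kinetics follow the first-order binding model", {
  sen <- sensor_model(k_on = 0.125 / 1010, k_off = 0.125, f_max = 5)
  H <- 2
  mkconc <- function(C, T, fps) {
    new_movie(array(C, c(H, H, T)), 0.5, fps, 0, numeric(), units = "nM")
  }
  # zero concentration -> zero response
  expect_true(all(apply_sensor(mkconc(0, 10, 10), sen)$frames == 0))

  # constant C = Kd held to steady state -> f_max / 2
  dff <- apply_sensor(mkconc(1010, 400, 5), sen)
  expect_lt(abs(dff$frames[1, 1, 400] - 2.5), 0.01)

  # step response: 10-90% rise time = ln(9) / (k_on C + k_off)
  C0 <- 4 * 1010
  a <- sen$k_on * C0 + sen$k_off
  dff <- apply_sensor(mkconc(C0, 400, 20), sen)
  tr <- dff$frames[1, 1, ]
  tt <- (seq_along(tr) - 1) / 20
  amp <- sen$f_max * sen$k_on * C0 / a
  t10 <- approx(tr, tt, xout = 0.1 * amp)$y
  t90 <- approx(tr, tt, xout = 0.9 * amp)$y
  expect_lt(abs((t90 - t10) - log(9) / a) / (log(9) / a), 0.02)

  expect_error(apply_sensor(mkconc(-1, 3, 10), sen), "non-negative")
})

test_that("fast sensors track the quasi-steady sigmoid on slow ramps", {
  kd <- 1010
  fast <- sensor_model(k_on = 50 / kd, k_off = 50, f_max = 5)
  Tn <- 200
  ramp <- seq(0, 2000, length.out = Tn)
  fr <- array(rep(ramp, each = 4), c(2, 2, Tn))
  conc <- new_movie(fr, 0.5, Tn / 20, 0, numeric(), units = "nM")
  dff <- apply_sensor(conc, fast)
  qs <- 5 * ramp / (ramp + kd)
  expect_lt(max(abs(dff$frames[1, 1, ] - qs)) / 5, 0.01)

  # hill != 1 uses the quasi-steady Hill mapping exactly
  h2 <- sensor_model(k_on = 0.1, k_off = 101, f_max = 4, hill = 2)
  d2 <- apply_sensor(conc, h2)
  expect_equal(d2$frames[1, 1, ],
               4 * ramp^2 / (ramp^2 + (101 / 0.1)^2), tolerance = 1e-12)
})

test_that("camera rendering round-trips and respects Poisson statistics", {
  H <- 8; T <- 12
  resp <- c(rep(0, 5), seq(0.3, 2, length.out = T - 5))
  fr <- array(rep(resp, each = H * H), c(H, H, T))
  dff <- new_movie(fr, 0.2, 10, 0, stimulus_times = 0.45, units = "% dF/F0")
  cam0 <- camera_model(pixel_size = 0.2, fps = 10, psf_sigma = 0,
                       photon_gain = Inf, f0_mean = 120, f0_cv = 0,
                       read_noise_sd = 0)
  mov <- render_camera(dff, cam0, seed = 1)
  rec <- compute_dff(mov, baseline_window = c(0, 0.45))
  expect_lt(max(abs(rec$frames[, , T] - fr[, , T])), 1e-9)

  # Poisson stage: mean of a constant pixel over many frames within 1%
  Tn <- 10000
  flat <- new_movie(array(0, c(2, 2, Tn)), 0.2, 10, 0, numeric())
  cam <- camera_model(pixel_size = 0.2, fps = 10, psf_sigma = 0,
                      photon_gain = 50, f0_mean = 80, f0_cv = 0,
                      read_noise_sd = 0)
  mv <- render_camera(flat, cam, seed = 9)
  expect_lt(abs(mean(mv$frames[1, 1, ]) - 80) / 80, 0.01)
})

test_that("heterogeneous baselines leave recovered dF/F0 unbiased", {
  H <- 40; T <- 14
  truth <- 2
  fr <- array(0, c(H, H, T))
  for (k in 7:T) fr[, , k] <- truth
  dff <- new_movie(fr, 0.2, 10, 0, stimulus_times = 0.55, units = "% dF/F0")
  cam <- camera_model(pixel_size = 0.2, fps = 10, psf_sigma = 0,
                      photon_gain = 150, f0_mean = 100, f0_cv = 0.3,
                      read_noise_sd = 0)
  mov <- render_camera(dff, cam, seed = 4)
  rec <- compute_dff(mov, baseline_window = c(0, 0.55))
  expect_lt(abs(mean(rec$frames[, , T]) - truth) / truth, 0.02)
})
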