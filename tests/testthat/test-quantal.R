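test_that("trace extraction averages the requested ROI", {
  H <- 20; T <- 8
  fr <- array(rep(seq_len(T), each = H * H), c(H, H, T))
  dff <- new_dff_movie(fr, matrix(1, H, H), 0.2, 10, 0, stimulus_times = 0.5)
  tr <- extract_trace(dff, c(2, 2), roi_radius = 0.5)
  expect_equal(tr$dff_pct, as.numeric(seq_len(T)))

  # ROI smaller than a pixel degenerates to the nearest pixel
  fr[3, 4, ] <- 99
  dff2 <- new_dff_movie(fr, matrix(1, H, H), 0.2, 10, 0,
                        stimulus_times = 0.5)
  tr2 <- extract_trace(dff2, c(0.6, 0.4), roi_radius = 0.05)
  expect_true(all(tr2$dff_pct == 99))

  expect_error(extract_trace(dff, c(30, 30)), "outside")
})

test_that("the double-exponential synaptic fit recovers its parameters", {
  tt <- seq(0, 30, by = 0.02)
  vv <- vesiq:::synaptic_curve(tt, 1, 0.1, 8, 0.5)
  f <- fit_synaptic(tt, vv, t0 = 0.5)
  expect_lt(abs(f$tau_on - 0.1) / 0.1, 0.01)
  expect_lt(abs(f$tau_off - 8) / 8, 0.01)
  peak <- max(vv)
  expect_lt(abs(f$amplitude - peak) / peak, 0.01)
  # exact numeric 10-90% rise of this curve (ln(9) tau_on = 0.2197 is the
  # tau_off -> infinity limit)
  expect_equal(f$rise_10_90, 0.1886, tolerance = 0.005)
})

test_that("slower decay barely moves the rise time", {
  tt <- seq(0, 120, by = 0.02)
  f1 <- fit_synaptic(tt, vesiq:::synaptic_curve(tt, 1, 0.1, 8, 0.5), t0 = 0.5)
  f4 <- fit_synaptic(tt, vesiq:::synaptic_curve(tt, 1, 0.1, 32, 0.5), t0 = 0.5)
  expect_lt(abs(f4$tau_off - 32) / 32, 0.02)
  expect_lt(abs(f4$rise_10_90 - f1$rise_10_90) / f1$rise_10_90, 0.15)
  expect_equal(f4$rise_10_90, 0.2079, tolerance = 0.005)
})

test_that("hopeless fits are flagged, not silently dropped", {
  expect_error(fit_synaptic(1:5, rnorm(5), t0 = 0), "10 samples")
  set.seed(2)
  f <- fit_synaptic(seq(0, 1, length.out = 20),
                    rep(c(1e6, -1e6), 10), t0 = 0.5)
  expect_true(is.na(f$amplitude) || f$converged)
})

test_that("success classification matches the threshold rule", {
  cl <- classify_events(c(0, 0, 0.45), sigma_noise = 0.05)
  expect_equal(cl$pr, 1 / 3)
  expect_identical(cl$n_success, 1L)

  expect_equal(classify_events(rep(0, 10))$pr, 0)
  expect_error(classify_events(numeric()), "no trials")
})

test_that("release probability estimates converge on large series", {
  site <- release_site(8, 8, q_true = 0.45)
  a <- generate_amplitude_series(site, make_protocol(1e4, 0.1),
                                 noise_sd = 0.045, seed = 12)
  cl <- classify_events(a$amplitude_pct)
  expect_lt(abs(cl$pr - 0.80), 0.01)
})

test_that("false-success rate under pure noise matches the 2.5-sigma tail", {
  rates <- vapply(1:50, function(s) {
    set.seed(700 + s)
    classify_events(rnorm(40, 0, 0.05), sigma_noise = 0.05)$pr
  }, numeric(1))
  expect_lt(mean(rates), 2 * pnorm(2.5, lower.tail = FALSE) + 0.01)
})

test_that("quantal analysis solves exact lattices", {
  suppressWarnings({
    qa <- quantal_analysis(c(0.45, 0.90, 0.45, 1.35), sigma_noise = 0.01)
  })
  expect_equal(qa$quantal_size_q, 0.45, tolerance = 1e-9)
  expect_equal(qa$avg_quanta, 1.75)
  expect_identical(qa$max_quanta, 3L)
  expect_equal(qa$release_probability_Pr, 1)

  # scale equivariance
  suppressWarnings({
    qb <- quantal_analysis(3 * c(0.45, 0.90, 0.45, 1.35), sigma_noise = 0.03)
  })
  expect_equal(qb$quantal_size_q, 3 * qa$quantal_size_q, tolerance = 1e-9)

  # degenerate data: all identical successes
  suppressWarnings({
    qc <- quantal_analysis(rep(0.5, 6), sigma_noise = 0.01)
  })
  expect_equal(qc$quantal_size_q, 0.5)
  expect_equal(qc$avg_quanta, 1)
})

test_that("the refined lattice minimum matches a dense brute-force oracle", {
  site <- release_site(8, 8, q_true = 0.45)
  oracle_q <- function(amps) {
    cl <- classify_events(amps)
    s <- amps[cl$trials$success]
    s <- s[s >= 0.5 * median(s)]
    grid <- seq(0.4 * median(s), 1.6 * median(s), length.out = 12000)
    L <- vapply(grid, vesiq:::lattice_residual, numeric(1), amps = s)
    i0 <- max(which(L <= min(L) * 1.5 + 1e-12))
    stats::optimize(vesiq:::lattice_residual,
                    c(grid[max(1, i0 - 1)], grid[min(12000, i0 + 1)]),
                    amps = s, tol = 1e-10)$minimum
  }
  for (s in c(3, 7, 19, 40)) {
    a <- generate_amplitude_series(site, make_protocol(40, 0.1),
                                   noise_sd = 0.045, seed = s)
    qa <- quantal_analysis(a$amplitude_pct)
    # agreement is limited by the coarse grid resolution of the estimator
    step <- 1.2 * median(a$amplitude_pct[a$amplitude_pct > 0.2]) / 1200
    expect_lt(abs(qa$quantal_size_q - oracle_q(a$amplitude_pct)),
              1.5 * step)
  }
})

test_that("control-preset series recover q, Pr and quantal content", {
  site <- release_site(8, 8, q_true = 0.45)
  a <- generate_amplitude_series(site, make_protocol(40, 0.1),
                                 noise_sd = 0.045, seed = 7)
  qa <- quantal_analysis(a$amplitude_pct)
  expect_lt(abs(qa$quantal_size_q - 0.45) / 0.45, 0.10)
  expect_lt(abs(qa$release_probability_Pr - 0.80), 0.10)
  # per-trial quanta agree with the generator's ground truth on successes
  agree <- mean(qa$per_trial_quanta[qa$trials$success] ==
                  a$true_quanta[qa$trials$success])
  expect_gt(agree, 0.9)
})

test_that("estimator medians stay within tolerance over 200 simulations", {
  # q is compared to the generative parameter; Pr and quantal content to
  # the realised truth of each 40-trial draw (at n = 40 the binomial
  # sampling error of Pr alone has a ~5% median, so comparing to the
  # parameter would measure the sample, not the estimator)
  site <- release_site(8, 8, q_true = 0.45)
  res <- vapply(1:200, function(s) {
    a <- generate_amplitude_series(site, make_protocol(40, 0.1),
                                   noise_sd = 0.045, seed = 5000 + s)
    qa <- quantal_analysis(a$amplitude_pct)
    pr_true <- mean(a$true_quanta > 0)
    avg_true <- mean(a$true_quanta[a$true_quanta > 0])
    c(q = abs(qa$quantal_size_q - 0.45) / 0.45,
      pr = abs(qa$release_probability_Pr - pr_true) / pr_true,
      avg = abs(qa$avg_quanta - avg_true) / avg_true)
  }, numeric(3))
  expect_lte(median(res["q", ]), 0.05)
  expect_lte(median(res["pr", ]), 0.05)
  expect_lte(median(res["avg", ]), 0.10)
})

test_that("disabling release eliminates detected events", {
  ttx <- release_site(8, 8, quanta = quanta_dist(c(1, 0, 0, 0, 0)),
                      q_true = 0.45)
  a <- generate_amplitude_series(ttx, make_protocol(40, 0.1), noise_sd = 0,
                                 seed = 2)
  expect_true(all(a$amplitude_pct == 0))
  expect_equal(classify_events(a$amplitude_pct)$pr, 0)
})

test_that("quantal histograms bin at a quarter of the quantal size", {
  site <- release_site(8, 8, q_true = 0.45)
  a <- generate_amplitude_series(site, make_protocol(60, 0.1),
                                 noise_sd = 0.045, seed = 3)
  qa <- quantal_analysis(a$amplitude_pct)
  expect_equal(unique(round(diff(qa$histogram$mid), 9)),
               round(qa$quantal_size_q / 4, 9))
  expect_equal(sum(qa$histogram$count), qa$n_trials)
})
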