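test_that("radial profiles sample the underlying field faithfully", {
  flat <- vesiq:::new_maxmap(matrix(1.7, 81, 81), 0.1)
  p <- radial_profile(flat, c(4, 4), dr = 0.1, r_max = 3)
  expect_true(all(abs(p$dff_pct - 1.7) < 1e-12))

  m <- exp_cone_map(lambda = 0.75, p0 = 2)
  p <- radial_profile(m, c(8, 8), dr = 0.1, r_max = 6)
  expect_lt(max(abs(p$dff_pct - 2 * exp(-p$r_um / 0.75)) /
                  (2 * exp(-p$r_um / 0.75))), 0.02)

  expect_error(radial_profile(m, c(50, 50)), "outside")
  expect_error(radial_profile(m, c(8, 8), dr = 1, r_max = 2), "3 \\* dr")
})

test_that("profiles of simulated sites decay monotonically beyond the cleft", {
  map <- mini_map()
  p <- radial_profile(map, c(4, 4), dr = 0.2, r_max = 3.5)
  beyond <- p$dff_pct[p$r_um > 0.3]
  expect_true(all(diff(beyond) <= 1e-9))
})

test_that("the exponential fit recovers exact and noisy length constants", {
  r <- seq(0.05, 7.95, by = 0.1)
  prof <- tibble::tibble(r_um = r, dff_pct = 2 * exp(-r / 0.75))
  attr(prof, "background") <- 0
  fit <- fit_length_constant(prof)
  expect_lt(abs(fit$lambda - 0.75), 1e-6)
  expect_lt(abs(fit$p0 - 2), 1e-6)
  expect_gt(fit$r_squared, 0.999999)

  # 2% noise: lambda within 5% (seeded)
  set.seed(31)
  noisy <- prof
  noisy$dff_pct <- noisy$dff_pct + rnorm(length(r), 0, 0.04)
  fit2 <- fit_length_constant(noisy)
  expect_lt(abs(fit2$lambda - 0.75) / 0.75, 0.05)

  expect_error(fit_length_constant(prof, fit_range = c(0, 0.3)), "5 profile")
})

test_that("lambda recovery median error stays below 5% over 50 noisy profiles", {
  r <- seq(0.05, 7.95, by = 0.1)
  base <- 2 * exp(-r / 0.75)
  errs <- vapply(1:50, function(s) {
    set.seed(400 + s)
    prof <- tibble::tibble(r_um = r, dff_pct = base + rnorm(length(r), 0, 0.04))
    attr(prof, "background") <- 0
    abs(fit_length_constant(prof)$lambda - 0.75) / 0.75
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("shape metrics are exact on discs and ellipses", {
  H <- 201; ps <- 0.05
  r <- vesiq:::radius_map(H, H, c(5, 5), ps)
  disc <- vesiq:::new_maxmap(ifelse(r <= 1, 2, 0), ps)
  s <- shape_metrics(disc, c(5, 5), count_outlets_annulus = NULL)
  expect_equal(s$fwhm_major_um, 2, tolerance = 0.02)
  expect_equal(s$fwhm_minor_um, 2, tolerance = 0.02)
  expect_equal(s$aspect_ratio, 1, tolerance = 0.01)
  expect_equal(s$roundness, 1, tolerance = 0.03)

  Hf <- 501; psf <- 0.02
  xf <- (seq_len(Hf) - 1) * psf
  ell <- outer(((xf - 5) / 0.25)^2, ((xf - 5) / 0.5)^2, "+") <= 1
  e <- shape_metrics(vesiq:::new_maxmap(ifelse(ell, 2, 0), psf), c(5, 5),
                     count_outlets_annulus = NULL)
  expect_equal(e$fwhm_major_um, 1, tolerance = 0.03)
  expect_equal(e$fwhm_minor_um, 0.5, tolerance = 0.03)
  expect_equal(e$aspect_ratio, 2, tolerance = 0.03)
  expect_equal(e$roundness, 0.5, tolerance = 0.03)
})

test_that("roundness equals 1 / aspect ratio on ideal ellipses", {
  H <- 201; ps <- 0.05
  x <- (seq_len(H) - 1) * ps
  for (ab in list(c(0.4, 0.4), c(0.3, 0.6), c(0.25, 0.9))) {
    ell <- outer(((x - 5) / ab[1])^2, ((x - 5) / ab[2])^2, "+") <= 1
    s <- shape_metrics(vesiq:::new_maxmap(ifelse(ell, 1, 0), ps), c(5, 5),
                       count_outlets_annulus = NULL)
    expect_lt(abs(s$roundness - 1 / s$aspect_ratio), 0.03)
  }
})

test_that("shape metrics flag masks truncated by the image border", {
  H <- 41; ps <- 0.1
  r <- vesiq:::radius_map(H, H, c(0.4, 2), ps)
  m <- vesiq:::new_maxmap(ifelse(r <= 1, 2, 0), ps)
  expect_warning(s <- shape_metrics(m, c(0.4, 2),
                                    count_outlets_annulus = NULL),
                 "truncated")
  expect_true(s$truncated)
})

test_that("outlet counting sees wedges but not isotropic profiles", {
  H <- 161; ps <- 0.1; ctr <- c(8, 8)
  r <- vesiq:::radius_map(H, H, ctr, ps)
  x <- (seq_len(H) - 1) * ps
  theta <- atan2(outer(x - ctr[2], rep(1, H)), outer(rep(1, H), x - ctr[1]))
  iso <- 2 * exp(-r / 0.75)
  expect_identical(count_outlets(vesiq:::new_maxmap(iso, ps), ctr), 0L)

  wedge2 <- iso * (1 + 0.6 * (abs(cos(theta)) > 0.94) * (r > 0.25))
  expect_identical(count_outlets(vesiq:::new_maxmap(wedge2, ps), ctr), 2L)

  ang3 <- pmin(abs(theta - 0), abs(theta - 2 * pi / 3),
               abs(theta + 2 * pi / 3), abs(theta - 2 * pi))
  wedge3 <- iso * (1 + 0.6 * (ang3 < 0.35) * (r > 0.25))
  expect_identical(count_outlets(vesiq:::new_maxmap(wedge3, ps), ctr), 3L)
})

test_that("simulated outlet wedges are counted exactly", {
  ol2 <- list(list(angle = 0, half_width = 20, k_factor = 0.1),
              list(angle = 180, half_width = 20, k_factor = 0.1))
  m2 <- profile_map("ssri", seed = 7)
  expect_identical(count_outlets(m2, c(8, 8)), 2L)
  m0 <- profile_map("control", seed = 7)
  expect_identical(count_outlets(m0, c(8, 8)), 0L)
})

test_that("band integrals match the closed form for an exponential cone", {
  m <- exp_cone_map(lambda = 0.75, p0 = 2, H = 321, ps = 0.05)
  b <- band_integrals(m, c(8, 8))
  # analytic: integral of r exp(-r/lambda) over each band / total to 8 um
  G <- function(x) (1 + x / 0.75) * exp(-x / 0.75)
  expected <- c(G(0) - G(0.5), G(0.5) - G(3), G(3) - G(8)) / (G(0) - G(8))
  expect_lt(max(abs(expected - c(0.144, 0.764, 0.092))), 0.001)
  expect_lt(max(abs(b$fraction - expected)), 0.01)
  expect_equal(sum(b$fraction), 1, tolerance = 1e-6)
})

test_that("a point source concentrates all mass in the inner band", {
  H <- 161; ps <- 0.1
  r <- vesiq:::radius_map(H, H, c(8, 8), ps)
  v <- ifelse(r < 0.4, 5, 0)
  b <- band_integrals(vesiq:::new_maxmap(v, ps), c(8, 8))
  expect_equal(b$fraction, c(1, 0, 0), tolerance = 1e-9)

  flat <- vesiq:::new_maxmap(matrix(1, H, H), ps)
  expect_error(band_integrals(flat, c(8, 8)), "background")
})

test_that("weakening clearance expands spread, width and mid-band mass", {
  maps <- lapply(c(1, 0.5, 0.25), function(sf) mini_map(ssri_factor = sf))
  lam <- vapply(maps, function(m) {
    fit_length_constant(radial_profile(m, c(4, 4), dr = 0.2, r_max = 3.8),
                        fit_range = c(0, 3.8))$lambda
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
  fw <- vapply(maps, function(m) {
    shape_metrics(m, c(4, 4), count_outlets_annulus = NULL)$fwhm_major_um
  }, numeric(1))
  expect_true(all(diff(fw) >= 0))
  mid <- vapply(maps, function(m) {
    r <- vesiq:::radius_map(nrow(m$values), ncol(m$values), c(4, 4),
                            m$pixel_size)
    sum(pmax(m$values - m$background_median, 0)[r >= 0.5 & r < 3])
  }, numeric(1))
  expect_true(all(diff(mid) > 0))
})

test_that("shape and band metrics are 90-degree rotation equivariant", {
  map <- mini_map(ssri_factor = 0.2,
                  outlets = list(list(angle = 0, half_width = 20,
                                      k_factor = 0.1),
                                 list(angle = 180, half_width = 20,
                                      k_factor = 0.1)))
  rot <- map
  rot$values <- t(map$values)[ncol(map$values):1, ]  # 90-degree rotation
  ctr <- c(4, 4)
  s1 <- shape_metrics(map, ctr)
  s2 <- shape_metrics(rot, ctr)
  for (f in c("fwhm_minor_um", "fwhm_major_um", "aspect_ratio", "roundness")) {
    expect_lt(abs(s1[[f]] - s2[[f]]) / s1[[f]], 0.02)
  }
  expect_identical(s1$n_outlets, s2$n_outlets)
  b1 <- band_integrals(map, ctr, edges = c(0, 0.5, 3))
  b2 <- band_integrals(rot, ctr, edges = c(0, 0.5, 3))
  expect_equal(b1$fraction, b2$fraction, tolerance = 0.02)
  f1 <- fit_length_constant(radial_profile(map, ctr, dr = 0.2, r_max = 3.8),
                            fit_range = c(0, 3.8))
  f2 <- fit_length_constant(radial_profile(rot, ctr, dr = 0.2, r_max = 3.8),
                            fit_range = c(0, 3.8))
  expect_lt(abs(f1$lambda - f2$lambda) / f1$lambda, 0.02)
})
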