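test_that("mean chord length follows Cauchy's 4V/S", {
  expect_equal(mean_chord(spherical_site(2.7)), 1.8, tolerance = 1e-12)
  expect_equal(mean_chord(list(kind = "sphere", diameter = 2.7)), 1.8)
  # right cylinder h = d: 4V/S = 4 (pi d^2 h / 4) / (pi d h + pi d^2 / 2)
  d <- 1
  want <- 4 * (pi * d^3 / 4) / (pi * d^2 + pi * d^2 / 2)
  expect_equal(mean_chord(list(kind = "cylinder", diameter = d, height = d)),
               want, tolerance = 1e-12)
  # Monte Carlo chord-sampling oracle
  expect_equal(mc_mean_chord_cylinder(1, 1), want, tolerance = 0.01)
  expect_error(mean_chord(list(kind = "torus", diameter = 1)), "non-convex|unknown")
  expect_error(spherical_site(-1), "positive")
})

test_that("TEPC gas-pressure scaling reproduces the tissue equivalence", {
  d <- tepc_site_scaling(12.7, pressure_mbar = 120)
  expect_equal(d, 2.7, tolerance = 0.10 * 2.7)
  expect_equal(tepc_site_scaling(12.7, pressure_mbar = 240), 2 * d,
               tolerance = 1e-12)
  expect_equal(tepc_site_scaling(12.7, pressure_mbar = 0), 0)
  expect_error(tepc_site_scaling(12.7, pressure_mbar = -1), "pressure")
})

test_that("site events are per-primary sums with y = epsilon / mean chord", {
  site <- spherical_site(2.7)
  # a 235.8 keV deposition in the site corresponds to y = 131 keV/um
  dep <- data.frame(event_id = 1L, x = 0, y = 0, z = 0, amount = 235.8,
                    source = "primary_ion")
  ev <- collect_site_events(dep, site, center = c(0, 0, 0))
  expect_equal(ev$y_kev_um, 131, tolerance = 1e-3)

  # constant-LET diameter crossing: y = 1.5 L
  L <- 100 # keV/um
  zs <- seq(-1.34e-4, 1.34e-4, length.out = 269) # just inside the sphere
  dep2 <- data.frame(event_id = 2L, x = 0, y = 0, z = zs,
                     amount = L * 2.7 / 269, source = "primary_ion")
  ev2 <- collect_site_events(dep2, site, center = c(0, 0, 0))
  expect_equal(ev2$y_kev_um, 1.5 * L, tolerance = 0.01)

  # mixed source labelling and non-intersecting tracks
  dep3 <- rbind(dep, data.frame(event_id = 1L, x = 0, y = 0, z = 1e-5,
                                amount = 1, source = "delta_electron"),
                data.frame(event_id = 3L, x = 1, y = 1, z = 1,
                           amount = 5, source = "primary_ion"))
  ev3 <- collect_site_events(dep3, site, center = c(0, 0, 0))
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$source, "mixed")
  expect_equal(nrow(collect_site_events(dep3[3, ], site, c(0, 0, 0))), 0L)
})

test_that("scored site energy never exceeds the booked beam energy", {
  b <- tiny_oxygen_bundle(n = 10, seed = 51)
  site <- spherical_site(0.5)
  ev <- collect_site_events(b, site, center = c(0, 0, 0.5e-4))
  expect_lte(sum(ev$epsilon_kev), sum(b$ledger$E_dep) * 1e3 * (1 + 1e-9))
})

test_that("spectrum moments and normalization are exact", {
  sp1 <- build_spectrum(c(5, 5, 5))
  expect_equal(sp1$y_F, 5); expect_equal(sp1$y_D, 5)
  expect_equal(sum(sp1$counts > 0), 1L)

  sp2 <- build_spectrum(c(1, 3))
  expect_equal(sp2$y_F, 2)
  expect_equal(sp2$y_D, 2.5)

  set.seed(60)
  y <- rlnorm(1e5, log(10), 0.5)
  sp3 <- build_spectrum(y)
  dy <- diff(sp3$log_bin_edges)
  expect_equal(sum(sp3$f_y * dy), 1, tolerance = 1e-9)
  expect_equal(sum(sp3$d_y * dy), 1, tolerance = 1e-9)
  # binned moments agree with event moments within 1%
  expect_equal(sum(sp3$y_mid * sp3$f_y * dy), mean(y), tolerance = 0.01)
  expect_equal(sum(sp3$y_mid^2 * sp3$f_y * dy) / sum(sp3$y_mid * sp3$f_y * dy),
               sp3$y_D, tolerance = 0.01)
  expect_error(build_spectrum(numeric(0)), "at least one")
})

test_that("y_D >= y_F for any event set and y scales inversely with chord", {
  set.seed(61)
  for (i in 1:5) {
    y <- rlnorm(200, log(runif(1, 1, 100)), runif(1, 0.1, 1))
    s <- build_spectrum(y)
    expect_gte(s$y_D, s$y_F)
  }
  dep <- data.frame(event_id = 1:3, x = 0, y = 0, z = 0,
                    amount = c(10, 20, 30), source = "primary_ion")
  y1 <- collect_site_events(dep, spherical_site(2.7), c(0, 0, 0))$y_kev_um
  y2 <- collect_site_events(dep, spherical_site(5.4), c(0, 0, 0))$y_kev_um
  expect_equal(y1 / y2, rep(2, 3), tolerance = 1e-12)
})

test_that("spectrum mode picks the tallest yd(y) bin, ties to lower y", {
  s <- build_spectrum(rep(7, 10))
  i <- which(s$counts > 0)
  expect_equal(spectrum_mode(s), s$y_mid[i])
  # bimodal: taller mode wins
  set.seed(62)
  y <- c(rlnorm(3000, log(3), 0.08), rlnorm(500, log(60), 0.08))
  s2 <- build_spectrum(y)
  # dose weighting makes the high-y component taller here
  expect_gt(spectrum_mode(s2), 30)
  # component selection needs event-based spectra
  expect_error(spectrum_mode(s2, component = "primary_ion"), "event-based")
})

test_that("Poisson hit statistics match the closed form", {
  ps <- poisson_hit_stats(3e6, 100)
  expect_equal(ps$mean_hits, 3)
  expect_equal(ps$p_zero, exp(-3), tolerance = 1e-12)
  expect_lt(ps$p_zero, 0.05)
  expect_equal(unname(ps$p_k["k2"]), exp(-3) * 9 / 2, tolerance = 1e-12)
  # partial sums: k <= 10 covers at least 99.9% at m = 3 (series oracle)
  expect_gte(sum(ps$p_k), sum(exp(-3) * 3^(0:10) / factorial(0:10)) - 1e-12)
  expect_gte(sum(ps$p_k), 0.999)
  expect_equal(poisson_hit_stats(0, 100)$p_zero, 1)
  expect_error(poisson_hit_stats(-1, 100), "fluence")
})
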