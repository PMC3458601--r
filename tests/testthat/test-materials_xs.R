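test_that("built-in material table has consistent constants", {
  w <- get_material("water")
  expect_equal(w$density, 1.0)
  # PDG approximate formula, evaluated independently, for beryllium
  x0_be <- 716.4 * 9.0122 / (4 * 5 * log(287 / sqrt(4)))
  expect_equal(get_material("beryllium")$X0, x0_be, tolerance = 1e-3)
  for (nm in c("water", "beryllium", "carbon", "te-gas", "air")) {
    m <- get_material(nm)
    expect_equal(m$electron_density, m$density * 6.02214076e23 * m$Z / m$A,
                 tolerance = 1e-9)
  }
  expect_error(get_material("unobtainium"), "available")
  expect_error(material("bad", Z = 4, A = 9, density = -1, I = 60, X0 = 65),
               "density")
})

test_that("species constructors enforce invariants", {
  expect_equal(species("carbon")$z, 6)
  expect_error(species("proton", z = 0, mass_number = 1, rest_mass = 938),
               "z must be")
  expect_error(species("x", z = 1, mass_number = 1, rest_mass = -1), "rest mass")
})

test_that("stopping power matches an independent Bethe implementation", {
  sp <- species("proton"); w <- get_material("water")
  got <- stopping_power(158.6, sp, w)
  want <- bethe_oracle(158.6, 1, 1, sp$rest_mass, w$Z / w$A, w$density, w$I)
  expect_equal(got, want, tolerance = 1e-6)
  # falling branch is monotone
  expect_gt(stopping_power(200, sp, w), stopping_power(400, sp, w))
  # below validity floor
  expect_error(stopping_power(0.5, sp, w), "floor")
  expect_warning(stopping_power(0.5, sp, w, low_energy = "clamp"), "clamp")
})

test_that("stopping power scales as z^2 at equal velocity", {
  w <- get_material("water")
  p <- species("proton")
  # same mass, doubled charge: identical kinematics, exact z^2 scaling
  z2 <- species("z2", z = 2, mass_number = 1, rest_mass = p$rest_mass)
  expect_equal(stopping_power(100, z2, w) / stopping_power(100, p, w), 4,
               tolerance = 1e-12)
  # equal-velocity carbon / proton: ratio 36 up to the tiny Tmax mass terms
  c12 <- species("carbon")
  Tc <- 100 * (c12$rest_mass / 12) / p$rest_mass # equal beta
  expect_equal(stopping_power(Tc, c12, w) / stopping_power(100, p, w), 36,
               tolerance = 1e-3)
})

test_that("kinematic maximum delta energy follows the closed form", {
  c12 <- species("carbon")
  g <- 1 + 300 / 931.49410242
  b2g2 <- g^2 - 1
  r <- 0.51099895 / c12$rest_mass
  want <- 2 * 0.51099895 * b2g2 / (1 + 2 * g * r + r^2)
  expect_equal(tmax_delta(300, c12), want, tolerance = 1e-9)
  expect_equal(want, 0.76, tolerance = 0.01)
  expect_equal(tmax_delta(0, c12), 0)
  # heavy-ion limit: with the mass terms suppressed, Tmax -> 2 me b2 g2
  heavy <- species("heavy", z = 1, mass_number = 1e6, rest_mass = 1e6 * 931.494)
  gh <- 1 + 300 / 931.494
  expect_equal(tmax_delta(300, heavy), 2 * 0.51099895 * (gh^2 - 1),
               tolerance = 1e-4)
})

test_that("screened Rutherford DCS has the Berger angular shape", {
  sp <- species("proton"); be <- get_material("beryllium")
  kin <- iontrack:::.kinematics(158.6, sp)
  eta <- 1e-4
  th <- c(0.01, 0.1, 0.5, 2)
  dcs <- screened_rutherford_dcs(kin$pc, kin$beta, sp, be, th, eta)
  # algebraic ratio identity
  for (i in 1:3) {
    want <- ((1 - cos(th[4]) + 2 * eta) / (1 - cos(th[i]) + 2 * eta))^2
    expect_equal(dcs[i] / dcs[4], want, tolerance = 1e-12)
  }
  # finite at theta = 0, strictly decreasing
  expect_true(is.finite(screened_rutherford_dcs(kin$pc, kin$beta, sp, be, 0, eta)))
  expect_true(all(diff(dcs) < 0))
  # unscreened theta^-4 limit: dcs(2 theta)/dcs(theta) -> 1/16
  r <- screened_rutherford_dcs(kin$pc, kin$beta, sp, be, 2e-4, 1e-12) /
    screened_rutherford_dcs(kin$pc, kin$beta, sp, be, 1e-4, 1e-12)
  expect_equal(r, 1 / 16, tolerance = 1e-3)
})

test_that("closed-form cross section above cutoff matches quadrature", {
  sp <- species("proton"); be <- get_material("beryllium")
  kin <- iontrack:::.kinematics(158.6, sp)
  for (eta in c(1e-6, 1e-3)) {
    for (thmin in c(1e-3, 0.1)) {
      want <- sigma_quadrature(kin$pc, kin$beta, sp, be, thmin, eta)
      got <- elastic_sigma_above(kin$pc, kin$beta, sp, be, thmin, eta)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("elastic polar-angle sampler hits its CDF bounds and shape", {
  expect_equal(sample_elastic_polar_angle(0, 1e-4), 0)
  expect_equal(sample_elastic_polar_angle(1, 1e-4), pi)
  # chi-squared goodness of fit against the quadrature-normalized DCS
  sp <- species("proton"); be <- get_material("beryllium")
  kin <- iontrack:::.kinematics(158.6, sp)
  nbin <- 20
  for (eta in c(1e-6, 1e-4, 1e-2)) {
    edges <- sample_elastic_polar_angle(seq(0, 1, length.out = nbin + 1), eta)
    pq <- elastic_bin_probs_quadrature(kin$pc, kin$beta, sp, be, eta, edges)
    set.seed(4242)
    th <- sample_elastic_polar_angle(runif(1e5), eta)
    counts <- tabulate(findInterval(th, edges, rightmost.closed = TRUE),
                       nbins = nbin)
    p <- suppressWarnings(chisq.test(counts, p = pq)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("elastic mean free path behaves like 1/(n sigma)", {
  sp <- species("proton"); be <- get_material("beryllium")
  l1 <- elastic_mean_free_path(158.6, sp, be, 1e-3)
  l2 <- elastic_mean_free_path(158.6, sp, be, 2e-3)
  expect_gt(l2, l1)
  kin <- iontrack:::.kinematics(158.6, sp)
  eta <- screening_eta(158.6, sp, be)
  want <- 1 / (be$n_atoms * sigma_quadrature(kin$pc, kin$beta, sp, be, 1e-3, eta))
  expect_equal(l1, want, tolerance = 1e-6)
  vac <- material("vacuumish", Z = 4, A = 9.0122, density = 1e-20,
                  I = 63.7, X0 = 65)
  expect_gt(elastic_mean_free_path(158.6, sp, vac, 1e-3), 1e15)
  expect_error(elastic_mean_free_path(158.6, sp, be, 0), "theta_min")
})

test_that("delta-ray energy sampler matches the truncated 1/T^2 density", {
  expect_equal(sample_delta_energy(0, 1, 100), 1)
  expect_equal(sample_delta_energy(1, 1, 100), 100)
  expect_error(sample_delta_energy(0.5, 10, 10), "Tcut < Tmax")
  set.seed(77)
  x <- sample_delta_energy(runif(1e6), 1, 100)
  # analytic mean of the truncated 1/T^2 density
  m <- (1 * 100 / (100 - 1)) * log(100 / 1)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - m), 3 * se)
})

test_that("delta emission angle follows binary-encounter kinematics", {
  expect_equal(delta_emission_angle(100, 100), 0)
  expect_equal(delta_emission_angle(50, 100), pi / 4)
  expect_equal(delta_emission_angle(1e-9, 100), pi / 2, tolerance = 1e-4)
  expect_error(delta_emission_angle(101, 100), "exceed")
})

test_that("compiled stopping power agrees with the R reference", {
  sp <- species("carbon"); w <- get_material("water")
  Ts <- c(2, 10, 50, 300)
  expect_equal(iontrack:::cpp_stopping_power(Ts, unclass(sp), unclass(w)),
               stopping_power(Ts, sp, w), tolerance = 1e-12)
})
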