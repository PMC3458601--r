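test_that("without elastic scattering ions travel exactly straight", {
  b <- run_beam(list(species = "proton", T_per_u = 158.6, n_primaries = 25,
                     seed = 3),
                geometry_slab("beryllium", 0.66),
                physics_config(elastic_scattering = FALSE))
  expect_true(all(b$exits$dx == 0))
  expect_true(all(b$exits$dy == 0))
  expect_true(all(b$exits$dz == 1))
  # and every primary deposit lies on the entry axis
  expect_true(all(b$deposits$x == 0))
  expect_true(all(b$deposits$y == 0))
})

test_that("a zero-thickness slab is the identity", {
  res <- transport_ion(list(position = c(0, 0, 0), direction = c(0, 0, 1),
                            T_per_u = 158.6, species = species("proton")),
                       geometry_slab("water", 0))
  expect_equal(nrow(res$deposits), 0)
  expect_equal(res$exit$T_per_u, 158.6)
  expect_equal(res$exit$direction, c(0, 0, 1))
})

test_that("ions stopping in a thick slab deposit their full energy", {
  sp <- species("proton")
  b <- run_beam(list(species = sp, T_per_u = 30, n_primaries = 30, seed = 5),
                geometry_slab("water", 2),
                physics_config(elastic_scattering = TRUE, straggling = FALSE),
                scoring = list(store_deposits = FALSE))
  expect_true(all(b$exits$exited == 0))
  expect_true(all(abs(b$ledger$E_in - b$ledger$E_dep) / b$ledger$E_in < 1e-9))
  # stopping depth agrees with the CSDA range quadrature oracle
  r_csda <- csda_range(30, sp, get_material("water"))
  expect_lt(abs(mean(b$exits$z) - r_csda) / r_csda, 0.01)
})

test_that("per-track energy ledger closes with all physics enabled", {
  b <- tiny_oxygen_bundle(n = 15, seed = 21)
  err <- abs(b$ledger$E_in - b$ledger$E_dep - b$ledger$E_exit) / b$ledger$E_in
  expect_true(all(err < 1e-9))
  # deposits actually stored sum to no more than the booked total
  expect_lte(sum(b$deposits$amount) * 1e-3, sum(b$ledger$E_dep) * (1 + 1e-9))
})

test_that("runs are bit-reproducible from the seed and order-independent", {
  b1 <- tiny_oxygen_bundle(n = 10, seed = 31)
  b2 <- tiny_oxygen_bundle(n = 10, seed = 31)
  expect_identical(b1$deposits, b2$deposits)
  expect_identical(b1$exits, b2$exits)
  b3 <- tiny_oxygen_bundle(n = 10, seed = 32)
  expect_false(identical(b1$exits, b3$exits))
})

test_that("beam preconditions are enforced", {
  expect_error(run_beam(list(species = "proton", T_per_u = 100,
                             n_primaries = 0, seed = 1),
                        geometry_slab("water", 1)),
               "n_primaries")
  expect_error(transport_ion(list(position = c(0, 0, 0),
                                  direction = c(0, 0, 2),
                                  T_per_u = 100, species = species("proton")),
                             geometry_slab("water", 1)),
               "unit vector")
})

test_that("fitted width grows with thickness as Highland predicts", {
  sp <- species("proton")
  w <- vapply(c(0.15, 0.6), function(x) {
    bm <- gottschalk_benchmark(list(material = "beryllium", thickness_cm = x),
                               n_primaries = 8000, seed = 5)
    bm$fit$width
  }, numeric(1))
  hl_ratio <- as.numeric(highland_width(158.6, sp, 0.6, "beryllium")) /
    as.numeric(highland_width(158.6, sp, 0.15, "beryllium"))
  expect_equal(w[2] / w[1], hl_ratio, tolerance = 0.05)
})

test_that("scattering statistics are invariant under beam azimuth", {
  geom <- geometry_slab("beryllium", 0.66)
  phys <- physics_config()
  tilt <- 1 * pi / 180
  init_x <- cbind(0, 0, 0, sin(tilt), 0, cos(tilt), 158.6)[rep(1, 2000), ]
  init_y <- cbind(0, 0, 0, 0, sin(tilt), cos(tilt), 158.6)[rep(1, 2000), ]
  bx <- run_beam(list(species = "proton", T_per_u = 158.6, n_primaries = 2000,
                      seed = 8),
                 geom, phys, scoring = list(store_deposits = FALSE),
                 init_states = init_x)
  by <- run_beam(list(species = "proton", T_per_u = 158.6, n_primaries = 2000,
                      seed = 9),
                 geom, phys, scoring = list(store_deposits = FALSE),
                 init_states = init_y)
  # angle relative to the respective beam axis
  ax <- acos(pmin(1, bx$exits$dx * sin(tilt) + bx$exits$dz * cos(tilt)))
  ay <- acos(pmin(1, by$exits$dy * sin(tilt) + by$exits$dz * cos(tilt)))
  expect_equal(sqrt(mean(ax^2)), sqrt(mean(ay^2)), tolerance = 0.05)
})

test_that("slow-ion tracks show visible angular deflection over a micron", {
  b <- tiny_oxygen_bundle(n = 10, seed = 13, elastic = TRUE)
  th <- atan2(sqrt(b$exits$dx^2 + b$exits$dy^2), b$exits$dz)
  expect_gt(max(th), 1e-3)   # milliradian-scale deflection is visible
  b0 <- tiny_oxygen_bundle(n = 10, seed = 13, elastic = FALSE)
  expect_true(all(atan2(sqrt(b0$exits$dx^2 + b0$exits$dy^2), b0$exits$dz) == 0))
})

test_that("delta electrons conserve energy and respect their range scale", {
  dep <- transport_electron(list(position = c(0, 0, 0), direction = c(0, 0, 1),
                                 energy_kev = 5), "water", seed = 1)
  expect_equal(sum(dep$amount), 5, tolerance = 1e-12)
  # excursion distribution: 90th percentile within a factor 2 of the
  # practical range R = 4e-6 T^1.75 g/cm^2
  exc <- vapply(1:300, function(i) {
    d <- transport_electron(list(position = c(0, 0, 0),
                                 direction = c(0, 0, 1), energy_kev = 1),
                            "water", seed = i)
    max(sqrt(d$x^2 + d$y^2 + d$z^2))
  }, numeric(1))
  r_prac <- 4e-6 * 1^1.75 / 1.0
  p90 <- unname(quantile(exc, 0.9))
  expect_gt(p90, r_prac / 2)
  expect_lte(p90, r_prac * 2)
  # higher energy reaches farther
  exc10 <- vapply(1:100, function(i) {
    d <- transport_electron(list(position = c(0, 0, 0),
                                 direction = c(0, 0, 1), energy_kev = 10),
                            "water", seed = i)
    max(sqrt(d$x^2 + d$y^2 + d$z^2))
  }, numeric(1))
  expect_gt(max(exc10), max(exc))
})

test_that("single-track transport reports secondaries", {
  res <- transport_ion(list(position = c(0, 0, 0), direction = c(0, 0, 1),
                            T_per_u = 2.57, species = species("oxygen")),
                       geometry_slab("water", 1e-4),
                       physics_config(delta_transport = TRUE, tcut_kev = 0.5,
                                      max_substep_cm = 1e-7,
                                      min_substep_cm = 1e-9),
                       seed = 2)
  expect_gt(nrow(res$secondaries), 0)
  expect_true(all(res$secondaries$energy_kev >= 0.5))
})

test_that("the discrete-collision cutoff is converged at its default", {
  cv <- theta_min_convergence("beryllium", n_primaries = 6000, seed = 19)
  # halving theta_min changes the fitted width consistently with noise
  expect_lt(cv$delta_over_sigma, 3)
})
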