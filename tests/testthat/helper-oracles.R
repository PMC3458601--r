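# Independent oracles used across the suite. These are deliberately
# separate implementations from the package code paths they check.

# Bethe electronic stopping power, re-coded from scratch (MeV/cm).
bethe_oracle <- function(T_per_u, z, mass_number, rest_mass_mev, ZA, rho, I_ev) {
  mu <- rest_mass_mev / max(mass_number, 1)
  g <- 1 + T_per_u / mu
  b2 <- (g^2 - 1) / g^2
  me <- 0.51099895
  ratio <- me / rest_mass_mev
  tmax <- 2 * me * b2 * g^2 / (1 + 2 * g * ratio + ratio^2)
  I_mev <- I_ev * 1e-6
  0.307075 * z^2 * ZA * rho / b2 *
    (0.5 * log(2 * me * b2 * g^2 * tmax / I_mev^2) - b2)
}

# Total screened Rutherford cross section above theta_min by adaptive
# quadrature of the differential form (cm^2). Integrates in log(theta) so
# the near-forward theta^-3 behaviour is resolved.
sigma_quadrature <- function(p, beta, sp, mat, theta_min, eta) {
  f <- function(v) {
    th <- exp(v)
    screened_rutherford_dcs(p, beta, sp, mat, th, eta) * 2 * pi * sin(th) * th
  }
  integrate(f, log(theta_min), log(pi), rel.tol = 1e-10,
            subdivisions = 500L)$value
}

# Bin probabilities of the elastic polar-angle distribution from per-bin
# quadrature of the DCS (the oracle for the sampler's distribution).
elastic_bin_probs_quadrature <- function(p, beta, sp, mat, eta, edges) {
  per <- vapply(seq_len(length(edges) - 1), function(i) {
    a <- max(edges[i], 1e-12)
    sigma_quadrature(p, beta, sp, mat, a, eta) -
      (if (edges[i + 1] >= pi) 0 else
        sigma_quadrature(p, beta, sp, mat, edges[i + 1], eta))
  }, numeric(1))
  per / sum(per)
}

# Monte Carlo mean chord length of a convex body from isotropic uniform
# chords (mu-randomness: uniform points on a bounding sphere, isotropic
# directions, chord = intersection length).
mc_mean_chord_cylinder <- function(d, h, n = 4e4, seed = 1) {
  set.seed(seed)
  R <- sqrt((d / 2)^2 + (h / 2)^2) * 1.0001
  # invariant line measure: isotropic directions, uniform offsets on the
  # perpendicular disk
  cost <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  u <- cbind(sqrt(1 - cost^2) * cos(phi), sqrt(1 - cost^2) * sin(phi), cost)
  rr <- R * sqrt(runif(n)); aa <- runif(n, 0, 2 * pi)
  # plane perpendicular to each direction through a disk offset
  lens <- vapply(seq_len(n), function(i) {
    dvec <- u[i, ]
    # orthonormal frame
    a <- if (abs(dvec[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- a - sum(a * dvec) * dvec; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(dvec[2] * e1[3] - dvec[3] * e1[2],
            dvec[3] * e1[1] - dvec[1] * e1[3],
            dvec[1] * e1[2] - dvec[2] * e1[1])
    p0 <- rr[i] * (cos(aa[i]) * e1 + sin(aa[i]) * e2) - R * dvec
    chord_len_cylinder(p0, dvec, d / 2, h / 2)
  }, numeric(1))
  sum(lens) / sum(lens > 0)
}

chord_len_cylinder <- function(p0, u, rad, hh) {
  # entry/exit parameters of line p0 + t u with cylinder x^2+y^2<=rad^2, |z|<=hh
  a <- u[1]^2 + u[2]^2
  ts <- c()
  if (a > 1e-12) {
    b <- 2 * (p0[1] * u[1] + p0[2] * u[2])
    cc <- p0[1]^2 + p0[2]^2 - rad^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) return(0)
    t1 <- (-b - sqrt(disc)) / (2 * a); t2 <- (-b + sqrt(disc)) / (2 * a)
  } else {
    if (p0[1]^2 + p0[2]^2 > rad^2) return(0)
    t1 <- -Inf; t2 <- Inf
  }
  if (abs(u[3]) > 1e-12) {
    tz1 <- (-hh - p0[3]) / u[3]; tz2 <- (hh - p0[3]) / u[3]
    lo <- max(t1, min(tz1, tz2)); hi <- min(t2, max(tz1, tz2))
  } else {
    if (abs(p0[3]) > hh) return(0)
    lo <- t1; hi <- t2
  }
  max(hi - lo, 0)
}

# small standard run used by several tests
tiny_oxygen_bundle <- function(n = 20, seed = 9, elastic = TRUE) {
  run_beam(list(species = "oxygen", T_per_u = 2.57, n_primaries = n, seed = seed),
           geometry_slab("water", 1e-4),
           physics_config(elastic_scattering = elastic, tcut_kev = 0.5,
                          max_substep_cm = 1e-7, min_substep_cm = 1e-9,
                          delta_transport = TRUE, delta_max_points = 64L))
}
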