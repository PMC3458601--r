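#' Electronic (collision) stopping power
#'
#' Bethe stopping power without shell, density or Barkas corrections (a
#' few-percent systematic at the energies this package targets):
#' \deqn{-dE/dx = K z^2 \frac{Z}{A}\frac{\rho}{\beta^2}
#'   \left[\tfrac12\ln\frac{2 m_e c^2 \beta^2\gamma^2 T_{max}}{I^2}
#'   - \beta^2\right]}
#' with the full kinematic maximum energy transfer \eqn{T_{max}}.
#'
#' @param T_per_u kinetic energy per nucleon (MeV/u); vectorised.
#' @param species a [species()] object.
#' @param material a [material()] object.
#' @param low_energy below the 1 MeV/u validity floor either `"error"`
#'   (default) or `"clamp"` (evaluate at the floor, with a warning).
#' @return Stopping power in MeV/cm (positive).
#' @export
stopping_power <- function(T_per_u, species, material,
                           low_energy = c("error", "clamp")) {
  low_energy <- match.arg(low_energy)
  floor_mev <- 1.0
  if (any(T_per_u < floor_mev)) {
    if (low_energy == "error") {
      stop(sprintf("stopping_power: T_per_u below the %g MeV/u validity floor", floor_mev))
    }
    warning("stopping_power: clamping T_per_u to the 1 MeV/u validity floor")
    T_per_u <- pmax(T_per_u, floor_mev)
  }
  me <- .const$me_c2
  kin <- .kinematics(T_per_u, species)
  tmax <- tmax_delta(T_per_u, species)          # MeV
  I_mev <- material$I * 1e-6
  arg <- 2 * me * kin$beta2 * kin$gamma^2 * tmax / I_mev^2
  .const$K_bethe * species$z^2 * (material$Z / material$A) *
    material$density / kin$beta2 * (0.5 * log(arg) - kin$beta2)
}

#' Maximum kinematic energy transfer to a free electron
#'
#' \deqn{T_{max} = \frac{2 m_e c^2 \beta^2\gamma^2}
#'   {1 + 2\gamma m_e/M + (m_e/M)^2}}
#'
#' @inheritParams stopping_power
#' @return Maximum delta-ray energy in MeV; vectorised over `T_per_u`.
#' @export
tmax_delta <- function(T_per_u, species) {
  stopifnot(all(T_per_u >= 0))
  me <- .const$me_c2
  M <- species$rest_mass
  kin <- .kinematics(T_per_u, species)
  2 * me * kin$beta2 * kin$gamma^2 /
    (1 + 2 * kin$gamma * me / M + (me / M)^2)
}

#' Screening parameter of the elastic cross section
#'
#' Moliere screening angle form
#' \eqn{\eta = \frac14 (\hbar / (p\, a_{TF}))^2} with the Thomas-Fermi
#' radius \eqn{a_{TF} = 0.885\, a_0 Z^{-1/3}} of the target atom. This is
#' the standard companion to the screened Rutherford cross section; it can
#' be overridden by passing an explicit `eta` to the sampling functions.
#'
#' @inheritParams stopping_power
#' @return Dimensionless screening parameter (> 0).
#' @export
screening_eta <- function(T_per_u, species, material) {
  kin <- .kinematics(T_per_u, species)
  a_tf <- 0.885 * .const$a0_fm * material$Z^(-1 / 3)  # fm
  0.25 * (.const$hbar_c / (kin$pc * a_tf))^2
}

#' Screened Rutherford elastic differential cross section
#'
#' \deqn{\frac{d\sigma}{d\Omega} =
#'   \left(\frac{z Z e^2}{p v}\right)^2 \frac{1}{(1-\cos\theta+2\eta)^2}}
#' Finite at \eqn{\theta = 0} thanks to the screening \eqn{\eta}, and
#' strictly decreasing in \eqn{\theta}.
#'
#' @param p momentum (MeV/c).
#' @param beta velocity in units of c.
#' @param species,material projectile and target.
#' @param theta polar scattering angle in radians, in `[0, pi]`; vectorised.
#' @param eta screening parameter (see [screening_eta()]).
#' @return Differential cross section in cm^2/sr.
#' @export
screened_rutherford_dcs <- function(p, beta, species, material, theta, eta) {
  stopifnot(all(theta >= 0), all(theta <= pi), eta > 0)
  C_fm <- species$z * material$Z * .const$e2 / (p * beta)  # fm
  C2 <- C_fm^2 * .const$fm2_to_cm2                         # cm^2
  C2 / (1 - cos(theta) + 2 * eta)^2
}

#' Sample a polar elastic scattering angle (exact inverse CDF)
#'
#' The screened Rutherford cross section integrates in closed form, giving
#' the exact sampling rule \eqn{1-\cos\theta = 2\eta u/(1+\eta-u)} for a
#' uniform deviate `u`. The azimuth is sampled separately, uniform on
#' `[0, 2 pi)`.
#'
#' @param u uniform(0,1) deviates (vectorised).
#' @param eta screening parameter (> 0).
#' @return Polar angles in radians; `u = 0` maps to 0 and `u = 1` to pi.
#' @export
sample_elastic_polar_angle <- function(u, eta) {
  stopifnot(all(u >= 0), all(u <= 1), eta > 0)
  t <- 2 * eta * u / (1 + eta - u)
  acos(pmin(1, pmax(-1, 1 - t)))
}

#' Total elastic cross section above a cutoff angle
#'
#' Closed-form integral of the screened Rutherford cross section over
#' \eqn{\theta > \theta_{min}}:
#' \deqn{\sigma(>\theta_{min}) = 2\pi C^2\left[\frac{1}{t_{min}+2\eta}
#'   - \frac{1}{2+2\eta}\right]}, \eqn{t_{min} = 1-\cos\theta_{min}}.
#'
#' @inheritParams screened_rutherford_dcs
#' @param theta_min cutoff polar angle in radians (> 0).
#' @return Cross section in cm^2.
#' @export
elastic_sigma_above <- function(p, beta, species, material, theta_min, eta) {
  stopifnot(theta_min > 0, eta > 0)
  C_fm <- species$z * material$Z * .const$e2 / (p * beta)
  C2 <- C_fm^2 * .const$fm2_to_cm2
  tmin <- 1 - cos(theta_min)
  2 * pi * C2 * (1 / (tmin + 2 * eta) - 1 / (2 + 2 * eta))
}

#' Elastic mean free path between discrete collisions
#'
#' `1 / (n_atoms * sigma(> theta_min))`. The cutoff `theta_min` separates
#' discrete collisions from the (ignored) sub-cutoff deflections and
#' controls simulation cost; the mean free path is strictly increasing in
#' `theta_min`.
#'
#' @inheritParams stopping_power
#' @param theta_min cutoff polar angle in radians (> 0).
#' @param eta optional screening parameter override.
#' @return Mean free path in cm (`Inf` for a vacuum-like medium).
#' @export
elastic_mean_free_path <- function(T_per_u, species, material, theta_min,
                                   eta = NULL) {
  if (!(theta_min > 0)) stop("theta_min must be > 0")
  kin <- .kinematics(T_per_u, species)
  if (is.null(eta)) eta <- screening_eta(T_per_u, species, material)
  sig <- elastic_sigma_above(kin$pc, kin$beta, species, material, theta_min, eta)
  1 / (material$n_atoms * sig)
}

#' Sample a delta-ray energy from the truncated 1/T^2 spectrum
#'
#' Free-electron (Rutherford) knock-on spectrum between the production
#' threshold `Tcut` and the kinematic maximum `Tmax`, sampled by exact
#' inversion: \eqn{T_\delta = T_{cut} T_{max} /
#' (T_{max} - u (T_{max}-T_{cut}))}.
#'
#' @param u uniform(0,1) deviates (vectorised).
#' @param Tcut production threshold (keV).
#' @param Tmax kinematic maximum (keV); must exceed `Tcut`.
#' @return Delta-ray energies in keV, in `[Tcut, Tmax]`.
#' @export
sample_delta_energy <- function(u, Tcut, Tmax) {
  if (!(Tcut > 0) || Tcut >= Tmax) stop("need 0 < Tcut < Tmax")
  stopifnot(all(u >= 0), all(u <= 1))
  Tcut * Tmax / (Tmax - u * (Tmax - Tcut))
}

#' Delta-ray emission angle from binary-encounter kinematics
#'
#' Non-relativistic free-electron ejection: \eqn{\cos^2\theta =
#' T_\delta/T_{max}}, measured from the ion direction. The hardest
#' knock-ons go forward, soft electrons are ejected near 90 degrees.
#'
#' @param T_delta delta-ray energy (keV); vectorised.
#' @param Tmax kinematic maximum (keV).
#' @return Emission polar angle in radians.
#' @export
delta_emission_angle <- function(T_delta, Tmax) {
  if (any(T_delta > Tmax)) stop("T_delta must not exceed Tmax")
  stopifnot(all(T_delta > 0))
  acos(sqrt(T_delta / Tmax))
}

#' Mean number of delta rays above threshold per unit path
#'
#' Close-collision (Rutherford) yield
#' \eqn{dN/dx = (K/2) z^2 (Z/A) \rho \beta^{-2} (1/T_{cut} - 1/T_{max})}.
#'
#' @inheritParams stopping_power
#' @param Tcut production threshold (keV).
#' @return Delta rays per cm.
#' @export
delta_yield <- function(T_per_u, species, material, Tcut) {
  kin <- .kinematics(T_per_u, species)
  tmax_kev <- tmax_delta(T_per_u, species) * 1e3
  if (Tcut >= tmax_kev) return(0)
  0.5 * .const$K_bethe * species$z^2 * (material$Z / material$A) *
    material$density / kin$beta2 * (1 / (Tcut * 1e-3) - 1 / (tmax_kev * 1e-3))
}

#' Bohr energy-loss straggling standard deviation for a path length
#'
#' Gaussian (Bohr) straggling with variance
#' \eqn{\Omega^2 = K m_e c^2 z^2 (Z/A) \rho \Delta x} (MeV^2).
#'
#' @inheritParams stopping_power
#' @param dx path length (cm).
#' @return Standard deviation of the energy loss over `dx`, in MeV.
#' @export
bohr_straggling_sigma <- function(species, material, dx) {
  sqrt(.const$K_bethe * .const$me_c2 * species$z^2 *
         (material$Z / material$A) * material$density * dx)
}

#' CSDA range by quadrature of the inverse stopping power
#'
#' Integrates `1/S(T)` from the 1 MeV/u validity floor up to `T_per_u`
#' (total kinetic energy basis, returning cm of path).
#'
#' @inheritParams stopping_power
#' @return Range in cm.
#' @export
csda_range <- function(T_per_u, species, material) {
  n_u <- max(species$mass_number, 1)
  vapply(T_per_u, function(Tu) {
    if (Tu <= 1) return(0)
    integrate(function(t) n_u / stopping_power(t, species, material),
              lower = 1, upper = Tu, rel.tol = 1e-9)$value
  }, numeric(1))
}

# Log-spaced energy/range tables handed to the compiled transport core.
.range_table <- function(species, material, T_top, n = 300L) {
  Tg <- exp(seq(log(1.0), log(T_top), length.out = n))
  n_u <- max(species$mass_number, 1)
  inv_s <- n_u / stopping_power(Tg, species, material)
  # cumulative trapezoid of 1/S dT
  dT <- diff(Tg)
  R <- c(0, cumsum(0.5 * (inv_s[-1] + inv_s[-n]) * dT))
  list(T = Tg, R = R)
}
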