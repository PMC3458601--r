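#' @useDynLib iontrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef dpois integrate lm residuals rexp rnorm
#'   runif setNames uniroot vcov
#' @importFrom utils modifyList write.table
NULL

.iontrack_env <- new.env(parent = emptyenv())

.material_table <- function() {
  if (is.null(.iontrack_env$materials)) {
    path <- system.file("extdata", "materials.yaml", package = "iontrack")
    tab <- yaml::read_yaml(path)
    .iontrack_env$materials <- tab$materials
  }
  .iontrack_env$materials
}

#' Construct a material
#'
#' A target medium is described by a single (effective) atomic species:
#' atomic number `Z`, molar mass `A`, mass density, mean excitation energy
#' `I` and radiation length `X0`. The electron density is derived as
#' `density * N_A * Z / A` and is therefore consistent by construction.
#'
#' @param name label for the material.
#' @param Z effective atomic number (dimensionless).
#' @param A atomic mass (g/mol).
#' @param density mass density (g/cm^3).
#' @param I mean excitation energy (eV).
#' @param X0 radiation length (g/cm^2).
#' @param reference_pressure_mbar for gases, the pressure at which `density`
#'   applies (used by [tepc_site_scaling()]); `NA` for condensed media.
#' @return An object of class `"material"`.
#' @export
material <- function(name, Z, A, density, I, X0,
                     reference_pressure_mbar = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(density > 0)) stop("material density must be > 0")
  if (!(I > 0)) stop("material mean excitation energy I must be > 0")
  if (!(X0 > 0)) stop("material radiation length X0 must be > 0")
  if (!(Z > 0 && A > 0)) stop("material Z and A must be > 0")
  m <- list(
    name = name, Z = Z, A = A, density = density, I = I, X0 = X0,
    reference_pressure_mbar = reference_pressure_mbar,
    electron_density = density * .const$N_A * Z / A,
    n_atoms = density * .const$N_A / A
  )
  class(m) <- "material"
  m
}

#' Look up a built-in material
#'
#' Built-in media: `water`, `beryllium`, `carbon` (graphite), `te-gas`
#' (propane-based tissue-equivalent gas at standard pressure) and `air`.
#' Entries come from a versioned YAML table shipped with the package; use
#' [material()] to build custom media or override constants.
#'
#' @param name one of the built-in material names.
#' @return A `"material"` object (immutable constants).
#' @examples
#' get_material("water")$density # 1 g/cm^3
#' @export
get_material <- function(name) {
  tab <- .material_table()
  if (!name %in% names(tab)) {
    stop(sprintf("unknown material '%s'; available: %s",
                 name, paste(names(tab), collapse = ", ")))
  }
  e <- tab[[name]]
  material(name, Z = e$Z, A = e$A, density = e$density, I = e$I, X0 = e$X0,
           reference_pressure_mbar = e$reference_pressure_mbar %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: Z=%.3f A=%.3f g/mol rho=%.4g g/cm^3 I=%.1f eV X0=%.2f g/cm^2\n",
              x$name, x$Z, x$A, x$density, x$I, x$X0))
  invisible(x)
}

.species_table <- list(
  proton   = list(z = 1, mass_number = 1,  rest_mass = 938.27208816),
  helium   = list(z = 2, mass_number = 4,  rest_mass = 4 * 931.49410242),
  carbon   = list(z = 6, mass_number = 12, rest_mass = 12 * 931.49410242),
  oxygen   = list(z = 8, mass_number = 16, rest_mass = 16 * 931.49410242),
  electron = list(z = 1, mass_number = 0,  rest_mass = 0.51099895)
)

#' Construct a projectile species
#'
#' @param name one of `proton`, `helium`, `carbon`, `oxygen`, `electron`,
#'   or any label when the remaining arguments are given explicitly.
#' @param z charge number (>= 1 for ions).
#' @param mass_number nucleon number (0 for the electron).
#' @param rest_mass rest energy in MeV.
#' @return An object of class `"species"`.
#' @examples
#' species("carbon")
#' @export
species <- function(name, z = NULL, mass_number = NULL, rest_mass = NULL) {
  if (is.null(z)) {
    if (!name %in% names(.species_table)) {
      stop(sprintf("unknown species '%s'; available: %s (or give z, mass_number, rest_mass)",
                   name, paste(names(.species_table), collapse = ", ")))
    }
    e <- .species_table[[name]]
    z <- e$z; mass_number <- e$mass_number; rest_mass <- e$rest_mass
  }
  if (z < 1) stop("species charge number z must be >= 1")
  if (!(rest_mass > 0)) stop("species rest mass must be > 0")
  s <- list(name = name, z = z, mass_number = mass_number, rest_mass = rest_mass)
  class(s) <- "species"
  s
}

#' @export
print.species <- function(x, ...) {
  cat(sprintf("<species> %s: z=%d A=%g m=%.3f MeV\n",
              x$name, as.integer(x$z), x$mass_number, x$rest_mass))
  invisible(x)
}

# Relativistic kinematics from kinetic energy per nucleon.
# For ions the per-nucleon rest energy is rest_mass / mass_number; for the
# proton this is its true rest energy. Returns beta, gamma, and pc (total
# momentum, MeV/c).
.kinematics <- function(T_per_u, sp) {
  m_u <- if (sp$mass_number > 0) sp$rest_mass / sp$mass_number else sp$rest_mass
  n_u <- max(sp$mass_number, 1)
  gamma <- 1 + T_per_u / m_u
  beta2 <- 1 - 1 / gamma^2
  beta <- sqrt(beta2)
  pc <- gamma * beta * m_u * n_u
  list(beta = beta, beta2 = beta2, gamma = gamma, pc = pc)
}
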