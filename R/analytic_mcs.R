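#' Highland multiple-Coulomb-scattering width
#'
#' Parameterized approximation to Moliere theory for the Gaussian core of
#' the projected scattering-angle distribution:
#' \deqn{\theta_0 = \frac{14.1\,\mathrm{MeV}}{p \beta c}\, z
#'   \sqrt{x/X_0}\,\left[1 + \tfrac19 \log_{10}(x/X_0)\right]}
#' evaluated once for the whole thickness (single-evaluation form, the
#' variant matching the original parameterization). The result carries a
#' `validity` attribute flagging `x/X0` outside the formula's stated range
#' (1e-3 to 100 radiation lengths).
#'
#' @param T kinetic energy in MeV (total, not per nucleon).
#' @param species a [species()] object.
#' @param x traversed thickness in cm (> 0).
#' @param material a [material()] object or name.
#' @return Projected-angle Gaussian width in degrees.
#' @examples
#' highland_width(158.6, species("proton"), 0.66, "beryllium") # ~0.30 deg
#' @export
highland_width <- function(T, species, x, material) {
  if (is.character(material)) material <- get_material(material)
  if (!(x > 0)) stop("thickness x must be > 0")
  T_per_u <- T / max(species$mass_number, 1)
  kin <- .kinematics(T_per_u, species)
  x_over_X0 <- x * material$density / material$X0
  theta0 <- 14.1 / (kin$pc * kin$beta) * species$z * sqrt(x_over_X0) *
    (1 + log10(x_over_X0) / 9)
  out <- theta0 * 180 / pi
  attr(out, "x_over_X0") <- x_over_X0
  attr(out, "validity") <- if (x_over_X0 < 1e-3 || x_over_X0 > 100) {
    "x/X0 outside the parameterization's stated validity (1e-3 .. 100)"
  } else "ok"
  out
}

#' Fit a Gaussian to the core of an angular histogram
#'
#' Least-squares fit of `A exp(-theta^2 / (2 sigma^2))` to the histogram
#' counts, restricted to the central core `|theta| <= 2.5 sigma_robust`
#' where `sigma_robust` is an interquartile-range width estimate; the
#' range is re-derived once from the first fit. Restricting to the core
#' excludes the single-scattering (Rutherford) tail, the convention used
#' in proton scattering benchmarks.
#'
#' @param hist an [score_projected_angles()] histogram.
#' @param core_factor half-width of the fit range in units of the robust
#'   width estimate.
#' @return An object of class `"gaussian_fit"`: `width` and
#'   `width_uncertainty` (degrees, covariance-based), `fit_range`
#'   (degrees), `chi2_per_dof`, and the `fit` object.
#' @export
fit_gaussian_core <- function(hist, core_factor = 2.5) {
  e <- hist$bin_edges
  centers <- (e[-length(e)] + e[-1]) / 2
  counts <- hist$counts

  # robust width from histogram quantiles
  cum <- cumsum(counts) / sum(counts)
  qf <- function(p) {
    i <- which(cum >= p)[1]
    lo <- if (i == 1) 0 else cum[i - 1]
    e[i] + (p - lo) / (cum[i] - lo) * (e[i + 1] - e[i])
  }
  sigma0 <- (qf(0.75) - qf(0.25)) / 1.349
  if (!(sigma0 > 0)) stop("degenerate histogram: cannot estimate a width")

  fit_once <- function(sig) {
    keep <- abs(centers) <= core_factor * sig & counts > 0
    if (sum(keep) < 10) {
      stop("fewer than 10 non-empty bins in the fit range; widen the binning")
    }
    th <- centers[keep]; ct <- counts[keep]
    fit <- minpack.lm::nlsLM(
      ct ~ A * exp(-th^2 / (2 * s^2)),
      start = list(A = max(ct), s = sig),
      weights = 1 / pmax(ct, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(fit = fit, n = sum(keep))
  }
  f1 <- fit_once(sigma0)
  s1 <- abs(coef(f1$fit)[["s"]])
  f2 <- fit_once(s1)

  co <- coef(f2$fit)
  s_hat <- abs(co[["s"]])
  se <- tryCatch(sqrt(diag(vcov(f2$fit)))[["s"]], error = function(e) NA_real_)
  res <- residuals(f2$fit)
  # Pearson chi2 with Poisson variance
  keep <- abs(centers) <= core_factor * s_hat & counts > 0
  pred <- co[["A"]] * exp(-centers[keep]^2 / (2 * s_hat^2))
  chi2 <- sum((counts[keep] - pred)^2 / pmax(pred, 1))
  dof <- max(f2$n - 2, 1)
  out <- list(width = s_hat, width_uncertainty = se,
              fit_range = core_factor * s_hat,
              chi2_per_dof = chi2 / dof, fit = f2$fit)
  class(out) <- "gaussian_fit"
  out
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> width = (%.4f +/- %.4f) deg, |theta| <= %.3f deg, chi2/dof = %.2f\n",
              x$width, x$width_uncertainty, x$fit_range, x$chi2_per_dof))
  invisible(x)
}
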