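#' Spherical tissue-equivalent site
#'
#' @param tissue_diameter_um site diameter at tissue density (um).
#' @param material site medium (defaults to water as the tissue surrogate).
#' @return Object of class `"spherical_site"` with the mean chord length
#'   `2d/3` of a sphere.
#' @export
spherical_site <- function(tissue_diameter_um, material = get_material("water")) {
  if (!(tissue_diameter_um > 0)) stop("site diameter must be positive")
  s <- list(tissue_diameter_um = tissue_diameter_um, material = material,
            mean_chord_um = 2 * tissue_diameter_um / 3)
  class(s) <- "spherical_site"
  s
}

#' Mean chord length of a convex body
#'
#' Cauchy's formula `<l> = 4 V / S` for isotropic uniform random chords
#' through a convex body; specializes to `2d/3` for a sphere.
#'
#' @param body a [spherical_site()], or a list with `kind = "sphere"`
#'   (field `diameter`) or `kind = "cylinder"` (fields `diameter`,
#'   `height`). Units are preserved.
#' @return Mean chord length.
#' @export
mean_chord <- function(body) {
  if (inherits(body, "spherical_site")) {
    return(2 * body$tissue_diameter_um / 3)
  }
  kind <- body$kind %||% stop("body must have a 'kind'")
  if (identical(kind, "sphere")) {
    d <- body$diameter
    if (!(d > 0)) stop("positive dimensions required")
    2 * d / 3
  } else if (identical(kind, "cylinder")) {
    d <- body$diameter; h <- body$height
    if (!(d > 0 && h > 0)) stop("positive dimensions required")
    V <- pi * d^2 / 4 * h
    S <- pi * d * h + pi * d^2 / 2
    4 * V / S
  } else {
    stop(sprintf("unsupported (non-convex or unknown) body kind '%s'", kind))
  }
}

#' Tissue-equivalent site diameter of a TEPC gas cavity
#'
#' A low-pressure tissue-equivalent proportional counter emulates a
#' micrometer tissue site: `d_tissue = d_cavity * rho_gas(P) / rho_tissue`
#' with ideal-gas density scaling from the gas's reference density. A
#' 12.7 mm cavity of propane-based TE gas at 120 mbar corresponds to about
#' 2.7 um of tissue.
#'
#' @param cavity_diameter_mm physical cavity diameter (mm).
#' @param gas a gas [material()] carrying `reference_pressure_mbar`.
#' @param pressure_mbar operating gas pressure (>= 0).
#' @param tissue_density_g_cm3 tissue density (default 1).
#' @return Tissue-equivalent diameter in um.
#' @export
tepc_site_scaling <- function(cavity_diameter_mm = 12.7,
                              gas = get_material("te-gas"),
                              pressure_mbar,
                              tissue_density_g_cm3 = 1) {
  if (pressure_mbar < 0) stop("pressure must be >= 0")
  if (is.na(gas$reference_pressure_mbar)) {
    stop("gas material must carry a reference_pressure_mbar")
  }
  rho_gas <- gas$density * pressure_mbar / gas$reference_pressure_mbar
  cavity_diameter_mm * 1e3 * rho_gas / tissue_density_g_cm3 # mm -> um
}

#' Collect single-event energy depositions in a spherical site
#'
#' Groups deposits by primary (`event_id`): all deposits of one primary
#' and its delta rays falling inside the site form one microdosimetric
#' event with energy imparted `epsilon` and lineal energy
#' `y = epsilon / <l>`. Primaries that deposit nothing in the site are not
#' events.
#'
#' @param bundle a [run_beam()] track bundle, or a deposit data frame.
#' @param site a [spherical_site()].
#' @param center site centre `c(x, y, z)` in cm.
#' @return Data frame of events: `event_id`, `epsilon_kev`, `y_kev_um`,
#'   `source` (`primary_ion`, `delta_electron`, or `mixed`).
#' @export
collect_site_events <- function(bundle, site, center) {
  dep <- if (is.data.frame(bundle)) bundle else bundle$deposits
  if (nrow(dep) == 0) return(.empty_events())
  r_cm <- site$tissue_diameter_um / 2 * 1e-4
  inside <- (dep$x - center[1])^2 + (dep$y - center[2])^2 +
    (dep$z - center[3])^2 <= r_cm^2
  dep <- dep[inside, , drop = FALSE]
  if (nrow(dep) == 0) return(.empty_events())
  eps <- rowsum(dep$amount, dep$event_id)
  is_primary <- rowsum(as.numeric(dep$source == "primary_ion"), dep$event_id) > 0
  is_delta <- rowsum(as.numeric(dep$source == "delta_electron"), dep$event_id) > 0
  src <- ifelse(is_primary & is_delta, "mixed",
                ifelse(is_primary, "primary_ion", "delta_electron"))
  data.frame(event_id = as.integer(rownames(eps)),
             epsilon_kev = as.numeric(eps),
             y_kev_um = as.numeric(eps) / site$mean_chord_um,
             source = as.character(src))
}

.empty_events <- function() {
  data.frame(event_id = integer(0), epsilon_kev = numeric(0),
             y_kev_um = numeric(0), source = character(0))
}

#' Build a microdosimetric spectrum from events
#'
#' Frequency density `f(y)`, dose density `d(y) = y f(y) / y_F`, and the
#' dose-weighted display values `y d(y)` per logarithmic interval (the
#' semi-log convention in which equal areas carry equal dose). The
#' frequency- and dose-mean lineal energies `y_F` and `y_D` are computed
#' from the event list, not from the binned spectrum.
#'
#' @param events event data frame from [collect_site_events()], or a
#'   numeric vector of `y` values.
#' @param bins_per_decade logarithmic bin density (default 40).
#' @param y_range_kev_um spectrum range in keV/um.
#' @return An object of class `"microdose_spectrum"`.
#' @export
build_spectrum <- function(events, bins_per_decade = 40,
                           y_range_kev_um = c(0.01, 1000)) {
  y <- if (is.data.frame(events)) events$y_kev_um else as.numeric(events)
  if (length(y) < 1) stop("at least one event is required")
  stopifnot(all(y > 0))
  nb <- ceiling(bins_per_decade * log10(y_range_kev_um[2] / y_range_kev_um[1]))
  edges <- y_range_kev_um[1] * 10^(seq(0, nb) / bins_per_decade)
  idx <- findInterval(y, edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= nb
  counts <- tabulate(idx[inside], nbins = nb)
  dy <- diff(edges)
  y_F <- mean(y)
  y_D <- sum(y^2) / sum(y)
  f_y <- counts / length(y) / dy
  ymid <- sqrt(edges[-length(edges)] * edges[-1])
  # normalize the dose density with the binned first moment so that the
  # closure integral(d(y) dy) = 1 holds exactly; y_F and y_D themselves are
  # reported from the event list, not from binned values
  y_F_binned <- sum(ymid * f_y * dy)
  d_y <- ymid * f_y / y_F_binned
  sp <- list(log_bin_edges = edges, counts = counts, f_y = f_y, d_y = d_y,
             yd_y = ymid * d_y, y_mid = ymid, y_F = y_F, y_D = y_D,
             n_events = length(y),
             events = if (is.data.frame(events)) events else NULL)
  class(sp) <- "microdose_spectrum"
  sp
}

#' @export
print.microdose_spectrum <- function(x, ...) {
  cat(sprintf("<microdose_spectrum> %d events, y_F = %.3g, y_D = %.3g keV/um\n",
              x$n_events, x$y_F, x$y_D))
  invisible(x)
}

#' Mode of the dose-weighted spectrum
#'
#' Position of the maximum of `y d(y)`, optionally restricted to events of
#' one source component (requires the spectrum to have been built from an
#' event data frame). Ties break toward lower y; the returned position is
#' the geometric centre of the winning bin.
#'
#' @param spectrum a [build_spectrum()] result.
#' @param component `"all"`, `"primary_ion"`, `"delta_electron"`, or
#'   `"mixed"`.
#' @return Mode position in keV/um.
#' @export
spectrum_mode <- function(spectrum, component = "all") {
  if (component != "all") {
    ev <- spectrum$events
    if (is.null(ev)) stop("component selection requires an event-based spectrum")
    ev <- ev[ev$source == component, , drop = FALSE]
    if (nrow(ev) == 0) stop(sprintf("no events with source '%s'", component))
    spectrum <- build_spectrum(ev,
                               bins_per_decade = round(1 / log10(spectrum$log_bin_edges[2] /
                                                                   spectrum$log_bin_edges[1])),
                               y_range_kev_um = range(spectrum$log_bin_edges))
  }
  spectrum$y_mid[which.max(spectrum$yd_y)]
}

#' Poisson fluence-to-hit statistics
#'
#' For a particle fluence and a target cross-sectional area the number of
#' traversals per target is Poisson with mean `m = fluence * area`. Used
#' to ask, e.g., what fraction of cell nuclei see no ion hit ("streak") at
#' a given fluence.
#'
#' @param fluence_cm2 particle fluence (ions/cm^2, >= 0).
#' @param area_um2 target cross-sectional area (um^2, > 0).
#' @param k_max largest hit multiplicity reported individually.
#' @return List with `mean_hits`, `p_zero`, and `p_k` (named vector for
#'   k = 0..k_max).
#' @examples
#' poisson_hit_stats(3e6, 100)$p_zero # e^-3, just under 5%
#' @export
poisson_hit_stats <- function(fluence_cm2, area_um2, k_max = 10) {
  if (fluence_cm2 < 0) stop("fluence must be >= 0")
  if (!(area_um2 > 0)) stop("area must be > 0")
  m <- fluence_cm2 * area_um2 * 1e-8  # um^2 -> cm^2
  k <- 0:k_max
  list(mean_hits = m, p_zero = exp(-m),
       p_k = setNames(stats::dpois(k, m), paste0("k", k)))
}
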