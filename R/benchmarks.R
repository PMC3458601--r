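#' Proton multiple-scattering benchmark (Gottschalk configuration)
#'
#' Transports 158.6 MeV protons through a thin slab with discrete
#' screened-Rutherford elastic scattering, histograms the projected exit
#' angles in 0.03 degree bins, fits the Gaussian core, and compares with
#' Highland's analytic width and with Gottschalk's measured widths
#' (0.30 degrees for 0.66 cm beryllium, 0.26 degrees for 0.30 cm carbon).
#'
#' @param target `"beryllium"` (0.66 cm) or `"carbon"` (0.30 cm), or a
#'   list with `material` and `thickness_cm` for a custom slab.
#' @param n_primaries number of protons (default 2e4).
#' @param seed master seed.
#' @param T_mev beam kinetic energy (MeV).
#' @param bin_width_deg angular bin width.
#' @param theta_min_deg discrete-collision cutoff.
#' @return List with the fitted `"gaussian_fit"`, the Highland width, the
#'   measured reference width, and the histogram.
#' @export
gottschalk_benchmark <- function(target = "beryllium", n_primaries = 2e4,
                                 seed = 1, T_mev = 158.6,
                                 bin_width_deg = 0.03, theta_min_deg = 0.001) {
  presets <- list(
    beryllium = list(material = "beryllium", thickness_cm = 0.66,
                     measured_deg = 0.30, measured_unc_deg = 0.01),
    carbon = list(material = "carbon", thickness_cm = 0.30,
                  measured_deg = 0.26, measured_unc_deg = 0.01))
  tgt <- if (is.character(target)) {
    if (!target %in% names(presets)) {
      stop("target must be 'beryllium', 'carbon', or a custom list")
    }
    presets[[target]]
  } else target
  sp <- species("proton")
  geom <- geometry_slab(tgt$material, tgt$thickness_cm)
  phys <- physics_config(elastic_scattering = TRUE,
                         theta_min_deg = theta_min_deg,
                         straggling = TRUE, delta_transport = FALSE)
  bundle <- run_beam(list(species = sp, T_per_u = T_mev,
                          n_primaries = n_primaries, seed = seed),
                     geom, phys, scoring = list(store_deposits = FALSE))
  hist <- score_projected_angles(bundle$exits, bin_width_deg)
  fit <- fit_gaussian_core(hist)
  hl <- highland_width(T_mev, sp, tgt$thickness_cm, geom$material)
  list(fit = fit, histogram = hist,
       highland_deg = as.numeric(hl),
       measured_deg = tgt$measured_deg %||% NA_real_,
       measured_unc_deg = tgt$measured_unc_deg %||% NA_real_,
       bundle_exits = bundle$exits)
}

#' Radial dose of a slow ion track, with and without elastic scattering
#'
#' Runs paired beams (identical random sub-streams) of a low-energy ion
#' through a micrometer water slab with full delta-electron transport, and
#' scores the radial dose profile for both physics settings. The elastic
#' deflection of the primary moves its ionization pattern off the axis on
#' the nanometer scale, which lowers the dose in the track core.
#'
#' @param species_name primary ion (default oxygen).
#' @param T_per_u beam energy (default 2.57 MeV/u).
#' @param thickness_um water slab thickness (default 1 um).
#' @param n_primaries total primaries per physics setting.
#' @param seed master seed (shared by both settings).
#' @param tcut_kev delta production threshold; 0.5 keV resolves the
#'   nanometer penumbra.
#' @param core_radius_nm radius of the "track core" used for the paired
#'   per-primary core-energy comparison.
#' @param batch_size primaries per scoring batch (bounds memory).
#' @return List with `profile_on`, `profile_off` (radial dose profiles),
#'   and `core_kev_on`, `core_kev_off` (per-primary core energies, paired
#'   by seed).
#' @export
radial_dose_study <- function(species_name = "oxygen", T_per_u = 2.57,
                              thickness_um = 1, n_primaries = 1000, seed = 1,
                              tcut_kev = 0.5, core_radius_nm = 1,
                              batch_size = 100) {
  sp <- species(species_name)
  geom <- geometry_slab("water", thickness_um * 1e-4)
  shells <- radial_shells()
  run_setting <- function(elastic_on) {
    phys <- physics_config(elastic_scattering = elastic_on,
                           tcut_kev = tcut_kev,
                           max_substep_cm = 1e-7, min_substep_cm = 1e-9,
                           straggling = TRUE, delta_transport = TRUE,
                           delta_max_points = 64L)
    energy <- numeric(length(shells) - 1)
    core <- numeric(0)
    done <- 0
    while (done < n_primaries) {
      nb <- min(batch_size, n_primaries - done)
      bundle <- run_beam(list(species = sp, T_per_u = T_per_u,
                              n_primaries = nb, seed = seed + done),
                         geom, phys)
      prof <- radial_dose(bundle$deposits, shells,
                          slab_length_cm = geom$thickness_cm,
                          density_g_cm3 = geom$material$density)
      energy <- energy + prof$energy_kev
      dep <- bundle$deposits
      r_nm <- sqrt(dep$x^2 + dep$y^2) * 1e7
      core_batch <- vapply(seq_len(nb), function(i) {
        sum(dep$amount[dep$event_id == i & r_nm < core_radius_nm])
      }, numeric(1))
      core <- c(core, core_batch)
      done <- done + nb
    }
    prof$energy_kev <- energy
    prof$dose_gy <- energy * .const$gy_per_kev_per_g / prof$shell_mass_g
    list(profile = prof, core = core)
  }
  on <- run_setting(TRUE)
  off <- run_setting(FALSE)
  list(profile_on = on$profile, profile_off = off$profile,
       core_kev_on = on$core, core_kev_off = off$core)
}

#' Lineal-energy spectrum at the Bragg peak of a carbon beam
#'
#' Two-phase protocol for the primary-ion component of a TEPC spectrum in
#' a water phantom: (1) transport the pencil beam with CSDA energy loss
#' and Bohr straggling, tally the depth-dose curve, and locate its
#' maximum; (2) re-run with a spherical tissue-equivalent site on the axis
#' at that depth, transporting delta electrons in a window around the site
#' (elsewhere their energy deposits locally, which cannot affect the
#' site), and collect one energy-imparted event per traversing primary.
#' Lineal energies use the 2d/3 mean chord of the sphere.
#'
#' @param n_primaries primaries per phase (default 1e4).
#' @param seed master seed.
#' @param species_name,T_per_u beam (default 300 MeV/u carbon).
#' @param site_diameter_um tissue-equivalent site diameter (default 2.7).
#' @param depth_bin_cm depth-dose bin width for peak finding.
#' @param bins_per_decade spectrum binning.
#' @return List with the event table, the `"microdose_spectrum"`, the
#'   `yd(y)` mode (keV/um), the Bragg depth (cm), and the depth-dose
#'   curve.
#' @export
tepc_bragg_spectrum <- function(n_primaries = 1e4, seed = 1,
                                species_name = "carbon", T_per_u = 300,
                                site_diameter_um = 2.7, depth_bin_cm = 0.02,
                                bins_per_decade = 40) {
  sp <- species(species_name)
  range_cm <- csda_range(T_per_u, sp, get_material("water"))
  thick <- 1.15 * range_cm
  geom <- geometry_slab("water", thick)
  nbin <- ceiling(thick / depth_bin_cm)

  # phase 1: depth-dose tally, local delta deposition
  phys1 <- physics_config(elastic_scattering = FALSE, straggling = TRUE,
                          delta_transport = FALSE)
  b1 <- run_beam(list(species = sp, T_per_u = T_per_u,
                      n_primaries = n_primaries, seed = seed),
                 geom, phys1,
                 scoring = list(store_deposits = FALSE,
                                depth_edges = c(0, depth_bin_cm, nbin)))
  depth_kev <- b1$depth_kev
  peak_bin <- which.max(depth_kev)
  z_peak <- (peak_bin - 0.5) * depth_bin_cm

  # phase 2: site scoring with windowed delta transport
  site <- spherical_site(site_diameter_um)
  r_cm <- site_diameter_um / 2 * 1e-4
  delta_win <- z_peak + c(-60e-4, 60e-4)       # +/- 60 um
  fine_win <- c(z_peak - 3 * 2 * r_cm, z_peak + 3 * 2 * r_cm, 5e-6)
  phys2 <- physics_config(elastic_scattering = FALSE, straggling = TRUE,
                          delta_transport = TRUE,
                          delta_window_z_cm = delta_win,
                          fine_window_z_cm = fine_win,
                          delta_max_points = 64L,
                          delta_point_spacing_cm = 5e-6)
  b2 <- run_beam(list(species = sp, T_per_u = T_per_u,
                      n_primaries = n_primaries, seed = seed),
                 geom, phys2,
                 scoring = list(store_deposits = TRUE,
                                store_zlim = z_peak + c(-2 * r_cm, 2 * r_cm) * 2,
                                store_sphere = c(0, 0, z_peak, r_cm)))
  events <- collect_site_events(b2, site, center = c(0, 0, z_peak))
  if (nrow(events) == 0) stop("no primary deposited energy in the site")
  spec <- build_spectrum(events, bins_per_decade = bins_per_decade)
  list(events = events, spectrum = spec,
       mode_kev_um = spectrum_mode(spec),
       z_peak_cm = z_peak, range_cm = range_cm,
       depth_dose = list(edges_cm = seq(0, nbin) * depth_bin_cm,
                         dose_kev = depth_kev))
}

#' Convergence check for the discrete-collision cutoff
#'
#' The elastic single-scattering cutoff `theta_min` splits discrete
#' collisions from ignored sub-cutoff deflections and is the one numerical
#' parameter of the multiple-scattering model. This check re-runs a
#' scattering benchmark with the cutoff halved and reports the change of
#' the fitted core width in units of the combined fit uncertainty: a
#' converged cutoff changes the width by an amount consistent with noise.
#'
#' @param target benchmark target (see [gottschalk_benchmark()]).
#' @param n_primaries protons per run.
#' @param seed master seed (shared between the two runs).
#' @param theta_min_deg cutoff to validate.
#' @return List with both fits, the width difference, and
#'   `delta_over_sigma`, the difference over the combined uncertainty.
#' @export
theta_min_convergence <- function(target = "beryllium", n_primaries = 6000,
                                  seed = 1, theta_min_deg = 0.001) {
  b1 <- gottschalk_benchmark(target, n_primaries, seed,
                             theta_min_deg = theta_min_deg)
  b2 <- gottschalk_benchmark(target, n_primaries, seed,
                             theta_min_deg = theta_min_deg / 2)
  d <- b2$fit$width - b1$fit$width
  sig <- sqrt(b1$fit$width_uncertainty^2 + b2$fit$width_uncertainty^2)
  list(fit = b1$fit, fit_halved = b2$fit, delta_deg = d,
       delta_over_sigma = abs(d) / sig)
}
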