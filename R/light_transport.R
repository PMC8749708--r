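#' Optical properties of a medium at one wavelength
#'
#' @param mu_a absorption coefficient (1/cm).
#' @param mu_s_prime reduced scattering coefficient (1/cm).
#' @param g scattering anisotropy, in (-1, 1). The scattering coefficient
#'   used by the Monte Carlo is `mu_s = mu_s_prime / (1 - g)`.
#' @param wavelength_nm wavelength (nm).
#' @return An object of class `pali_optics`.
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.9, wavelength_nm) {
  stopifnot(mu_a >= 0, mu_s_prime >= 0, g > -1, g < 1, wavelength_nm > 0)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g,
                 wavelength_nm = wavelength_nm),
            class = "pali_optics")
}

#' Effective attenuation coefficient (diffusion theory)
#'
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s_prime))`, the asymptotic exponential
#' decay rate of fluence with depth in a diffusive medium.
#'
#' @param mu_a absorption coefficient (1/cm).
#' @param mu_s_prime reduced scattering coefficient (1/cm).
#' @return Effective attenuation (1/cm).
#' @export
mu_eff <- function(mu_a, mu_s_prime) {
  stopifnot(all(mu_a >= 0), all(mu_s_prime >= 0))
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Neck-tissue optical properties at the pump and probe wavelengths
#'
#' mu_a = 0.22 / 0.235 1/cm and mu_s' = 9.1 / 7.3 1/cm at 660 / 830 nm.
#'
#' @param g scattering anisotropy (default 0.9).
#' @return Named list with `pump` and `probe` `pali_optics` entries.
#' @export
neck_tissue_optics <- function(g = 0.9) {
  list(pump  = optical_properties(0.22, 9.1, g, 660),
       probe = optical_properties(0.235, 7.3, g, 830))
}

#' Pulsed illumination beam
#'
#' Circular flat-top beam normal to the phantom surface.
#'
#' @param radius_mm beam radius (mm).
#' @param pulse_fluence_mJcm2 surface pulse fluence (mJ/cm^2).
#' @param wavelength_nm wavelength (nm).
#' @param pulse_duration_s pulse duration (s).
#' @return An object of class `pali_beam`.
#' @export
beam_spec <- function(radius_mm = 5, pulse_fluence_mJcm2, wavelength_nm,
                      pulse_duration_s = 5e-9) {
  stopifnot(radius_mm > 0, pulse_fluence_mJcm2 > 0, wavelength_nm > 0,
            pulse_duration_s > 0)
  structure(list(radius_mm = radius_mm,
                 pulse_fluence_mJcm2 = pulse_fluence_mJcm2,
                 wavelength_nm = wavelength_nm,
                 pulse_duration_s = pulse_duration_s),
            class = "pali_beam")
}

#' Build a voxelized tissue phantom with an embedded dye-loaded node
#'
#' A rectangular grid of neck-tissue optical properties at the pump and probe
#' wavelengths, with a spherical node containing methylene blue centered on
#' the beam axis at a configurable depth. The node's pump-wavelength
#' absorption is raised by the ground-state monomer absorption
#' (`sigma_g * N_A * conc / 1000`) and its probe-wavelength absorption by the
#' ground-state extinction at the probe wavelength.
#'
#' @param depth_mm node center depth below the illuminated surface (mm).
#' @param node_radius_mm node radius (mm); 0 gives a homogeneous slab.
#' @param dye_conc_M total MB concentration in the node (M).
#' @param grid_mm grid extent c(x, y, z) in mm.
#' @param voxel_mm isotropic voxel size (mm).
#' @param optics list with `pump` and `probe` `pali_optics` (background).
#' @param photophys a `pali_photophysics` object for the dye constants.
#' @return An object of class `pali_phantom` with per-voxel absorption arrays
#'   `mua_pump` and `mua_probe` (1/cm), homogeneous scattering, node index
#'   vector `node_idx`, and grid metadata.
#' @export
build_phantom <- function(depth_mm, node_radius_mm = 3, dye_conc_M = 4e-4,
                          grid_mm = c(40, 40, 35), voxel_mm = 0.2,
                          optics = neck_tissue_optics(),
                          photophys = photophysics()) {
  stopifnot(voxel_mm > 0, node_radius_mm >= 0, depth_mm > 0,
            length(grid_mm) == 3)
  dims <- as.integer(round(grid_mm / voxel_mm))
  center <- c(grid_mm[1] / 2, grid_mm[2] / 2, depth_mm)
  if (node_radius_mm > 0) {
    if (depth_mm - node_radius_mm < 0 || depth_mm + node_radius_mm > grid_mm[3] ||
        center[1] - node_radius_mm < 0 || center[1] + node_radius_mm > grid_mm[1] ||
        center[2] - node_radius_mm < 0 || center[2] + node_radius_mm > grid_mm[2])
      stop("node extends outside the phantom grid")
  }

  mua_pump <- array(optics$pump$mu_a, dims)
  mua_probe <- array(optics$probe$mu_a, dims)

  node_idx <- integer(0)
  monomer_conc <- 0
  if (node_radius_mm > 0) {
    cx <- (seq_len(dims[1]) - 0.5) * voxel_mm
    cy <- (seq_len(dims[2]) - 0.5) * voxel_mm
    cz <- (seq_len(dims[3]) - 0.5) * voxel_mm
    d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, `+`),
                (cz - center[3])^2, `+`)
    node_idx <- which(d2 <= node_radius_mm^2)
    monomer_conc <- monomer_fraction(dye_conc_M, photophys$k_dim) * dye_conc_M
    # ground-state monomer absorption: cross-section to 1/cm
    mua_mb_pump <- photophys$sigma_g * .pali_const$avogadro * monomer_conc / 1000
    mua_mb_probe <- log(10) * photophys$eps_ground_probe * monomer_conc
    mua_pump[node_idx] <- mua_pump[node_idx] + mua_mb_pump
    mua_probe[node_idx] <- mua_probe[node_idx] + mua_mb_probe
  }

  structure(list(dims = dims, voxel_mm = voxel_mm, grid_mm = grid_mm,
                 center_mm = center, depth_mm = depth_mm,
                 node_radius_mm = node_radius_mm,
                 dye_conc_M = dye_conc_M, monomer_conc_M = monomer_conc,
                 node_idx = node_idx, optics = optics,
                 photophys = photophys,
                 mua_pump = mua_pump, mua_probe = mua_probe),
            class = "pali_phantom")
}

#' @export
print.pali_phantom <- function(x, ...) {
  cat(sprintf("PALI phantom: %d x %d x %d voxels (%.2g mm), node r=%.3g mm at depth %.3g mm, [MB]=%.3g M\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_mm,
              x$node_radius_mm, x$depth_mm, x$dye_conc_M))
  invisible(x)
}

#' Monte Carlo fluence simulation
#'
#' Photon-packet Monte Carlo with Henyey-Greenstein scattering,
#' continuous absorption weighting, index-matched boundaries and Russian
#' roulette. The returned map is normalized so that the launched energy
#' equals `pulse_fluence x beam area`; voxel values are fluence per pulse in
#' J/cm^2. Deterministic given `seed`.
#'
#' @param phantom a `pali_phantom`.
#' @param beam a `pali_beam`; its wavelength selects the pump or probe
#'   absorption map (matched against `phantom$optics`).
#' @param n_photons number of photon packets (>= 1e4).
#' @param seed integer RNG seed.
#' @param mua_override optional per-voxel absorption array (1/cm) replacing
#'   the phantom's map at this wavelength (used for the triplet-updated
#'   probe run).
#' @param roulette_threshold,roulette_survival Russian-roulette weight
#'   threshold and survival probability.
#' @return An object of class `pali_fluence` with `values` (J/cm^2 array),
#'   energy-balance tallies, and grid metadata.
#' @export
monte_carlo_fluence <- function(phantom, beam, n_photons = 1e5, seed = 1,
                                mua_override = NULL,
                                roulette_threshold = 1e-4,
                                roulette_survival = 0.1) {
  stopifnot(inherits(phantom, "pali_phantom"), inherits(beam, "pali_beam"),
            n_photons >= 1e4)
  wl <- beam$wavelength_nm
  if (wl == phantom$optics$pump$wavelength_nm) {
    opt <- phantom$optics$pump; mua <- phantom$mua_pump
  } else if (wl == phantom$optics$probe$wavelength_nm) {
    opt <- phantom$optics$probe; mua <- phantom$mua_probe
  } else stop("beam wavelength matches neither phantom wavelength")
  if (!is.null(mua_override)) {
    stopifnot(all(dim(mua_override) == phantom$dims))
    if (any(mua_override < 0)) stop("negative absorption in override map")
    mua <- mua_override
  }

  g <- opt$g
  mus <- opt$mu_s_prime / (1 - g)          # 1/cm
  mus_mm <- rep(mus / 10, length(mua))     # 1/mm per voxel
  mua_mm <- as.numeric(mua) / 10

  res <- mc_fluence_cpp(mua_mm, mus_mm, phantom$dims, phantom$voxel_mm, g,
                        beam$radius_mm, phantom$center_mm[1],
                        phantom$center_mm[2], as.integer(n_photons),
                        roulette_threshold, roulette_survival,
                        as.double(seed))

  area_cm2 <- pi * (beam$radius_mm / 10)^2
  e_photon_J <- beam$pulse_fluence_mJcm2 * 1e-3 * area_cm2 / n_photons
  v_cm3 <- (phantom$voxel_mm / 10)^3
  values <- array(res$track_mm / 10 / v_cm3 * e_photon_J, phantom$dims)

  structure(list(values = values, wavelength_nm = wl,
                 n_photons = n_photons, seed = seed,
                 voxel_mm = phantom$voxel_mm, dims = phantom$dims,
                 balance = res[c("launched", "absorbed", "escaped",
                                 "killed", "gained")]),
            class = "pali_fluence")
}

#' @export
print.pali_fluence <- function(x, ...) {
  cat(sprintf("Fluence map at %g nm: %d x %d x %d voxels, %g photons, seed %d\n",
              x$wavelength_nm, x$dims[1], x$dims[2], x$dims[3],
              x$n_photons, x$seed))
  invisible(x)
}

#' On-axis fluence depth profile
#'
#' Mean fluence within `radius_mm` of the beam axis, per depth slice. Used to
#' compare the Monte Carlo against the diffusion-theory slope `-mu_eff`.
#'
#' @param fluence a `pali_fluence`.
#' @param radius_mm lateral averaging radius around the axis (mm).
#' @return Data frame with `depth_mm` and `fluence` columns.
#' @export
axial_profile <- function(fluence, radius_mm = 2) {
  d <- fluence$dims; dv <- fluence$voxel_mm
  cx <- (seq_len(d[1]) - 0.5) * dv - d[1] * dv / 2
  cy <- (seq_len(d[2]) - 0.5) * dv - d[2] * dv / 2
  mask <- outer(cx^2, cy^2, `+`) <= radius_mm^2
  prof <- apply(fluence$values, 3, function(sl) mean(sl[mask]))
  data.frame(depth_mm = (seq_len(d[3]) - 0.5) * dv, fluence = prof)
}

#' Update the probe-wavelength absorption with a triplet population
#'
#' Returns a copy of the phantom whose probe absorption map inside the node
#' is raised by `ln(10) * eps_triplet * conc`, along with the pure triplet
#' contribution (needed to isolate the decaying part of the photoacoustic
#' signal).
#'
#' @param phantom a `pali_phantom`.
#' @param triplet_map per-voxel triplet concentration (M): either a full
#'   array or a vector over `phantom$node_idx`. Must be zero outside the
#'   node and non-negative.
#' @param eps_triplet triplet molar extinction (1/(M cm)); defaults to the
#'   phantom's photophysics.
#' @return The phantom with updated `mua_probe` and an added
#'   `mua_triplet` array (1/cm, the triplet-only contribution).
#' @export
update_probe_absorption <- function(phantom, triplet_map,
                                    eps_triplet = phantom$photophys$eps_triplet) {
  stopifnot(inherits(phantom, "pali_phantom"))
  if (is.array(triplet_map)) {
    stopifnot(all(dim(triplet_map) == phantom$dims))
    outside <- triplet_map
    outside[phantom$node_idx] <- 0
    if (any(outside != 0)) stop("triplet concentration nonzero outside node")
    tn <- triplet_map[phantom$node_idx]
  } else {
    stopifnot(length(triplet_map) == length(phantom$node_idx))
    tn <- triplet_map
  }
  if (any(tn < 0)) stop("negative triplet concentrations")
  mua_t <- array(0, phantom$dims)
  mua_t[phantom$node_idx] <- triplet_absorption_coeff(tn, eps_triplet)
  phantom$mua_triplet <- mua_t
  phantom$mua_probe <- phantom$mua_probe + mua_t
  phantom
}

#' Write / read a fluence map as plain text
#'
#' Long-format CSV (ix, iy, iz, fluence) for nonzero voxels plus a JSON
#' metadata sidecar with grid dimensions, wavelength, photon count and seed.
#'
#' @param fluence a `pali_fluence`.
#' @param path CSV output path (metadata written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_fluence <- function(fluence, path) {
  idx <- which(fluence$values != 0)
  ai <- arrayInd(idx, fluence$dims)
  df <- data.frame(ix = ai[, 1], iy = ai[, 2], iz = ai[, 3],
                   fluence = fluence$values[idx])
  write.csv(df, path, row.names = FALSE)
  meta <- fluence[c("wavelength_nm", "n_photons", "seed", "voxel_mm", "dims",
                    "balance")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fluence
#' @export
read_fluence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path)
  values <- array(0, meta$dims)
  values[cbind(df$ix, df$iy, df$iz)] <- df$fluence
  structure(list(values = values, wavelength_nm = meta$wavelength_nm,
                 n_photons = meta$n_photons, seed = meta$seed,
                 voxel_mm = meta$voxel_mm, dims = meta$dims,
                 balance = as.list(meta$balance)),
            class = "pali_fluence")
}
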