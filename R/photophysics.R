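#' Methylene-blue photophysical parameters
#'
#' Bundles the dye constants that drive triplet-state pumping and probing.
#' Defaults are literature-typical values for methylene blue (MB): triplet
#' quantum yield ~0.52, ground-state absorption cross-section at 660 nm
#' derived from a monomer molar extinction of ~95,000 1/(M cm), and a
#' triplet-triplet molar extinction at the 830 nm probe wavelength of
#' 1.4e4 1/(M cm). All are overridable here or via a YAML constants file
#' (see [load_photophysics()]).
#'
#' @param eta triplet quantum yield (dimensionless, in (0, 1]).
#' @param sigma_g ground-state absorption cross-section at the pump
#'   wavelength (cm^2 per molecule).
#' @param eps_triplet triplet-state molar extinction coefficient at the probe
#'   wavelength (1/(M cm), decadic).
#' @param eps_ground_probe ground-state molar extinction at the probe
#'   wavelength (1/(M cm)); contributes a non-decaying background absorption.
#' @param pump_pulse_s pump pulse duration in seconds (default 5 ns, typical
#'   of a Q-switched OPO).
#' @param k_dim monomer-dimer equilibrium constant (1/M). The default 2500
#'   1/M gives 50% monomers at a 400 uM total concentration.
#' @param total_conc_M total MB concentration in the node (M).
#' @return An object of class `pali_photophysics`.
#' @export
photophysics <- function(eta = 0.52,
                         sigma_g = 3.632e-16,
                         eps_triplet = 1.4e4,
                         eps_ground_probe = 500,
                         pump_pulse_s = 5e-9,
                         k_dim = 2500,
                         total_conc_M = 4e-4) {
  stopifnot(eta > 0, eta <= 1, sigma_g > 0, eps_triplet > 0,
            eps_ground_probe >= 0, pump_pulse_s > 0, k_dim >= 0,
            total_conc_M > 0)
  structure(list(eta = eta, sigma_g = sigma_g, eps_triplet = eps_triplet,
                 eps_ground_probe = eps_ground_probe,
                 pump_pulse_s = pump_pulse_s, k_dim = k_dim,
                 total_conc_M = total_conc_M),
            class = "pali_photophysics")
}

#' Load photophysical constants from a YAML file
#'
#' With `path = NULL` the packaged defaults file
#' (`system.file("extdata", "mb_constants.yaml", package = "pali")`) is read.
#' Fields missing from the file fall back to [photophysics()] defaults.
#'
#' @param path path to a YAML file, or `NULL` for the packaged defaults.
#' @return A `pali_photophysics` object.
#' @export
load_photophysics <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mb_constants.yaml", package = "pali")
  vals <- yaml::read_yaml(path)
  do.call(photophysics, vals[intersect(names(vals), names(formals(photophysics)))])
}

#' @export
print.pali_photophysics <- function(x, ...) {
  cat("Methylene-blue photophysics\n")
  cat(sprintf("  eta = %.3g  sigma_g = %.3g cm^2  eps_T = %.3g 1/(M cm)\n",
              x$eta, x$sigma_g, x$eps_triplet))
  cat(sprintf("  pump pulse = %.3g s  k_dim = %.3g 1/M  total [MB] = %.3g M\n",
              x$pump_pulse_s, x$k_dim, x$total_conc_M))
  invisible(x)
}

#' Triplet-state population after a square pump pulse
#'
#' Two-state pumping kinetics: ground-state molecules enter the triplet state
#' at rate `beta` and decay back at rate `alpha`, giving a triplet
#' concentration at the end of a pulse of duration `t` of
#' `nt = beta * n / (alpha + beta) * (1 - exp(-(alpha + beta) * t))`.
#'
#' @param beta pumping rate (1/s); may be a vector (e.g. per voxel).
#' @param n total photoactive (monomer) concentration (M).
#' @param alpha triplet decay rate (1/s).
#' @param t pulse duration (s).
#' @return Triplet concentration (M), same shape as `beta`; `0 <= nt < n`.
#' @export
triplet_population <- function(beta, n, alpha, t) {
  stopifnot(all(beta >= 0), all(n >= 0), all(alpha >= 0), all(t >= 0))
  k <- max(length(beta), length(n), length(alpha), length(t))
  beta <- rep_len(beta, k); n <- rep_len(n, k)
  alpha <- rep_len(alpha, k); t <- rep_len(t, k)
  s <- alpha + beta
  out <- numeric(k)
  pos <- s > 0 & t > 0
  out[pos] <- beta[pos] * n[pos] / s[pos] * (1 - exp(-s[pos] * t[pos]))
  out
}

#' Pumping rate from the local fluence rate
#'
#' `beta = eta * sigma_g * phi / (h * nu)`, with `phi` the fluence rate at the
#' pump wavelength and `nu = c / lambda` the photon frequency.
#'
#' @param params a `pali_photophysics` object.
#' @param fluence_rate fluence rate (W/cm^2); vectorized.
#' @param wavelength_nm pump wavelength (nm).
#' @return Pumping rate (1/s).
#' @export
pump_rate <- function(params, fluence_rate, wavelength_nm) {
  stopifnot(inherits(params, "pali_photophysics"),
            all(fluence_rate >= 0), wavelength_nm > 0)
  h_nu <- .pali_const$planck_J_s * .pali_const$c_light_m_s /
    (wavelength_nm * 1e-9)
  params$eta * params$sigma_g * fluence_rate / h_nu
}

#' Stern-Volmer calibration object
#'
#' Linear relation between the triplet decay rate and oxygen partial
#' pressure: `kt = kQ * pO2 + k0`.
#'
#' @param kQ quenching rate per unit oxygen partial pressure (1/(s mmHg)).
#' @param k0 oxygen-independent decay rate (1/s).
#' @return An object of class `pali_sv_cal`.
#' @export
stern_volmer_cal <- function(kQ, k0) {
  stopifnot(kQ > 0, k0 > 0)
  structure(list(kQ = kQ, k0 = k0), class = "pali_sv_cal")
}

#' Default Stern-Volmer calibration
#'
#' Derived from flash-photolysis decay rates of 6.05e5 1/s at 150 mmHg and
#' 1.84e4 1/s at 0 mmHg: `k0 = 1.84e4`, `kQ = (6.05e5 - 1.84e4)/150`.
#'
#' @return A `pali_sv_cal` object.
#' @export
default_stern_volmer <- function() {
  stern_volmer_cal(kQ = (6.05e5 - 1.84e4) / 150, k0 = 1.84e4)
}

#' @export
print.pali_sv_cal <- function(x, ...) {
  cat(sprintf("Stern-Volmer calibration: kt = %.4g * pO2 + %.4g 1/s\n",
              x$kQ, x$k0))
  invisible(x)
}

#' Triplet decay rate at a given oxygen partial pressure
#'
#' @param cal a `pali_sv_cal` object.
#' @param pO2 oxygen partial pressure (mmHg); vectorized.
#' @return Decay rate `kt = kQ * pO2 + k0` (1/s).
#' @export
stern_volmer_rate <- function(cal, pO2) {
  stopifnot(inherits(cal, "pali_sv_cal"), all(pO2 >= 0))
  cal$kQ * pO2 + cal$k0
}

#' Fit a Stern-Volmer calibration line
#'
#' Ordinary least-squares line through (pO2, kt) points; with exactly two
#' points this is exact interpolation.
#'
#' @param pO2 oxygen partial pressures (mmHg), at least 2 distinct values.
#' @param kt measured decay rates (1/s), same length.
#' @return A `pali_sv_cal` object.
#' @export
calibrate_stern_volmer <- function(pO2, kt) {
  stopifnot(length(pO2) == length(kt), length(pO2) >= 2)
  if (length(unique(pO2)) < 2)
    stop("degenerate calibration: all pO2 values identical")
  fit <- lm(kt ~ pO2)
  stern_volmer_cal(kQ = unname(coef(fit)[2]), k0 = unname(coef(fit)[1]))
}

#' Invert a decay rate to oxygen partial pressure
#'
#' `pO2 = (kt - k0)/kQ`. Rates below `k0` are physically impossible
#' (negative oxygen); they are clamped to 0 and flagged via the `"clamped"`
#' attribute.
#'
#' @param cal a `pali_sv_cal` object.
#' @param kt decay rate (1/s); vectorized.
#' @return Oxygen partial pressure (mmHg) with logical attribute `clamped`.
#' @export
invert_to_pO2 <- function(cal, kt) {
  stopifnot(inherits(cal, "pali_sv_cal"))
  p <- (kt - cal$k0) / cal$kQ
  clamped <- p < 0
  p[clamped] <- 0
  attr(p, "clamped") <- clamped
  p
}

#' Monomer fraction of the dye at equilibrium
#'
#' Monomer-dimer equilibrium `D = k_dim * m^2` with mass balance
#' `total = m + 2 D`, i.e. `2 k_dim m^2 + m - total = 0`. Solved in closed
#' form for the positive root.
#'
#' @param total_conc total dye concentration (M).
#' @param k_dim dimerization equilibrium constant (1/M).
#' @return Monomer fraction `m / total` in (0, 1].
#' @export
monomer_fraction <- function(total_conc, k_dim) {
  stopifnot(all(total_conc > 0), all(k_dim >= 0))
  m <- ifelse(k_dim == 0, total_conc,
              (-1 + sqrt(1 + 8 * k_dim * total_conc)) /
                (4 * ifelse(k_dim == 0, 1, k_dim)))
  m / total_conc
}

#' Absorption coefficient of the triplet state
#'
#' Converts a (decadic) molar extinction coefficient and concentration to a
#' natural absorption coefficient: `mu_a = ln(10) * eps * conc` (1/cm).
#' The ln(10) factor converts the conventional decadic extinction to the
#' natural (base-e) coefficient used by the light-transport and pressure
#' models.
#'
#' @param conc_triplet triplet concentration (M); vectorized.
#' @param eps_triplet molar extinction coefficient (1/(M cm), decadic).
#' @return Absorption coefficient (1/cm).
#' @export
triplet_absorption_coeff <- function(conc_triplet, eps_triplet) {
  stopifnot(all(conc_triplet >= 0), all(eps_triplet >= 0))
  log(10) * eps_triplet * conc_triplet
}

#' Simulate a flash-photolysis transmission transient
#'
#' A continuous-wave probe beam crosses a cuvette of path length `L`; an
#' initial triplet population `T0` decays at rate `kt`, so the probe
#' transmission recovers as
#' `T(t) = exp(-ln(10) * eps_T * T0 * exp(-kt t) * L)`.
#'
#' @param params a `pali_photophysics` object (supplies `eps_triplet`).
#' @param kt triplet decay rate (1/s).
#' @param path_length_cm probe path length through the sample (cm).
#' @param initial_triplet initial triplet concentration (M).
#' @param times_s sample times (s), sorted ascending.
#' @return Data frame with columns `time_s` and `transmission`.
#' @export
simulate_flash_photolysis <- function(params, kt, path_length_cm,
                                      initial_triplet, times_s) {
  stopifnot(inherits(params, "pali_photophysics"), path_length_cm > 0,
            initial_triplet >= 0, !is.unsorted(times_s))
  conc <- initial_triplet * exp(-kt * times_s)
  trans <- exp(-triplet_absorption_coeff(conc, params$eps_triplet) *
                 path_length_cm)
  data.frame(time_s = times_s, transmission = trans)
}

#' Read a flash-photolysis trace from CSV
#'
#' Expects columns `time_s` and `transmission`.
#'
#' @param path CSV path.
#' @return Data frame with columns `time_s`, `transmission`.
#' @export
read_flash_photolysis <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "transmission") %in% names(df)))
    stop("CSV must have columns time_s and transmission")
  df[order(df$time_s), c("time_s", "transmission")]
}
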