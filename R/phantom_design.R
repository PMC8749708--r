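#' Fit the effective attenuation of a dilution series
#'
#' Transmission through a fixed path `d` of a scattering/absorbing fluid at
#' fractional concentration `f` is modeled as a single decaying exponential
#' `T = exp(-mu_eff * d * f)` (an effective-attenuation approximation to
#' diffusive transport; this is the model the transmission data are fit to).
#' Fitting is done by ordinary least squares in log-transmission space, which
#' linearizes the model.
#'
#' @param fractions fractional concentrations (dimensionless, in [0, 1]).
#' @param transmission transmission fractions, each in (0, 1] (1 = the
#'   transmission through water).
#' @param d_cm fixed optical path length (cm), default 1 (cuvette).
#' @return Fitted `mu_eff` (1/cm).
#' @export
fit_attenuation <- function(fractions, transmission, d_cm = 1) {
  stopifnot(length(fractions) == length(transmission),
            length(fractions) >= 3, d_cm > 0)
  if (any(transmission > 1)) stop("transmission fractions above 1")
  if (any(transmission <= 0)) stop("transmission fractions must be positive")
  slope <- unname(coef(lm(log(transmission) ~ 0 + fractions))[1])
  max(-slope / d_cm, 0)
}

#' Design an Intralipid / India-ink tissue-mimicking mixture
#'
#' Given per-unit-fraction coefficients measured for the two stocks
#' (Intralipid scattering, ink absorption; the ink's scattering and the
#' Intralipid's absorption are assumed negligible), the required fractional
#' concentrations are simply `target / per-fraction coefficient`,
#' independently for each component.
#'
#' @param target_mu_a target absorption (1/cm).
#' @param target_mu_s_prime target reduced scattering (1/cm).
#' @param scatter_coeff_per_fraction Intralipid reduced scattering per unit
#'   fractional concentration (1/cm).
#' @param absorb_coeff_per_fraction ink absorption per unit fractional
#'   concentration (1/cm).
#' @return An object of class `pali_recipe`: fractions, predicted mu_a,
#'   mu_s', and mu_eff.
#' @export
design_mixture <- function(target_mu_a, target_mu_s_prime,
                           scatter_coeff_per_fraction,
                           absorb_coeff_per_fraction) {
  stopifnot(target_mu_a > 0, target_mu_s_prime > 0,
            scatter_coeff_per_fraction > 0, absorb_coeff_per_fraction > 0)
  f_scatter <- target_mu_s_prime / scatter_coeff_per_fraction
  f_absorb <- target_mu_a / absorb_coeff_per_fraction
  if (f_scatter > 1 || f_absorb > 1)
    stop(sprintf("infeasible recipe: required fractions %.3g (scatterer), %.3g (absorber) exceed 1",
                 f_scatter, f_absorb))
  structure(list(fraction_scatterer = f_scatter,
                 fraction_absorber = f_absorb,
                 scatter_coeff_per_fraction = scatter_coeff_per_fraction,
                 absorb_coeff_per_fraction = absorb_coeff_per_fraction,
                 mu_a = target_mu_a, mu_s_prime = target_mu_s_prime,
                 mu_eff = mu_eff(target_mu_a, target_mu_s_prime)),
            class = "pali_recipe")
}

#' @export
print.pali_recipe <- function(x, ...) {
  cat(sprintf("Phantom mixture: scatterer fraction %.4g, absorber fraction %.4g\n",
              x$fraction_scatterer, x$fraction_absorber))
  cat(sprintf("  predicted mu_a = %.3g, mu_s' = %.3g, mu_eff = %.3g 1/cm\n",
              x$mu_a, x$mu_s_prime, x$mu_eff))
  invisible(x)
}

#' Read a transmission dilution series from CSV
#'
#' Expects columns `fraction` and `transmission`.
#'
#' @param path CSV path.
#' @return Data frame sorted by fraction.
#' @export
read_transmission_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("fraction", "transmission") %in% names(df)))
    stop("CSV must have columns fraction and transmission")
  df[order(df$fraction), c("fraction", "transmission")]
}
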