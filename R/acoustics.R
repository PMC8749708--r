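#' Focused single-element transducer specification
#'
#' @param center_frequency_MHz transducer center frequency (default 5 MHz).
#' @param fractional_bandwidth -6 dB fractional bandwidth (default 0.6).
#' @param element_diameter_mm element diameter (default 12.7 mm).
#' @param focal_length_mm geometric focal length (default 25 mm).
#' @param position_mm transducer face center c(x, y, z) in grid coordinates
#'   (z < 0 is above the illuminated surface). Conventionally placed so the
#'   focal point sits at the node center.
#' @param sampling_rate_MHz RF sampling rate (default 50 MHz).
#' @return An object of class `pali_transducer`.
#' @export
transducer_spec <- function(center_frequency_MHz = 5,
                            fractional_bandwidth = 0.6,
                            element_diameter_mm = 12.7,
                            focal_length_mm = 25,
                            position_mm = c(0, 0, 0),
                            sampling_rate_MHz = 50) {
  stopifnot(center_frequency_MHz > 0, fractional_bandwidth > 0,
            fractional_bandwidth < 2, element_diameter_mm > 0,
            focal_length_mm > 0, length(position_mm) == 3,
            sampling_rate_MHz > 2 * center_frequency_MHz)
  structure(list(center_frequency_MHz = center_frequency_MHz,
                 fractional_bandwidth = fractional_bandwidth,
                 element_diameter_mm = element_diameter_mm,
                 focal_length_mm = focal_length_mm,
                 position_mm = position_mm,
                 sampling_rate_MHz = sampling_rate_MHz),
            class = "pali_transducer")
}

#' Place a transducer focused on the phantom's node
#'
#' Positions the element on the beam axis above the surface so its focal
#' point coincides with the node center.
#'
#' @param phantom a `pali_phantom`.
#' @param xdcr a `pali_transducer` template.
#' @return The transducer with `position_mm` set.
#' @export
focus_on_node <- function(phantom, xdcr = transducer_spec()) {
  xdcr$position_mm <- c(phantom$center_mm[1], phantom$center_mm[2],
                        phantom$depth_mm - xdcr$focal_length_mm)
  xdcr
}

#' RF trace container
#'
#' @param samples numeric sample vector (pressure-equivalent units, kPa scale).
#' @param sampling_rate_MHz sampling rate (MHz).
#' @param sos_m_s speed of sound (default 1540 m/s).
#' @param t0_s time of the first sample relative to the generating laser
#'   pulse (s).
#' @return An object of class `pali_rf_trace`.
#' @export
rf_trace <- function(samples, sampling_rate_MHz, sos_m_s = 1540, t0_s = 0) {
  stopifnot(all(is.finite(samples)), sampling_rate_MHz > 0, sos_m_s > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_MHz = sampling_rate_MHz,
                 sos_m_s = sos_m_s, t0_s = t0_s),
            class = "pali_rf_trace")
}

#' @export
print.pali_rf_trace <- function(x, ...) {
  cat(sprintf("RF trace: %d samples at %g MHz (%.2f us), sos %g m/s\n",
              length(x$samples), x$sampling_rate_MHz,
              length(x$samples) / x$sampling_rate_MHz, x$sos_m_s))
  invisible(x)
}

#' Trace sample times (s)
#' @param trace a `pali_rf_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0_s + (seq_along(trace$samples) - 1) / (trace$sampling_rate_MHz * 1e6)
}

#' Initial photoacoustic pressure map
#'
#' `p0 = Grueneisen * mu_a * fluence`. With `mu_a` in 1/cm and fluence in
#' J/cm^2 the product is an absorbed energy density in J/cm^3; 1 J/cm^3
#' corresponds to 1 MPa, so the returned map is in kPa
#' (`1000 * Gamma * mu_a * phi`).
#'
#' @param grueneisen Grueneisen parameter (dimensionless, default 0.2).
#' @param mu_a_map per-voxel absorption (1/cm), same grid as the fluence.
#' @param fluence a `pali_fluence`.
#' @return An object of class `pali_pressure` (kPa array + grid metadata).
#' @export
initial_pressure <- function(grueneisen = 0.2, mu_a_map, fluence) {
  stopifnot(inherits(fluence, "pali_fluence"), grueneisen >= 0)
  if (!all(dim(mu_a_map) == fluence$dims))
    stop("absorption map and fluence grids do not match")
  if (any(mu_a_map < 0)) stop("negative absorption coefficients")
  structure(list(values = 1000 * grueneisen * mu_a_map * fluence$values,
                 grueneisen = grueneisen, voxel_mm = fluence$voxel_mm,
                 dims = fluence$dims),
            class = "pali_pressure")
}

#' Project an initial pressure map onto a focused transducer
#'
#' Far-field time-of-flight projection replacing a full-wave simulation: each
#' voxel contributes its pressure at delay `r / sos` with `1/r` spherical
#' spreading, an obliquity factor `cos(theta)` and a hard aperture cone of
#' half-angle `asin((D/2)/F)` about the transducer axis (+z). The binned
#' series is then band-passed by a zero-phase Gaussian transducer response
#' centered on the element's center frequency. Acoustic attenuation is
#' neglected.
#'
#' @param pressure a `pali_pressure`.
#' @param xdcr a `pali_transducer`; must lie outside the pressure support.
#' @param sos_m_s speed of sound (m/s, default 1540).
#' @param n_samples trace length; default covers the farthest grid corner.
#' @return A `pali_rf_trace` (time origin at the laser pulse). Carries a
#'   `focus_in_grid` attribute: `FALSE` flags a focal point outside the grid.
#' @export
project_to_transducer <- function(pressure, xdcr, sos_m_s = 1540,
                                  n_samples = NULL) {
  stopifnot(inherits(pressure, "pali_pressure"),
            inherits(xdcr, "pali_transducer"))
  d <- pressure$dims; dv <- pressure$voxel_mm
  pos <- xdcr$position_mm
  fs_Hz <- xdcr$sampling_rate_MHz * 1e6

  focus <- pos + c(0, 0, xdcr$focal_length_mm)
  focus_in_grid <- all(focus >= 0) && all(focus <= d * dv)
  if (!focus_in_grid)
    warning("transducer focal point lies outside the pressure grid")

  corners <- as.matrix(expand.grid(c(0, d[1] * dv), c(0, d[2] * dv),
                                   c(0, d[3] * dv)))
  rmax_mm <- max(sqrt(rowSums(sweep(corners, 2, pos)^2)))
  if (is.null(n_samples))
    n_samples <- ceiling(rmax_mm * 1e-3 / sos_m_s * fs_Hz) + 64L

  raw <- numeric(n_samples)
  keep <- which(pressure$values != 0)
  if (length(keep)) {
    ai <- arrayInd(keep, d)
    x <- (ai[, 1] - 0.5) * dv - pos[1]
    y <- (ai[, 2] - 0.5) * dv - pos[2]
    z <- (ai[, 3] - 0.5) * dv - pos[3]
    if (pos[3] > dv && all(pos > dv) && all(pos < d * dv - dv))
      stop("transducer position lies inside the pressure grid")
    # near-field voxels sit outside the far-field model's validity; clamp
    # the spreading distance at one voxel so surface-coupled elements work
    r <- pmax(sqrt(x^2 + y^2 + z^2), dv)
    cos_th <- z / r                       # axis is +z
    half_angle <- asin(min(1, xdcr$element_diameter_mm / 2 /
                             xdcr$focal_length_mm))
    w <- pressure$values[keep] * dv^3 * cos_th / r
    w[cos_th < cos(half_angle)] <- 0
    bin <- floor(r * 1e-3 / sos_m_s * fs_Hz) + 1L
    w[bin > n_samples] <- 0  # arrivals past the requested trace are dropped
    nz <- w != 0
    if (any(nz)) {
      acc <- rowsum(w[nz], bin[nz])
      raw[as.integer(rownames(acc))] <- acc[, 1]
    }
  }

  samples <- bandpass_gaussian(raw, fs_Hz, xdcr$center_frequency_MHz * 1e6,
                               xdcr$fractional_bandwidth)
  out <- rf_trace(samples, xdcr$sampling_rate_MHz, sos_m_s)
  attr(out, "focus_in_grid") <- focus_in_grid
  out
}

# Zero-phase Gaussian band-pass around f0 (transducer impulse response model).
# Fractional bandwidth is interpreted as FWHM of the passband / f0.
bandpass_gaussian <- function(x, fs_Hz, f0_Hz, frac_bw) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs_Hz
  f <- ifelse(f > fs_Hz / 2, f - fs_Hz, f)
  sf <- frac_bw * f0_Hz / (2 * sqrt(2 * log(2)))
  H <- exp(-((abs(f) - f0_Hz)^2) / (2 * sf^2))
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

#' Additive receiver noise model
#'
#' Zero-mean i.i.d. Gaussian noise with a standard deviation given by the
#' noise-equivalent pressure (NEP), in the same units as the trace samples.
#'
#' @param nep noise-equivalent pressure (>= 0).
#' @param seed optional integer seed; if given, [add_noise()] is
#'   deterministic for this model.
#' @return An object of class `pali_noise`.
#' @export
noise_model <- function(nep, seed = NULL) {
  stopifnot(nep >= 0)
  structure(list(nep = nep, seed = seed), class = "pali_noise")
}

#' Add receiver noise to an RF trace
#'
#' @param trace a `pali_rf_trace`.
#' @param noise a `pali_noise`. With `noise$seed` set, the same noise
#'   realization is produced on every call; with `seed = NULL` the current
#'   RNG stream is used.
#' @return The noisy `pali_rf_trace`.
#' @export
add_noise <- function(trace, noise) {
  stopifnot(inherits(trace, "pali_rf_trace"), inherits(noise, "pali_noise"))
  if (noise$nep == 0) return(trace)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  trace$samples <- trace$samples + rnorm(length(trace$samples), 0, noise$nep)
  trace
}

rms <- function(x) sqrt(mean(x^2))
p2p <- function(x) max(x) - min(x)

#' Noise-equivalent pressure from a transducer/hydrophone pair
#'
#' `NEP = Unoise * Hsig / Usig`: the pre-arrival RMS of the transducer trace,
#' referred to pressure through the ratio of the hydrophone's to the
#' transducer's peak-to-peak response to the same photoacoustic source.
#'
#' @param u_trace transducer `pali_rf_trace`.
#' @param h_trace hydrophone `pali_rf_trace` (pressure-calibrated units).
#' @param arrival_window_s c(start, end) of the photoacoustic arrival, in
#'   seconds on each trace's time axis.
#' @return NEP in the hydrophone's pressure units.
#' @export
compute_nep <- function(u_trace, h_trace, arrival_window_s) {
  stopifnot(inherits(u_trace, "pali_rf_trace"),
            inherits(h_trace, "pali_rf_trace"),
            length(arrival_window_s) == 2,
            arrival_window_s[1] < arrival_window_s[2])
  tu <- trace_times(u_trace); th <- trace_times(h_trace)
  pre <- tu < arrival_window_s[1]
  in_u <- tu >= arrival_window_s[1] & tu <= arrival_window_s[2]
  in_h <- th >= arrival_window_s[1] & th <= arrival_window_s[2]
  if (!any(pre)) stop("no pre-arrival samples in transducer trace")
  if (!any(in_u) || !any(in_h)) stop("empty arrival window")
  u_sig <- p2p(u_trace$samples[in_u])
  if (u_sig == 0) stop("no detectable transducer signal in arrival window")
  rms(u_trace$samples[pre]) * p2p(h_trace$samples[in_h]) / u_sig
}

#' Signal-to-noise ratio of an RF trace
#'
#' Peak-to-peak amplitude in the signal window divided by twice the RMS in
#' the noise window (one of several SNR conventions; pinned because the
#' depth-limit thresholds depend on it).
#'
#' @param trace a `pali_rf_trace`.
#' @param signal_window_s,noise_window_s c(start, end) windows in seconds;
#'   must be disjoint and non-empty.
#' @return SNR (dimensionless); `Inf` if the noise window RMS is zero.
#' @export
snr <- function(trace, signal_window_s, noise_window_s) {
  stopifnot(inherits(trace, "pali_rf_trace"))
  if (max(signal_window_s[1], noise_window_s[1]) <
      min(signal_window_s[2], noise_window_s[2]))
    stop("signal and noise windows overlap")
  tt <- trace_times(trace)
  s <- trace$samples[tt >= signal_window_s[1] & tt <= signal_window_s[2]]
  n <- trace$samples[tt >= noise_window_s[1] & tt <= noise_window_s[2]]
  if (!length(s) || !length(n)) stop("empty SNR window")
  den <- 2 * rms(n)
  if (den == 0) return(Inf)
  p2p(s) / den
}

#' Read an RF trace from CSV
#'
#' Expects columns `time_s` and `amplitude` on a uniform time grid.
#'
#' @param path CSV path.
#' @param sos_m_s speed of sound to attach (m/s).
#' @return A `pali_rf_trace`.
#' @export
read_rf_csv <- function(path, sos_m_s = 1540) {
  df <- read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("CSV must have columns time_s and amplitude")
  df <- df[order(df$time_s), ]
  dt <- diff(df$time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("time samples are not uniformly spaced")
  rf_trace(df$amplitude, 1 / dt[1] / 1e6, sos_m_s, t0_s = df$time_s[1])
}

#' Write an RF trace to CSV
#' @param trace a `pali_rf_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rf_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace_times(trace),
                       amplitude = trace$samples),
            path, row.names = FALSE)
  invisible(path)
}
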