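#' Logarithmically spaced pump-probe delay schedule
#'
#' Geometric progression of `n` delays from `t_min` to `t_max` inclusive
#' (default: twelve delays from 0.5 to 1000 us), sampling all regions of an
#' exponential decay evenly on the log axis.
#'
#' @param n number of delays (>= 2).
#' @param t_min_us,t_max_us first and last delay (us), `0 < t_min < t_max`.
#' @return An object of class `pali_schedule` (numeric delays in us).
#' @export
delay_schedule <- function(n = 12, t_min_us = 0.5, t_max_us = 1000) {
  stopifnot(n >= 2, t_min_us > 0, t_min_us < t_max_us)
  d <- exp(seq(log(t_min_us), log(t_max_us), length.out = n))
  d[1] <- t_min_us; d[n] <- t_max_us
  structure(d, class = "pali_schedule")
}

#' Forward model: clean RF traces for one phantom / oxygenation
#'
#' Runs the two-pass optical simulation and the acoustic projection once,
#' producing the three clean trace components from which frames at any
#' pump-probe delay can be composed:
#' \itemize{
#'   \item `sig`: probe signal from triplet-state absorption (decays with
#'     delay as `exp(-kt * tau)`),
#'   \item `bg`: probe signal from non-triplet (tissue + ground-state dye)
#'     absorption (delay-independent),
#'   \item `pump`: pump-generated artifact signal.
#' }
#' Pipeline: pump Monte Carlo -> per-voxel pumping rate and triplet
#' population at the end of the pump pulse -> probe Monte Carlo with the
#' triplet-updated absorption -> initial pressure -> time-of-flight
#' projection to the focused transducer.
#'
#' @param phantom a `pali_phantom`.
#' @param beam_pump,beam_probe `pali_beam` objects (660 / 830 nm defaults).
#' @param kt_truth triplet decay rate used for the triplet population (1/s).
#' @param xdcr a `pali_transducer`; if `position_mm` is c(0,0,0) it is
#'   focused on the node via [focus_on_node()].
#' @param n_photons photon packets per Monte Carlo run.
#' @param grueneisen Grueneisen parameter.
#' @param seed master seed; pump and probe runs use derived sub-seeds.
#' @return An object of class `pali_forward` with the three
#'   `pali_rf_trace` components, the extraction gate, and metadata.
#' @export
simulate_forward <- function(phantom,
                             beam_pump = beam_spec(pulse_fluence_mJcm2 = 10,
                                                   wavelength_nm = 660),
                             beam_probe = beam_spec(pulse_fluence_mJcm2 = 15,
                                                    wavelength_nm = 830),
                             kt_truth,
                             xdcr = transducer_spec(),
                             n_photons = 1e5,
                             grueneisen = 0.2,
                             seed = 1) {
  stopifnot(inherits(phantom, "pali_phantom"), kt_truth >= 0)
  if (all(xdcr$position_mm == 0)) xdcr <- focus_on_node(phantom, xdcr)

  fl_pump <- monte_carlo_fluence(phantom, beam_pump, n_photons,
                                 seed = derive_seed(seed, 1))

  # triplet population at the end of the pump pulse, node voxels only
  pp <- phantom$photophys
  phi_rate <- fl_pump$values[phantom$node_idx] / beam_pump$pulse_duration_s
  beta <- pump_rate(pp, phi_rate, beam_pump$wavelength_nm)
  nt <- triplet_population(beta, phantom$monomer_conc_M, kt_truth,
                           beam_pump$pulse_duration_s)

  ph2 <- update_probe_absorption(phantom, nt)
  fl_probe <- monte_carlo_fluence(ph2, beam_probe, n_photons,
                                  seed = derive_seed(seed, 2))

  p_sig <- initial_pressure(grueneisen, ph2$mua_triplet, fl_probe)
  p_bg <- initial_pressure(grueneisen, phantom$mua_probe, fl_probe)
  p_pump <- initial_pressure(grueneisen, phantom$mua_pump, fl_pump)

  # the acquisition only uses samples up to the focal arrival gate, so the
  # traces are truncated a few microseconds past it (far-corner background
  # arrivals beyond that never enter the estimator)
  sos <- 1540
  arrival_s <- xdcr$focal_length_mm * 1e-3 / sos
  gate_half_s <- phantom$node_radius_mm * 1e-3 / sos +
    2 / (xdcr$center_frequency_MHz * 1e6)
  n_keep <- ceiling((arrival_s + gate_half_s + 4e-6) *
                      xdcr$sampling_rate_MHz * 1e6)

  sig <- project_to_transducer(p_sig, xdcr, n_samples = n_keep)
  bg <- project_to_transducer(p_bg, xdcr, n_samples = n_keep)
  pump <- project_to_transducer(p_pump, xdcr, n_samples = n_keep)

  structure(list(sig = sig, bg = bg, pump = pump, xdcr = xdcr,
                 kt_truth = kt_truth, phantom_depth_mm = phantom$depth_mm,
                 arrival_s = arrival_s, gate_s = arrival_s + c(-1, 1) * gate_half_s,
                 triplet_peak_M = if (length(nt)) max(nt) else 0,
                 n_photons = n_photons, seed = seed),
            class = "pali_forward")
}

# shift a sample vector left by `k` samples, zero-filling the tail
shift_left <- function(x, k) {
  n <- length(x)
  if (k <= 0) return(x)
  if (k >= n) return(numeric(n))
  c(x[(k + 1):n], numeric(k))
}

#' Simulate one acquisition: frames, corrections, per-delay amplitudes
#'
#' Composes per-delay pump+probe and pump-only frames from a forward model,
#' applies the acquisition protocol, and returns corrected per-delay
#' amplitudes. Frames are acquired in a window starting at the probe firing,
#' so the probe signal arrives at a fixed time while the pump artifact slides
#' earlier as the delay grows. Per frame, the pulse energy is jittered and
#' the samples scale with it; the correction chain is: per-frame energy
#' normalization, averaging of the 100 + 100 frames, pump-artifact
#' subtraction, subtraction of the corrected trace at the longest delay
#' (triplet fully decayed there - removes the non-decaying background), and
#' peak-to-peak amplitude extraction in a gate centered on the expected
#' focal arrival. The peak and trough sample positions are located once on
#' the shortest-delay (highest SNR) corrected trace and reused at every
#' delay, so the amplitude is linear in the trace and receiver noise enters
#' it with zero mean. The longest delay is retained as the (excluded)
#' reference row.
#'
#' @param fwd a `pali_forward`.
#' @param schedule a `pali_schedule` of pump-probe delays (us).
#' @param n_averages frames of each kind per delay (default 100).
#' @param noise a `pali_noise` (per-frame additive receiver noise).
#' @param seed integer seed for noise and energy jitter.
#' @param energy_jitter fractional SD of the per-frame pulse energy.
#' @param nominal_energy_mJ nominal per-pulse energy used for normalization.
#' @return A `pali_dataset`: data frame with columns `delay_us`, `amplitude`,
#'   `stderr`, `excluded`, plus attributes `snr` (recorded on the averaged
#'   corrected trace at the shortest delay), `kt_truth`, `seed`.
#' @export
acquire_dataset <- function(fwd, schedule = delay_schedule(),
                            n_averages = 100,
                            noise = noise_model(0),
                            seed = 1,
                            energy_jitter = 0.02,
                            nominal_energy_mJ = 1) {
  stopifnot(inherits(fwd, "pali_forward"), n_averages >= 1,
            inherits(noise, "pali_noise"))
  delays_s <- as.numeric(schedule) * 1e-6
  n_delay <- length(delays_s)
  fs_Hz <- fwd$sig$sampling_rate_MHz * 1e6
  nsamp <- length(fwd$sig$samples)
  tt <- trace_times(fwd$sig)
  gate <- tt >= fwd$gate_s[1] & tt <= fwd$gate_s[2]
  if (!any(gate)) stop("amplitude gate falls outside the trace")

  set.seed(seed)
  mean_traces <- vector("list", n_delay)
  amp_mean <- amp_se <- numeric(n_delay)
  frame_mats <- vector("list", n_delay)

  for (j in seq_len(n_delay)) {
    tau <- delays_s[j]
    shift_k <- round(tau * fs_Hz)
    pump_shifted <- shift_left(fwd$pump$samples, shift_k)
    clean_pp <- fwd$sig$samples * exp(-fwd$kt_truth * tau) + fwd$bg$samples +
      pump_shifted

    # per-frame relative pulse energies (the clean signal scales with them;
    # normalization divides them back out, so only the noise term keeps a
    # 1/energy factor)
    rel_pp <- exp(rnorm(n_averages, 0, energy_jitter))
    rel_po <- exp(rnorm(n_averages, 0, energy_jitter))
    if (noise$nep > 0) {
      noise_pp <- matrix(rnorm(nsamp * n_averages, 0, noise$nep),
                         nsamp, n_averages)
      noise_po <- matrix(rnorm(nsamp * n_averages, 0, noise$nep),
                         nsamp, n_averages)
      pp_frames <- clean_pp + sweep(noise_pp, 2, rel_pp, `/`)
      mean_po <- pump_shifted + rowMeans(sweep(noise_po, 2, rel_po, `/`))
    } else {
      pp_frames <- matrix(clean_pp, nsamp, n_averages)
      mean_po <- pump_shifted
    }
    mean_traces[[j]] <- rowMeans(pp_frames) - mean_po
    frame_mats[[j]] <- pp_frames[gate, , drop = FALSE] - mean_po[gate]
  }

  # background subtraction at the trace level: the corrected trace at the
  # longest delay (triplet fully decayed) is subtracted from all others
  ref <- mean_traces[[n_delay]]
  for (j in seq_len(n_delay)) mean_traces[[j]] <- mean_traces[[j]] - ref

  # peak-to-peak amplitude at the extremal sample positions of the
  # shortest-delay trace (highest SNR): linear in the trace, so receiver
  # noise enters the amplitudes with zero mean instead of the positive bias
  # a max/min scan over noisy samples would add
  gi <- which(gate)
  first <- mean_traces[[1]][gi]
  i_max <- gi[which.max(first)]; i_min <- gi[which.min(first)]
  g_max <- match(i_max, gi); g_min <- match(i_min, gi)
  for (j in seq_len(n_delay)) {
    amp_mean[j] <- if (j == n_delay) 0 else
      mean_traces[[j]][i_max] - mean_traces[[j]][i_min]
    amp_se[j] <- sd(frame_mats[[j]][g_max, ] - frame_mats[[j]][g_min, ]) /
      sqrt(n_averages)
  }

  # recorded SNR: averaged corrected trace at the shortest delay
  noise_win <- c(tt[1], max(tt[1] + 1 / fs_Hz, fwd$gate_s[1] - 2e-6))
  rec_snr <- if (noise$nep == 0) Inf else
    snr(rf_trace(mean_traces[[1]], fwd$sig$sampling_rate_MHz,
                 fwd$sig$sos_m_s), fwd$gate_s, noise_win)

  out <- data.frame(delay_us = as.numeric(schedule), amplitude = amp_mean,
                    stderr = amp_se,
                    excluded = seq_len(n_delay) == n_delay)
  structure(out, class = c("pali_dataset", "data.frame"),
            snr = rec_snr, kt_truth = fwd$kt_truth, seed = seed,
            nep = noise$nep, n_averages = n_averages)
}

#' Full pump-probe acquisition simulation
#'
#' Convenience wrapper running [simulate_forward()] then [acquire_dataset()].
#'
#' @inheritParams simulate_forward
#' @inheritParams acquire_dataset
#' @param cal_truth ground-truth `pali_sv_cal`.
#' @param pO2_truth true oxygen partial pressure (mmHg).
#' @return A `pali_dataset` (see [acquire_dataset()]).
#' @export
simulate_acquisition <- function(phantom,
                                 beam_pump = beam_spec(pulse_fluence_mJcm2 = 10,
                                                       wavelength_nm = 660),
                                 beam_probe = beam_spec(pulse_fluence_mJcm2 = 15,
                                                        wavelength_nm = 830),
                                 photophys = phantom$photophys,
                                 cal_truth = default_stern_volmer(),
                                 pO2_truth = 150,
                                 schedule = delay_schedule(),
                                 n_averages = 100,
                                 noise = noise_model(0),
                                 seed = 1,
                                 xdcr = transducer_spec(),
                                 n_photons = 1e5,
                                 grueneisen = 0.2) {
  stopifnot(pO2_truth >= 0)
  kt <- stern_volmer_rate(cal_truth, pO2_truth)
  fwd <- simulate_forward(phantom, beam_pump, beam_probe, kt_truth = kt,
                          xdcr = xdcr, n_photons = n_photons,
                          grueneisen = grueneisen,
                          seed = derive_seed(seed, 10))
  acquire_dataset(fwd, schedule, n_averages, noise,
                  seed = derive_seed(seed, 11))
}

#' Subtract the pump artifact from a pump+probe frame
#'
#' Samplewise difference of the two frames after per-frame pulse-energy
#' normalization.
#'
#' @param pump_probe,pump_only frame lists with fields `rf`
#'   (`pali_rf_trace`), `delay_us`, and `pulse_energy_mJ`.
#' @return The corrected `pali_rf_trace`.
#' @export
subtract_pump_artifact <- function(pump_probe, pump_only) {
  a <- normalize_by_energy(pump_probe); b <- normalize_by_energy(pump_only)
  if (a$rf$sampling_rate_MHz != b$rf$sampling_rate_MHz ||
      length(a$rf$samples) != length(b$rf$samples))
    stop("frame sampling mismatch")
  if (!isTRUE(all.equal(a$delay_us, b$delay_us)))
    stop("frame delay mismatch")
  out <- a$rf
  out$samples <- a$rf$samples - b$rf$samples
  out
}

#' Normalize a frame by its pulse energy
#'
#' @param frame a frame list with fields `rf` and `pulse_energy_mJ`.
#' @return The frame with samples divided by the pulse energy and
#'   `pulse_energy_mJ` reset to 1.
#' @export
normalize_by_energy <- function(frame) {
  if (is.null(frame$pulse_energy_mJ) || frame$pulse_energy_mJ <= 0)
    stop("non-positive pulse energy")
  frame$rf$samples <- frame$rf$samples / frame$pulse_energy_mJ
  frame$pulse_energy_mJ <- 1
  frame
}

#' Subtract the long-delay background from per-delay amplitudes
#'
#' The amplitude at the reference delay (conventionally the longest
#' scheduled delay, where the triplet state has fully decayed) is subtracted
#' from all entries; the reference entry is flagged for exclusion from
#' fitting. For amplitudes `A exp(-k tau) + B` this leaves
#' `A (exp(-k tau) - exp(-k tau_max))`; the residual term is negligible when
#' `k * tau_max >> 1`.
#'
#' @param amplitudes per-delay amplitude vector.
#' @param delays_us matching delays (us).
#' @param reference_delay_us the reference delay; must be the longest.
#' @return Data frame with `delay_us`, `amplitude`, `excluded`.
#' @export
subtract_background <- function(amplitudes, delays_us,
                                reference_delay_us = max(delays_us)) {
  stopifnot(length(amplitudes) == length(delays_us))
  if (reference_delay_us != max(delays_us))
    stop("reference delay must be the longest scheduled delay")
  i <- which(delays_us == reference_delay_us)[1]
  data.frame(delay_us = delays_us,
             amplitude = amplitudes - amplitudes[i],
             excluded = seq_along(delays_us) == i)
}

#' Peak-to-peak amplitude within a time gate
#'
#' @param trace a `pali_rf_trace`.
#' @param gate_s c(start, end) gate in seconds, conventionally centered on
#'   the expected arrival time (focal distance / speed of sound).
#' @return Peak-to-peak amplitude (scalar).
#' @export
extract_amplitude <- function(trace, gate_s) {
  stopifnot(inherits(trace, "pali_rf_trace"), length(gate_s) == 2)
  tt <- trace_times(trace)
  inside <- tt >= gate_s[1] & tt <= gate_s[2]
  if (!any(inside)) stop("empty amplitude gate")
  p2p(trace$samples[inside])
}

#' Export / import a PALI dataset as CSV
#'
#' Columns `delay_us`, `amplitude`, `stderr`, `excluded`; attributes go to a
#' JSON sidecar on write.
#'
#' @param dataset a `pali_dataset`.
#' @param path CSV path.
#' @return `path` (write) or a `pali_dataset` (read).
#' @export
write_dataset <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  meta <- list(snr = attr(dataset, "snr"), kt_truth = attr(dataset, "kt_truth"),
               seed = attr(dataset, "seed"), nep = attr(dataset, "nep"),
               n_averages = attr(dataset, "n_averages"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path)
  if (!all(c("delay_us", "amplitude") %in% names(df)))
    stop("CSV must have columns delay_us and amplitude")
  if (is.null(df$stderr)) df$stderr <- NA_real_
  if (is.null(df$excluded)) df$excluded <- FALSE
  structure(df, class = c("pali_dataset", "data.frame"))
}
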