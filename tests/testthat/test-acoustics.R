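test_that("initial pressure follows the Grueneisen relation with kPa units", {
  ph <- tiny_phantom()
  fl <- monte_carlo_fluence(ph, beam_spec(pulse_fluence_mJcm2 = 10,
                                          wavelength_nm = 660), 1e4, seed = 2)
  # zero absorption -> zero pressure
  p0 <- initial_pressure(0.2, array(0, ph$dims), fl)
  expect_true(all(p0$values == 0))
  # doubling fluence doubles pressure
  fl2 <- fl; fl2$values <- 2 * fl$values
  pa <- initial_pressure(0.2, ph$mua_pump, fl)
  pb <- initial_pressure(0.2, ph$mua_pump, fl2)
  expect_equal(pb$values, 2 * pa$values, tolerance = 1e-12)
  # unit check: Gamma 0.2, mu_a 1 1/cm, phi 0.015 J/cm^2 -> 3e-3 J/cm^3 = 3 kPa
  flu <- fl; flu$values[] <- 0.015
  pu <- initial_pressure(0.2, array(1, ph$dims), flu)
  expect_equal(pu$values[1], 3, tolerance = 1e-12)
  # grid mismatch is an error
  expect_error(initial_pressure(0.2, array(1, ph$dims + 1L), fl), "match")
})

test_that("time-of-flight projection arrives at r/sos and superposes", {
  xd <- transducer_spec(focal_length_mm = 25,
                        position_mm = c(12, 12, -15))  # focus at (12,12,10)
  pm <- point_pressure(1, at_mm = c(12, 12, 10))
  tr <- expect_warning(project_to_transducer(pm, xd, sos_m_s = 1540),
                       regexp = NA)
  # peak envelope at 25 mm / 1540 m/s ~ 16.23 us
  t_peak <- trace_times(tr)[which.max(abs(tr$samples))]
  expect_equal(t_peak, 25e-3 / 1540, tolerance = 0.02)

  # superposition: two sources equal the sum of the single-source traces
  pm2 <- point_pressure(0.7, at_mm = c(10.8, 12, 8))
  both <- pm; both$values <- pm$values + pm2$values
  s_both <- project_to_transducer(both, xd)$samples
  s_sum <- project_to_transducer(pm, xd)$samples +
    project_to_transducer(pm2, xd)$samples
  expect_equal(s_both, s_sum, tolerance = 1e-10)

  # zero map -> zero trace; focus outside grid -> warning
  z <- pm; z$values[] <- 0
  expect_true(all(project_to_transducer(z, xd)$samples == 0))
  xd_far <- transducer_spec(position_mm = c(12, 12, -40))
  expect_warning(project_to_transducer(pm, xd_far), "focal point")
})

test_that("projection is linear on random pressure maps", {
  set.seed(31)
  xd <- transducer_spec(position_mm = c(12, 12, -15))
  a <- point_pressure(0); b <- point_pressure(0)
  sub <- a$values[, , 6:14]
  a$values[, , 6:14] <- array(runif(length(sub)), dim(sub))
  b$values[, , 6:14] <- array(runif(length(sub)), dim(sub))
  mix <- a; mix$values <- 2 * a$values + 3 * b$values
  expect_equal(project_to_transducer(mix, xd)$samples,
               2 * project_to_transducer(a, xd)$samples +
                 3 * project_to_transducer(b, xd)$samples,
               tolerance = 1e-9)
})

test_that("additive noise realizes the requested NEP deterministically", {
  tr <- rf_trace(numeric(1e4), 50)
  expect_identical(add_noise(tr, noise_model(0)), tr)
  n1 <- add_noise(tr, noise_model(2.5, seed = 4))
  n2 <- add_noise(tr, noise_model(2.5, seed = 4))
  expect_identical(n1$samples, n2$samples)
  expect_equal(sd(n1$samples), 2.5, tolerance = 0.05)
})

test_that("NEP arithmetic reproduces the transfer-ratio definition", {
  # constructed traces: pre-arrival noise RMS 2, Usig 100, Hsig 50
  fs <- 50
  n <- 1000
  u <- numeric(n); h <- numeric(n)
  set.seed(8)
  pre <- 1:450                                     # all samples before the window
  u[pre] <- rnorm(450)
  u[pre] <- u[pre] / sqrt(mean(u[pre]^2)) * 2      # exact RMS 2
  u[500] <- 60; u[510] <- -40                      # p2p 100
  h[500] <- 30; h[510] <- -20                      # p2p 50
  ut <- rf_trace(u, fs); ht <- rf_trace(h, fs)
  win <- c(450, 600) / (fs * 1e6)
  expect_equal(compute_nep(ut, ht, win), 2 * 50 / 100, tolerance = 1e-12)
  # unity transfer: Hsig = Usig -> NEP = Unoise
  expect_equal(compute_nep(ut, ut, win), 2, tolerance = 1e-12)
  # linear in the hydrophone response
  ht10 <- rf_trace(10 * h, fs)
  expect_equal(compute_nep(ut, ht10, win), 10 * compute_nep(ut, ht, win))
  # no transducer signal is an error
  u0 <- u; u0[500] <- 0; u0[510] <- 0
  expect_error(compute_nep(rf_trace(u0, fs), ht, win), "no detectable")
})

test_that("SNR definition behaves under scaling, nulls and zero noise", {
  fs <- 50
  sig_win <- c(100, 200) / (fs * 1e6)
  noise_win <- c(300, 400) / (fs * 1e6)
  # pure noise in both windows: median SNR over seeds is small
  meds <- vapply(1:40, function(s) {
    set.seed(s)
    snr(rf_trace(rnorm(500), fs), sig_win, noise_win)
  }, 0)
  expect_lt(median(meds), 3)
  # noiseless signal with silent noise window -> infinity flag
  x <- numeric(500); x[110:130] <- sin(1:21)
  expect_identical(snr(rf_trace(x, fs), sig_win, noise_win), Inf)
  # doubling the signal doubles SNR at fixed noise
  set.seed(2)
  y <- rnorm(500); y2 <- y
  y[110:130] <- y[110:130] + 50 * sin(1:21)
  y2[110:130] <- y2[110:130] + 100 * sin(1:21)
  s1 <- snr(rf_trace(y, fs), sig_win, noise_win)
  s2 <- snr(rf_trace(y2, fs), sig_win, noise_win)
  expect_equal(s2 / s1, 2, tolerance = 0.1)
  expect_error(snr(rf_trace(y, fs), sig_win, sig_win), "overlap")
})

test_that("RF traces round-trip through CSV", {
  tr <- rf_trace(sin(1:200), 50, t0_s = 1e-6)
  path <- file.path(tempdir(), "trace.csv")
  write_rf_csv(tr, path)
  tr2 <- read_rf_csv(path)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-9)
  expect_equal(tr2$sampling_rate_MHz, 50, tolerance = 1e-6)
  unlink(path)
})
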