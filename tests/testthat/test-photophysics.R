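test_that("triplet population has the right limits and saturation", {
  expect_equal(triplet_population(1e6, 4e-4, 1e6, 0), 0)
  s <- 2e6
  expect_equal(triplet_population(1e6, 4e-4, 1e6, 1e3 / s),
               1e6 * 4e-4 / s, tolerance = 1e-12)
  # alpha + beta = 0 limit: no pumping, returns 0 without error
  expect_equal(triplet_population(0, 4e-4, 0, 1e-6), 0)
  # bounded by the saturation value and monotone in t
  ts <- 10^seq(-9, -3, length.out = 20)
  nt <- triplet_population(1e6, 4e-4, 1e6, ts)
  expect_true(all(diff(nt) >= 0))
  expect_true(all(diff(nt[ts < 1e-6]) > 0))
  expect_true(all(nt < 4e-4))
})

test_that("triplet population matches stiff-ODE integration of the pumping model", {
  skip_if_not_installed("deSolve")
  # oracle: integrate dG/dt = -beta G, dT/dt = beta G - alpha T directly.
  # The closed form assumes the ground state is not depleted (G ~ n), so the
  # oracle uses the same linear pumping term evaluated at constant n.
  ode_oracle <- function(beta, n, alpha, t) {
    if (t == 0) return(0)
    f <- function(t, y, p) list(c(p$beta * p$n - (p$alpha + p$beta) * y[1]))
    out <- deSolve::lsoda(c(T = 0), c(0, t), f,
                          list(beta = beta, n = n, alpha = alpha),
                          rtol = 1e-10, atol = 1e-22)
    unname(out[nrow(out), "T"])
  }
  grid <- expand.grid(alpha = c(1e4, 1e5, 1e6, 1e7, 1e8),
                      beta = c(1e4, 1e5, 1e6, 1e7, 1e8),
                      t = c(1e-9, 5e-9, 1e-8, 1e-7, 1e-6))
  n <- 4e-4
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(triplet_population(g$beta, n, g$alpha, g$t),
                 ode_oracle(g$beta, n, g$alpha, g$t),
                 tolerance = 1e-6)
  }
})

test_that("pump rate is eta sigma phi / (h nu)", {
  pp <- photophysics(eta = 0.5, sigma_g = 1e-16)
  expect_equal(pump_rate(pp, 0, 660), 0)
  expect_equal(pump_rate(pp, 2e6, 660), 2 * pump_rate(pp, 1e6, 660))
  # oracle: photon energy at 660 nm computed by hand
  h_nu <- 6.62607015e-34 * 2.99792458e8 / 660e-9  # ~3.01e-19 J
  expect_equal(pump_rate(pp, 1e6, 660), 0.5 * 1e-16 * 1e6 / h_nu,
               tolerance = 1e-12)
})

test_that("Stern-Volmer rate, calibration and inversion are consistent", {
  cal <- default_stern_volmer()
  expect_equal(stern_volmer_rate(cal, 0), cal$k0)
  # derived from the printed flash-photolysis rates at 0/150 mmHg
  expect_equal(stern_volmer_rate(cal, 150), 6.05e5, tolerance = 5e-3)
  expect_true(all(diff(stern_volmer_rate(cal, seq(0, 200, 10))) > 0))

  # two-point interpolation is exact
  cal2 <- calibrate_stern_volmer(c(0, 150), c(cal$k0, cal$k0 + 150 * cal$kQ))
  expect_equal(cal2$kQ, cal$kQ, tolerance = 1e-12)
  expect_equal(cal2$k0, cal$k0, tolerance = 1e-12)

  # noiseless round trip at 5 points, inversion to 1e-10
  p <- c(0, 30, 75, 120, 150)
  cal3 <- calibrate_stern_volmer(p, stern_volmer_rate(cal, p))
  expect_equal(invert_to_pO2(cal3, stern_volmer_rate(cal, p)),
               p, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.numeric(invert_to_pO2(cal, cal$k0)), 0)

  # kt below k0 clamps to zero with a flag
  r <- invert_to_pO2(cal, cal$k0 - 1)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clamped"))

  # kt = k0 + 10 kQ maps to exactly 10 mmHg (the clinical error scale)
  expect_equal(as.numeric(invert_to_pO2(cal, cal$k0 + 10 * cal$kQ)), 10)

  expect_error(calibrate_stern_volmer(c(50, 50), c(1, 2)), "degenerate")
})

test_that("noisy calibration matches the normal-equations closed form", {
  set.seed(42)
  kQ <- 3.91e3; k0 <- 1.84e4
  p <- c(0, 40, 75, 110, 150)
  kt <- k0 + kQ * p + rnorm(5, 0, 1e3)
  cal <- calibrate_stern_volmer(p, kt)
  # oracle: (X'X)^-1 X'y assembled by hand
  X <- cbind(1, p)
  beta <- solve(t(X) %*% X, t(X) %*% kt)
  expect_equal(cal$k0, unname(beta[1, 1]), tolerance = 1e-10)
  expect_equal(cal$kQ, unname(beta[2, 1]), tolerance = 1e-10)
})

test_that("monomer fraction solves the dimerization equilibrium", {
  expect_equal(monomer_fraction(4e-4, 0), 1.0)
  # 50% monomers at 400 uM with K = 2500 1/M
  expect_equal(monomer_fraction(4e-4, 2500), 0.5, tolerance = 1e-12)
  # residual oracle: the root satisfies the mass balance
  for (total in c(1e-5, 4e-4, 2e-3)) {
    for (K in c(10, 2500, 1e5)) {
      m <- monomer_fraction(total, K) * total
      expect_lt(abs(m + 2 * K * m^2 - total) / total, 1e-10)
    }
  }
  # monotone decreasing in K and in total concentration
  fr_K <- monomer_fraction(4e-4, c(0, 10, 100, 1000, 1e4))
  expect_true(all(diff(fr_K) < 0))
  fr_tot <- monomer_fraction(c(1e-5, 1e-4, 1e-3, 1e-2), 2500)
  expect_true(all(diff(fr_tot) < 0))
})

test_that("extinction converts to a natural absorption coefficient", {
  expect_equal(triplet_absorption_coeff(0, 1e4), 0)
  expect_equal(triplet_absorption_coeff(2e-4, 1e4),
               2 * triplet_absorption_coeff(1e-4, 1e4))
  expect_equal(triplet_absorption_coeff(1e-4, 1e4), log(10), tolerance = 1e-12)
})

test_that("flash photolysis transient recovers and round-trips the rate", {
  pp <- photophysics()
  times <- seq(0, 3e-4, length.out = 200)
  fp <- simulate_flash_photolysis(pp, kt = 1.84e4, path_length_cm = 1,
                                  initial_triplet = 5e-6, times_s = times)
  # triplet absorbs the probe: transmission starts low and recovers
  expect_lt(fp$transmission[1], fp$transmission[nrow(fp)])
  expect_true(all(diff(fp$transmission) > 0))

  # zero initial triplet: flat at baseline 1
  flat <- simulate_flash_photolysis(pp, 1.84e4, 1, 0, times)
  expect_equal(flat$transmission, rep(1, length(times)))

  # -ln(T) decays as a single exponential in kt; fit recovers it to 0.1%
  fit <- fit_decay(fp$time_s * 1e6, -log(fp$transmission), model = "single")
  expect_equal(fit$selected_rate, 1.84e4, tolerance = 1e-3)
})

test_that("photophysics defaults load from the packaged constants file", {
  pp <- load_photophysics()
  expect_s3_class(pp, "pali_photophysics")
  expect_equal(pp$total_conc_M, 4e-4)
  expect_equal(pp$eta, photophysics()$eta)
})
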