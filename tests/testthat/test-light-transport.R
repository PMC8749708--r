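test_that("phantom geometry places and sizes the node correctly", {
  ph <- build_phantom(4, 3, voxel_mm = 0.2, grid_mm = c(40, 40, 35))
  # node center voxel sits 4 mm below the surface on the beam axis
  ai <- arrayInd(ph$node_idx, ph$dims)
  z_center <- mean(range((ai[, 3] - 0.5) * ph$voxel_mm))
  expect_equal(z_center, 4, tolerance = 0.05)

  # voxelized node volume ~ (4/3) pi r^3 within a one-voxel-shell tolerance
  vol <- length(ph$node_idx) * ph$voxel_mm^3
  r <- 3
  shell <- 4 * pi * r^2 * ph$voxel_mm
  expect_lt(abs(vol - 4 / 3 * pi * r^3), shell)

  # zero radius gives a homogeneous slab
  slab <- build_phantom(4, 0, voxel_mm = 0.8, grid_mm = c(24, 24, 14))
  expect_length(slab$node_idx, 0)
  expect_equal(length(unique(as.numeric(slab$mua_pump))), 1L)

  # node protruding through the surface is rejected
  expect_error(build_phantom(2, 3), "outside")
})

test_that("mu_eff reproduces the diffusion-theory values for neck tissue", {
  expect_equal(mu_eff(0, 9.1), 0)
  expect_equal(mu_eff(0.22, 9.1), 2.48, tolerance = 1e-3)
  expect_equal(round(mu_eff(0.22, 9.1), 1), 2.5)
  expect_equal(mu_eff(0.235, 7.3), 2.31, tolerance = 1e-2)
})

test_that("Monte Carlo passes the vacuum limit and conserves energy", {
  optics <- list(pump = optical_properties(0, 0, 0, 660),
                 probe = optical_properties(0, 0, 0, 830))
  ph <- build_phantom(6, 0, grid_mm = c(24, 24, 14), voxel_mm = 0.8,
                      optics = optics)
  beam <- beam_spec(radius_mm = 8, pulse_fluence_mJcm2 = 10,
                    wavelength_nm = 660)
  fl <- monte_carlo_fluence(ph, beam, n_photons = 2e4, seed = 3)
  # collimated, non-interacting: on-axis fluence equals the incident fluence
  mid <- round(ph$dims[1:2] / 2)
  axis_fluence <- fl$values[mid[1], mid[2], ]
  expect_equal(axis_fluence, rep(10e-3, ph$dims[3]), tolerance = 0.05)
  # all weight escapes out of the far face
  b <- fl$balance
  expect_equal(b$escaped, b$launched, tolerance = 1e-12)
})

test_that("Monte Carlo energy ledger balances in scattering tissue", {
  ph <- tiny_phantom()
  beam <- beam_spec(pulse_fluence_mJcm2 = 10, wavelength_nm = 660)
  fl <- monte_carlo_fluence(ph, beam, n_photons = 2e4, seed = 5)
  b <- fl$balance
  expect_lt(abs(b$launched + b$gained - (b$absorbed + b$escaped + b$killed)) /
              b$launched, 1e-9)
})

test_that("Monte Carlo is reproducible and linear in pulse fluence", {
  ph <- tiny_phantom()
  b1 <- beam_spec(pulse_fluence_mJcm2 = 10, wavelength_nm = 660)
  b2 <- beam_spec(pulse_fluence_mJcm2 = 20, wavelength_nm = 660)
  f1 <- monte_carlo_fluence(ph, b1, 1e4, seed = 9)
  f1b <- monte_carlo_fluence(ph, b1, 1e4, seed = 9)
  expect_identical(f1$values, f1b$values)
  f2 <- monte_carlo_fluence(ph, b2, 1e4, seed = 9)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-12)
})

test_that("node fluence decreases with node depth", {
  beam <- beam_spec(pulse_fluence_mJcm2 = 10, wavelength_nm = 660)
  node_mean <- vapply(c(4, 7, 10), function(d) {
    ph <- build_phantom(d, 2, grid_mm = c(24, 24, 16), voxel_mm = 0.8)
    fl <- monte_carlo_fluence(ph, beam, 3e4, seed = 21)
    mean(fl$values[ph$node_idx])
  }, 0)
  expect_true(all(diff(node_mean) < 0))
})

test_that("probe absorption update adds the triplet coefficient inside the node only", {
  ph <- tiny_phantom()
  base <- ph$mua_probe
  # zero triplet map leaves the phantom unchanged
  ph0 <- update_probe_absorption(ph, rep(0, length(ph$node_idx)), 1e4)
  expect_equal(ph0$mua_probe, base)

  # uniform 1e-5 M at eps 1e4 raises node mu_a by ln(10) * 0.1
  ph1 <- update_probe_absorption(ph, rep(1e-5, length(ph$node_idx)), 1e4)
  expect_equal(ph1$mua_probe[ph$node_idx] - base[ph$node_idx],
               rep(log(10) * 0.1, length(ph$node_idx)), tolerance = 1e-12)
  outside <- setdiff(seq_along(base), ph$node_idx)
  expect_equal(ph1$mua_probe[outside], base[outside])

  # misplaced or negative concentrations are rejected
  bad <- array(0, ph$dims); bad[1, 1, 1] <- 1e-5
  expect_error(update_probe_absorption(ph, bad), "outside node")
  expect_error(update_probe_absorption(ph, rep(-1e-6, length(ph$node_idx))),
               "negative")
})

test_that("fluence maps survive a plain-text write/read round trip", {
  ph <- tiny_phantom()
  fl <- monte_carlo_fluence(ph, beam_spec(pulse_fluence_mJcm2 = 10,
                                          wavelength_nm = 660), 1e4, seed = 2)
  path <- file.path(tempdir(), "fluence.csv")
  write_fluence(fl, path)
  fl2 <- read_fluence(path)
  expect_equal(fl2$values, fl$values, tolerance = 1e-12)
  expect_equal(fl2$wavelength_nm, 660)
  unlink(c(path, paste0(path, ".json")))
})
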