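test_that("rate errors map to mmHg through the calibration slope", {
  cal <- default_stern_volmer()
  expect_equal(decay_error_mmHg(cal$k0, cal$k0, cal), 0)
  expect_equal(decay_error_mmHg(cal$k0 + 10 * cal$kQ, cal$k0, cal), 10)
  # invariant to a common rate offset
  expect_equal(decay_error_mmHg(5e5 + 777, 3e5 + 777, cal),
               decay_error_mmHg(5e5, 3e5, cal))
})

test_that("clinical imaging depth returns the first exceedance with bracket", {
  s <- fake_summary(c(4, 7, 10, 13), 0, error_mmHg = c(2, 4, 12, 30))
  d <- clinical_imaging_depth(s, 0)
  expect_equal(as.numeric(d), 10)
  expect_equal(attr(d, "bracket"), c(7, 10))

  # all below threshold: beyond-range sentinel
  s2 <- fake_summary(c(4, 7, 10, 13), 0, error_mmHg = c(1, 2, 3, 4))
  d2 <- clinical_imaging_depth(s2, 0)
  expect_identical(as.numeric(d2), Inf)
  expect_equal(attr(d2, "bracket"), c(13, Inf))

  # zero threshold flags the first nonzero error
  s3 <- fake_summary(c(4, 7, 10), 0, error_mmHg = c(0, 0.5, 3))
  expect_equal(as.numeric(clinical_imaging_depth(s3, 0, threshold_mmHg = 0)), 7)
  expect_error(clinical_imaging_depth(fake_summary(4, 0, 1), 0), "2 swept")
})

test_that("measurement depth limit applies the two-standard-deviation rule", {
  # mean 8%, SD 3%: zero lies beyond 2 SD -> unreliable
  s <- fake_summary(c(4, 7), 0, mean_pct = c(5, 8), sd_pct = c(3, 3))
  expect_equal(as.numeric(measurement_depth_limit(s, 0)), 7)
  # mean 5%, SD 3%: within 2 SD everywhere -> sentinel
  s2 <- fake_summary(c(4, 7), 0, mean_pct = c(4, 5), sd_pct = c(3, 3))
  expect_identical(as.numeric(measurement_depth_limit(s2, 0)), Inf)
  # exact zero mean error at all depths -> sentinel
  s3 <- fake_summary(c(4, 7), 0, mean_pct = 0, sd_pct = 1)
  expect_identical(as.numeric(measurement_depth_limit(s3, 0)), Inf)
})

test_that("SNR profile aggregates per cell and reports monotonicity", {
  s <- fake_summary(rep(c(4, 7, 10), 2), rep(c(0, 150), each = 3),
                    mean_snr = c(90, 40, 12, 100, 45, 14))
  prof <- snr_profile(s)
  expect_equal(nrow(prof), 6)
  expect_true(all(attr(prof, "monotone_nonincreasing")))
  s$mean_snr[2] <- 200
  expect_false(attr(snr_profile(s), "monotone_nonincreasing")[["0"]])
})

test_that("a small noiseless sweep recovers truth at every depth", {
  cfg <- depth_sweep_config(depths_mm = c(4, 7), pO2_mmHg = 150,
                            replicates = 2, n_averages = 2, n_photons = 1e4,
                            nep = 0, voxel_mm = 0.8, grid_mm = c(24, 24, 14),
                            seed = 5)
  res <- run_depth_sweep(cfg)
  expect_true(all(res$summary$pct_error < 0.1))
  expect_identical(as.numeric(clinical_imaging_depth(res, 150)), Inf)
  # noiseless recorded SNR is flagged infinite
  expect_true(all(!is.finite(res$cells$snr)))

  # rerun with the same seed is identical
  res2 <- run_depth_sweep(cfg)
  expect_identical(res$cells, res2$cells)
})

test_that("noise degrades deeper cells more while the signal stays detectable", {
  # in the responsive regime (recorded SNR well above 1 at both depths) the
  # deeper cell has lower SNR and more dispersed recovered rates
  cfg <- depth_sweep_config(depths_mm = c(4, 7), pO2_mmHg = 150,
                            replicates = 6, n_averages = 10, n_photons = 2e4,
                            nep = "auto", target_snr = 150,
                            voxel_mm = 0.8, grid_mm = c(24, 24, 16),
                            seed = 9)
  res <- run_depth_sweep(cfg)
  s <- res$summary[order(res$summary$depth_mm), ]
  expect_lt(s$mean_snr[2], s$mean_snr[1])
  expect_gt(s$mean_snr[2], 3)
  expect_gt(s$sd_rate[2], s$sd_rate[1])
})
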