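# Shared small fixtures, built in code.

# fast phantom for pipeline tests: coarse voxels, small grid
tiny_phantom <- function(depth_mm = 4, radius_mm = 3) {
  build_phantom(depth_mm, radius_mm, grid_mm = c(24, 24, 14), voxel_mm = 0.8)
}

# forward model cache so several tests can reuse one Monte Carlo run
.fwd_cache <- new.env(parent = emptyenv())
cached_forward <- function(pO2 = 150, n_photons = 1e4, seed = 7) {
  key <- sprintf("p%s_n%g_s%d", pO2, n_photons, seed)
  if (is.null(.fwd_cache[[key]])) {
    kt <- stern_volmer_rate(default_stern_volmer(), pO2)
    .fwd_cache[[key]] <- simulate_forward(tiny_phantom(), kt_truth = kt,
                                          n_photons = n_photons, seed = seed)
  }
  .fwd_cache[[key]]
}

# single-voxel pressure map for projection tests
point_pressure <- function(value = 1, at_mm = c(12, 12, 10),
                           grid_mm = c(24, 24, 14), voxel_mm = 0.8) {
  dims <- as.integer(round(grid_mm / voxel_mm))
  v <- array(0, dims)
  idx <- pmax(1, pmin(dims, ceiling(at_mm / voxel_mm)))
  v[idx[1], idx[2], idx[3]] <- value
  structure(list(values = v, grueneisen = 0.2, voxel_mm = voxel_mm,
                 dims = dims),
            class = "pali_pressure")
}

# minimal sweep-summary data frame for the depth-criteria functions
fake_summary <- function(depths, pO2, error_mmHg = 0, mean_pct = 0,
                         sd_pct = 1, mean_snr = 10) {
  data.frame(depth_mm = depths, pO2_mmHg = pO2,
             mean_rate = NA, sd_rate = NA, pct_error = mean_pct,
             mean_pct_error = mean_pct, sd_pct_error = sd_pct,
             error_mmHg = error_mmHg, mean_snr = mean_snr,
             n_ok = 7)
}
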