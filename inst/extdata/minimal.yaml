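# Minimal single-acquisition fixture: 4 mm node in a small fast grid,
# noiseless, reduced photon count. Intended for smoke tests of the CLI.
depth_mm: 4
node_radius_mm: 3
dye_conc_M: 4.0e-4
grid_mm: [24, 24, 14]
voxel_mm: 0.8
pO2_mmHg: 150
n_averages: 4
n_photons: 1.0e4
nep: 0
n_delays: 12
t_min_us: 0.5
t_max_us: 1000
fit_model: auto
seed: 1
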