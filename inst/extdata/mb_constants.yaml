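# Methylene-blue photophysical defaults (literature-typical values; all
# overridable). Units noted per field.
eta: 0.52                 # triplet quantum yield (dimensionless)
sigma_g: 3.632e-16        # ground-state absorption cross-section at 660 nm (cm^2)
eps_triplet: 1.4e4        # triplet molar extinction at 830 nm (1/(M cm), decadic)
eps_ground_probe: 500     # ground-state molar extinction at 830 nm (1/(M cm))
pump_pulse_s: 5.0e-9      # pump pulse duration (s)
k_dim: 2500               # monomer-dimer equilibrium constant (1/M)
total_conc_M: 4.0e-4      # total MB concentration (M)
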