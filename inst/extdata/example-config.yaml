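# Example micellekin pipeline configuration.
# Every omitted key falls back to the protocol defaults (submicellar
# cutoff 6, 10 repeats of 300 molecules, jackknife ratio 0.9, fit window
# 5000-15000 reduced time units).
surfactant:
  name: sds-like
  charged: true
  beta: 0.7          # counterion binding degree; required for ionic runs
  molar_mass: 288.4  # g/mol, for phi = V_m * C_tot under unit density
  wt_percent: 1.0
thermo:
  target_peak_n: 20  # micellar mode of the calibrated landscape
  c1: 0.01           # monomer density, reduced units
  aspect_ratio: 5    # length:girth, sets the packing penalty h
kinetics:
  n_max: 60
  t_end: 20000
  dt: 20
protocol:
  n_repeats: 10
  n_molecules: 300
  j_ratio: 0.9
  seed: 1
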