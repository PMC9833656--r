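# Default run configuration for the digital twin. Every physical quantity
# carries a unit tag; values are normalized to SI on load.
magnet:
  F0: 6.13e6 N/(A^2 m^3)
  x0: 2.258 mm
  I_max: 1 A
bead:
  d: 6.35 mm
  density: 7850 kg/m^3
cell:
  c_d: 1.68e-3 N s/m
  cell_mass: 10 mg
sample:
  l0: 8 mm
  d: 1 mm
  k: 5 N/m
  c: 0.1 N s/m
ccd:
  n_pixels: 3648
  pitch: 8 um
  frame_rate: 200 Hz
  adc_bits: 8
  noise_sd: 12 ADU
  delay_frames: 0
controller:
  p1: -60 1/s
  p2_real: -6.5 1/s
  p2_imag: 1 1/s
  I_init: 0.02 A
protocol:
  kind: ramp
  strain_rate: 2e-3 1/s
  target_strain: "0.1"
x_start: 8 mm
seed: 1
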