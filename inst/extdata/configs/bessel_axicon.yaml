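source:
  wavelength: 488 nm
  power: 1 mW
  profile: gaussian
  e2_width: 1 mm
element:
  kind: axicon
  alpha: 5 deg
  radius: 12.7 mm
  n_lens: 1.4631
  helical_order: 0
detector:
  distance: 10 mm
  extent:
  - 40 um
  - 40 um
  bins:
  - 40
  - 40
  normalization: max_pixel
run:
  n_packets: 1.0e+07
  seed: 1.0
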