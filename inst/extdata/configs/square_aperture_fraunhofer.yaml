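source:
  wavelength: 351 nm
  power: 1 mW
  profile: plane
element:
  kind: square_aperture
  side: 100 um
  screen_distance: 284.9 mm
detector:
  distance: 284.9 mm
  extent:
  - 8 mm
  - 100 um
  bins:
  - 160
  - 1
  ylim:
  - -50 um
  - 50 um
  normalization: max_pixel
run:
  n_packets: 1.0e+07
  seed: 1.0
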