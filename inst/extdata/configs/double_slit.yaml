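source:
  wavelength: 488 nm
  power: 1 mW
  profile: plane
element:
  kind: slit_pair
  slit_width: 4.88 um
  separation: 39.04 um
  screen_distance: 4.88 mm
  screen_extent: 1 mm
  slit_length: 10 um
detector:
  distance: 4.88 mm
  extent:
  - 1 mm
  - 20 um
  bins:
  - 2048
  - 1
  ylim:
  - -10 um
  - 10 um
  normalization: max_pixel
run:
  n_packets: 1.0e+07
  seed: 1.0
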