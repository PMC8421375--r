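source:
  wavelength: 488 nm
  power: 1 mW
  profile: gaussian
  e2_width: 0.5 mm
element:
  kind: planoconvex_lens
  radius: 5 mm
  thickness: 2.2 mm
  roc: 4.6 mm
  n_lens: 1.4631
detector:
  distance: 9.933 mm
  extent:
  - 40 um
  - 40 um
  bins:
  - 40
  - 1
  ylim:
  - -20 um
  - 20 um
  normalization: max_pixel
run:
  n_packets: 1000000.0
  seed: 1.0
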