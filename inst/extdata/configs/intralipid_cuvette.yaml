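source:
  wavelength: 488 nm
  power: 1 mW
  profile: gaussian
  e2_width: 2 mm
element:
  kind: axicon
  alpha: 5 deg
  radius: 12.7 mm
  n_lens: 1.4631
medium:
  thickness: 2 mm
  width: 2 mm
  height: 2 mm
  distance: 10 mm
  entry_window: 30 um
  intralipid_volume_ul: 2.0
  scaling: table
  g: 0.82
  'n': 1.33
detector:
  distance: 12 mm
  extent:
  - 40 um
  - 40 um
  bins:
  - 40
  - 40
  normalization: max_pixel
run:
  n_packets: 1000000.0
  seed: 1.0
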