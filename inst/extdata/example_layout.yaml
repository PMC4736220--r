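# Illustrative mini configuration: 4 phantom locations, 2 tissues.
# Weights are ICRP 103 values; the mapping and fractions are didactic.
locations: [thyroid_l, thyroid_r, mandible, calvarium]
tissues:
  thyroid:
    weight: 0.04
    fraction: 1.0
    locations: [thyroid_l, thyroid_r]
  bone_marrow:
    weight: 0.12
    fraction: 0.165
    locations: [mandible, calvarium]
design:
  n_exposures: 50
  exposure_s: 5
  single_exposure_s: 0.6
known_dose: 10      # mGy delivered to the calibration dosimeters
dose_to_uSv: 1000   # tissue doses in mGy -> effective dose in uSv
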