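# Synthetic mIEF gel: 12 lanes, pH 5.2-7.8 gradient, four Hb bands with
# contents 0.80/0.05/0.10/0.05, mild noise.
image_width: 640
image_height: 640
n_lanes: 12
lane_width: 30
pH_low: 5.2
pH_high: 7.8
background_level: 200
illumination_gradient: 0.02
noise_sigma: 2
lane_curvature: 0
bubble_count: 2
exposure_scale: 1
seed: 1
bands:
  - class_label: HbA1c_A0
    pI: 6.80
    amplitude: 150
    sigma_y: 5
    fraction: 0.80
  - class_label: HbF
    pI: 7.10
    amplitude: 120
    sigma_y: 4
    fraction: 0.05
  - class_label: MetHb
    pI: 7.35
    amplitude: 120
    sigma_y: 4
    fraction: 0.10
  - class_label: HbA2
    pI: 7.60
    amplitude: 120
    sigma_y: 4
    fraction: 0.05
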