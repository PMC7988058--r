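# Packaged demo: a small synthetic cohort exercising the whole pipeline.
# Run with:  filtrad run --config demo_config.yaml --out <dir>
cohort:
  n_patients: 12
  beta_mpp: -0.117
  seed: 731
  phantom:
    grid_shape: [14, 40, 40]
    spacing_mm: [2.5, 1.0, 1.0]
ssf_list: [0, 2, 3, 4, 5, 6]
screen_p: 0.05
endpoints: [os, pfs]
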