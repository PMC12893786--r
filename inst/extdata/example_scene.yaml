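# Example synthetic-scene configuration for `pam synth`.
duration_s: 2.0
sample_rate: 576000
ambient_spl_db: 95
snap_rate: 1
clicks:
  - carrier_khz: 86
    sigma_us: 8
    splpp_db: 160
    onset_s: 0.5
  - carrier_khz: 95
    sigma_us: 6
    splpp_db: 158
    onset_s: 1.2
whistles:
  - shape: upsweep
    duration_ms: 350
    freq_anchors_khz: [5, 9]
    snr_db: 20
    onset_s: 0.8
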