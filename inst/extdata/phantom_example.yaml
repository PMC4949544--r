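# Example configuration for `relb1map phantom --config ...`
# Synthetic 8-channel torso-like phantom (all lengths in fractions of the
# half field of view; angles in degrees at this boundary).
grid: [64, 64]
semi_axes: [0.75, 0.55]
n_channels: 8
coil_scale: 1.15
decay: 0.4
f_peak: 1.0
snr: 5300
params:
  TR_ms: 6
  TE_ms: 2.1
  T1_ms: 451
  T2star_ms: 25
  theta_ref_deg: 273
  drive_scheme:
    kind: logarithmic
    n_drives: 4
    tol: 0.02
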