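# Example configuration for `relb1map design-drives --config ...`
# 7 T in-vivo-style sequence; minimum drive from the 1% linearity rule.
TR_ms: 6
TE_ms: 2.1
T1_ms: 451
T2star_ms: 25
theta_ref_deg: 273
drive_scheme:
  kind: logarithmic
  n_drives: 4
  tol: 0.01
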