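# Example configuration for `relb1map simulate --config ...`
# Full-size Monte Carlo error-characterisation study at TR/T1 = 0.01.
theta_ref_deg: 273
tr_over_t1: [0.01]
TE: 4
T2star: 100
snr_levels: [1.0, 0.22, 0.05]
snr_ref: 5300
n_repeats: 50
n_drives: [3, 4, 6, 12]
schemes: [linear, logarithmic]
d_min_tol: 0.01
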