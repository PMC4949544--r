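# relb1map

Relative transmit-field (B1+) mapping for parallel-transmit MRI in the
presence of a large transmit dynamic range.

## The problem

Parallel transmission (PTx) needs a per-channel map of the transmit field.
Surface transmit elements produce fields that are very strong at the body
wall and weak at depth, so no single low-flip-angle (LFA) spoiled gradient
echo (SPGR) image works everywhere: a drive low enough to stay linear next
to the coil is noise-limited at depth, and a drive strong enough at depth
saturates near the coil. `relb1map` implements the multi-drive answer:
acquire SPGR images at several RF drive scales `d_1 < ... < d_N <= 1` per
channel and combine them per voxel with a maximum-likelihood estimator that
automatically rejects saturated measurements.

## The method

The SPGR steady-state signal at flip angle θ_j = f·d_j·θ_ref is

    S_j = M0·R·(1−E1)·e^(−TE/T2*)·e^(iφ) · sinθ_j / (1 − E1·cosθ_j) + ε(σ),
    E1 = e^(−TR/T1),

which is ≈ ρ·f·d_j at low flip angle. Drive-normalized measurements
S'_j = S_j/d_j (noise σ'_j = σ/d_j) share the mean ρf while unsaturated.
For each model order k the closed-form maximum-likelihood estimate and its
log-likelihood are

    γ̂_k = Σ_{j≤k} d_j²·S'_j / Σ_{j≤k} d_j²,
    L_k(γ̂_k) = −k·ln2π − Σ_{j≤k} [2·lnσ'_j + |S'_j − γ̂_k|²/(2σ'_j²)],

and the reconstruction keeps k_max = argmax_k L_k(γ̂_k): saturated
measurements pay a residual penalty that outweighs their likelihood gain and
are excluded. The complex γ̂ images of all channels are then turned into
relative maps rT_j = I_j / Σ_c |I_c| (magnitudes sum to 1; receive field and
tissue factors cancel; relative phases preserved).

The package also provides drive-scheme design from a linearity tolerance
(`min_drive()`, `make_drive_scheme()` with linear or logarithmic spacing), a
synthetic multi-channel phantom with ground truth, the Monte Carlo
error-characterisation study (`run_study()`), background noise estimation,
and NIfTI/JSON input-output plus a command-line front end
(`exec/relb1map`: `phantom`, `design-drives`, `reconstruct`, `relmap`,
`simulate`).

## Worked example

Design a 4-drive logarithmic scheme for a 7 T body-array protocol
(TR = 6 ms, T1 = 451 ms, reference flip angle 273°), simulate an 8-channel
phantom acquisition, reconstruct, and score against the ground truth:

```r
library(relb1map)

p <- spgr_params(TR = 6, T1 = 451, theta_ref = 273 * pi / 180,
                 TE = 2.1, T2star = 25)
round(100 * saturation_error(p, 1 * pi / 180), 2)
#> [1] 1.13        # a 1-degree flip is linear to ~1.1% at this TR/T1

d_min <- min_drive(p, f_max = 1, tol = 0.02)
make_drive_scheme(as.numeric(d_min), 4, "logarithmic")
#> RF drive scheme (logarithmic, N = 4):
#>   0.004896  0.02883  0.1698  1

cfg   <- phantom_config(seed = 1)      # 64x64, 8 channels, SNR 5300
truth <- make_transmit_fields(cfg)
acq   <- simulate_acquisition(truth, cfg)
rec   <- reconstruct_stack(acq$stack, acq$drives, acq$sigma)
maps  <- relative_map(rec$gamma)
maps
#> Relative B1+ maps: 64 x 64 voxels, 8 channels (ch1, ch2, ..., ch8)
#>   0 voxel(s) with zero denominator

recovery_report(truth, maps)[1:3, 1:4]
#>   channel mag_mean mag_median mag_p95
#> 1       1  0.00052    0.00028 0.00164
#> 2       2  0.00062    0.00039 0.00194
#> 3       3  0.00071    0.00051 0.00204
```

The relative-map magnitudes are recovered to a few parts in 10^4 across the
object, and `rec$k_max` (1 near the coils, 4 at depth) shows the estimator
discarding saturated high-drive measurements exactly where the field is
strong.

A single saturated voxel, by hand:

```r
select_kmax(voxel_series(c(0.1, 0.5), drives = c(0.1, 1), sigma = 0.01))
#> MLE reconstruction: k_max = 1 of 2
#>   gamma_hat = 1 +0i  (|.| = 1, arg = 0 rad)
```

The second measurement (0.5 after normalization, 50 σ' below the first) is
rejected and only the low-drive measurement is kept.

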