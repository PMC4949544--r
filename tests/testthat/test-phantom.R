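# smaller grid than the default keeps the suite fast; physics unchanged
small_config <- function(...) phantom_config(grid = c(32, 32), ...)

test_that("transmit fields peak at the coil and decay exponentially", {
  cfg <- small_config()
  truth <- make_transmit_fields(cfg)
  fm <- Mod(truth$f_maps)
  for (c_i in seq_len(cfg$n_channels))
    expect_equal(max(fm[, , c_i][truth$mask]), cfg$f_peak)
  # monotone decay along the ray from channel 1's coil (on +x axis)
  # through the object centre: row through the centre, decreasing towards -x
  mid <- ceiling(cfg$grid[2] / 2)
  prof <- fm[, mid, 1]
  inside <- which(truth$mask[, mid])
  expect_true(all(diff(prof[inside]) > 0))  # increases towards the +x coil
  # exponential decay: log-magnitude is linear in distance with slope -1/L
  g <- truth$coils[1, ]
  x <- seq(-1, 1, length.out = cfg$grid[1])[inside]
  y0 <- seq(-1, 1, length.out = cfg$grid[2])[mid]
  dist <- sqrt((x - g["x"])^2 + (y0 - g["y"])^2)
  fit <- stats::lm(log(prof[inside]) ~ dist)
  expect_equal(unname(stats::coef(fit)[2]), -1 / cfg$decay,
               tolerance = 1e-6)
  # dynamic range across the object is large (>= 20:1 by default)
  expect_gte(max(fm[, , 1][truth$mask]) / min(fm[, , 1][truth$mask]), 20)
  # true relative maps satisfy the unit-magnitude-sum invariant inside
  sums <- apply(Mod(truth$rT_true$rT), c(1, 2), sum)
  expect_equal(sums[truth$mask], rep(1, sum(truth$mask)), tolerance = 1e-12)
})

test_that("simulated acquisition follows the forward model plus noise", {
  cfg <- small_config(snr = Inf)
  truth <- make_transmit_fields(cfg)
  acq <- simulate_acquisition(truth, cfg)
  expect_equal(acq$sigma, 0)
  # noise-free voxel values equal the SPGR forward model directly
  p <- cfg$params
  idx <- which(truth$mask, arr.ind = TRUE)[1, ]
  f <- truth$f_maps[idx[1], idx[2], 3]
  d <- as.numeric(cfg$drives)
  manual <- spgr_signal(p, Mod(f), d) * truth$receive[idx[1], idx[2]] *
    exp(1i * Arg(f))
  expect_equal(acq$stack[idx[1], idx[2], 3, ], manual, tolerance = 1e-12)
  # background is pure noise (zero when noise-free)
  expect_true(all(acq$stack[!truth$mask] == 0))
  # doubling M0 doubles every noise-free intensity
  cfg2 <- small_config(snr = Inf,
                       params = spgr_params(TR = 6, TE = 2.1, T1 = 451,
                                            T2star = 25,
                                            theta_ref = 273 * pi / 180,
                                            M0 = 2))
  acq2 <- simulate_acquisition(make_transmit_fields(cfg2), cfg2)
  expect_equal(acq2$stack, 2 * acq$stack, tolerance = 1e-12)
})

test_that("noise level is reproducible and recoverable from the background", {
  cfg <- small_config(seed = 9)
  truth <- make_transmit_fields(cfg)
  acq <- simulate_acquisition(truth, cfg)
  expect_gt(acq$sigma, 0)
  bg <- acq$stack[, , 1, 1][!truth$mask]
  expect_gte(length(bg), 200)
  expect_equal(estimate_sigma(bg), acq$sigma, tolerance = 0.1)
  # same seed, same data
  acq_again <- simulate_acquisition(truth, cfg)
  expect_identical(acq$stack, acq_again$stack)
})

test_that("recovery report is zero for a perfect reconstruction", {
  cfg <- small_config()
  truth <- make_transmit_fields(cfg)
  rep0 <- recovery_report(truth, truth$rT_true)
  expect_equal(max(rep0$mag_p95), 0)
  expect_equal(max(rep0$ph_p95), 0)
  expect_error(recovery_report(truth,
                               relative_map(array(1 + 0i, c(4, 4, 2)))),
               "grid")
})

test_that("full pipeline recovers the true relative maps", {
  # noise-free, fully linear regime: tiny reference angle, moderate drives
  lin_cfg <- small_config(
    params = spgr_params(TR = 6, TE = 2.1, T1 = 451, T2star = 25,
                         theta_ref = 1e-4),
    drives = drive_scheme(c(0.25, 0.5, 1)), snr = Inf)
  truth <- make_transmit_fields(lin_cfg)
  acq <- simulate_acquisition(truth, lin_cfg)
  rec <- reconstruct_stack(acq$stack, acq$drives,
                           sigma = max(Mod(acq$stack)) * 1e-9)
  rep_lin <- recovery_report(truth, relative_map(rec$gamma))
  expect_lt(max(rep_lin$mag_p95), 1e-6)
  expect_lt(max(rep_lin$ph_p95), 1e-6)

  # default noisy phantom: drives designed at a 2% linearity tolerance
  cfg <- small_config(seed = 2)
  truth <- make_transmit_fields(cfg)
  acq <- simulate_acquisition(truth, cfg)
  rec <- reconstruct_stack(acq$stack, acq$drives, acq$sigma)
  maps <- relative_map(rec$gamma)
  repn <- recovery_report(truth, maps)
  expect_lt(max(repn$mag_median), 0.02)
  # regression pin from the first validated run of this configuration
  expect_lt(max(repn$mag_median), 0.002)

  # k_max anti-correlates with the local field strength
  rho_s <- vapply(seq_len(cfg$n_channels), function(c_i)
    stats::cor(rec$k_max[, , c_i][truth$mask],
               Mod(truth$f_maps[, , c_i])[truth$mask],
               method = "spearman"), numeric(1))
  expect_true(all(rho_s < 0))

  # lowest-drive-only maps are noisier where the field is weak
  d1 <- as.numeric(cfg$drives)[1]
  maps_d1 <- relative_map(acq$stack[, , , 1] / d1)
  low <- array(truth$mask, dim(maps$rT)) & (Mod(truth$f_maps) < 0.2)
  err_mle <- abs(Mod(maps$rT[low]) - Mod(truth$rT_true$rT[low]))
  err_d1 <- abs(Mod(maps_d1$rT[low]) - Mod(truth$rT_true$rT[low]))
  expect_lt(stats::median(err_mle), stats::median(err_d1))
})
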