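#' Configuration for the synthetic multi-channel phantom
#'
#' Describes a 2-D elliptical object surrounded by a ring of transmit
#' elements, emulating a body-array acquisition: each channel's transmit
#' field is strongest at the object surface next to its element and decays
#' with distance, giving the large dynamic range (>= 20:1 across the object
#' by default) that the multi-drive MLE reconstruction is designed for. A
#' smooth complex receive field stands in for the combined receive channels.
#'
#' Coordinates are normalized so the field of view spans `[-1, 1]` in both
#' directions.
#'
#' @param grid Image dimensions, length-2 integer vector. Default
#'   `c(64, 64)`.
#' @param semi_axes Ellipse semi-axes of the object in FOV units. Default
#'   `c(0.75, 0.55)` (axial torso-like).
#' @param n_channels Number of transmit elements placed uniformly on a ring
#'   just outside the object. Default 8.
#' @param coil_scale Ring radius as a multiple of the object ellipse.
#'   Default 1.15 (must be > 1 so elements sit outside the object).
#' @param decay Transmit-field decay length in FOV units: `|f|` falls as
#'   `exp(-distance / decay)` from each element. Default 0.4, giving a
#'   dynamic range of about 50:1 across the object.
#' @param f_peak Peak transmit sensitivity: `|f|` at the object voxel
#'   nearest each element. Default 1.
#' @param phase_rate Transmit phase advance in rad per FOV unit of distance
#'   from the element (a smooth propagation-like phase). Default 2.
#' @param params An [spgr_params()] object. Default: 7 T liver-protocol-like
#'   constants (TR = 6 ms, TE = 2.1 ms, T1 = 451 ms, T2* = 25 ms,
#'   theta_ref = 273 deg).
#' @param drives A [drive_scheme()]. Default: 4 logarithmically spaced
#'   drives with the minimum set by [min_drive()] at a 2 % linearity
#'   tolerance for `f_peak`.
#' @param snr Reference signal-to-noise ratio: maximum noise-free signal
#'   magnitude over the whole acquisition divided by the noise standard
#'   deviation. Default 5300. `Inf` gives noise-free data.
#' @param seed RNG seed for the noise draws. Default 1.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid = c(64, 64),
                           semi_axes = c(0.75, 0.55),
                           n_channels = 8,
                           coil_scale = 1.15,
                           decay = 0.4,
                           f_peak = 1,
                           phase_rate = 2,
                           params = spgr_params(TR = 6, TE = 2.1, T1 = 451,
                                                T2star = 25,
                                                theta_ref = 273 * pi / 180),
                           drives = NULL,
                           snr = 5300,
                           seed = 1L) {
  stopifnot(length(grid) == 2L, all(grid >= 8),
            length(semi_axes) == 2L, all(semi_axes > 0),
            all(semi_axes < 1),
            n_channels >= 1, coil_scale > 1,
            decay > 0, f_peak > 0, snr > 0,
            inherits(params, "spgr_params"))
  if (is.null(drives)) {
    dmin <- suppressMessages(min_drive(params, f_max = f_peak, tol = 0.02))
    drives <- if (dmin >= 1) drive_scheme(1) else
      make_drive_scheme(as.numeric(dmin), 4, "logarithmic")
  }
  if (!inherits(drives, "drive_scheme")) drives <- drive_scheme(drives)
  structure(list(grid = as.integer(grid), semi_axes = semi_axes,
                 n_channels = as.integer(n_channels),
                 coil_scale = coil_scale, decay = decay, f_peak = f_peak,
                 phase_rate = phase_rate, params = params, drives = drives,
                 snr = snr, seed = as.integer(seed)),
            class = "phantom_config")
}

# normalized pixel-center coordinate grids and object mask
phantom_geometry <- function(config) {
  nx <- config$grid[1]; ny <- config$grid[2]
  x <- seq(-1, 1, length.out = nx)
  y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  mask <- (X / config$semi_axes[1])^2 + (Y / config$semi_axes[2])^2 <= 1
  ang <- 2 * pi * (seq_len(config$n_channels) - 1) / config$n_channels
  coils <- cbind(x = config$coil_scale * config$semi_axes[1] * cos(ang),
                 y = config$coil_scale * config$semi_axes[2] * sin(ang))
  list(X = X, Y = Y, mask = mask, coils = coils)
}

#' Generate ground-truth transmit and receive fields
#'
#' Builds, per channel, a complex transmit-sensitivity image whose magnitude
#' decays exponentially with distance from the channel's element (normalized
#' so the object voxel nearest the element has `|f| = f_peak`) and whose
#' phase advances smoothly with that distance plus a per-channel offset.
#' Also builds the shared smooth complex receive field and the true relative
#' maps and linear-coefficient image against which reconstructions can be
#' scored.
#'
#' @param config A [phantom_config()].
#' @return A `ground_truth` object: list with `f_maps` (complex array
#'   `[x, y, channel]`, zero outside the object), `rT_true`
#'   (`relative_maps` of the true fields), `receive` (complex matrix),
#'   `rho` (complex matrix: the linear coefficient
#'   \eqn{\rho = M_0 R e^{-TE/T_2^*} e^{i\phi}\theta_{ref}} per voxel),
#'   `mask`, and `coils`.
#' @export
make_transmit_fields <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- phantom_geometry(config)
  if (!any(g$mask)) stop("degenerate geometry: object mask is empty")
  nch <- config$n_channels
  f_maps <- array(0 + 0i, c(config$grid, nch))
  for (c_i in seq_len(nch)) {
    dist <- sqrt((g$X - g$coils[c_i, 1])^2 + (g$Y - g$coils[c_i, 2])^2)
    mag <- exp(-dist / config$decay)
    mag <- mag / max(mag[g$mask]) * config$f_peak
    ph <- -config$phase_rate * dist + 2 * pi * (c_i - 1) / nch
    fc <- mag * exp(1i * ph)
    fc[!g$mask] <- 0 + 0i
    f_maps[, , c_i] <- fc
  }
  # smooth receive field: broad off-center lobe over a uniform floor,
  # with a gentle linear phase ramp
  receive <- (0.6 + 0.8 * exp(-((g$X - 0.2)^2 + (g$Y + 0.6)^2) / 0.5)) *
    exp(1i * (0.3 * g$X + 0.2 * g$Y + 0.5))
  rho <- config$params$M0 * receive *
    exp(-config$params$TE / config$params$T2star) *
    exp(1i * config$params$phi) * config$params$theta_ref
  structure(list(f_maps = f_maps, rT_true = relative_map(f_maps),
                 receive = receive, rho = rho, mask = g$mask,
                 coils = g$coils),
            class = "ground_truth")
}

#' Simulate a multi-channel, multi-drive SPGR acquisition
#'
#' Evaluates the SPGR steady-state signal at every voxel for every channel
#' and drive — flip angle \eqn{\theta = |f| d \theta_{ref}}, complex phase
#' from the transmit field and the receive weight — and adds independent
#' complex Gaussian noise. The noise standard deviation is set from the
#' maximum noise-free signal magnitude over the whole dataset divided by
#' `config$snr` (the reference-SNR convention; the strongest voxel plays the
#' role of a region next to a receive element). Background voxels outside
#' the object are pure noise.
#'
#' @param truth A [make_transmit_fields()] result.
#' @param config The [phantom_config()] used to build `truth`.
#' @return A list with `stack` (complex array `[x, y, channel, drive]`),
#'   `sigma` (the noise standard deviation actually used; 0 when
#'   `snr = Inf`), `drives` and `config`.
#' @export
simulate_acquisition <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "phantom_config"))
  p <- config$params
  d <- as.numeric(config$drives)
  nd <- length(d)
  nch <- config$n_channels
  dm <- c(config$grid, nch, nd)
  E1 <- exp(-p$TR / p$T1)
  pref <- p$M0 * exp(-p$TE / p$T2star) * exp(1i * p$phi) * (1 - E1)
  stack <- array(0 + 0i, dm)
  for (c_i in seq_len(nch)) {
    f <- truth$f_maps[, , c_i]
    fm <- Mod(f)
    phs <- exp(1i * Arg(f))
    phs[fm == 0] <- 0 + 0i  # background carries no signal
    for (j in seq_len(nd)) {
      theta <- fm * d[j] * p$theta_ref
      stack[, , c_i, j] <- pref * truth$receive * phs *
        sin(theta) / (1 - E1 * cos(theta))
    }
  }
  sigma <- if (is.infinite(config$snr)) 0 else max(Mod(stack)) / config$snr
  if (sigma > 0) {
    set.seed(config$seed)
    n <- length(stack)
    stack <- stack + complex(real = rnorm(n, sd = sigma),
                             imaginary = rnorm(n, sd = sigma))
  }
  list(stack = stack, sigma = sigma, drives = config$drives,
       config = config)
}

#' Score reconstructed relative maps against the ground truth
#'
#' Per-channel summaries, over the object mask, of the absolute error in
#' relative-map magnitude `||rT_est| - |rT_true||` and of the absolute
#' wrapped phase error.
#'
#' Reconstructed images carry the common receive-chain phase, which cancels
#' between channels but not against the ground-truth transmit phase; only
#' relative phases are physically determined. The phase error is therefore
#' computed after removing, per voxel, the common-mode phase offset across
#' channels (the circular mean of the per-channel est-vs-truth phase
#' differences).
#'
#' @param truth A [make_transmit_fields()] result.
#' @param recon A `relative_maps` object on the same grid (e.g. from
#'   [relative_map()] applied to reconstructed channel images).
#' @return A data frame with one row per channel: mean, median and 95th
#'   percentile of the magnitude error, and the same for the phase error
#'   (radians).
#' @export
recovery_report <- function(truth, recon) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(recon, "relative_maps"))
  if (!identical(dim(truth$rT_true$rT), dim(recon$rT)))
    stop("reconstruction grid does not match the ground truth")
  nch <- dim(recon$rT)[3]
  m <- truth$mask
  # per-voxel common-mode phase offset across channels
  delta <- vapply(seq_len(nch), function(c_i) {
    est <- recon$rT[, , c_i][m]
    tru <- truth$rT_true$rT[, , c_i][m]
    est * Conj(tru)
  }, complex(sum(m)))
  common <- Arg(rowSums(delta / pmax(Mod(delta), .Machine$double.eps)))
  rows <- lapply(seq_len(nch), function(c_i) {
    est <- recon$rT[, , c_i][m]
    tru <- truth$rT_true$rT[, , c_i][m]
    mag_err <- abs(Mod(est) - Mod(tru))
    ph_err <- abs(Arg(exp(1i * (Arg(est) - Arg(tru) - common))))
    data.frame(channel = c_i,
               mag_mean = mean(mag_err),
               mag_median = stats::median(mag_err),
               mag_p95 = unname(stats::quantile(mag_err, 0.95)),
               ph_mean = mean(ph_err),
               ph_median = stats::median(ph_err),
               ph_p95 = unname(stats::quantile(ph_err, 0.95)))
  })
  do.call(rbind, rows)
}
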