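#' Configuration of the Monte Carlo error-characterisation study
#'
#' Defines the grid of simulated conditions under which the multi-drive MLE
#' reconstruction is scored: transmit sensitivities spanning the full
#' dynamic range, sequence TR/T1 ratios, SNR levels expressed as fractions
#' of a reference SNR, drive counts and sampling schemes. Defaults follow
#' the study design the method was characterised with: 50 sensitivities
#' linearly spaced on [0.001, 1], a reference flip angle of 273 degrees,
#' TR/T1 in {0.01, 0.07}, TE = 4 ms, T2* = 100 ms, SNR levels of 100 %,
#' 22 % and 5 % of SNR_ref = 5300, 50 noise repeats, N in {3, 4, 6, 12}
#' drives, both linear and logarithmic sampling, and a minimum drive chosen
#' by the 1 % linearity rule.
#'
#' The simulated transmit phase is pi/4 so that the relative phase error
#' metric has a well-defined nonzero denominator.
#'
#' @param f_grid Transmit sensitivities to simulate.
#' @param theta_ref Reference flip angle (radians).
#' @param tr_over_t1 TR/T1 ratios (TR is held at 10 ms and T1 varied).
#' @param TE,T2star Echo time and apparent transverse relaxation (ms).
#' @param snr_levels Fractions of `snr_ref`.
#' @param snr_ref Reference SNR (maximum noise-free signal magnitude over
#'   the cell's whole sensitivity grid and drive set, divided by the noise
#'   standard deviation).
#' @param n_repeats Independent noise instances per condition (>= 2).
#' @param n_drives Drive counts to test.
#' @param schemes Drive sampling schemes, subset of
#'   `c("linear", "logarithmic")`.
#' @param d_min_tol Linearity tolerance for the minimum-drive rule.
#' @param phi True transmit phase (radians).
#' @param seed RNG seed.
#' @return A `study_config` object.
#' @export
study_config <- function(f_grid = seq(0.001, 1, length.out = 50),
                         theta_ref = 273 * pi / 180,
                         tr_over_t1 = c(0.01, 0.07),
                         TE = 4, T2star = 100,
                         snr_levels = c(1, 0.22, 0.05),
                         snr_ref = 5300,
                         n_repeats = 50,
                         n_drives = c(3, 4, 6, 12),
                         schemes = c("linear", "logarithmic"),
                         d_min_tol = 0.01,
                         phi = pi / 4,
                         seed = 1L) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  stopifnot(length(f_grid) >= 1, all(f_grid > 0), all(f_grid <= 1),
            theta_ref > 0, all(tr_over_t1 > 0),
            length(snr_levels) >= 1, all(snr_levels > 0),
            n_repeats >= 2, all(n_drives >= 2),
            d_min_tol > 0, d_min_tol < 0.5)
  structure(list(f_grid = f_grid, theta_ref = theta_ref,
                 tr_over_t1 = tr_over_t1, TE = TE, T2star = T2star,
                 snr_levels = snr_levels, snr_ref = snr_ref,
                 n_repeats = as.integer(n_repeats),
                 n_drives = as.integer(n_drives), schemes = schemes,
                 d_min_tol = d_min_tol, phi = phi, seed = as.integer(seed)),
            class = "study_config")
}

# SPGR parameter set for one TR/T1 cell of the study
study_params <- function(config, trt1) {
  spgr_params(TR = 10, T1 = 10 / trt1, TE = config$TE,
              T2star = config$T2star, theta_ref = config$theta_ref,
              phi = config$phi)
}

#' Run the Monte Carlo reconstruction-error study
#'
#' For every combination of sampling scheme, drive count N, SNR level and
#' TR/T1: designs the drive scheme (minimum drive from the linearity rule,
#' maximum drive 1), simulates `n_repeats` noisy multi-drive SPGR
#' measurement series at each transmit sensitivity on the grid, reconstructs
#' each series with the saturation-rejecting MLE, and summarises the
#' per-sensitivity complex estimates \eqn{\eta_{a,b}} into the error
#' metrics
#' \deqn{\bar\delta_a = 1 - |\bar\eta_a / (\rho f_a)|, \qquad
#'       \bar\delta^{ph}_a = 1 - \angle\bar\eta_a / \angle(\rho f_a),}
#' where \eqn{\bar\eta_a} is the complex mean over noise instances. The
#' noise standard deviation of each cell is the maximum noise-free signal
#' magnitude over that cell's full sensitivity grid and drive set divided by
#' (SNR level x `snr_ref`).
#'
#' Deterministic given `config$seed`. With `snr_levels` containing `Inf`
#' the corresponding cells are noise-free (a nominal reconstruction sigma of
#' 1e-9 times the maximum signal is used, since the likelihood needs a
#' positive noise level).
#'
#' @param config A [study_config()].
#' @return A data frame of class `b1_error_table` with one row per
#'   (scheme, N, snr, tr_over_t1, f): columns `delta_mag`, `delta_mag_sd`,
#'   `delta_ph`, `delta_ph_sd`, `kmax_mode`, `d_min`, `sigma_norm` (sigma
#'   as a fraction of \eqn{|\rho|}).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  out <- list()
  for (trt1 in config$tr_over_t1) {
    p <- study_params(config, trt1)
    dmin <- as.numeric(
      suppressMessages(min_drive(p, f_max = 1, tol = config$d_min_tol)))
    rho <- spgr_prefactor(p) * p$theta_ref
    for (scheme in config$schemes) for (N in config$n_drives) {
      drives <- make_drive_scheme(dmin, N, scheme)
      d <- as.numeric(drives)
      # noise-free signals: f on rows, drives on columns
      S0 <- t(vapply(config$f_grid,
                     function(f) spgr_signal(p, f, d), complex(N)))
      s_max <- max(Mod(S0))
      for (snr_frac in config$snr_levels) {
        cell <- simulate_cell(S0, d, s_max, snr_frac, config, rho)
        cell$scheme <- scheme; cell$N <- N; cell$snr <- snr_frac
        cell$tr_over_t1 <- trt1; cell$d_min <- dmin
        out[[length(out) + 1L]] <- cell
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[, c("scheme", "N", "snr", "tr_over_t1", "f", "delta_mag",
                 "delta_mag_sd", "delta_ph", "delta_ph_sd", "kmax_mode",
                 "d_min", "sigma_norm")]
  class(out) <- c("b1_error_table", "data.frame")
  out
}

# one (scheme, N, snr) cell: simulate repeats, reconstruct, summarise
simulate_cell <- function(S0, d, s_max, snr_frac, config, rho) {
  nf <- nrow(S0); N <- ncol(S0); B <- config$n_repeats
  noise_free <- is.infinite(snr_frac)
  sigma <- if (noise_free) 0 else s_max / (snr_frac * config$snr_ref)
  sigma_rec <- if (noise_free) s_max * 1e-9 else sigma
  # rows: (f index, repeat) pairs; f varies fastest
  S <- S0[rep(seq_len(nf), times = B), , drop = FALSE]
  if (!noise_free) {
    n <- length(S)
    S <- S + complex(real = rnorm(n, sd = sigma),
                     imaginary = rnorm(n, sd = sigma))
  }
  Sp <- S / rep(d, each = nrow(S))
  res <- mle_core(Sp, d, sigma_rec)
  eta <- matrix(res$gamma, nf, B)       # complex estimates eta_{a,b}
  kmx <- matrix(res$k_max, nf, B)
  true_sig <- rho * config$f_grid       # unsaturated normalized signal
  ratio <- eta / true_sig
  eta_bar <- rowMeans(eta)
  delta_b <- 1 - Mod(ratio)             # per-repeat magnitude error
  dph_b <- 1 - Arg(eta) / Arg(true_sig) # per-repeat phase error
  data.frame(
    f = config$f_grid,
    delta_mag = 1 - Mod(eta_bar / true_sig),
    delta_mag_sd = apply(delta_b, 1, stats::sd),
    delta_ph = 1 - Arg(eta_bar) / Arg(true_sig),
    delta_ph_sd = apply(dph_b, 1, stats::sd),
    kmax_mode = apply(kmx, 1, stat_mode),
    sigma_norm = sigma / Mod(rho))
}

stat_mode <- function(x) {
  tb <- tabulate(x)
  which.max(tb)
}

#' Per-repeat reconstruction behaviour at one transmit sensitivity
#'
#' Returns the data behind a complex-plane scatter demonstration: the
#' normalized samples at every drive level for each noise repeat, the
#' reconstructed estimate of each repeat, and the true unsaturated signal
#' \eqn{\rho f}. At large `f` the normalized samples of the highest drives
#' collapse towards the origin because of saturation, while the estimate
#' tracks the unsaturated drives.
#'
#' @param config A [study_config()].
#' @param f Transmit sensitivity in (0, 1].
#' @param scheme Sampling scheme for the demonstrated cell.
#' @param N Number of drives.
#' @param snr_frac SNR level as a fraction of `snr_ref` (`Inf` for
#'   noise-free).
#' @param tr_over_t1 TR/T1 ratio of the cell.
#' @return A list with `samples` (complex matrix `n_repeats x N` of
#'   normalized measurements), `estimates` (complex vector per repeat),
#'   `k_max` (integer per repeat), `true_signal` (\eqn{\rho f}), `drives`
#'   and `sigma`.
#' @export
scatter_demo <- function(config, f, scheme = "logarithmic", N = 3,
                         snr_frac = 0.05, tr_over_t1 = 0.01) {
  stopifnot(inherits(config, "study_config"), f > 0, f <= 1)
  set.seed(config$seed)
  p <- study_params(config, tr_over_t1)
  dmin <- as.numeric(
    suppressMessages(min_drive(p, f_max = 1, tol = config$d_min_tol)))
  drives <- make_drive_scheme(dmin, N, scheme)
  d <- as.numeric(drives)
  rho <- spgr_prefactor(p) * p$theta_ref
  S0 <- t(vapply(config$f_grid, function(ff) spgr_signal(p, ff, d),
                 complex(N)))
  s_max <- max(Mod(S0))
  noise_free <- is.infinite(snr_frac)
  sigma <- if (noise_free) 0 else s_max / (snr_frac * config$snr_ref)
  sigma_rec <- if (noise_free) s_max * 1e-9 else sigma
  B <- config$n_repeats
  S <- matrix(spgr_signal(p, f, d), B, N, byrow = TRUE)
  if (!noise_free)
    S <- S + complex(real = rnorm(B * N, sd = sigma),
                     imaginary = rnorm(B * N, sd = sigma))
  Sp <- S / rep(d, each = B)
  res <- mle_core(Sp, d, sigma_rec)
  list(samples = Sp, estimates = res$gamma, k_max = res$k_max,
       true_signal = rho * f, drives = drives, sigma = sigma)
}

#' Extract phase-error curves from a study table
#'
#' Filters an error table to the logarithmic-sampling cells and returns the
#' mean relative phase error \eqn{\bar\delta^{ph}_a} versus transmit
#' sensitivity for each SNR level and drive count (expected to scatter
#' around zero: the estimator is phase-unbiased).
#'
#' @param table A [run_study()] result.
#' @return A data frame with columns `snr`, `N`, `tr_over_t1`, `f`,
#'   `delta_ph`, `delta_ph_sd`.
#' @export
phase_error_curves <- function(table) {
  stopifnot(inherits(table, "data.frame"),
            all(c("scheme", "delta_ph") %in% names(table)))
  tb <- table[table$scheme == "logarithmic",
              c("snr", "N", "tr_over_t1", "f", "delta_ph", "delta_ph_sd")]
  if (nrow(tb) == 0)
    stop("table contains no logarithmic-sampling cells")
  rownames(tb) <- NULL
  tb
}
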