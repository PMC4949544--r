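#' Multi-drive measurement series for one voxel and channel
#'
#' @param signals Complex raw measurements, one per drive, in drive order.
#' @param drives A [drive_scheme()] (or ascending numeric vector of drives).
#' @param sigma Noise standard deviation per real/imaginary channel, in the
#'   same units as `signals` (> 0).
#' @return A `voxel_series` object.
#' @export
voxel_series <- function(signals, drives, sigma) {
  if (!inherits(drives, "drive_scheme")) drives <- drive_scheme(drives)
  stopifnot(length(signals) == length(drives),
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  structure(list(signals = as.complex(signals), drives = drives,
                 sigma = sigma),
            class = "voxel_series")
}

#' Normalize a measurement series by its RF drives
#'
#' Divides each raw measurement by its drive, `S'_j = S_j / d_j`, so that
#' unsaturated measurements share the common mean \eqn{\rho f}; the noise
#' scales accordingly to `sigma'_j = sigma / d_j`, strictly decreasing along
#' the ascending drives.
#'
#' @param series A [voxel_series()].
#' @return A `normalized_series` object with fields `normalized`, `sigmas`
#'   and `drives`.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "voxel_series"))
  d <- as.numeric(series$drives)
  if (any(d <= 0)) stop("drives must be positive")
  structure(list(normalized = series$signals / d,
                 sigmas = series$sigma / d,
                 drives = series$drives,
                 sigma = series$sigma),
            class = "normalized_series")
}

#' Log-likelihood of a signal estimate under the first k measurements
#'
#' Evaluates, for the model in which the first `k` normalized measurements
#' are independent draws from 2-D (complex) normal distributions with common
#' mean `gamma` and standard deviations `sigma'_j` per real/imaginary part:
#' \deqn{L_k(\gamma) = -k\ln(2\pi) - \sum_{j=1}^{k}\left[2\ln\sigma'_j +
#'       \frac{|S'_j-\gamma|^2}{2\sigma'^2_j}\right].}
#' The constant terms are kept exactly: they differ across `k` and drive the
#' model-order selection in [select_kmax()].
#'
#' @param norm A [normalize_series()] result.
#' @param gamma Complex signal estimate.
#' @param k Number of lowest-drive measurements to include, in `[1, N]`.
#' @return The log-likelihood value.
#' @export
loglik_k <- function(norm, gamma, k) {
  stopifnot(inherits(norm, "normalized_series"))
  N <- length(norm$normalized)
  if (!(length(k) == 1L && k >= 1 && k <= N && k == round(k)))
    stop("k must be an integer in [1, N]")
  jj <- seq_len(k)
  s <- norm$sigmas[jj]
  -k * log(2 * pi) -
    sum(2 * log(s) + Mod(norm$normalized[jj] - gamma)^2 / (2 * s^2))
}

#' Closed-form maximum-likelihood signal estimate from k measurements
#'
#' The unique maximizer of [loglik_k()] in `gamma` is the inverse-variance
#' weighted mean of the first `k` normalized measurements; since
#' `1/sigma'^2_j` is proportional to `d_j^2`, this is the drive-squared
#' weighted mean
#' \deqn{\hat\gamma_k = \frac{\sum_{j=1}^k d_j^2 S'_j}{\sum_{j=1}^k d_j^2}.}
#'
#' @inheritParams loglik_k
#' @return Complex estimate.
#' @export
gamma_hat_k <- function(norm, k) {
  stopifnot(inherits(norm, "normalized_series"))
  N <- length(norm$normalized)
  if (!(length(k) == 1L && k >= 1 && k <= N && k == round(k)))
    stop("k must be an integer in [1, N]")
  jj <- seq_len(k)
  w <- as.numeric(norm$drives)[jj]^2
  sum(w * norm$normalized[jj]) / sum(w)
}

#' Maximum-likelihood reconstruction with saturation rejection
#'
#' For each model order `k = 1..N` computes the closed-form estimate
#' \eqn{\hat\gamma_k} and its log-likelihood \eqn{L_k(\hat\gamma_k)}, then
#' selects \eqn{k_{max} = \arg\max_k L_k(\hat\gamma_k)}. Measurements beyond
#' `k_max` are deemed saturated and contribute nothing to the estimate. The
#' returned estimate is complex, carrying both the amplitude and the phase
#' of the unsaturated signal.
#'
#' Ties in the log-likelihood (within 1e-12) resolve to the larger `k`,
#' i.e. to using more data; exact ties have measure zero on real data.
#'
#' @param norm A [normalize_series()] result (or a [voxel_series()], which
#'   is normalized first).
#' @return A `recon_estimate` object: list with `gamma_hat` (complex),
#'   `k_max` (integer) and `loglik` (numeric vector of the N per-order
#'   log-likelihoods).
#' @export
#' @examples
#' vs <- voxel_series(c(0.1, 0.5), drives = c(0.1, 1), sigma = 0.01)
#' select_kmax(vs)  # second drive grossly saturated -> k_max = 1
select_kmax <- function(norm) {
  if (inherits(norm, "voxel_series")) norm <- normalize_series(norm)
  stopifnot(inherits(norm, "normalized_series"))
  N <- length(norm$normalized)
  gam <- vapply(seq_len(N), function(k) gamma_hat_k(norm, k), complex(1))
  ll <- vapply(seq_len(N), function(k) loglik_k(norm, gam[k], k), numeric(1))
  k_max <- max(which(ll >= max(ll) - 1e-12))
  structure(list(gamma_hat = gam[k_max], k_max = k_max, loglik = ll),
            class = "recon_estimate")
}

#' @export
print.recon_estimate <- function(x, ...) {
  cat(sprintf("MLE reconstruction: k_max = %d of %d\n",
              x$k_max, length(x$loglik)))
  cat(sprintf("  gamma_hat = %.6g %+.6gi  (|.| = %.6g, arg = %.4g rad)\n",
              Re(x$gamma_hat), Im(x$gamma_hat), Mod(x$gamma_hat),
              Arg(x$gamma_hat)))
  invisible(x)
}

# Vectorized core: Sp is a V x N complex matrix of normalized signals
# (rows = voxels), d the N drives, sigma the global noise sd. Returns
# list(gamma = complex V, k_max = integer V, loglik = V x N matrix).
# Identical model to select_kmax(), evaluated via cumulative sufficient
# statistics: the residual term of L_k collapses to
# (sum_j d_j^2 |S'_j|^2 - |sum_j d_j^2 S'_j|^2 / sum_j d_j^2) / (2 sigma^2).
mle_core <- function(Sp, d, sigma) {
  Sp <- matrix(as.complex(Sp), nrow = NROW(Sp))
  V <- nrow(Sp); N <- length(d)
  stopifnot(ncol(Sp) == N, sigma > 0)
  w <- d^2
  cw <- cumsum(w)
  # lower-triangular accumulator: (Sp * w) %*% Tk gives cumulative sums
  Tk <- outer(seq_len(N), seq_len(N), "<=") * 1
  B <- (Sp * rep(w, each = V)) %*% Tk                  # sum_{j<=k} w_j S'_j
  P <- (Mod(Sp)^2 * rep(w, each = V)) %*% Tk           # sum_{j<=k} w_j |S'_j|^2
  gamma_k <- B / rep(cw, each = V)
  const_k <- -seq_len(N) * log(2 * pi) - cumsum(2 * log(sigma / d))
  ll <- rep(const_k, each = V) - (Re(P) - Mod(B)^2 / rep(cw, each = V)) /
    (2 * sigma^2)
  # largest k within 1e-12 of the row maximum
  mx <- do.call(pmax, lapply(seq_len(N), function(k) ll[, k, drop = TRUE]))
  hit <- (ll >= mx - 1e-12) * rep(seq_len(N), each = V)
  k_max <- if (N == 1L) rep(1L, V) else max.col(hit, ties.method = "first")
  list(gamma = gamma_k[cbind(seq_len(V), k_max)],
       k_max = as.integer(k_max), loglik = ll)
}

#' Reconstruct a full multi-channel, multi-drive image stack
#'
#' Applies the per-voxel maximum-likelihood combination ([select_kmax()])
#' independently to every voxel of every transmit channel. The result is one
#' complex image per channel whose intensity is proportional to the
#' channel's transmit sensitivity (times the shared receive/tissue factor),
#' plus an integer map of how many low-drive measurements each voxel used.
#'
#' @param stack Complex 4-D array `[x, y, channel, drive]` of raw images.
#' @param drives A [drive_scheme()] (or ascending numeric vector) of length
#'   `dim(stack)[4]`.
#' @param sigma Global noise standard deviation per real/imaginary channel
#'   (> 0), e.g. from [estimate_sigma()].
#' @return A list with `gamma` (complex array `[x, y, channel]`), `k_max`
#'   (integer array `[x, y, channel]`), `drives` and `sigma`.
#' @export
reconstruct_stack <- function(stack, drives, sigma) {
  if (!inherits(drives, "drive_scheme")) drives <- drive_scheme(drives)
  dm <- dim(stack)
  if (length(dm) != 4L)
    stop("stack must be a 4-D array [x, y, channel, drive]")
  if (dm[4] != length(drives))
    stop("number of drive volumes (", dm[4], ") does not match the drive ",
         "scheme (", length(drives), ")")
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  d <- as.numeric(drives)
  nvox <- dm[1] * dm[2]
  gamma <- array(complex(1), dm[1:3])
  k_max <- array(NA_integer_, dm[1:3])
  for (ch in seq_len(dm[3])) {
    raw <- matrix(stack[, , ch, ], nrow = nvox)           # voxels x drives
    Sp <- raw / rep(d, each = nvox)                       # normalize
    res <- mle_core(Sp, d, sigma)
    gamma[, , ch] <- res$gamma
    k_max[, , ch] <- res$k_max
  }
  list(gamma = gamma, k_max = k_max, drives = drives, sigma = sigma)
}

#' Estimate the noise standard deviation from a background region
#'
#' Pools the sample variances of the real and imaginary parts of
#' signal-free (background) voxels about their respective means:
#' \eqn{\hat\sigma^2 = (SS_{Re} + SS_{Im}) / (2n - 2)}. This is the single
#' global noise level used by [reconstruct_stack()].
#'
#' @param background Complex vector of values from a signal-free region of
#'   interest (>= 20 samples).
#' @return Estimated standard deviation per real/imaginary channel. Warns if
#'   it is 0 (reconstruction requires a positive noise level).
#' @export
estimate_sigma <- function(background) {
  background <- as.complex(background)
  n <- length(background)
  if (n < 20)
    stop("need at least 20 background samples to estimate sigma (got ",
         n, ")")
  re <- Re(background); im <- Im(background)
  s <- sqrt((sum((re - mean(re))^2) + sum((im - mean(im))^2)) / (2 * n - 2))
  if (s == 0)
    warning("background is constant; estimated sigma is 0 but ",
            "reconstruction requires sigma > 0")
  s
}
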