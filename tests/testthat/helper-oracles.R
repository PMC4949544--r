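# Independent oracles used across tests.

# Brute-force maximizer of the k-term log-likelihood over a complex grid,
# written directly from the density formula (independent of the package's
# closed-form estimator). The likelihood is smooth and unimodal in gamma,
# so each refinement level keeps the maximum within one coarse cell; six
# levels reach ~1e-7 resolution.
oracle_gamma <- function(Sp, sigmas, k) {
  ll_direct <- function(gamma) {
    s <- sigmas[seq_len(k)]
    x <- Sp[seq_len(k)]
    vapply(gamma, function(g)
      sum(log(1 / (2 * pi * s^2)) - Mod(x - g)^2 / (2 * s^2)), numeric(1))
  }
  centre <- mean(Sp[seq_len(k)])
  span <- max(Mod(Sp[seq_len(k)] - centre), max(sigmas[seq_len(k)])) * 4 + 1e-9
  for (level in 1:8) {
    re <- seq(Re(centre) - span, Re(centre) + span, length.out = 41)
    im <- seq(Im(centre) - span, Im(centre) + span, length.out = 41)
    grid <- outer(re, im, function(a, b) complex(real = a, imaginary = b))
    vals <- ll_direct(as.vector(grid))
    centre <- as.vector(grid)[which.max(vals)]
    span <- span * 2 / 40  # one coarse cell either side
  }
  centre
}

# random small normalized series for property tests
random_series <- function(N = 3) {
  drives <- drive_scheme(sort(runif(N, 0.05, 1)))
  sigma <- runif(1, 0.005, 0.05)
  signals <- complex(real = rnorm(N), imaginary = rnorm(N)) *
    as.numeric(drives)
  voxel_series(signals, drives, sigma)
}

# default SPGR parameter sets reused across files
params_7t <- function() spgr_params(TR = 6, TE = 2.1, T1 = 451,
                                    T2star = 25,
                                    theta_ref = 273 * pi / 180)
params_sim <- function(trt1 = 0.01) spgr_params(TR = 10, T1 = 10 / trt1,
                                                TE = 4, T2star = 100,
                                                theta_ref = 273 * pi / 180)
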