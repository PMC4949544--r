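test_that("normalization divides signals and noise by the drives", {
  vs <- voxel_series(c(0.1 + 0i, 0.5 + 0.5i), drives = c(0.1, 0.25),
                     sigma = 0.01)
  nm <- normalize_series(vs)
  expect_equal(nm$normalized, c(1 + 0i, 2 + 2i))
  expect_equal(nm$sigmas, c(0.1, 0.04))
  # unit drives leave everything unchanged; zero signals stay zero
  vs1 <- voxel_series(c(0 + 0i, 0 + 0i, 0 + 0i),
                      drives = c(0.2, 0.5, 1), sigma = 1)
  expect_equal(normalize_series(vs1)$normalized, rep(0 + 0i, 3))
  expect_true(all(diff(normalize_series(vs1)$sigmas) < 0))
})

test_that("log-likelihood matches the closed form term by term", {
  vs <- voxel_series(c(0.1 + 0i, 0.5 + 0i), drives = c(0.1, 1),
                     sigma = 0.01)
  nm <- normalize_series(vs)
  # zero-residual single term: -ln(2*pi) - 2 ln(sigma'_1)
  expect_equal(loglik_k(nm, 1 + 0i, 1), -log(2 * pi) - 2 * log(0.1))
  expect_equal(loglik_k(nm, 1 + 0i, 1), 2.767293, tolerance = 1e-6)
  # adding a zero-residual term changes L by -ln(2*pi) - 2 ln(sigma'_k)
  vs2 <- voxel_series(c(0.2 + 0i, 1 + 0i), drives = c(0.2, 1), sigma = 0.05)
  nm2 <- normalize_series(vs2)
  expect_equal(loglik_k(nm2, 1 + 0i, 2) - loglik_k(nm2, 1 + 0i, 1),
               -log(2 * pi) - 2 * log(0.05))
  # residual term: |S' - gamma|^2 / (2 sigma'^2)
  expect_equal(loglik_k(nm, 1.5 + 0i, 1),
               -log(2 * pi) - 2 * log(0.1) - 0.25 / (2 * 0.01))
  expect_error(loglik_k(nm, 1 + 0i, 3), "integer in")
})

test_that("closed-form estimator equals the weighted mean and the oracle", {
  # hand-evaluated weighted mean
  vs <- voxel_series(c(0.2 + 0i, 1 + 0i), drives = c(0.1, 1), sigma = 0.01)
  nm <- normalize_series(vs)
  expect_equal(gamma_hat_k(nm, 1), 2 + 0i)
  expect_equal(gamma_hat_k(nm, 2), (0.01 * 2 + 1 * 1) / 1.01 + 0i)
  # constant series: weighted mean of a constant is the constant
  cc <- 0.3 - 0.2i
  vsc <- voxel_series(cc * c(0.2, 0.5, 1), drives = c(0.2, 0.5, 1),
                      sigma = 0.01)
  nmc <- normalize_series(vsc)
  for (k in 1:3) expect_equal(gamma_hat_k(nmc, k), cc)
  # oracle equivalence on randomized instances: the closed form matches
  # brute-force grid maximization of the likelihood for every k
  set.seed(42)
  for (rep in 1:50) {
    vs <- random_series(N = 3)
    nm <- normalize_series(vs)
    for (k in 1:3) {
      gh <- gamma_hat_k(nm, k)
      gb <- oracle_gamma(nm$normalized, nm$sigmas, k)
      expect_equal(gh, gb, tolerance = 1e-6)
    }
  }
})

test_that("inverse-variance weights are equivalent to drive-squared weights", {
  set.seed(7)
  vs <- random_series(N = 4)
  nm <- normalize_series(vs)
  w_alt <- 1 / nm$sigmas^2  # proportional to d^2, arbitrary rescaling
  for (k in 2:4) {
    jj <- seq_len(k)
    expect_equal(gamma_hat_k(nm, k),
                 sum(w_alt[jj] * nm$normalized[jj]) / sum(w_alt[jj]))
  }
})

test_that("model-order selection rejects saturated measurements", {
  # worked example: second drive grossly saturated
  vs <- voxel_series(c(0.1 + 0i, 0.5 + 0i), drives = c(0.1, 1),
                     sigma = 0.01)
  est <- select_kmax(vs)
  expect_equal(est$k_max, 1L)
  expect_equal(est$gamma_hat, 1 + 0i)
  expect_equal(est$loglik[1], 2.767293, tolerance = 1e-6)
  expect_equal(est$loglik[2], -2.236481, tolerance = 1e-6)

  # single measurement: k_max = 1, gamma = S'_1
  vs1 <- voxel_series(0.25 + 0.25i, drives = 0.5, sigma = 0.01)
  e1 <- select_kmax(vs1)
  expect_equal(e1$k_max, 1L)
  expect_equal(e1$gamma_hat, 0.5 + 0.5i)

  # noise-free unsaturated data with small sigma uses all N measurements
  d <- c(0.1, 0.3, 1)
  vsN <- voxel_series((2 + 1i) * d, drives = d, sigma = 1e-4)
  eN <- select_kmax(vsN)
  expect_equal(eN$k_max, 3L)
  expect_equal(eN$gamma_hat, 2 + 1i)

  # noise-free series depressed beyond drive k0 never uses the tail
  d4 <- c(0.05, 0.1, 0.5, 1)
  sp <- c(1, 1, 0.6, 0.3)  # normalized values; saturation from j = 3
  vs4 <- voxel_series(sp * d4, drives = d4, sigma = 0.01)
  expect_lte(select_kmax(vs4)$k_max, 2L)
})

test_that("estimates transform predictably under scaling and rotation", {
  # Phase: rotating all signals by e^{i a} leaves residuals and sigma'
  # untouched, so the likelihoods, and hence k_max, are exactly unchanged
  # and gamma rotates. Scale: multiplying signals and sigma by c rescales
  # every gamma_hat_k by c and shifts L_k by exactly -2 k ln(c) (the
  # density normalization); the shift is k-dependent, so the selected
  # model order is a function of the absolute noise level, not only of
  # the SNR pattern.
  set.seed(11)
  for (rep in 1:20) {
    vs <- random_series(N = 4)
    base <- select_kmax(normalize_series(vs))
    cmul <- runif(1, 0.1, 10)
    alpha <- runif(1, -pi, pi)
    scaled <- voxel_series(vs$signals * cmul, vs$drives, vs$sigma * cmul)
    rot <- voxel_series(vs$signals * exp(1i * alpha), vs$drives, vs$sigma)
    nms <- normalize_series(scaled)
    es <- select_kmax(nms)
    er <- select_kmax(normalize_series(rot))
    expect_equal(er$k_max, base$k_max)
    expect_equal(er$gamma_hat, base$gamma_hat * exp(1i * alpha),
                 tolerance = 1e-10)
    expect_equal(es$loglik, base$loglik - 2 * (1:4) * log(cmul),
                 tolerance = 1e-8)
    for (k in 1:4)
      expect_equal(gamma_hat_k(nms, k),
                   gamma_hat_k(normalize_series(vs), k) * cmul,
                   tolerance = 1e-10)
  }
})

test_that("stack reconstruction agrees with the per-voxel path", {
  set.seed(3)
  dm <- c(5, 4, 2, 3)  # x, y, channel, drive
  d <- c(0.1, 0.4, 1)
  stack <- array(complex(real = rnorm(prod(dm)),
                         imaginary = rnorm(prod(dm))), dm)
  sigma <- 0.2
  rec <- reconstruct_stack(stack, d, sigma)
  for (ch in 1:2) for (i in 1:5) for (j in 1:4) {
    vs <- voxel_series(stack[i, j, ch, ], d, sigma)
    est <- select_kmax(vs)
    expect_equal(rec$gamma[i, j, ch], est$gamma_hat, tolerance = 1e-12)
    expect_identical(rec$k_max[i, j, ch], est$k_max)
  }
  expect_error(reconstruct_stack(stack, c(0.1, 1), sigma), "drive")
  # 1x1 image reduces to a single voxel series
  one <- array(stack[1, 1, 1, ], c(1, 1, 1, 3))
  r1 <- reconstruct_stack(one, d, sigma)
  expect_equal(r1$gamma[1, 1, 1],
               select_kmax(voxel_series(stack[1, 1, 1, ], d, sigma))$gamma_hat)
})

test_that("background noise estimation pools real and imaginary parts", {
  set.seed(21)
  sigma <- 0.3
  bg <- complex(real = rnorm(200, 5, sigma),
                imaginary = rnorm(200, -2, sigma))
  expect_equal(estimate_sigma(bg), sigma, tolerance = 0.1)
  # pure-real perturbations of size a: pooling halves the variance mass,
  # sigma ~ a / sqrt(2) (exact pooled value n a^2 / (2n - 2) at n = 100)
  a <- 0.5
  bg2 <- complex(real = rep(c(a, -a), 50), imaginary = rep(0, 100))
  expect_equal(estimate_sigma(bg2), a * sqrt(100 / 198))
  expect_equal(estimate_sigma(bg2), a / sqrt(2), tolerance = 0.01)
  expect_warning(s0 <- estimate_sigma(rep(1 + 1i, 30)), "constant")
  expect_equal(s0, 0)
  expect_error(estimate_sigma(rep(1 + 1i, 5)), "at least 20")
})
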