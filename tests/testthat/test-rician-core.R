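test_that("log_i0 matches the series-expansion oracle and limits", {
  expect_identical(log_i0(0), 0)
  # series oracle at small arguments
  for (x in c(0.5, 1, 2, 10)) {
    expect_lt(abs(log_i0(x) - series_log_i0(x, 1000)) /
                abs(series_log_i0(x, 1000)), 1e-12)
  }
  # large-argument cross-check against the leading Hankel asymptotic
  x <- 1600  # Bessel argument scale of an SNR = 40 regime
  expect_lt(abs(log_i0(x) - (x - 0.5 * log(2 * pi * x))) / x, 1e-3)
  # the naive route overflows where the scaled route stays finite
  expect_true(is.finite(log_i0(800)))
  expect_true(is.infinite(log(besselI(800, 0))))
  # the two internal branches agree at the asymptotic switch point
  x_sw <- 10000.5
  direct <- log(besselI(x_sw, 0, expon.scaled = TRUE)) + x_sw
  expect_lt(abs(log_i0(x_sw) - direct) / direct, 1e-13)
  expect_error(log_i0(-1), "x >= 0")
})

test_that("series_log_i0 partial sums are monotone and nonconvergence errors", {
  # all series terms are nonnegative, so partial sums are nondecreasing
  vals <- vapply(c(1, 5, 20, 100, 1000),
                 function(n) series_log_i0(2, n, check = FALSE), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_identical(series_log_i0(0, 1), 0)
  # truncated series must refuse rather than return a wrong value
  expect_error(series_log_i0(5000, n_terms = 100), "did not converge")
})

test_that("rician_logpdf reduces to Rayleigh and is a proper density", {
  expect_equal(rician_logpdf(1, 0, 1), -0.5)
  for (A in c(0, 0.5, 1)) {
    for (sigma in c(0.05, 0.2, 1)) {
      total <- integrate(function(m) exp(rician_logpdf(m, A, sigma)),
                         lower = 0, upper = Inf, rel.tol = 1e-9)$value
      expect_lt(abs(total - 1), 1e-6)
    }
  }
  expect_error(rician_logpdf(0, 1, 1), "positive")
  expect_error(rician_logpdf(1, 1, 0), "sigma")
  expect_error(rician_logpdf(1, -1, 1), "nonnegative")
})

test_that("rician_logpdf peaks near A in the high-SNR (Gaussian) limit", {
  A <- 1
  sigma <- A / 50
  peak <- optimize(function(m) rician_logpdf(m, A, sigma),
                   interval = c(0.5, 1.5), maximum = TRUE)$maximum
  expect_lt(abs(peak - A), 0.1 * sigma)
})

test_that("expected_magnitude matches Rayleigh, Monte Carlo and high-SNR limits", {
  expect_equal(expected_magnitude(0, 1), sqrt(pi / 2), tolerance = 1e-12)
  # Monte-Carlo oracle from the complex-noise construction
  set.seed(42)
  n <- 1e6
  A <- 1
  sigma <- 0.5
  draws <- sqrt((A + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - expected_magnitude(A, sigma)), 3 * se)
  # converges to A from above as SNR grows
  expect_lt(expected_magnitude(10, 0.1) - 10, 1e-3)
  A_grid <- seq(0, 5, length.out = 40)
  em <- expected_magnitude(A_grid, 0.2)
  expect_true(all(em > A_grid))
  ratio <- em[-1] / A_grid[-1]
  expect_true(all(diff(ratio) < 0))  # E[M]/A decreases monotonically to 1
})

test_that("nlr_loss agrees with rician_logpdf and its minimiser with a grid oracle", {
  expect_equal(nlr_loss(matrix(1), matrix(0), 1)$value, 0.5)
  lv <- nlr_loss(matrix(runif(20, 0.5, 1.5), 4), matrix(1, 4, 5), 0.2)
  expect_equal(lv$value, mean(lv$per_voxel))
  # brute-force grid oracle for the scalar-amplitude minimiser of one voxel
  set.seed(7)
  sigma <- 0.2
  M <- matrix(add_rician_noise(rep(0.8, 10), sigma), 1)
  grid <- seq(0, 2 * max(M), length.out = 1e4)
  grid_loss <- vapply(grid,
                      function(a) nlr_loss(M, matrix(a, 1, 10), sigma)$value,
                      numeric(1))
  a_grid <- grid[which.min(grid_loss)]
  a_opt <- optim(1, fn = function(a) nlr_loss(M, matrix(a, 1, 10), sigma)$value,
                 gr = function(a) sum(nlr_loss_grad(M, matrix(a, 1, 10), sigma)),
                 method = "L-BFGS-B", lower = 0, upper = 2 * max(M))$par
  expect_lt(abs(a_opt - a_grid), diff(grid[1:2]))
})

test_that("nlr_loss gradient matches central finite differences", {
  set.seed(8)
  M <- matrix(runif(12, 0.3, 1.2), 3)
  A <- matrix(runif(12, 0.2, 1.0), 3)
  g <- nlr_loss_grad(M, A, 0.15)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(3, 4))) {
    Ap <- A; Ap[idx[1], idx[2]] <- A[idx[1], idx[2]] + eps
    Am <- A; Am[idx[1], idx[2]] <- A[idx[1], idx[2]] - eps
    fd <- (nlr_loss(M, Ap, 0.15)$value - nlr_loss(M, Am, 0.15)$value) /
      (2 * eps)
    expect_equal(g[idx[1], idx[2]], fd, tolerance = 1e-6)
  }
})

test_that("losses are invariant to measurement and voxel ordering", {
  set.seed(9)
  ds <- tiny_dataset(sigma = 0.1, reps = 1)
  A <- ivim_signal(ds$truth, ds$protocol, drop = FALSE)
  pm <- sample(ncol(ds$M))
  pv <- sample(nrow(ds$M))
  for (fn in list(function(M, A) nlr_loss(M, A, 0.1)$value, function(M, A)
    mse_loss(M, A)$value)) {
    base <- fn(ds$M, A)
    expect_equal(fn(ds$M[, pm], A[, pm]), base)
    expect_equal(fn(ds$M[pv, ], A[pv, ]), base)
  }
})

test_that("mse_loss hand values and mean-minimiser property", {
  M <- matrix(c(1, 0), 1)
  expect_equal(mse_loss(M, matrix(0, 1, 2))$value, 0.5)
  expect_equal(mse_loss(M, M)$value, 0)
  set.seed(10)
  Mv <- matrix(runif(10), 1)
  opt <- optimize(function(a) mse_loss(Mv, matrix(a, 1, 10))$value, c(0, 1))
  expect_equal(opt$minimum, mean(Mv), tolerance = 1e-4)
  expect_error(mse_loss(matrix(1, 2, 3), matrix(1, 2, 4)), "shape mismatch")
})

test_that("loss and gradient stay finite over the stability SNR range", {
  # magnitude batches simulated at SNR 0.5 through 40; every loss and
  # gradient value must be strictly finite
  grid <- make_parameter_grid(n_levels = 3)
  protocol <- test_protocol()
  for (snr in c(0.5, seq(2.5, 40, by = 2.5))) {
    sigma <- 1 / snr
    ds <- build_dataset(grid, protocol, sigma, reps_per_combo = 1,
                        seed = 300 + round(snr * 10))
    A <- ivim_signal(ds$truth, protocol, drop = FALSE)
    lv <- nlr_loss(ds$M, A, sigma)
    gv <- nlr_loss_grad(ds$M, A, sigma)
    expect_true(all(is.finite(lv$per_voxel)), label = paste("loss SNR", snr))
    expect_true(all(is.finite(gv)), label = paste("grad SNR", snr))
  }
})

test_that("noise_spec enforces sigma > 0 and derives SNR", {
  ns <- noise_spec(0.1)
  expect_equal(ns$snr * ns$sigma, 1)
  expect_equal(snr_to_noise(10)$sigma, 0.1)
  expect_error(noise_spec(0), "sigma")
  expect_error(noise_spec(-1), "sigma")
})
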