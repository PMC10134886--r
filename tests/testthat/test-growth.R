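test_that("growth reduces to exponential growth when nutrient never limits", {
  ## k_d = 0 and K1 -> 0 make mu = k_g throughout, so C(t) = C0 exp(a k_g t)
  p <- growth_params(list(k_g = 0.6, k_d = 0, K1 = 1e-9, gamma = 1e-9))
  traj <- simulate_growth(p, t_end = 1, dt = 0.01)
  expect_equal(traj$C[1], 0.1)
  expect_equal(tail(traj$C, 1), 0.1 * exp(0.6), tolerance = 1e-6)
})

test_that("mean growth rate follows the saturating nutrient law", {
  p <- growth_params(list(k_g = 0.6, K1 = 0.3, h1 = 2))
  expect_equal(mean_growth_rate(p, 0.3), 0.3)          # half-saturation
  expect_equal(mean_growth_rate(p, 0), 0)
  expect_equal(mean_growth_rate(p, 0.6), 0.48)         # 0.6*0.36/0.45
  expect_error(mean_growth_rate(p, -1), "nonnegative")
  ## monotone nondecreasing in N, saturating to k_g
  grid <- mean_growth_rate(p, seq(0, 50, length.out = 500))
  expect_true(all(diff(grid) >= 0))
  expect_lt(abs(tail(grid, 1) - 0.6), 1e-3)
})

test_that("default trajectory matches an independent fixed-step RK4 integration", {
  p <- growth_params("normal")
  traj <- simulate_growth(p, t_end = 6, dt = 0.5)
  ## independent oracle: classic fourth-order Runge-Kutta at dt = 1e-4
  f <- function(x) {
    g <- p$k_g * x[2]^p$h1 / (x[2]^p$h1 + p$K1^p$h1)
    d <- p$k_d * x[2]^p$h2 / (x[2]^p$h2 + p$K2^p$h2)
    c(x[1] * (p$a * g - d), -p$gamma * x[1] * (g - p$psi * d))
  }
  x <- c(p$C0, p$N0); h <- 1e-4
  for (i in seq_len(6 / h)) {
    k1 <- f(x); k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2); k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  end <- tail(traj, 1)
  expect_equal(end$C, x[1], tolerance = 1e-4)
  expect_equal(end$N, x[2], tolerance = 1e-4)
})

test_that("nutrient bookkeeping is conservative without death or recycling", {
  p <- growth_params(list(k_d = 0, psi = 0))
  traj <- simulate_growth(p, t_end = 10, dt = 0.1)
  ## with k_d = 0, dN = -gamma dC exactly
  expect_equal(p$gamma * (traj$C - p$C0), p$N0 - traj$N, tolerance = 1e-6)
})

test_that("mu(t) is nonincreasing while nutrient is depleted", {
  traj <- simulate_growth(growth_params("normal"), t_end = 14)
  expect_true(all(diff(traj$N) <= 1e-12))
  expect_true(all(diff(traj$mu) <= 1e-12))
})

test_that("corrected mean generation time applies the forward time shift", {
  traj <- normal_traj()
  ## epsilon = 0: exactly ln 2 / mu(t)
  t0 <- 4
  mu0 <- approx(traj$time, traj$mu, t0)$y
  expect_equal(corrected_mean_generation_time(traj, t0, epsilon = 0),
               log(2) / mu0, tolerance = 1e-10)
  ## constant mu: closed form regardless of epsilon
  flat <- traj
  flat$mu <- rep(0.3, nrow(flat))
  expect_equal(corrected_mean_generation_time(flat, 2, epsilon = 0.2),
               log(2) / 0.3, tolerance = 1e-12)
  ## declining mu: the shifted value is longer than the unshifted one
  expect_gt(corrected_mean_generation_time(traj, 7, 0.2),
            corrected_mean_generation_time(traj, 7, 0))
  ## beyond-grid lookups hold the final growth rate
  expect_equal(corrected_mean_generation_time(traj, max(traj$time), 0.2),
               log(2) / tail(traj$mu, 1), tolerance = 1e-10)
})

test_that("generation-time sampling matches truncated-normal moments", {
  smp <- generation_sampler()   # cv 0.25, min 0.2 h
  set.seed(42)
  draws <- replicate(2e4, sample_generation_time(0.9, smp))
  expect_true(all(draws >= 0.2))
  ## oracle: numerical moments of the normal density truncated at 0.2
  m <- 0.9; s <- 0.25 * 0.9
  z <- (0.2 - m) / s
  tr_mean <- m + s * dnorm(z) / (1 - pnorm(z))
  expect_equal(mean(draws), tr_mean, tolerance = 0.01)
  ## cv -> 0 limit returns the mean exactly
  expect_identical(sample_generation_time(2, generation_sampler(cv = 0)), 2)
})
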