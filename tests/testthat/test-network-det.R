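test_that("a linear birth-death system has the unique stable state k/d", {
  net <- build_birth_death_network(k = 80, d = 2)
  ss <- find_steady_states(net, 0, 0, find_unstable = FALSE)
  expect_identical(sum(ss$stable), 1L)
  expect_equal(ss$states$X[1], 40, tolerance = 1e-6)
})

test_that("steady states of a symmetric toggle match a 1-D root-finding oracle", {
  b <- 60; K <- 20; n <- 3
  net <- build_toggle_network(b, K, n, d = 1)
  ss <- find_steady_states(net, 0, 0)
  expect_identical(sum(ss$stable), 2L)
  ## oracle: x* solves x = F(F(x)) with F(y) = b K^n / (K^n + y^n);
  ## the stable pair is (hi, lo) with lo = F(hi); the saddle solves x = F(x)
  FF <- function(y) b * K^n / (K^n + y^n)
  saddle <- uniroot(function(x) x - FF(x), c(1e-3, b))$root
  hi <- uniroot(function(x) x - FF(FF(x)), c(saddle * 1.05, b * 1.05))$root
  lo <- FF(hi)
  stable <- ss$states[ss$stable, ]
  expect_equal(sort(stable$X), sort(c(lo, hi)), tolerance = 1e-5)
  expect_equal(sort(stable$Y), sort(c(lo, hi)), tolerance = 1e-5)
  un <- ss$states[!ss$stable, ]
  expect_identical(nrow(un), 1L)
  expect_equal(un$X, saddle, tolerance = 1e-4)
})

test_that("the switch is monostable-low at scarce Spo0A~P, bistable when high", {
  net <- sin_net()
  lo <- find_steady_states(net, MU_FAST, 0.05, find_unstable = FALSE)
  expect_identical(sum(lo$stable), 1L)
  expect_lt(lo$states$TapA[1], 500)
  hi <- find_steady_states(net, MU_FAST, 1)
  expect_identical(sum(hi$stable), 2L)
  ## the separating unstable state lies strictly between the stable branches
  expect_true(any(!hi$stable))
  tap <- hi$states$TapA
  expect_true(tap[!hi$stable][1] > min(tap[hi$stable]) &&
              tap[!hi$stable][1] < max(tap[hi$stable]))
})

test_that("high-branch TapA is nondecreasing in Spo0A~P at fixed growth", {
  net <- sin_net()
  highs <- vapply(c(0.4, 0.8, 1.5), function(s) {
    ss <- find_steady_states(net, MU_FAST, s, find_unstable = FALSE)
    max(ss$states$TapA[ss$stable])
  }, numeric(1))
  expect_true(all(diff(highs) >= -1e-6))
})

test_that("SinR/SlrR ratio analysis matches the synthesis-loss closed form", {
  ## same locus for every gene and regulation off: the ratio of totals is
  ## (production ratio) * (0.6 + mu) / (0.2 + mu), decreasing in mu
  p <- sin_network_params()
  p$p_sinI <- p$p_sinR <- p$p_slrR <- p$p_tapA <- 0.5
  net <- build_sin_network(p)
  mus <- c(0.1, 0.25, 0.45, 0.6)
  r <- sinr_slrr_ratio(net, mus)
  expect_true(all(diff(r$ratio) < 0))
  pred <- (p$a_sinR / p$a_slrR) * (0.6 + mus) / (0.2 + mus)
  expect_equal(r$ratio / r$ratio[1], pred / pred[1], tolerance = 0.05)
  ## restoring the real loci (slrR ori-proximal, sinR ori-distal)
  ## steepens the decrease
  r2 <- sinr_slrr_ratio(sin_net(), mus)
  expect_true(all(diff(r2$ratio) < 0))
  expect_lt(r2$ratio[4] / r2$ratio[1], r$ratio[4] / r$ratio[1])
})

test_that("hysteresis only appears inside the bistable window", {
  net <- sin_net()
  ## a path entirely below the bistable onset: identical up/down traces
  low_path <- c(0.01, 0.02, 0.03)
  h <- hysteresis_sweep(net, MU_FAST, low_path)
  up <- h$tapA[h$direction == "up"]
  down <- h$tapA[h$direction == "down"]   # returned in ascending spo0a order
  expect_equal(up, down, tolerance = 1e-4)
  ## a path through the window: branches disagree inside, agree outside
  path <- c(0.02, 0.3, 1, 2)
  h2 <- hysteresis_sweep(net, MU_FAST, path)
  up2 <- h2$tapA[h2$direction == "up"]
  down2 <- h2$tapA[h2$direction == "down"]
  expect_equal(up2[1], down2[1], tolerance = 1e-3)   # agree below the window
  expect_gt(max(down2 - up2), 500)                   # hysteresis inside
})

test_that("continuation scan agrees with naive multistart on a subgrid", {
  net <- sin_net()
  mu_g <- c(0.15, 0.3, 0.45)
  s_g <- c(0.05, 0.3, 1)
  bd <- scan_bifurcation(net, mu_g, s_g)
  expect_s3_class(bd, "bifurcation_diagram")
  for (i in seq_len(nrow(bd))) {
    naive <- find_steady_states(net, bd$mu[i], bd$spo0a[i], n_starts = 6,
                                find_unstable = FALSE)
    expect_identical(bd$n_stable[i], sum(naive$stable),
                     info = paste("cell", bd$mu[i], bd$spo0a[i]))
  }
  expect_true(all(bd$n_stable %in% 1:2))
})
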