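test_that("lineage records are bit-reproducible under a fixed seed", {
  net <- sin_net()
  a <- simulate_lineage(net, normal_traj(), default_spo0a_map(), "WT",
                        t_end = 6, seed = 7)
  b <- simulate_lineage(net, normal_traj(), default_spo0a_map(), "WT",
                        t_end = 6, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$events, b$events)
  c <- simulate_lineage(net, normal_traj(), default_spo0a_map(), "WT",
                        t_end = 6, seed = 8)
  expect_false(identical(a$counts, c$counts))
})

test_that("constitutive birth-death settles on Poisson stationary moments", {
  net <- build_birth_death_network(k = 50, d = 1)
  rec <- simulate_fixed_condition(net, mu = 0, spo0a = 0, t_end = 4000,
                                  sample_dt = 0.5, seed = 11,
                                  divisions = FALSE)
  x <- rec$counts[rec$sample_times > 20, "X"]
  ## stationary law is Poisson(50); allow 3 SE with an effective sample
  ## size deflated for the 0.5 h autocorrelation (rho = exp(-0.5))
  rho <- exp(-0.5)
  neff <- length(x) * (1 - rho) / (1 + rho)
  expect_lt(abs(mean(x) - 50), 3 * sqrt(50 / neff))
  expect_lt(abs(var(x) / 50 - 1), 0.1)
})

test_that("next-reaction engine matches a direct-method reference", {
  ## three-reaction toy: production, conversion, decay
  net <- reaction_network(
    species = data.frame(name = c("A", "B"), init = 0L, deg = c(2, 1)),
    reactions = list(
      reaction("make", 40, NULL, c(A = 1)),
      reaction("convert", 2, c(A = 1), c(B = 1)),
      reaction("decay", 1, c(B = 1))
    ))
  nrm <- simulate_fixed_condition(net, mu = 0, spo0a = 0, t_end = 2500,
                                  sample_dt = 1, seed = 21,
                                  divisions = FALSE)
  dir <- ssa_direct(net, spo0a = 0, t_end = 2500, sample_dt = 1, seed = 22)
  burn <- nrm$sample_times > 10
  ## stationary B is Poisson(40): compare both engines to it and each other
  b1 <- nrm$counts[burn, "B"]; b2 <- dir[burn, "B"]
  expect_lt(abs(mean(b1) - mean(b2)), 1.5)
  breaks <- c(-0.5, seq(25.5, 55.5, 2), Inf)
  h1 <- table(cut(b1, breaks)); h2 <- table(cut(b2, breaks))
  suppressWarnings(ct <- chisq.test(rbind(h1, h2)))
  expect_gt(ct$p.value, 1e-3)
})

test_that("binomial division conserves molecules and halves on average", {
  set.seed(5)
  counts <- c(SinR2 = 100L, TapA = 0L)
  kept <- matrix(0, 2000, 2)
  for (i in seq_len(2000)) {
    d <- divide_cell(counts)
    expect_identical(unname(d$kept + d$discarded), unname(counts))
    kept[i, ] <- d$kept
  }
  expect_identical(max(kept[, 2]), 0)        # zero parent -> zero daughters
  se <- sqrt(25 / 2000)
  expect_lt(abs(mean(kept[, 1]) - 50), 3 * se)
  expect_lt(abs(var(kept[, 1]) / 25 - 1), 0.2)
})

test_that("gene replication fires at p * tau_c into each cycle", {
  net <- sin_net()
  rec <- simulate_fixed_condition(net, mu = 0.4, spo0a = 0.3, t_end = 30,
                                  seed = 13)
  divs <- c(0, rec$events$division_times)
  reps <- rec$events$replication_times
  gene <- rec$events$replication_gene
  p <- setNames(net$genes$p, net$genes$name)
  for (i in seq_len(length(divs) - 1)) {
    tau <- divs[i + 1] - divs[i]
    tau_c <- 0.78 + 0.15 / (log(2) / tau)
    in_cycle <- reps >= divs[i] & reps < divs[i + 1]
    expected <- divs[i] + p[gene[in_cycle]] * tau_c
    expect_equal(unname(reps[in_cycle]), unname(expected), tolerance = 1e-8)
  }
})

test_that("transcription propensity doubles with gene copy number", {
  cmp <- sinswitch:::network_compile(sin_net())
  x <- rep(0, 12)
  a1 <- sinswitch:::propensities(cmp, x, spo0a = 1, dosage = rep(1, 4))
  a2 <- sinswitch:::propensities(cmp, x, spo0a = 1, dosage = rep(2, 4))
  tx <- grep("^tx_", vapply(sin_net()$reactions, `[[`, "", "name"))
  expect_equal(a2[tx], 2 * a1[tx])
  expect_equal(a2[-tx], a1[-tx])
})

test_that("large-copy stochastic kinetics converge to the mass-action ODE", {
  ## law-of-large-numbers check of the engine: a repression motif with
  ## zero-, first- and second-order reactions and a Hill modifier at
  ## 100x molecule numbers, compared with the mass-action ODE. (The full
  ## switch network is not used here: near its separatrix the mean of
  ## the stochastic process converges only slowly to the mean field.)
  f <- 100
  net <- reaction_network(
    species = data.frame(name = c("mR", "R2", "R4", "mT", "T"), init = 0L,
                         deg = c(8.3, 0.2, 0.2, 8.3, 1.0)),
    reactions = list(
      reaction("tx_R", 9 * f, NULL, c(mR = 1)),
      reaction("deg_mR", 8.3, c(mR = 1)),
      reaction("tl_R", 100, c(mR = 1), c(mR = 1, R2 = 1)),
      reaction("tet", (100 / 2408.856) / f, c(R2 = 2), c(R4 = 1)),
      reaction("untet", 5, c(R4 = 1), c(R2 = 2)),
      reaction("deg_R2", 0.2, c(R2 = 1)),
      reaction("deg_R4", 0.2, c(R4 = 1)),
      reaction("tx_T", 58 * f, NULL, c(mT = 1),
               modifier = list(type = "hill_rep", species = "R4",
                               K = 7.5 * f, n = 4)),
      reaction("deg_mT", 8.3, c(mT = 1)),
      reaction("tl_T", 200, c(mT = 1), c(mT = 1, T = 1)),
      reaction("deg_T", 1.0, c(T = 1))
    ))
  recs <- lapply(1:4, function(i)
    simulate_fixed_condition(net, mu = 0, spo0a = 0, t_end = 8,
                             sample_dt = 1, seed = 50 + i,
                             divisions = FALSE))
  m <- rowMeans(vapply(recs, function(r) as.numeric(r$counts[, "T"]),
                       numeric(9)))
  cmp <- sinswitch:::network_compile(net)
  rhs <- sinswitch:::network_rhs(cmp, 0, 0, numeric(0))
  ode <- deSolve::ode(setNames(rep(0, 5), net$species$name), 0:8, rhs, NULL)
  expect_equal(m[2:9], unname(ode[2:9, "T"]), tolerance = 0.03)
  mr4 <- rowMeans(vapply(recs, function(r) as.numeric(r$counts[, "R4"]),
                         numeric(9)))
  expect_equal(mr4[3:9], unname(ode[3:9, "R4"]), tolerance = 0.03)
})
test_that("switching statistics are bimodal only at permissive conditions", {
  net <- sin_net()
  init <- initial_state_low(net, MU_FAST, 1)
  ## permissive: fast growth, high Spo0A~P -- both states visited
  rec <- simulate_fixed_condition(net, MU_FAST, 1, t_end = 250,
                                  sample_dt = 0.5, seed = 31, init = init)
  on <- mean(rec$counts[, "TapA"] > 500)
  expect_gt(on, 0.05)
  expect_lt(on, 0.95)
  ## scarce Spo0A~P: expression stays low throughout
  rec0 <- simulate_fixed_condition(net, MU_FAST, 0.05, t_end = 250,
                                   sample_dt = 0.5, seed = 31, init = init)
  expect_lt(mean(rec0$counts[, "TapA"] > 500), 0.01)
  ## slow growth: the high state is not reachable either
  rec1 <- simulate_fixed_condition(net, 0.10, 1, t_end = 120,
                                   sample_dt = 0.5, seed = 31, init = init)
  expect_lt(mean(rec1$counts[, "TapA"] > 500), 0.05)
})
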