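## deterministic hand-built intensity table: intensities are either pure
## background level or background + 1000, so threshold calls are exact
make_table <- function(frac_on_spo, frac_on_nonspo, frac_spo = 0.4,
                       n = 200) {
  rows <- lapply(seq_along(frac_on_spo), function(img) {
    n_spo <- round(n * frac_spo)
    spo <- c(rep(TRUE, n_spo), rep(FALSE, n - n_spo))
    on <- logical(n)
    on[seq_len(round(frac_on_spo[img] * n_spo))] <- TRUE
    idx <- which(!spo)
    on[idx[seq_len(round(frac_on_nonspo[img] * length(idx)))]] <- TRUE
    data.frame(image_id = img, cell_id = seq_len(n),
               gfp_mean = 100 + 1000 * on, mcherry_mean = 100 + 1000 * spo,
               gfp_bg_mean = 100, gfp_bg_sd = 10,
               mch_bg_mean = 100, mch_bg_sd = 10)
  })
  do.call(rbind, rows)
}

test_that("synthetic generator honours its design constraints", {
  pars <- reporter_synth_params(n_images = 6, frac_on_gfp = 0.25,
                                frac_spo = 0.3, seed = 4)
  tab <- generate_reporter_table(pars)
  counts <- table(tab$image_id)
  expect_identical(length(counts), 6L)
  expect_true(all(counts >= 600 & counts <= 1600))
  truth <- attr(tab, "truth")
  expect_identical(nrow(truth), nrow(tab))
  ## independence case: the joint matches the product of marginals
  n <- nrow(truth)
  se <- sqrt(0.25 * 0.3 * 0.7 / n)
  expect_lt(abs(mean(truth$on & truth$spo) - 0.25 * 0.3), 3 * se + 0.25 * 0.3 * 0.05)
  ## infeasible joints are refused
  expect_error(reporter_synth_params(frac_on_gfp = 0.2, frac_spo = 0.3,
                                     joint_on_spo = 0.25), "infeasible")
})

test_that("zero expressing fraction leaves only background in GFP", {
  pars <- reporter_synth_params(n_images = 3, frac_on_gfp = 0,
                                frac_spo = 0.2, seed = 9)
  tab <- call_expressing(generate_reporter_table(pars))
  expect_lt(mean(tab$on_call), 0.01)   # only Gaussian tail exceedances
})

test_that("threshold calls recover well-separated mixtures", {
  pars <- reporter_synth_params(n_images = 9, frac_on_gfp = 0.2,
                                frac_spo = 0.3, seed = 2)
  tab <- call_expressing(generate_reporter_table(pars))
  truth <- attr(tab, "truth")
  expect_lt(abs(mean(tab$on_call) - mean(truth$on)), 0.02)
  expect_lt(abs(mean(tab$spo_call) - mean(truth$spo)), 0.02)
  ## lowering the threshold multiplier can only increase called fractions
  fr <- vapply(c(5, 3, 1),
               function(k) mean(call_expressing(tab, k)$on_call), numeric(1))
  expect_true(all(diff(fr) >= 0))
  ## a cell exactly at the background mean is off
  one <- tab[1, ]; one$gfp_mean <- one$gfp_bg_mean
  expect_false(call_expressing(one)$on_call)
})

test_that("generator is deterministic under its seed", {
  pars <- reporter_synth_params(seed = 123)
  expect_identical(generate_reporter_table(pars),
                   generate_reporter_table(pars))
})

test_that("end-to-end fraction recovery over random generator settings", {
  set.seed(77)
  for (i in 1:20) {
    f_on <- runif(1, 0.05, 0.5); f_spo <- runif(1, 0.1, 0.6)
    pars <- reporter_synth_params(n_images = 3, frac_on_gfp = f_on,
                                  frac_spo = f_spo, seed = 1000 + i)
    tab <- call_expressing(generate_reporter_table(pars))
    n <- nrow(tab)
    ## threshold calls add a small false-positive/negative rate on top of
    ## binomial sampling noise
    tol <- 3 * sqrt(f_on * (1 - f_on) / n) + 0.01
    expect_lt(abs(mean(tab$on_call) - f_on), tol)
  }
})

test_that("strain comparison reproduces hand-computed folds and Welch t", {
  a <- make_table(frac_on_spo = c(0.10, 0.125, 0.10),
                  frac_on_nonspo = c(0.20, 0.25, 0.25))
  b <- make_table(frac_on_spo = c(0.25, 0.25, 0.30),
                  frac_on_nonspo = c(0.30, 0.25, 0.35))
  cmp <- compare_strains(a, b)
  ## folds are exact ratios of the designed per-image fractions
  expect_equal(cmp$fold_A, c(0.20 / 0.10, 0.25 / 0.125, 0.25 / 0.10))
  expect_equal(cmp$fold_B, c(0.30 / 0.25, 0.25 / 0.25, 0.35 / 0.30))
  ## textbook Welch statistic on those folds
  m1 <- mean(cmp$fold_A); m2 <- mean(cmp$fold_B)
  v1 <- var(cmp$fold_A); v2 <- var(cmp$fold_B)
  t_hand <- (m1 - m2) / sqrt(v1 / 3 + v2 / 3)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  expect_identical(unname(cmp$excluded_images), c(0L, 0L))
})

test_that("images with an empty or zero conditional fraction are excluded", {
  a <- make_table(frac_on_spo = c(0, 0.10, 0.10),
                  frac_on_nonspo = c(0.2, 0.2, 0.2))
  b <- make_table(frac_on_spo = c(0.2, 0.2, 0.2),
                  frac_on_nonspo = c(0.2, 0.25, 0.3))
  cmp <- compare_strains(a, b)
  expect_identical(unname(cmp$excluded_images["A"]), 1L)
  expect_identical(length(cmp$fold_A), 2L)
})

test_that("matched generators give a near-zero strain difference", {
  pars1 <- reporter_synth_params(seed = 31)
  pars2 <- reporter_synth_params(seed = 32)
  cmp <- compare_strains(generate_reporter_table(pars1),
                         generate_reporter_table(pars2))
  expect_gt(cmp$p_value, 0.01)
})
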