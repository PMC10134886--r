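## Synthetic dual-reporter microscopy tables and their analysis:
## a stand-in for segmented micrograph measurements with the same
## statistical structure (on/off mixtures over a fluorescence background),
## plus the thresholding / per-image-fraction / fold-change /
## two-sample-test pipeline applied to them.

#' Parameters of the synthetic dual-reporter generator
#'
#' Emulates per-cell mean-intensity tables from dual-reporter microscopy:
#' GFP reports matrix-gene (tapA) activity, mCherry reports sporulation
#' (spoIIQ). Each cell draws a joint (on, spo) fate; "on" cells add a
#' log-normal signal on top of a normal background, "off" cells are
#' background only. The standard design is 9 images per strain (3 images
#' from each of 3 cultures) with 600-1600 cells per image.
#'
#' @param n_images number of images (default 9).
#' @param cells_min,cells_max per-image cell-count range (600-1600).
#' @param frac_on_gfp marginal fraction of matrix-on cells.
#' @param frac_spo marginal fraction of sporulating cells.
#' @param joint_on_spo probability of (on AND spo); default the product
#'   of the marginals (independence). Mutual exclusivity is emulated by
#'   setting it below the product.
#' @param gfp_on_meanlog,gfp_on_sdlog log-normal signal of on cells (a.u.).
#' @param mch_on_meanlog,mch_on_sdlog log-normal signal of spo cells.
#' @param bg_mean,bg_sd background intensity (both channels, a.u.).
#' @param seed integer seed.
#' @return object of class `reporter_synth_params`.
#' @export
reporter_synth_params <- function(n_images = 9, cells_min = 600,
                                  cells_max = 1600,
                                  frac_on_gfp = 0.2, frac_spo = 0.3,
                                  joint_on_spo = frac_on_gfp * frac_spo,
                                  gfp_on_meanlog = log(400),
                                  gfp_on_sdlog = 0.5,
                                  mch_on_meanlog = log(400),
                                  mch_on_sdlog = 0.5,
                                  bg_mean = 100, bg_sd = 10, seed = 1L) {
  stopifnot(n_images >= 1, cells_min >= 1, cells_max >= cells_min,
            frac_on_gfp >= 0, frac_on_gfp <= 1,
            frac_spo >= 0, frac_spo <= 1,
            gfp_on_sdlog > 0, mch_on_sdlog > 0, bg_sd > 0)
  ## the 2x2 joint must have nonnegative cells
  p11 <- joint_on_spo
  if (p11 < 0 || p11 > min(frac_on_gfp, frac_spo) ||
      1 - frac_on_gfp - frac_spo + p11 < 0)
    stop("infeasible joint on/spo fraction: ", p11)
  structure(as.list(environment()), class = "reporter_synth_params")
}

#' Generate a synthetic per-cell dual-reporter intensity table
#'
#' @param params a [reporter_synth_params()].
#' @return object of class `cell_intensity_table`: data frame with
#'   columns `image_id`, `cell_id`, `gfp_mean`, `mcherry_mean`, per-image
#'   background columns (`gfp_bg_mean`, `gfp_bg_sd`, `mch_bg_mean`,
#'   `mch_bg_sd`), and the ground-truth labels in
#'   `attr(, "truth")` (columns `on`, `spo`) for recovery tests.
#' @export
generate_reporter_table <- function(params) {
  stopifnot(inherits(params, "reporter_synth_params"))
  set.seed(params$seed)
  p11 <- params$joint_on_spo
  p10 <- params$frac_on_gfp - p11      # on, non-spo
  p01 <- params$frac_spo - p11         # off, spo
  p00 <- 1 - p11 - p10 - p01
  rows <- list(); truths <- list()
  for (img in seq_len(params$n_images)) {
    n <- sample(seq(params$cells_min, params$cells_max), 1)
    fate <- sample.int(4, n, replace = TRUE, prob = c(p11, p10, p01, p00))
    on <- fate %in% c(1, 2); spo <- fate %in% c(1, 3)
    gfp <- rnorm(n, params$bg_mean, params$bg_sd) +
      ifelse(on, stats::rlnorm(n, params$gfp_on_meanlog, params$gfp_on_sdlog), 0)
    mch <- rnorm(n, params$bg_mean, params$bg_sd) +
      ifelse(spo, stats::rlnorm(n, params$mch_on_meanlog, params$mch_on_sdlog), 0)
    rows[[img]] <- data.frame(
      image_id = img, cell_id = seq_len(n),
      gfp_mean = pmax(gfp, 0), mcherry_mean = pmax(mch, 0),
      gfp_bg_mean = params$bg_mean, gfp_bg_sd = params$bg_sd,
      mch_bg_mean = params$bg_mean, mch_bg_sd = params$bg_sd
    )
    truths[[img]] <- data.frame(image_id = img, cell_id = seq_len(n),
                                on = on, spo = spo)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truths)
  class(out) <- c("cell_intensity_table", "data.frame")
  out
}

#' Call expressing / sporulating cells by background thresholding
#'
#' A cell is called positive in a channel when its mean intensity exceeds
#' the per-image background mean by more than `k_sigma` background
#' standard deviations (the operational reading of "significantly higher
#' than background"; default 3).
#'
#' @param table a [generate_reporter_table()] table (or an externally
#'   loaded table with the same columns).
#' @param k_sigma threshold multiplier.
#' @return the table with logical columns `on_call` and `spo_call` added.
#' @export
call_expressing <- function(table, k_sigma = 3) {
  need <- c("gfp_mean", "mcherry_mean", "gfp_bg_mean", "gfp_bg_sd",
            "mch_bg_mean", "mch_bg_sd")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing background/intensity columns: ",
                         paste(miss, collapse = ", "))
  table$on_call <- table$gfp_mean > table$gfp_bg_mean +
    k_sigma * table$gfp_bg_sd
  table$spo_call <- table$mcherry_mean > table$mch_bg_mean +
    k_sigma * table$mch_bg_sd
  table
}

per_image_stats <- function(called) {
  sp <- split(called, called$image_id)
  do.call(rbind, lapply(sp, function(d) {
    spo <- d$spo_call
    data.frame(
      image_id = d$image_id[1], n = nrow(d),
      frac_on = mean(d$on_call),
      frac_on_spo = if (any(spo)) mean(d$on_call[spo]) else NA_real_,
      frac_on_nonspo = if (any(!spo)) mean(d$on_call[!spo]) else NA_real_
    )
  }))
}

#' Compare two strains' reporter tables
#'
#' Computes, per image, the fraction of matrix-on cells among
#' non-sporulating and sporulating cells and their fold change
#' (non-spo / spo); images where either conditional fraction is zero or
#' undefined are excluded from the fold-change set (with a recorded
#' count). Strains are compared by a two-sample t test (Welch by
#' default) on the per-image fold changes.
#'
#' @param tableA,tableB called tables ([call_expressing()] output) for
#'   the two strains.
#' @param k_sigma threshold passed to [call_expressing()] when the input
#'   has no calls yet.
#' @param welch use the Welch (unequal-variance) t test (default `TRUE`).
#' @return list with per-strain per-image statistics, per-image fold
#'   changes, their means and SDs, the t statistic and p value, and the
#'   number of excluded images.
#' @export
compare_strains <- function(tableA, tableB, k_sigma = 3, welch = TRUE) {
  prep <- function(tb) {
    if (!"on_call" %in% names(tb)) tb <- call_expressing(tb, k_sigma)
    per_image_stats(tb)
  }
  a <- prep(tableA); b <- prep(tableB)
  if (nrow(a) < 2 || nrow(b) < 2) stop("need at least 2 images per strain")
  folds <- function(d) {
    f <- d$frac_on_nonspo / d$frac_on_spo
    bad <- !is.finite(f)
    list(fold = f[!bad], excluded = sum(bad))
  }
  fa <- folds(a); fb <- folds(b)
  tt <- t.test(fa$fold, fb$fold, var.equal = !welch)
  list(
    per_image = list(A = a, B = b),
    fold_A = fa$fold, fold_B = fb$fold,
    mean_fold_A = mean(fa$fold), sd_fold_A = sd(fa$fold),
    mean_fold_B = mean(fb$fold), sd_fold_B = sd(fb$fold),
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    excluded_images = c(A = fa$excluded, B = fb$excluded)
  )
}
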