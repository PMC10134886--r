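#' Thresholds for single-cell fate classification
#'
#' A cell is "sporulating" if the growth rate of the cycle in force at
#' the observation time is below `mu_spo` (default 0.17/h), and
#' "matrix-on" if its TapA reporter count strictly exceeds `tapa_on`
#' (default 500 molecules, the upper edge of the first histogram bin).
#' The default observation time is T8 (8 h after culture start).
#'
#' @param mu_spo sporulation growth-rate threshold (1/h).
#' @param tapa_on expression threshold (molecules).
#' @param observation_time observation time (h).
#' @return object of class `fate_thresholds`.
#' @export
fate_thresholds <- function(mu_spo = 0.17, tapa_on = 500,
                            observation_time = 8) {
  stopifnot(mu_spo > 0, tapa_on >= 0, observation_time >= 0)
  structure(list(mu_spo = mu_spo, tapa_on = tapa_on,
                 observation_time = observation_time),
            class = "fate_thresholds")
}

ensemble_at <- function(records, time, species = "TapA") {
  st <- records[[1]]$sample_times
  k <- which(abs(st - time) < 1e-9)
  if (length(k) != 1)
    stop("observation time ", time, " is not a common sample time")
  data.frame(
    tapa = vapply(records, function(r) as.numeric(r$counts[k, species]),
                  numeric(1)),
    mu = vapply(records, function(r) r$mu_at[k], numeric(1))
  )
}

#' Classify cells as sporulating / matrix-expressing
#'
#' @param records a `lineage_ensemble` (or list of `lineage_record`s) on
#'   a common sample grid.
#' @param thresholds a [fate_thresholds()].
#' @return data frame with one row per cell: `tapa`, `mu`, logicals
#'   `spo` and `on`.
#' @export
classify_cells <- function(records, thresholds = fate_thresholds()) {
  d <- ensemble_at(records, thresholds$observation_time)
  d$spo <- d$mu < thresholds$mu_spo
  d$on <- d$tapa > thresholds$tapa_on
  d
}

#' Population summary of fate labels
#'
#' Fractions of matrix-expressing cells overall and conditioned on
#' sporulation status, conditional mean TapA levels, and the expression
#' histogram (bin width `bin_width` from zero; the first bin, holding the
#' non-expressing majority, is conventionally displayed on a broken
#' axis). Empty subgroups yield `NA` conditional means, not zero.
#'
#' @param labels output of [classify_cells()].
#' @param bin_width histogram bin width in molecules (default 500).
#' @return object of class `population_summary`.
#' @export
summarize_population <- function(labels, bin_width = 500) {
  stopifnot(nrow(labels) > 0)
  frac <- function(x) if (length(x)) mean(x) else NA_real_
  cmean <- function(v, sel) if (any(sel)) mean(v[sel]) else NA_real_
  breaks <- seq(0, max(labels$tapa, bin_width) + bin_width, by = bin_width)
  h <- hist(labels$tapa, breaks = breaks, plot = FALSE)
  out <- list(
    n = nrow(labels),
    fraction_on_all = frac(labels$on),
    fraction_spo = frac(labels$spo),
    fraction_on_spo = cmean(labels$on, labels$spo),
    fraction_on_nonspo = cmean(labels$on, !labels$spo),
    mean_tapa_all = mean(labels$tapa),
    mean_tapa_on = cmean(labels$tapa, labels$on),
    mean_tapa_off = cmean(labels$tapa, !labels$on),
    histogram = data.frame(lower = head(h$breaks, -1),
                           upper = tail(h$breaks, -1),
                           count = h$counts)
  )
  structure(out, class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<population_summary> n = %d\n",
           "  fraction on (all / spo / non-spo): %.3f / %s / %s\n",
           "  mean TapA (all / on): %.1f / %s\n"),
    x$n, x$fraction_on_all,
    formatC(x$fraction_on_spo, digits = 3, format = "f"),
    formatC(x$fraction_on_nonspo, digits = 3, format = "f"),
    x$mean_tapa_all,
    formatC(x$mean_tapa_on, digits = 1, format = "f")))
  invisible(x)
}

#' Population-mean expression dynamics
#'
#' Pointwise ensemble mean of a species over time with a bootstrap
#' confidence band (cells resampled with replacement).
#'
#' @param records a `lineage_ensemble` on a common sample grid.
#' @param species species name (default `"TapA"`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level.
#' @return data frame with columns `time`, `mean`, `lower`, `upper`.
#' @export
mean_dynamics <- function(records, species = "TapA", n_boot = 1000,
                          level = 0.95) {
  st <- records[[1]]$sample_times
  for (r in records)
    if (!identical(r$sample_times, st))
      stop("lineages are not on a common sample grid")
  m <- vapply(records, function(r) as.numeric(r$counts[, species]),
              numeric(length(st)))
  mu <- rowMeans(m)
  n <- ncol(m)
  alpha <- (1 - level) / 2
  bs <- replicate(n_boot, rowMeans(m[, sample.int(n, n, replace = TRUE),
                                     drop = FALSE]))
  data.frame(time = st, mean = mu,
             lower = apply(bs, 1, quantile, alpha),
             upper = apply(bs, 1, quantile, 1 - alpha))
}

#' Fraction of expressing cells over time
#'
#' @param records a `lineage_ensemble`.
#' @param tapa_on expression threshold (molecules).
#' @param species species name.
#' @return data frame with columns `time`, `fraction_on`.
#' @export
fraction_dynamics <- function(records, tapa_on = 500, species = "TapA") {
  st <- records[[1]]$sample_times
  m <- vapply(records, function(r) as.numeric(r$counts[, species]),
              numeric(length(st)))
  data.frame(time = st, fraction_on = rowMeans(m > tapa_on))
}

#' Peak time of a noisy time series
#'
#' Argmax of a centred three-point moving average; raw argmax on a
#' stochastic mean is fragile to single-sample spikes.
#'
#' @param time time grid.
#' @param value series values.
#' @return the smoothed peak time.
#' @export
peak_time <- function(time, value) {
  stopifnot(length(time) == length(value), length(time) >= 3)
  sm <- stats::filter(value, rep(1 / 3, 3), sides = 2)
  sm[1] <- value[1]; sm[length(sm)] <- value[length(value)]
  time[which.max(sm)]
}
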