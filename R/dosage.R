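#' Chromosomal gene locus
#'
#' A locus is identified by its normalised distance `p` from the
#' replication origin: `p = 0` at oriC, `p = 1` at the terminus.
#' Replication is assumed to start right after division and proceed at
#' constant speed, so the gene is replicated `p * tau_c` hours into the
#' cycle, where `tau_c` is the C period.
#'
#' @param name gene name.
#' @param p normalised origin distance in `[0, 1]`.
#' @return object of class `gene_locus`.
#' @export
gene_locus <- function(name, p) {
  stopifnot(is.character(name), length(p) == 1, p >= 0, p <= 1)
  structure(list(name = name, p = p), class = "gene_locus")
}

#' C period (replication duration) as a function of growth rate
#'
#' `tau_c = 0.78 + 0.15/mu` hours: replication takes longer in slow
#' growth, but much less so than the cell cycle itself (`ln 2 / mu`), so
#' slow-growing cells spend most of the cycle with fully replicated
#' chromosomes.
#'
#' @param mu growth rate(s), 1/h, positive.
#' @return C-period duration(s), h.
#' @export
c_period <- function(mu) {
  if (any(mu <= 0)) stop("growth rate must be positive")
  0.78 + 0.15 / mu
}

#' Cycle-averaged gene copy number
#'
#' The exponential-age-weighted average copy number of a locus at
#' position `p` is `n = 2^(1 - p tau_c / tau_cyc)` with
#' `tau_cyc = ln(2)/mu`; it equals 2 for an origin-proximal gene
#' (`p = 0`) at any growth rate and reduces to the terminus value
#' `2^(1 - tau_c/tau_cyc)` at `p = 1`. Values are clipped to `[1, 2]`;
#' if replication of the locus would not finish within one cycle
#' (`p tau_c > tau_cyc`, multifork territory, which this model does not
#' cover) a warning is raised and 1 is returned.
#'
#' @param locus a [gene_locus()] (or a bare numeric `p`).
#' @param mu growth rate, 1/h, positive.
#' @return average copy number in `[1, 2]`.
#' @export
average_copy_number <- function(locus, mu) {
  p <- if (inherits(locus, "gene_locus")) locus$p else locus
  stopifnot(p >= 0, p <= 1)
  if (any(mu <= 0)) stop("growth rate must be positive")
  frac <- p * c_period(mu) / (log(2) / mu)
  if (any(frac > 1))
    warning("replication of locus would not complete within one cycle; ",
            "copy number clipped to 1")
  pmin(2, pmax(1, 2^(1 - frac)))
}

#' Replication schedule of loci within one cell cycle
#'
#' @param loci list of [gene_locus()] objects.
#' @param mu growth rate for this cycle, 1/h.
#' @param tau_cyc realised cycle duration (h); default `ln(2)/mu`.
#' @return object of class `copy_schedule` with per-locus replication
#'   times `p * tau_c` (h after birth).
#' @export
copy_schedule <- function(loci, mu, tau_cyc = log(2) / mu) {
  stopifnot(mu > 0, tau_cyc > 0)
  tc <- c_period(mu)
  p <- vapply(loci, function(l) l$p, numeric(1))
  times <- p * tc
  clipped <- times > tau_cyc
  if (any(clipped))
    warning("replication of ", paste(vapply(loci[clipped], `[[`, "", "name"),
                                     collapse = ", "),
            " does not finish within the cycle; copy number stays 1")
  structure(list(
    tau_c = tc, tau_cyc = tau_cyc,
    replication_times = setNames(times, vapply(loci, `[[`, "", "name"))
  ), class = "copy_schedule")
}

#' Instantaneous copy number of a locus at a given cell age
#'
#' 1 before the locus replication event, 2 after it (the event time is
#' `p * tau_c` after birth; a gene at the origin is therefore duplicated
#' from birth).
#'
#' @param locus a [gene_locus()].
#' @param cell_age age within the cycle (h), in `[0, tau_cyc]`.
#' @param schedule a [copy_schedule()].
#' @return integer copy number, 1 or 2.
#' @export
copy_number_at <- function(locus, cell_age, schedule) {
  stopifnot(inherits(schedule, "copy_schedule"))
  if (any(cell_age < 0) || any(cell_age > schedule$tau_cyc))
    stop("cell age outside the cycle [0, ", schedule$tau_cyc, "]")
  ev <- schedule$replication_times[[locus$name]]
  if (is.null(ev)) stop("locus ", locus$name, " not in schedule")
  ifelse(ev > schedule$tau_cyc | cell_age < ev, 1L, 2L)
}
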