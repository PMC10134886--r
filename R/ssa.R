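## Stochastic lineage simulation: R wrappers around the compiled
## next-reaction engine, plus a plain direct-method reference
## implementation used to cross-validate the engine.

new_lineage_record <- function(raw, net, sample_times, seed) {
  counts <- raw$counts
  colnames(counts) <- net$species$name
  structure(list(
    sample_times = sample_times,
    counts = counts,
    mu_at = raw$mu_at,
    spo0a_at = raw$spo0a_at,
    events = list(
      division_times = raw$division_times,
      replication_times = raw$replication_times,
      replication_gene = if (length(raw$replication_gene) &&
                             !is.null(net$genes))
        net$genes$name[raw$replication_gene] else character(0)
    ),
    n_events = raw$n_events,
    seed = seed
  ), class = "lineage_record")
}

#' @export
print.lineage_record <- function(x, ...) {
  cat(sprintf(
    "<lineage_record> %d samples to %.3g h, %d divisions, %.3g reaction events\n",
    length(x$sample_times), max(x$sample_times),
    length(x$events$division_times), x$n_events))
  invisible(x)
}

#' Stochastic simulation at fixed growth rate and Spo0A~P
#'
#' Runs the next-reaction simulation of a network in a dividing cell with
#' constant conditions: every cycle draws its duration from a normal
#' distribution with mean `ln(2)/mu` (CV and minimum from `sampler`),
#' genes replicate at `p * tau_c` after birth, and all species are
#' binomially partitioned at division (one daughter is followed). With
#' `divisions = FALSE` the network is simulated as plain well-mixed
#' kinetics (used for toy-network validation).
#'
#' @param network a [reaction_network()].
#' @param mu growth rate (1/h); ignored if `divisions = FALSE`.
#' @param spo0a Spo0A~P input (uM).
#' @param t_end simulation horizon (h).
#' @param sample_dt sampling interval (h); samples lie on
#'   `seq(0, t_end, sample_dt)`.
#' @param seed integer seed (all engine randomness flows from it).
#' @param init named integer vector of initial counts; defaults to the
#'   network's `species$init`.
#' @param sampler a [generation_sampler()].
#' @param divisions include the cell cycle (default `TRUE`).
#' @return a `lineage_record`.
#' @export
simulate_fixed_condition <- function(network, mu, spo0a, t_end = 200,
                                     sample_dt = 0.5, seed = 1L,
                                     init = NULL,
                                     sampler = generation_sampler(),
                                     divisions = TRUE) {
  stopifnot(t_end >= sample_dt, spo0a >= 0)
  if (divisions) stopifnot(mu > 0)
  cmp <- network_compile(network)
  x0 <- lineage_init(network, init)
  sample_times <- seq(0, t_end, by = sample_dt)
  set.seed(seed)
  raw <- .ssa_run(cmp, x0, t_end, sample_times,
                  0L, mu, numeric(0), numeric(0),
                  0L, spo0a, numeric(0), numeric(0),
                  sampler$epsilon, if (divisions) sampler$cv else 0,
                  sampler$min_gen, sampler$max_retry, divisions)
  new_lineage_record(raw, network, sample_times, seed)
}

lineage_init <- function(network, init) {
  if (is.null(init)) return(as.integer(network$species$init))
  if (!is.null(names(init))) {
    x <- setNames(as.integer(network$species$init), network$species$name)
    x[names(init)] <- as.integer(init)
    return(unname(x))
  }
  as.integer(init)
}

#' Stochastic simulation of one cell lineage under starvation
#'
#' Implements the per-cycle protocol: at each cycle start the mean
#' generation time is computed from the population growth trajectory with
#' the time-shift correction ([corrected_mean_generation_time()]), a
#' cycle duration is drawn (CV 0.25, minimum 0.2 h), the cycle growth
#' rate is `ln(2)/tau_cyc`, the Spo0A~P level for the cycle is the map
#' evaluated at that growth rate, gene replication is scheduled at
#' `p * tau_c`, and at division species are binomially partitioned and
#' one daughter followed.
#'
#' @param network a [reaction_network()].
#' @param traj a [simulate_growth()] trajectory covering `t_end`.
#' @param map a `spo0a_map`.
#' @param strain a [strain_preset()] or name.
#' @param t_end simulation horizon (h).
#' @param sample_times observation times (h), within `[0, t_end]`.
#' @param sampler a [generation_sampler()].
#' @param seed integer seed.
#' @param init initial counts (see [simulate_fixed_condition()]).
#' @return a `lineage_record`.
#' @export
simulate_lineage <- function(network, traj, map, strain, t_end = 14,
                             sample_times = seq(0, t_end, 0.5),
                             sampler = generation_sampler(), seed = 1L,
                             init = NULL) {
  stopifnot(inherits(traj, "growth_trajectory"),
            max(sample_times) <= t_end, min(sample_times) >= 0)
  if (max(traj$time) < t_end)
    stop("growth trajectory (", max(traj$time), " h) shorter than t_end")
  if (is.character(strain)) strain <- strain_preset(strain)
  cmp <- network_compile(network)
  x0 <- lineage_init(network, init)
  ## tabulate the map once; the engine interpolates S(mu) per cycle
  mu_grid <- seq(1e-3, max(0.75, max(traj$mu) * 1.2), length.out = 400)
  s_grid <- spo0a_of_growth(map, strain, mu_grid)
  set.seed(seed)
  raw <- .ssa_run(cmp, x0, t_end, sample_times,
                  1L, 0, traj$time, traj$mu,
                  1L, 0, mu_grid, s_grid,
                  sampler$epsilon, sampler$cv, sampler$min_gen,
                  sampler$max_retry, TRUE)
  rec <- new_lineage_record(raw, network, sample_times, seed)
  rec$strain <- strain$name
  rec
}

#' Simulate an ensemble of independent lineages
#'
#' Lineage `i` uses child seed `seed + i` (a documented counter scheme:
#' the root seed plus the 1-based lineage index), so any subset of the
#' ensemble can be reproduced independently.
#'
#' @inheritParams simulate_lineage
#' @param n_lineages number of lineages.
#' @param init initial counts used for every lineage; default: the low
#'   deterministic steady state at the initial growth rate, computed once.
#' @return object of class `lineage_ensemble` (list of `lineage_record`s
#'   with attributes `strain`, `sample_times`).
#' @export
simulate_ensemble <- function(network, traj, map, strain, n_lineages = 200,
                              t_end = 14, sample_times = seq(0, t_end, 0.5),
                              sampler = generation_sampler(), seed = 1L,
                              init = NULL) {
  if (is.character(strain)) strain <- strain_preset(strain)
  if (is.null(init)) {
    mu0 <- traj$mu[1]
    init <- initial_state_low(network, mu0,
                              spo0a_of_growth(map, strain, mu0))
  }
  recs <- lapply(seq_len(n_lineages), function(i)
    simulate_lineage(network, traj, map, strain, t_end, sample_times,
                     sampler, seed = seed + i, init = init))
  structure(recs, strain = strain$name, sample_times = sample_times,
            class = "lineage_ensemble")
}

#' @export
print.lineage_ensemble <- function(x, ...) {
  cat(sprintf("<lineage_ensemble> %d lineages, strain %s\n",
              length(x), attr(x, "strain")))
  invisible(x)
}

#' Binomial partitioning of a cell at division
#'
#' Each molecule goes to either daughter with probability 1/2; gene
#' copies reset to 1. Returns both daughters so conservation can be
#' checked; the simulator follows the `kept` daughter.
#'
#' @param counts named integer vector of molecule counts.
#' @return list with `kept` and `discarded` count vectors.
#' @export
divide_cell <- function(counts) {
  stopifnot(all(counts >= 0))
  kept <- rbinom(length(counts), counts, 0.5)
  names(kept) <- names(counts)
  list(kept = kept, discarded = counts - kept)
}

#' Direct-method (first-reaction-free) reference simulator
#'
#' A deliberately simple Gillespie direct-method implementation in plain
#' R, without cell cycles: total propensity, exponential waiting time,
#' categorical reaction choice. Used as an independent cross-check of the
#' compiled next-reaction engine on small networks.
#'
#' @param network a [reaction_network()].
#' @param spo0a Spo0A~P input for modifier terms (uM).
#' @param t_end horizon (h).
#' @param sample_dt sampling interval (h).
#' @param seed integer seed.
#' @param init initial counts.
#' @return matrix of sampled counts (rows = times, columns = species).
#' @export
ssa_direct <- function(network, spo0a = 0, t_end = 100, sample_dt = 0.5,
                       seed = 1L, init = NULL) {
  cmp <- network_compile(network)
  x <- as.numeric(lineage_init(network, init))
  set.seed(seed)
  sample_times <- seq(0, t_end, by = sample_dt)
  out <- matrix(NA_real_, length(sample_times), length(x),
                dimnames = list(NULL, network$species$name))
  t <- 0; sk <- 1
  repeat {
    a <- propensities(cmp, x, spo0a)
    a0 <- sum(a)
    tnext <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
    while (sk <= length(sample_times) && sample_times[sk] <= min(tnext, t_end)) {
      out[sk, ] <- x; sk <- sk + 1
    }
    if (tnext > t_end || sk > length(sample_times)) break
    t <- tnext
    j <- sample.int(length(a), 1, prob = a)
    x <- x + cmp$stoich[, j]
    if (any(x < 0)) stop("negative count in direct-method simulation")
  }
  out
}
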