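## Shared fixtures. Expensive objects (the default network, growth
## trajectories, lineage ensembles) are built lazily and cached so that
## several test files can reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

sin_net <- function() cached("sin_net", build_sin_network())

normal_traj <- function() cached(
  "normal_traj", simulate_growth(growth_params("normal"), t_end = 15))

slow_traj <- function() cached(
  "slow_traj", simulate_growth(growth_params("slow"), t_end = 15))

## the reference fast growth rate used for one-parameter cuts: the
## initial growth rate of the normal scenario
MU_FAST <- 0.45

## strain ensembles for the population-dynamics and fate checks
strain_ensemble <- function(strain, n = 200, seed = 5) {
  cached(paste0("ens_", strain, "_", n, "_", seed), {
    simulate_ensemble(sin_net(), normal_traj(), default_spo0a_map(),
                      strain, n_lineages = n, t_end = 14, seed = seed)
  })
}

## a hand-built ensemble of minimal lineage records with known labels:
## `on` cells get TapA counts above, `off` below, the 500 threshold
fake_ensemble <- function(on, mu, times = c(0, 8)) {
  stopifnot(length(on) == length(mu))
  lapply(seq_along(on), function(i) {
    counts <- matrix(0L, length(times), 12)
    colnames(counts) <- sin_net()$species$name
    counts[, "TapA"] <- if (on[i]) 1500L else 40L
    structure(list(sample_times = times, counts = counts,
                   mu_at = rep(mu[i], length(times)),
                   spo0a_at = rep(1, length(times)),
                   events = list(), n_events = 0, seed = i),
              class = "lineage_record")
  })
}
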