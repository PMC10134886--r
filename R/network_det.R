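## Deterministic engine: steady states, stability, bifurcation scans.

## Right-hand side of the deterministic ODE in molecule counts.
## Mass action (x^2 for a homodimerisation), Hill modifiers, cycle-average
## gene dosage, and dilution of every species at rate mu.
network_rhs <- function(cmp, mu, spo0a, dosage) {
  nr <- length(cmp$rate)
  force(dosage)
  function(t, x, p) {
    x <- pmax(x, 0)
    flux <- numeric(nr)
    for (j in seq_len(nr)) {
      v <- cmp$rate[j]
      if (cmp$re1[j] >= 0) {
        v <- v * x[cmp$re1[j] + 1L]
        if (cmp$re2[j] >= 0) v <- v * x[cmp$re2[j] + 1L]
      }
      if (cmp$mtype[j] != 0L) v <- v * modifier_factor(cmp, j, x, spo0a)
      if (cmp$gene[j] >= 0L) v <- v * dosage[cmp$gene[j] + 1L]
      flux[j] <- v
    }
    list(as.vector(cmp$stoich %*% flux) - mu * x)
  }
}

network_dosage <- function(net, mu) {
  if (is.null(net$genes)) return(numeric(0))
  vapply(net$genes$p, function(p) average_copy_number(p, mu), numeric(1))
}

## diverse deterministic starting states: repressor-rich corner, empty,
## antirepressor-rich corner, and scaled variants
default_starts <- function(net, n_starts) {
  ns <- nrow(net$species)
  spn <- net$species$name
  mk <- function(...) {
    x <- setNames(rep(0, ns), spn); v <- list(...)
    x[names(v)] <- unlist(v); x
  }
  starts <- list(zero = mk())
  if ("SinR2" %in% spn)
    starts$low <- mk(SinR2 = 150, SinR4 = 80, mRNA_sinR = 2)
  if ("SlrR2" %in% spn)
    starts$high <- mk(SlrR2 = 2000, mRNA_slrR = 10, TapA = 2000)
  if (ns <= 2) {  # toy networks: corners per species
    for (i in seq_len(ns)) {
      x <- setNames(rep(0, ns), spn); x[i] <- 500
      starts[[paste0("corner", i)]] <- x
    }
  }
  extra <- n_starts - length(starts)
  if (extra > 0) {
    base <- Reduce(pmax, starts)
    scales <- seq(0.15, 0.85, length.out = extra)
    for (k in seq_len(extra))
      starts[[paste0("scaled", k)]] <- base * scales[k]
  }
  starts[seq_len(min(length(starts), max(n_starts, length(starts))))]
}

integrate_to_ss <- function(rhs, x0, chunk = 80, max_time = 4000,
                            rate_tol = 1e-9) {
  x <- x0; t <- 0
  while (t < max_time) {
    out <- deSolve::ode(x, c(0, chunk / 2, chunk), rhs, NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    if (any(!is.finite(out)))
      stop("steady-state integration diverged at t = ", t)
    x <- pmax(out[nrow(out), -1], 0)
    t <- t + chunk
    dx <- rhs(0, x, NULL)[[1]]
    if (max(abs(dx) / (abs(x) + 1)) < rate_tol) break
  }
  list(x = x, residual = max(abs(rhs(0, x, NULL)[[1]]) / (abs(x) + 1)),
       converged = t < max_time)
}

numeric_jacobian <- function(rhs, x, eps = NULL) {
  n <- length(x)
  f0 <- rhs(0, x, NULL)[[1]]
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- if (is.null(eps)) max(1e-6, 1e-6 * abs(x[i])) else eps
    xp <- x; xp[i] <- xp[i] + h
    J[, i] <- (rhs(0, xp, NULL)[[1]] - f0) / h
  }
  J
}

newton_polish <- function(rhs, x, iters = 50, tol = 1e-10) {
  for (k in seq_len(iters)) {
    f <- rhs(0, x, NULL)[[1]]
    if (max(abs(f) / (abs(x) + 1)) < tol) break
    J <- numeric_jacobian(rhs, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    ## damped to stay in the positive orthant
    lam <- 1
    while (any(x + lam * step < -1e-6) && lam > 1e-4) lam <- lam / 2
    x <- pmax(x + lam * step, 0)
  }
  x
}

#' Find the deterministic steady states of a network
#'
#' Integrates from several diverse initial states (all-empty,
#' repressor-rich, antirepressor-rich corners and scaled blends) until
#' the relative state change per hour falls below `rate_tol`, clusters
#' the endpoints, polishes each by damped Newton iteration, and
#' classifies stability from the eigenvalues of a numerical Jacobian.
#' When exactly two stable states are found, the separating unstable
#' state is located by bisecting the straight segment between them on
#' basin membership and polishing the basin-boundary point.
#'
#' @param network a [reaction_network()].
#' @param mu growth rate (1/h).
#' @param spo0a Spo0A~P input (uM).
#' @param n_starts number of initial states (>= 2).
#' @param rate_tol convergence tolerance on relative state change per hour.
#' @param find_unstable also search for the separating unstable state.
#' @return object of class `steady_states`: list with `states` (a data
#'   frame of per-species counts), `stable`, `branch`, `residual`.
#' @export
find_steady_states <- function(network, mu, spo0a, n_starts = 6,
                               rate_tol = 1e-9, find_unstable = TRUE) {
  stopifnot(n_starts >= 2, mu >= 0, spo0a >= 0)
  cmp <- network_compile(network)
  rhs <- network_rhs(cmp, mu, spo0a, network_dosage(network, mu))
  starts <- default_starts(network, n_starts)
  ends <- list(); res <- numeric(0)
  for (x0 in starts) {
    fit <- integrate_to_ss(rhs, x0, rate_tol = rate_tol)
    if (!fit$converged)
      stop("no steady-state convergence; worst residual ", fit$residual)
    x <- newton_polish(rhs, fit$x)
    ends[[length(ends) + 1]] <- x
    res <- c(res, max(abs(rhs(0, x, NULL)[[1]]) / (abs(x) + 1)))
  }
  ## cluster endpoints by relative distance
  uniq <- list(ends[[1]]); ures <- res[1]
  for (k in seq_along(ends)[-1]) {
    isnew <- all(vapply(uniq, function(u)
      max(abs(ends[[k]] - u) / (abs(u) + 1)) > 1e-4, logical(1)))
    if (isnew) { uniq[[length(uniq) + 1]] <- ends[[k]]; ures <- c(ures, res[k]) }
  }
  stab <- vapply(uniq, function(x) {
    ev <- eigen(numeric_jacobian(rhs, x), only.values = TRUE)$values
    all(Re(ev) < 1e-8)
  }, logical(1))
  states <- do.call(rbind, uniq)
  colnames(states) <- cmp$species
  readout <- if ("TapA" %in% cmp$species) "TapA" else cmp$species[1]
  ord <- order(states[, readout])
  states <- states[ord, , drop = FALSE]; stab <- stab[ord]; ures <- ures[ord]
  branch <- rep("unstable", nrow(states))
  st_idx <- which(stab)
  if (length(st_idx) >= 1) branch[st_idx[1]] <- "low"
  if (length(st_idx) == 2) branch[st_idx[2]] <- "high"
  out <- list(states = as.data.frame(states), stable = stab, branch = branch,
              residual = ures, mu = mu, spo0a = spo0a, readout = readout)
  class(out) <- "steady_states"
  if (find_unstable && sum(stab) == 2 && !any(!stab)) {
    un <- try(unstable_between(rhs, states[st_idx[1], ], states[st_idx[2], ],
                               readout_idx = match(readout, cmp$species)),
              silent = TRUE)
    if (!inherits(un, "try-error") && !is.null(un)) {
      out$states <- rbind(out$states, as.data.frame(t(un)))
      out$stable <- c(out$stable, FALSE)
      out$branch <- c(out$branch, "unstable")
      out$residual <- c(out$residual,
                        max(abs(rhs(0, un, NULL)[[1]]) / (abs(un) + 1)))
    }
  }
  out
}

## bisection on the segment between two stable states to straddle the
## basin boundary, then polish toward the saddle
unstable_between <- function(rhs, xa, xb, readout_idx, iters = 40) {
  basin_of <- function(x) {
    fit <- integrate_to_ss(rhs, x, chunk = 60, max_time = 1500, rate_tol = 1e-7)
    da <- max(abs(fit$x - xa) / (abs(xa) + 1))
    db <- max(abs(fit$x - xb) / (abs(xb) + 1))
    if (da < db) "a" else "b"
  }
  lo <- 0; hi <- 1
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    x <- (1 - mid) * xa + mid * xb
    if (basin_of(x) == "a") lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  x <- (1 - (lo + hi) / 2) * xa + (lo + hi) / 2 * xb
  ## slide along the basin boundary: trajectories started on it approach
  ## the saddle before the unstable direction ejects them, so take the
  ## point of minimal velocity along the orbit, then polish
  out <- deSolve::ode(x, seq(0, 40, 0.25), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  vel <- apply(out[, -1, drop = FALSE], 1, function(z)
    max(abs(rhs(0, pmax(z, 0), NULL)[[1]]) / (abs(z) + 1)))
  ## velocity dips at the saddle pass, grows during ejection, then falls
  ## again at the stable attractor: take the first local minimum
  k <- which(diff(vel) > 0)[1]
  if (is.na(k)) k <- which.min(vel)
  x <- pmax(out[k, -1], 0)
  x <- newton_polish(rhs, x, iters = 100)
  f <- rhs(0, x, NULL)[[1]]
  if (max(abs(f) / (abs(x) + 1)) > 1e-6) return(NULL)
  ev <- eigen(numeric_jacobian(rhs, x), only.values = TRUE)$values
  if (all(Re(ev) < 1e-8)) return(NULL)   # not a saddle
  x
}

#' @export
print.steady_states <- function(x, ...) {
  cat(sprintf("<steady_states> mu = %.3g, Spo0A~P = %.3g uM: %d state(s)\n",
              x$mu, x$spo0a, nrow(x$states)))
  for (i in seq_len(nrow(x$states)))
    cat(sprintf("  %-8s %s  %s = %.4g\n", x$branch[i],
                if (x$stable[i]) "stable  " else "unstable",
                x$readout, x$states[i, x$readout]))
  invisible(x)
}

#' Two-parameter bifurcation scan
#'
#' Counts stable steady states on a (growth rate, Spo0A~P) grid. Each
#' cell is seeded by the converged states of its scanned neighbour
#' (parameter continuation) in addition to the default corner starts, so
#' both branches are tracked through the bistable region.
#'
#' @param network a [reaction_network()].
#' @param mu_grid sorted growth-rate grid (1/h).
#' @param spo0a_grid sorted Spo0A~P grid (uM).
#' @param rate_tol convergence tolerance (see [find_steady_states()]).
#' @return object of class `bifurcation_diagram`: data frame with
#'   columns `mu`, `spo0a`, `n_stable`, `tapA_low`, `tapA_high`.
#' @export
scan_bifurcation <- function(network, mu_grid, spo0a_grid, rate_tol = 1e-8) {
  stopifnot(length(mu_grid) > 0, length(spo0a_grid) > 0,
            !is.unsorted(mu_grid), !is.unsorted(spo0a_grid))
  cmp <- network_compile(network)
  readout <- if ("TapA" %in% cmp$species) "TapA" else cmp$species[1]
  ridx <- match(readout, cmp$species)
  rows <- list()
  prev_col <- vector("list", length(spo0a_grid))
  for (im in seq_along(mu_grid)) {
    mu <- mu_grid[im]
    dos <- network_dosage(network, mu)
    prev_cell <- NULL
    for (is in seq_along(spo0a_grid)) {
      s <- spo0a_grid[is]
      rhs <- network_rhs(cmp, mu, s, dos)
      starts <- default_starts(network, 3)
      for (sd_ in c(prev_cell, prev_col[[is]])) starts[[length(starts) + 1]] <- sd_
      ends <- list()
      for (x0 in starts) {
        fit <- integrate_to_ss(rhs, x0, rate_tol = rate_tol)
        if (!fit$converged) stop("non-convergence at mu=", mu, " spo0a=", s,
                                 " residual ", fit$residual)
        x <- newton_polish(rhs, fit$x)
        isnew <- all(vapply(ends, function(u)
          max(abs(x - u) / (abs(u) + 1)) > 1e-4, logical(1)))
        if (isnew) ends[[length(ends) + 1]] <- x
      }
      stab <- vapply(ends, function(x) {
        ev <- eigen(numeric_jacobian(rhs, x), only.values = TRUE)$values
        all(Re(ev) < 1e-8)
      }, logical(1))
      ends <- ends[stab]
      tap <- vapply(ends, `[[`, numeric(1), ridx)
      rows[[length(rows) + 1]] <- data.frame(
        mu = mu, spo0a = s, n_stable = length(ends),
        tapA_low = min(tap), tapA_high = max(tap)
      )
      prev_cell <- ends
      prev_col[[is]] <- ends
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bifurcation_diagram", "data.frame")
  out
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  nb <- sum(x$n_stable == 2)
  cat(sprintf("<bifurcation_diagram> %d cells, %d bistable\n", nrow(x), nb))
  invisible(x)
}

#' Total SinR to total SlrR ratio without transcriptional regulation
#'
#' Disables the repression of slrR by the SinR tetramer and computes, at
#' each growth rate, the steady-state ratio of total SinR to total SlrR
#' in monomer equivalents (free, oligomeric and complexed). Because SlrR
#' is degraded fast while SinR is diluted, and because slrR sits near the
#' replication origin while sinR sits near the terminus, the ratio rises
#' as growth slows -- the repressive arm of the feed-forward loop.
#'
#' @param network a [build_sin_network()] network.
#' @param mu_grid growth rates (1/h), positive.
#' @param spo0a Spo0A~P input held fixed (uM).
#' @return data frame with columns `mu`, `sinr_total`, `slrr_total`,
#'   `ratio`.
#' @export
sinr_slrr_ratio <- function(network, mu_grid, spo0a = 0.5) {
  stopifnot(all(mu_grid > 0))
  ## remove the SinR4 repression of slrR transcription
  net2 <- network
  for (j in seq_along(net2$reactions))
    if (net2$reactions[[j]]$name == "tx_slrR")
      net2$reactions[[j]]$modifier <- NULL
  cmp <- network_compile(net2)
  hetero <- attr(network, "sini_stoich")
  if (is.null(hetero)) hetero <- "heterodimer"
  rows <- lapply(mu_grid, function(mu) {
    rhs <- network_rhs(cmp, mu, spo0a, network_dosage(net2, mu))
    fit <- integrate_to_ss(rhs, setNames(rep(0, nrow(net2$species)),
                                         net2$species$name))
    x <- newton_polish(rhs, fit$x)
    names(x) <- cmp$species
    ir_r <- if (hetero == "heterodimer") 1 else 2
    sinr <- 2 * x["SinR2"] + 4 * x["SinR4"] + ir_r * x["SinI_SinR"] +
      2 * x["SlrR2_SinR2"]
    slrr <- 2 * x["SlrR2"] + 2 * x["SlrR2_SinR2"] +
      if ("SlrR" %in% cmp$species) x["SlrR"] else 0
    if (slrr <= 0) stop("zero SlrR steady state at mu = ", mu)
    data.frame(mu = mu, sinr_total = unname(sinr), slrr_total = unname(slrr),
               ratio = unname(sinr / slrr))
  })
  do.call(rbind, rows)
}

#' Hysteresis sweep along a Spo0A~P path
#'
#' Follows the steady state by continuation while Spo0A~P is stepped up
#' and then back down at fixed growth rate. Inside a bistable window the
#' upward and downward traces occupy different branches; outside they
#' coincide.
#'
#' @param network a [reaction_network()].
#' @param mu growth rate (1/h).
#' @param spo0a_path increasing vector of Spo0A~P values; the sweep runs
#'   up this path then back down.
#' @return data frame with columns `spo0a`, `direction`, `tapA`.
#' @export
hysteresis_sweep <- function(network, mu, spo0a_path) {
  stopifnot(!is.unsorted(spo0a_path))
  cmp <- network_compile(network)
  dos <- network_dosage(network, mu)
  readout <- if ("TapA" %in% cmp$species) "TapA" else cmp$species[1]
  ridx <- match(readout, cmp$species)
  starts <- default_starts(network, 3)
  x_lo <- starts$low
  if (is.null(x_lo)) x_lo <- setNames(rep(0, nrow(network$species)),
                                      network$species$name)
  ## the downward sweep descends from whatever branch the
  ## antirepressor-rich corner reaches at the top of the path ("cells
  ## starting high remain high" inside the bistable window)
  x_hi <- if (!is.null(starts$high)) starts$high else x_lo
  run <- function(path, x, dir) {
    out <- vector("list", length(path))
    for (i in seq_along(path)) {
      rhs <- network_rhs(cmp, mu, path[i], dos)
      fit <- integrate_to_ss(rhs, x)
      x <- newton_polish(rhs, fit$x)
      out[[i]] <- data.frame(spo0a = path[i], direction = dir,
                             tapA = unname(x[ridx]))
    }
    list(trace = do.call(rbind, out), state = x)
  }
  up <- run(spo0a_path, x_lo, "up")
  down <- run(rev(spo0a_path), x_hi, "down")
  rbind(up$trace, down$trace[nrow(down$trace):1, ])
}

#' Low steady state as initial condition for stochastic runs
#'
#' Rounds the low-TapA stable steady state at the given conditions to
#' integer molecule counts; used to initialise lineages at culture start.
#'
#' @param network a [reaction_network()].
#' @param mu growth rate (1/h).
#' @param spo0a Spo0A~P input (uM).
#' @return named integer vector of counts.
#' @export
initial_state_low <- function(network, mu, spo0a) {
  ss <- find_steady_states(network, mu, spo0a, find_unstable = FALSE)
  i <- which(ss$branch == "low")[1]
  if (is.na(i)) i <- which(ss$stable)[1]
  x <- round(as.numeric(ss$states[i, ]))
  setNames(as.integer(pmax(x, 0)), colnames(ss$states))
}
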