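#' Growth-model parameters for a named scenario
#'
#' Parameters of the Moser-type batch-growth model
#' \deqn{dC/dt = C (a k_g N^{h_1}/(N^{h_1}+K_1^{h_1})
#'              - k_d N^{h_2}/(N^{h_2}+K_2^{h_2}))}
#' \deqn{dN/dt = -\gamma C (k_g N^{h_1}/(N^{h_1}+K_1^{h_1})
#'              - \psi k_d N^{h_2}/(N^{h_2}+K_2^{h_2}))}
#' where `C` is cell density (OD), `N` the nutrient normalised to 1 at
#' inoculation, and the population-mean growth rate is
#' `mu(N) = k_g N^h1 / (N^h1 + K1^h1)`.
#'
#' Two scenarios are bundled: `"normal"` emulates biofilm-inducing minimal
#' medium, calibrated so that the mean growth rate declines through the
#' sporulation threshold (0.17/h) between 8 and 9 h after inoculation;
#' `"slow"` emulates the nitrogen-reduced variant of the same medium and
#' differs only in the yield coefficient `gamma`, so the nutrient is
#' exhausted earlier.
#'
#' @param scenario `"normal"`, `"slow"`, or a named list overriding any
#'   subset of fields.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(scenario = "normal") {
  base <- list(
    k_g = 1.1,    # max growth rate, 1/h
    k_d = 0.15,   # max death/sporulation rate, 1/h
    K1  = 1.5,    # half-saturation, growth
    K2  = 0.3,    # half-saturation, death/sporulation
    h1  = 1,      # Hill coefficient, growth
    h2  = 2,      # Hill coefficient, death
    gamma = 1.4,  # yield: nutrient consumed per OD
    psi = 0.5,    # fraction of nutrient recycled by death
    a   = 1,      # growth-term prefactor
    C0  = 0.1,    # inoculation density (OD)
    N0  = 1,      # nutrient, normalised
    death_uses_K2 = TRUE
  )
  if (is.character(scenario)) {
    scenario <- match.arg(scenario, c("normal", "slow"))
    if (scenario == "slow") base$gamma <- 4.0
  } else if (is.list(scenario)) {
    unknown <- setdiff(names(scenario), names(base))
    if (length(unknown))
      stop("unknown growth parameter(s): ", paste(unknown, collapse = ", "))
    base[names(scenario)] <- scenario
  } else stop("scenario must be a name or a list of overrides")
  validate_growth_params(base)
  structure(base, class = "growth_params")
}

validate_growth_params <- function(p) {
  stopifnot(
    p$k_g > 0, p$k_d >= 0, p$K1 > 0, p$K2 > 0,
    p$h1 >= 1, p$h2 >= 1, p$gamma > 0,
    p$psi >= 0, p$psi <= 1, p$C0 > 0, p$N0 > 0
  )
  invisible(p)
}

#' Population-mean growth rate at a given nutrient level
#'
#' `mu = k_g N^h1 / (N^h1 + K1^h1)`: zero at exhausted nutrient, half
#' the maximum at `N = K1`, saturating to `k_g` in excess nutrient.
#'
#' @param params a [growth_params()] object.
#' @param N nutrient level(s), nonnegative.
#' @return growth rate(s), 1/h.
#' @export
mean_growth_rate <- function(params, N) {
  if (any(N < 0)) stop("nutrient level must be nonnegative")
  params$k_g * N^params$h1 / (N^params$h1 + params$K1^params$h1)
}

#' Simulate batch growth dynamics
#'
#' Integrates the Moser-type model with an adaptive stiff-capable solver
#' (lsoda, rtol 1e-8 / atol 1e-10) and returns the cell-density,
#' nutrient and mean-growth-rate trajectories on a regular grid.
#'
#' @param params a [growth_params()] object.
#' @param t_end simulation horizon (h).
#' @param dt output grid spacing (h).
#' @return object of class `growth_trajectory`: a data frame with columns
#'   `time`, `C`, `N`, `mu`, and the parameters in `attr(, "params")`.
#' @export
simulate_growth <- function(params, t_end = 14, dt = 0.01) {
  stopifnot(inherits(params, "growth_params"), t_end > 0, dt > 0)
  rhs <- function(t, x, p) {
    Kd <- if (isTRUE(p$death_uses_K2)) p$K2 else p$K1
    g <- p$k_g * x[2]^p$h1 / (x[2]^p$h1 + p$K1^p$h1)
    d <- p$k_d * x[2]^p$h2 / (x[2]^p$h2 + Kd^p$h2)
    list(c(x[1] * (p$a * g - d), -p$gamma * x[1] * (g - p$psi * d)))
  }
  out <- deSolve::ode(
    y = c(C = params$C0, N = params$N0),
    times = seq(0, t_end, by = dt),
    func = rhs, parms = params,
    method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  if (any(!is.finite(out)))
    stop("growth integration produced non-finite state near t = ",
         signif(out[which(!is.finite(out[, "C"] + out[, "N"]))[1], 1], 4), " h")
  traj <- data.frame(
    time = out[, "time"],
    C = pmax(out[, "C"], 0),
    N = pmax(out[, "N"], 0)
  )
  traj$mu <- mean_growth_rate(params, traj$N)
  structure(traj, params = params, class = c("growth_trajectory", "data.frame"))
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf(
    "<growth_trajectory> %d points over %.3g h; mu: %.3g -> %.3g 1/h\n",
    nrow(x), max(x$time), x$mu[1], x$mu[nrow(x)]
  ))
  invisible(x)
}

## linear interpolation of mu(t); beyond the grid, hold the last value
mu_at_time <- function(traj, t) {
  stats::approx(traj$time, traj$mu, xout = pmin(pmax(t, 0), max(traj$time)),
                rule = 2)$y
}

#' Generation-time sampler settings
#'
#' Generation times are drawn from a normal distribution with coefficient
#' of variation `cv` about the (time-shift corrected) mean generation
#' time; draws below `min_gen` are rejected and redrawn. `epsilon`
#' controls the forward time shift applied to the mean (see
#' [corrected_mean_generation_time()]).
#'
#' @param cv coefficient of variation (default 0.25).
#' @param min_gen minimum admissible generation time in hours (default 0.2).
#' @param epsilon time-shift factor (default 0.2).
#' @param max_retry retry cap for the rejection loop.
#' @return object of class `generation_sampler`.
#' @export
generation_sampler <- function(cv = 0.25, min_gen = 0.2, epsilon = 0.2,
                               max_retry = 1000L) {
  stopifnot(cv >= 0, min_gen > 0, epsilon >= 0, max_retry >= 1)
  structure(list(cv = cv, min_gen = min_gen, epsilon = epsilon,
                 max_retry = as.integer(max_retry)),
            class = "generation_sampler")
}

#' Time-shift-corrected mean generation time
#'
#' A cell cycle starting at time `t` spans times later than `t`, over
#' which the population growth rate keeps falling; using `ln(2)/mu(t)`
#' directly would bias lineages fast. The correction evaluates the growth
#' rate a fraction `epsilon` of one doubling ahead:
#' `tau_cyc(t) = ln(2)/mu(t + dt)` with `dt = epsilon ln(2)/mu(t)`.
#' Past the trajectory grid the final growth rate is used.
#'
#' @param traj a [simulate_growth()] trajectory.
#' @param t cycle start time (h).
#' @param epsilon time-shift factor (default 0.2).
#' @return mean generation time (h).
#' @export
corrected_mean_generation_time <- function(traj, t, epsilon = 0.2) {
  stopifnot(t >= 0, t <= max(traj$time))
  mu0 <- mu_at_time(traj, t)
  if (mu0 <= 0) stop("degenerate growth: mu(t) = 0 at t = ", t)
  dt <- epsilon * log(2) / mu0
  mu1 <- mu_at_time(traj, t + dt)
  if (mu1 <= 0) stop("degenerate growth: mu(t + dt) = 0 at t = ", t + dt)
  log(2) / mu1
}

#' Sample one generation time
#'
#' Normal draw with mean `mean_tau` and sd `cv * mean_tau`, redrawn until
#' the value is at least `min_gen` (rejection sampling; lineages are never
#' discarded). With `cv = 0` the mean is returned exactly.
#'
#' @param mean_tau mean generation time (h), positive.
#' @param sampler a [generation_sampler()].
#' @return one generation time (h).
#' @export
sample_generation_time <- function(mean_tau, sampler = generation_sampler()) {
  stopifnot(mean_tau > 0)
  if (sampler$cv == 0) return(max(mean_tau, sampler$min_gen))
  for (i in seq_len(sampler$max_retry)) {
    tau <- rnorm(1, mean_tau, sampler$cv * mean_tau)
    if (tau >= sampler$min_gen) return(tau)
  }
  stop("generation-time rejection loop exceeded ", sampler$max_retry,
       " retries (mean_tau = ", mean_tau, ")")
}
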