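#' Strain presets for the growth-rate to Spo0A~P mapping
#'
#' The upstream phosphorelay (KinA/KinC -> Spo0F -> Spo0B -> Spo0A) is not
#' modelled reaction-by-reaction; it is wrapped as a pluggable mapping
#' from growth rate to Spo0A~P concentration. The default mapping for
#' each strain is a decreasing sigmoid in growth rate,
#' `S(mu) = S0 + (Smax - S0) * Kmu^h / (Kmu^h + mu^h)`,
#' parameterised so that the known qualitative orderings hold:
#' at slow growth `dsda > dkinC > WT > dkinA`, at fast growth
#' `WT > dkinC` (the WT and dkinC curves cross once), and `dsda` exceeds
#' WT throughout.
#'
#' `mu_spo` is the per-strain sporulation growth-rate threshold used by
#' the fate module (default 0.17/h for every strain; the `dsda` strain
#' may be configured lower since its sporulation starts earlier).
#'
#' @param name one of `"WT"`, `"dkinA"`, `"dkinC"`, `"dsda"`.
#' @param ... overrides for `Smax`, `S0`, `Kmu`, `h`, `mu_spo`.
#' @return object of class `strain_preset`.
#' @export
strain_preset <- function(name = c("WT", "dkinA", "dkinC", "dsda"), ...) {
  name <- match.arg(name)
  defaults <- list(
    WT    = list(Smax = 2.0, S0 = 0.010, Kmu = 0.29, h = 8, mu_spo = 0.17),
    dkinA = list(Smax = 1.2, S0 = 0.005, Kmu = 0.24, h = 8, mu_spo = 0.17),
    dkinC = list(Smax = 2.8, S0 = 0.005, Kmu = 0.25, h = 10, mu_spo = 0.17),
    dsda  = list(Smax = 3.2, S0 = 0.015, Kmu = 0.33, h = 8, mu_spo = 0.17)
  )[[name]]
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown preset field(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(c(list(name = name), defaults), class = "strain_preset")
}

#' Default phenomenological growth-rate to Spo0A~P map
#'
#' Returns a map object usable by [spo0a_of_growth()] and the lineage
#' simulator. The default implementation is the per-strain sigmoid
#' described in [strain_preset()] (provenance `"phenomenological"`). An
#' externally computed map can be supplied as a table of (mu, spo0a)
#' pairs per strain via `spo0a_map_from_table()`, e.g. output of a full
#' phosphorelay model (provenance `"phosphorelay-ode"`).
#'
#' @return object of class `spo0a_map`.
#' @export
default_spo0a_map <- function() {
  f <- function(strain, mu) {
    stopifnot(inherits(strain, "strain_preset"))
    if (any(mu < 0)) stop("growth rate must be nonnegative")
    with(strain, S0 + (Smax - S0) * Kmu^h / (Kmu^h + mu^h))
  }
  structure(list(fun = f, provenance = "phenomenological"),
            class = "spo0a_map")
}

#' Build a Spo0A~P map from a tabulated (mu, spo0a) relation
#'
#' Accepts a data frame with columns `strain`, `mu`, `spo0a` (for example
#' produced by an external phosphorelay ODE model) and interpolates
#' linearly in `mu`, holding end values beyond the tabulated range.
#'
#' @param table data frame with columns `strain`, `mu`, `spo0a`.
#' @param provenance provenance tag stored on the map.
#' @return object of class `spo0a_map`.
#' @export
spo0a_map_from_table <- function(table, provenance = "phosphorelay-ode") {
  stopifnot(all(c("strain", "mu", "spo0a") %in% names(table)))
  if (any(table$spo0a < 0)) stop("tabulated Spo0A~P must be nonnegative")
  tabs <- split(table[c("mu", "spo0a")], table$strain)
  f <- function(strain, mu) {
    nm <- if (inherits(strain, "strain_preset")) strain$name else strain
    tb <- tabs[[nm]]
    if (is.null(tb)) stop("strain ", nm, " not present in the table")
    stats::approx(tb$mu, tb$spo0a, xout = mu, rule = 2)$y
  }
  structure(list(fun = f, provenance = provenance), class = "spo0a_map")
}

#' Evaluate a Spo0A~P map
#'
#' @param map a `spo0a_map` (default [default_spo0a_map()]).
#' @param strain a [strain_preset()] or strain name.
#' @param mu growth rate(s), 1/h, nonnegative.
#' @return Spo0A~P concentration(s), uM.
#' @export
spo0a_of_growth <- function(map, strain, mu) {
  stopifnot(inherits(map, "spo0a_map"))
  if (is.character(strain)) strain <- strain_preset(strain)
  map$fun(strain, mu)
}

#' Contract check for a Spo0A~P map
#'
#' Verifies on a dense growth-rate grid that the map is nonnegative and
#' monotone nonincreasing in growth rate for every strain. Called before
#' a map is used in a lineage ensemble.
#'
#' @param map a `spo0a_map`.
#' @param strains strain names to check.
#' @param mu_max top of the checked growth-rate range.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_spo0a_map <- function(map, strains = c("WT", "dkinA", "dkinC", "dsda"),
                               mu_max = 0.7) {
  grid <- seq(1e-3, mu_max, length.out = 1000)
  for (nm in strains) {
    s <- spo0a_of_growth(map, nm, grid)
    if (any(s < 0)) stop("map produces negative Spo0A~P for ", nm)
    if (any(diff(s) > 1e-9)) stop("map not nonincreasing in mu for ", nm)
  }
  invisible(TRUE)
}

#' Promoter activity under the direct Spo0A~P activation-repression model
#'
#' The alternative ("traditional") hypothesis posits that matrix
#' promoters are activated by moderate Spo0A~P and repressed again at
#' high Spo0A~P, modelled as a product of an activating and a repressing
#' Hill term:
#' \deqn{P \propto \frac{S^{n_1}}{S^{n_1}+K_1^{n_1}}
#'                 \frac{K_2^{n_2}}{S^{n_2}+K_2^{n_2}}}
#' with `n1 = 1.5`, `n2 = 8`, `K1 = 0.15`, `K2 = 0.8` (uM). The response
#' is zero at `S = 0`, rises, then shuts off sharply past `K2`.
#'
#' @param spo0a Spo0A~P concentration(s), uM, nonnegative.
#' @param n_t1,n_t2,K_t1,K_t2 Hill parameters.
#' @return relative promoter activity in `[0, 1]`.
#' @export
traditional_promoter_activity <- function(spo0a, n_t1 = 1.5, n_t2 = 8,
                                          K_t1 = 0.15, K_t2 = 0.8) {
  if (any(spo0a < 0)) stop("Spo0A~P must be nonnegative")
  stopifnot(n_t1 > 0, n_t2 > 0, K_t1 > 0, K_t2 > 0, K_t1 < K_t2)
  act <- spo0a^n_t1 / (spo0a^n_t1 + K_t1^n_t1)
  rep <- K_t2^n_t2 / (spo0a^n_t2 + K_t2^n_t2)
  act * rep
}
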