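#' Declare one reaction of a reaction network
#'
#' Reactions use mass-action kinetics in molecule counts: the propensity
#' of `A + B -> ...` is `rate * A * B`, of `2A -> ...` is
#' `rate * A * (A - 1)` (deterministically `rate * A^2`), and of a
#' zero- or first-order reaction `rate` times the reactant count.
#' Transcription reactions may carry a regulatory `modifier` (an
#' activating Hill term in the Spo0A~P input, or a repressing Hill term
#' in a network species) and a `gene`, whose copy number (1 or 2 in the
#' stochastic engine, the cycle average in the deterministic engine)
#' multiplies the rate.
#'
#' @param name reaction label.
#' @param rate rate constant (per hour, count units).
#' @param reactants,products named integer vectors of stoichiometries
#'   (names are species); `NULL` for none.
#' @param modifier `NULL`, or
#'   `list(type = "spo0a_act", K = , n = )` (multiplies by
#'   `S^n/(S^n + K^n)` with S the Spo0A~P input, K in uM), or
#'   `list(type = "hill_rep", species = , K = , n = )` (multiplies by
#'   `K^n/(K^n + x^n)`, K in counts).
#' @param gene gene name whose dosage scales the rate, or `NA`.
#' @return a `reaction` list.
#' @export
reaction <- function(name, rate, reactants = NULL, products = NULL,
                     modifier = NULL, gene = NA_character_) {
  stopifnot(rate >= 0)
  if (!is.null(reactants)) stopifnot(all(reactants > 0), sum(reactants) <= 2)
  if (!is.null(modifier))
    stopifnot(modifier$type %in% c("spo0a_act", "hill_rep"))
  list(name = name, rate = rate, reactants = reactants, products = products,
       modifier = modifier, gene = gene)
}

#' Assemble a reaction network object
#'
#' @param species data frame with columns `name` and `init` (initial
#'   molecule counts); a `deg` column of first-order loss rates (1/h) is
#'   used by [dilution_augmented_rates()].
#' @param reactions list of [reaction()]s.
#' @param genes data frame with columns `name` and `p` (normalised origin
#'   distance of each transcribed locus).
#' @param volume_fl cell volume (fL) used for count/concentration
#'   conversion; 4 by default.
#' @return object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, genes = NULL, volume_fl = 4) {
  stopifnot(volume_fl > 0, !anyDuplicated(species$name))
  for (r in reactions) {
    for (s in c(names(r$reactants), names(r$products)))
      if (!s %in% species$name) stop("reaction ", r$name,
                                     " references unknown species ", s)
    if (!is.na(r$gene) && (is.null(genes) || !r$gene %in% genes$name))
      stop("reaction ", r$name, " references unknown gene ", r$gene)
    if (!is.null(r$modifier) && r$modifier$type == "hill_rep" &&
        !r$modifier$species %in% species$name)
      stop("modifier of ", r$name, " references unknown species")
  }
  structure(list(species = species, reactions = reactions,
                 genes = genes, volume_fl = volume_fl),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions, %d gene loci\n",
              nrow(x$species), length(x$reactions),
              if (is.null(x$genes)) 0L else nrow(x$genes)))
  invisible(x)
}

#' Default kinetic parameters of the SinI-SinR-SlrR network
#'
#' Constants stated for the organism are fixed: mRNA degradation 8.3/h
#' (5-min half-life), SlrR degradation 0.6/h, other proteins 0.2/h,
#' translation 200/h per mRNA (protein dimers therefore appear at 100/h),
#' cell volume 4 fL. Binding constants are of the order measured in
#' vitro for these interactions; transcription rates and the repression
#' thresholds were calibrated once so that the deterministic switch is
#' monostable-low below about 0.1 uM Spo0A~P, bistable above it with a
#' high branch that saturates past 0.4 uM, and loses bistability when
#' growth slows below roughly 0.3/h (see the package vignette for the
#' calibration account). Each value carries a `provenance` tag.
#'
#' @return named list of parameters with a `provenance` attribute.
#' @export
sin_network_params <- function() {
  nav <- .NAV_4FL
  p <- list(
    ## transcription, counts/h per gene copy
    a_sinI = 8, a_sinR = 9, a_slrR = 11, a_tapA = 58,
    ## promoter regulation
    K_act = 0.15, n_act = 2,      # Spo0A~P activation of sinI (uM)
    K_slrR = 7.5, K_tapA = 7.5,   # SinR4 repression thresholds (counts)
    n_rep = 4,
    ## translation and degradation, 1/h
    tl_rate = 200, deg_mrna = 8.3, deg_protein = 0.2, deg_slrr = 0.6,
    deg_tapa = 1.0,
    ## protein-protein interactions (bimolecular in counts/h)
    kf_I2 = 80 / nav,  kr_I2 = 10,
    kf_R4 = 100 / nav, kr_R4 = 5,
    kf_IR = 200 / nav, kr_IR = 2 / nav,
    kf_LR = 200 / nav, kr_LR = 0.2,
    ## gene loci (normalised origin distance)
    p_sinI = 0.95, p_sinR = 0.95, p_slrR = 0.05, p_tapA = 0.8
  )
  prov <- c(
    a_sinI = "calibrated", a_sinR = "calibrated", a_slrR = "calibrated",
    a_tapA = "calibrated", K_act = "calibrated", n_act = "calibrated",
    K_slrR = "calibrated", K_tapA = "calibrated", n_rep = "calibrated",
    tl_rate = "text", deg_mrna = "text", deg_protein = "text",
    deg_slrr = "text", deg_tapa = "default",
    kf_I2 = "default", kr_I2 = "default", kf_R4 = "default",
    kr_R4 = "default", kf_IR = "default", kr_IR = "default",
    kf_LR = "default", kr_LR = "default",
    p_sinI = "default", p_sinR = "default", p_slrR = "default",
    p_tapA = "default"
  )
  attr(p, "provenance") <- prov
  p
}

#' Build the SinI-SinR-SlrR reaction network
#'
#' Species: the four mRNAs, SinI monomer and dimer, SinR dimer and
#' tetramer, the SinI.SinR sequestration product, SlrR dimer, the
#' SlrR2.SinR2 heterotetramer, and the TapA reporter. Structure:
#' Spo0A~P activates sinI transcription; sinR is constitutive; slrR and
#' tapA are repressed by the SinR tetramer; SinI dimers sequester SinR
#' dimers; SlrR dimers bind SinR dimers into a heterotetramer whose SlrR
#' moiety is still degraded quickly (releasing the SinR dimer), which
#' together with the gene positions (slrR origin-proximal, sinI/sinR
#' origin-distal) makes the SinR:SlrR balance growth-rate sensitive.
#'
#' @param params parameter list as from [sin_network_params()]; any
#'   subset may be overridden by passing a modified copy.
#' @param sini_sinr_stoich `"heterodimer"`: `I2 + R2 <-> 2 (I.R)`
#'   (default); `"i2r2"`: `I2 + R2 <-> I2R2` (single complex).
#' @param slrr_production `"dimer"` (default): translation emits SlrR
#'   dimers directly; `"monomer"`: emits monomers with fast dimerisation.
#' @return a [reaction_network()].
#' @export
build_sin_network <- function(params = sin_network_params(),
                              sini_sinr_stoich = c("heterodimer", "i2r2"),
                              slrr_production = c("dimer", "monomer")) {
  sini_sinr_stoich <- match.arg(sini_sinr_stoich)
  slrr_production <- match.arg(slrr_production)
  q <- params
  sp <- data.frame(
    name = c("mRNA_sinI", "mRNA_sinR", "mRNA_slrR", "mRNA_tapA",
             "SinI", "SinI2", "SinR2", "SinR4", "SinI_SinR",
             "SlrR2", "SlrR2_SinR2", "TapA"),
    init = 0L,
    deg = c(rep(q$deg_mrna, 4), rep(q$deg_protein, 5),
            q$deg_slrr, q$deg_slrr + q$deg_protein, q$deg_tapa)
  )
  if (slrr_production == "monomer")
    sp <- rbind(sp, data.frame(name = "SlrR", init = 0L, deg = q$deg_slrr))
  genes <- data.frame(
    name = c("sinI", "sinR", "slrR", "tapA"),
    p = c(q$p_sinI, q$p_sinR, q$p_slrR, q$p_tapA)
  )
  rx <- list(
    reaction("tx_sinI", q$a_sinI, NULL, c(mRNA_sinI = 1),
             modifier = list(type = "spo0a_act", K = q$K_act, n = q$n_act),
             gene = "sinI"),
    reaction("tx_sinR", q$a_sinR, NULL, c(mRNA_sinR = 1), gene = "sinR"),
    reaction("tx_slrR", q$a_slrR, NULL, c(mRNA_slrR = 1),
             modifier = list(type = "hill_rep", species = "SinR4",
                             K = q$K_slrR, n = q$n_rep),
             gene = "slrR"),
    reaction("tx_tapA", q$a_tapA, NULL, c(mRNA_tapA = 1),
             modifier = list(type = "hill_rep", species = "SinR4",
                             K = q$K_tapA, n = q$n_rep),
             gene = "tapA"),
    reaction("deg_mRNA_sinI", q$deg_mrna, c(mRNA_sinI = 1)),
    reaction("deg_mRNA_sinR", q$deg_mrna, c(mRNA_sinR = 1)),
    reaction("deg_mRNA_slrR", q$deg_mrna, c(mRNA_slrR = 1)),
    reaction("deg_mRNA_tapA", q$deg_mrna, c(mRNA_tapA = 1)),
    reaction("tl_sinI", q$tl_rate, c(mRNA_sinI = 1),
             c(mRNA_sinI = 1, SinI = 1)),
    ## dimeric proteins appear at half the monomeric translation rate
    reaction("tl_sinR", q$tl_rate / 2, c(mRNA_sinR = 1),
             c(mRNA_sinR = 1, SinR2 = 1)),
    reaction("tl_tapA", q$tl_rate, c(mRNA_tapA = 1),
             c(mRNA_tapA = 1, TapA = 1)),
    reaction("dim_sinI", q$kf_I2, c(SinI = 2), c(SinI2 = 1)),
    reaction("undim_sinI", q$kr_I2, c(SinI2 = 1), c(SinI = 2)),
    reaction("tet_sinR", q$kf_R4, c(SinR2 = 2), c(SinR4 = 1)),
    reaction("untet_sinR", q$kr_R4, c(SinR4 = 1), c(SinR2 = 2)),
    reaction("bind_LR", q$kf_LR, c(SlrR2 = 1, SinR2 = 1),
             c(SlrR2_SinR2 = 1)),
    reaction("unbind_LR", q$kr_LR, c(SlrR2_SinR2 = 1),
             c(SlrR2 = 1, SinR2 = 1)),
    reaction("deg_SinI", q$deg_protein, c(SinI = 1)),
    reaction("deg_SinI2", q$deg_protein, c(SinI2 = 1)),
    reaction("deg_SinR2", q$deg_protein, c(SinR2 = 1)),
    reaction("deg_SinR4", q$deg_protein, c(SinR4 = 1)),
    reaction("deg_SlrR2", q$deg_slrr, c(SlrR2 = 1)),
    ## degradation of the complexed SlrR moiety frees the SinR dimer;
    ## degradation of the complexed SinR moiety frees the SlrR dimer
    reaction("deg_LR_slrr", q$deg_slrr, c(SlrR2_SinR2 = 1), c(SinR2 = 1)),
    reaction("deg_LR_sinr", q$deg_protein, c(SlrR2_SinR2 = 1),
             c(SlrR2 = 1)),
    reaction("deg_TapA", q$deg_tapa, c(TapA = 1))
  )
  rx <- c(rx, if (sini_sinr_stoich == "heterodimer") list(
    reaction("bind_IR", q$kf_IR, c(SinI2 = 1, SinR2 = 1), c(SinI_SinR = 2)),
    reaction("unbind_IR", q$kr_IR, c(SinI_SinR = 2),
             c(SinI2 = 1, SinR2 = 1)),
    reaction("deg_IR", q$deg_protein, c(SinI_SinR = 1))
  ) else list(
    reaction("bind_IR", q$kf_IR, c(SinI2 = 1, SinR2 = 1), c(SinI_SinR = 1)),
    reaction("unbind_IR", q$kr_IR * .NAV_4FL, c(SinI_SinR = 1),
             c(SinI2 = 1, SinR2 = 1)),
    reaction("deg_IR", q$deg_protein, c(SinI_SinR = 1))
  ))
  if (slrr_production == "dimer") {
    rx <- c(rx, list(
      reaction("tl_slrR", q$tl_rate / 2, c(mRNA_slrR = 1),
               c(mRNA_slrR = 1, SlrR2 = 1))
    ))
  } else {
    rx <- c(rx, list(
      reaction("tl_slrR", q$tl_rate, c(mRNA_slrR = 1),
               c(mRNA_slrR = 1, SlrR = 1)),
      reaction("dim_slrR", q$kf_I2 * 10, c(SlrR = 2), c(SlrR2 = 1)),
      reaction("deg_SlrR", q$deg_slrr, c(SlrR = 1))
    ))
  }
  net <- reaction_network(sp, rx, genes)
  attr(net, "params") <- params
  attr(net, "sini_stoich") <- sini_sinr_stoich
  net
}

#' Effective per-species loss rates under growth dilution
#'
#' In the deterministic engine every species is additionally diluted at
#' the growth rate, so the effective loss is `k_deg + mu`. The stochastic
#' engine uses `k_deg` alone: dilution is realised physically by binomial
#' partitioning at division. Because SlrR is degraded fast (0.6/h), a
#' change in growth rate perturbs its effective loss much less, in
#' relative terms, than that of stable proteins such as SinR (0.2/h) --
#' one arm of the incoherent feed-forward loop.
#'
#' @param network a [reaction_network()].
#' @param mu growth rate, 1/h, nonnegative.
#' @return named numeric vector of effective loss rates (1/h).
#' @export
dilution_augmented_rates <- function(network, mu) {
  stopifnot(mu >= 0)
  setNames(network$species$deg + mu, network$species$name)
}

#' Toy constitutive birth-death network
#'
#' Production at constant rate `k`, first-order loss at `d`: the count is
#' Poisson(k/d) at stationarity. Used to validate the stochastic engine
#' against closed-form moments.
#'
#' @param k production rate (counts/h).
#' @param d loss rate (1/h).
#' @return a [reaction_network()] with one species `X`.
#' @export
build_birth_death_network <- function(k = 50, d = 1) {
  reaction_network(
    species = data.frame(name = "X", init = 0L, deg = d),
    reactions = list(
      reaction("birth", k, NULL, c(X = 1)),
      reaction("death", d, c(X = 1))
    )
  )
}

#' Toy two-gene mutual-repressor (toggle) network
#'
#' Symmetric toggle: each protein represses the other's production with
#' a Hill term. Deterministically `dx/dt = b K^n/(K^n + y^n) - d x` and
#' symmetrically for `y`; bistable for sufficiently large `b/(dK)` and
#' `n > 1`. Used to cross-check steady-state finding and hysteresis
#' machinery on a system whose saddle-node points can be located by
#' one-dimensional root finding.
#'
#' @param b maximal production (counts/h).
#' @param K repression threshold (counts).
#' @param n Hill coefficient.
#' @param d loss rate (1/h).
#' @return a [reaction_network()] with species `X`, `Y`.
#' @export
build_toggle_network <- function(b = 60, K = 20, n = 3, d = 1) {
  reaction_network(
    species = data.frame(name = c("X", "Y"), init = 0L, deg = d),
    reactions = list(
      reaction("make_X", b, NULL, c(X = 1),
               modifier = list(type = "hill_rep", species = "Y", K = K, n = n)),
      reaction("make_Y", b, NULL, c(Y = 1),
               modifier = list(type = "hill_rep", species = "X", K = K, n = n)),
      reaction("deg_X", d, c(X = 1)),
      reaction("deg_Y", d, c(Y = 1))
    )
  )
}

## ---- internal: compile a network to flat arrays for the engines ----

network_compile <- function(net) {
  spn <- net$species$name
  nr <- length(net$reactions)
  ns <- length(spn)
  stoich <- matrix(0L, ns, nr, dimnames = list(spn, NULL))
  re1 <- re2 <- integer(nr)
  rate <- numeric(nr)
  mtype <- integer(nr); mspec <- integer(nr)
  mK <- numeric(nr); mn <- numeric(nr)
  gene <- integer(nr)
  gn <- if (is.null(net$genes)) character(0) else net$genes$name
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    rate[j] <- r$rate
    idx <- function(s) match(s, spn)
    if (!is.null(r$reactants))
      for (s in names(r$reactants))
        stoich[idx(s), j] <- stoich[idx(s), j] - as.integer(r$reactants[[s]])
    if (!is.null(r$products))
      for (s in names(r$products))
        stoich[idx(s), j] <- stoich[idx(s), j] + as.integer(r$products[[s]])
    rs <- r$reactants
    if (is.null(rs)) { re1[j] <- -1L; re2[j] <- -1L }
    else if (length(rs) == 1 && rs[[1]] == 1) {
      re1[j] <- idx(names(rs)) - 1L; re2[j] <- -1L
    } else if (length(rs) == 1 && rs[[1]] == 2) {
      re1[j] <- idx(names(rs)) - 1L; re2[j] <- re1[j]
    } else {
      re1[j] <- idx(names(rs)[1]) - 1L; re2[j] <- idx(names(rs)[2]) - 1L
    }
    m <- r$modifier
    if (is.null(m)) { mtype[j] <- 0L; mspec[j] <- -1L }
    else if (m$type == "spo0a_act") {
      mtype[j] <- 1L; mspec[j] <- -1L; mK[j] <- m$K; mn[j] <- m$n
    } else {
      mtype[j] <- 2L; mspec[j] <- idx(m$species) - 1L
      mK[j] <- m$K; mn[j] <- m$n
    }
    gene[j] <- if (is.na(r$gene)) -1L else match(r$gene, gn) - 1L
  }
  list(stoich = stoich, re1 = re1, re2 = re2, rate = rate,
       mtype = mtype, mspec = mspec, mK = mK, mn = mn, gene = gene,
       gene_p = if (length(gn)) net$genes$p else numeric(0),
       species = spn, genes = gn)
}

## modifier factor for a compiled reaction, vector state x (counts), input S
modifier_factor <- function(cmp, j, x, spo0a) {
  switch(cmp$mtype[j] + 1L,
    1,                                                  # none
    spo0a^cmp$mn[j] / (spo0a^cmp$mn[j] + cmp$mK[j]^cmp$mn[j]),
    cmp$mK[j]^cmp$mn[j] /
      (cmp$mK[j]^cmp$mn[j] + x[cmp$mspec[j] + 1L]^cmp$mn[j])
  )
}

## stochastic propensities for compiled network (R reference path)
propensities <- function(cmp, x, spo0a, dosage = NULL) {
  nr <- length(cmp$rate)
  a <- numeric(nr)
  for (j in seq_len(nr)) {
    v <- cmp$rate[j]
    if (cmp$re1[j] >= 0) {
      if (cmp$re2[j] == cmp$re1[j]) {
        n <- x[cmp$re1[j] + 1L]; v <- v * n * (n - 1)
      } else {
        v <- v * x[cmp$re1[j] + 1L]
        if (cmp$re2[j] >= 0) v <- v * x[cmp$re2[j] + 1L]
      }
    }
    v <- v * modifier_factor(cmp, j, x, spo0a)
    if (cmp$gene[j] >= 0 && !is.null(dosage)) v <- v * dosage[cmp$gene[j] + 1L]
    a[j] <- v
  }
  a
}
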