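#' @include AllClasses.R AllGenerics.R modelParams.R
NULL

## Genotype-class moments under linkage equilibrium, with exact handling of
## fixed loci (p_j = 1): the "exactly one mutation" class is evaluated as a
## Poisson-binomial term by exclusion instead of the p/(1-p) shortcut.
## Returns P0 (no mutation), P1 (exactly one), and the leave-one-out
## variants P0mi, P1mi over the background of each locus i.
.excludedMoments <- function(p) {
  L <- length(p)
  q <- 1 - p
  zero <- which(q == 0)
  m <- length(zero)
  if (m == 0L) {
    P0 <- prod(q)
    r <- p / q
    S <- sum(r)
    P0mi <- P0 / q
    return(list(P0 = P0, P1 = P0 * S, P0mi = P0mi, P1mi = P0mi * (S - r)))
  }
  P0mi <- numeric(L)
  P1mi <- numeric(L)
  if (m == 1L) {
    j <- zero
    prodq <- prod(q[-j])          # all loci except j ancestral
    P0mi[j] <- prodq
    P1mi[-j] <- prodq / q[-j]     # the one background mutation is locus j
    P1mi[j] <- prodq * sum(p[-j] / q[-j])
    return(list(P0 = 0, P1 = prodq, P0mi = P0mi, P1mi = P1mi))
  }
  if (m == 2L) {
    # with two fixed loci, "exactly one background mutation" is possible
    # only from the viewpoint of a fixed locus (the other one is mutant)
    for (i in zero) {
      others <- setdiff(seq_len(L), zero)
      P1mi[i] <- prod(q[others])
    }
  }
  list(P0 = 0, P1 = 0, P0mi = P0mi, P1mi = P1mi)
}

#' Phenotype-class probabilities and mean trait value
#'
#' Under linkage equilibrium the genotype classes are Poisson-binomial in
#' the allele frequencies: `P0` \eqn{= \prod_j (1-p_j)} is the probability
#' of carrying no mutation (ancestral phenotype \eqn{Z_0 = 0}), `P1` the
#' probability of exactly one mutation (phenotype \eqn{\delta}), and the
#' remainder carries the full mutant phenotype \eqn{Z_1 = 1}.  The mean
#' trait is \eqn{\bar Z = \delta P_1 + (1 - P_0 - P_1)}, which reduces to
#' \eqn{1 - P_0} under complete redundancy.  Loci fixed for the mutant
#' (`p_j = 1`) are handled exactly by exclusion.
#'
#' @param p numeric vector of mutant allele frequencies in `[0, 1]`.
#' @param delta single-mutant phenotype value in `[0.5, 1]`.
#' @return list with elements `P0`, `P1`, `meanZ`.
#' @examples
#' phenotypeMoments(c(0.95, 0), delta = 1)      # P0 = 0.05, meanZ = 0.95
#' phenotypeMoments(c(0.5, 0.5), delta = 0.5)   # meanZ = 0.5
#' @export
phenotypeMoments <- function(p, delta = 1) {
  stopifnot(all(is.finite(p)), all(p >= 0), all(p <= 1))
  em <- .excludedMoments(p)
  meanZ <- if (delta == 1) 1 - em$P0 else
    delta * em$P1 + (1 - em$P0 - em$P1)
  list(P0 = em$P0, P1 = em$P1, meanZ = meanZ)
}

#' Stopping metric: residual fraction of the maximal fitness increase
#'
#' The adaptive phase ends when the population mean fitness \eqn{\bar W}
#' has covered all but a fraction \eqn{f_w} of the maximal attainable
#' increase: \deqn{\frac{W(Z_1) - \bar W}{W(Z_1) - W(Z_0)} = f_w.}
#' With the Malthusian fitness \eqn{W(Z) = sZ} the selection coefficient
#' cancels and the metric equals \eqn{1 - \bar Z}; under complete
#' redundancy this is the residual proportion of individuals with the
#' ancestral phenotype, \eqn{P_0}.
#'
#' @inheritParams phenotypeMoments
#' @param s selection coefficient; retained for signature clarity only
#'   (it cancels), must be non-zero when supplied.
#' @return scalar metric value in `[0, 1]`.
#' @examples
#' stoppingMetric(c(0.95, 0), delta = 1)  # 0.05
#' @export
stoppingMetric <- function(p, delta = 1, s = NULL) {
  if (!is.null(s) && s == 0) stop("'s' must be non-zero")
  1 - phenotypeMoments(p, delta)$meanZ
}

#' Marginal allele fitnesses at every locus
#'
#' Under linkage equilibrium, selection acts on each locus through the
#' marginal (background-averaged) fitness of its two alleles.  For the
#' mutant allele at locus i the conditional mean trait is 1 under complete
#' redundancy and \eqn{\delta P_0^{(-i)} + (1 - P_0^{(-i)})} under relaxed
#' redundancy, with \eqn{P_0^{(-i)} = \prod_{j \ne i}(1 - p_j)}; for the
#' ancestral allele it is \eqn{1 - P_0^{(-i)}} (complete) or
#' \eqn{\delta P_1^{(-i)} + (1 - P_0^{(-i)} - P_1^{(-i)})} (relaxed).
#' The returned values are the Wrightian sampling weights for discrete
#' time, `1 + s * E[Z | allele]`.
#'
#' @inheritParams phenotypeMoments
#' @param s current Malthusian selection coefficient (`sD` before the
#'   environmental change, `sB` after).
#' @return list with numeric vectors `wMut`, `wAnc` (length `L`).
#' @examples
#' marginalFitnesses(c(0.5, 0.5), delta = 0.5, s = 0.1)
#' @export
marginalFitnesses <- function(p, delta = 1, s) {
  stopifnot(all(is.finite(p)), all(p >= 0), all(p <= 1), is.finite(s))
  em <- .excludedMoments(p)
  if (delta == 1) {
    wMut <- rep(1 + s, length(p))
    wAnc <- 1 + s * (1 - em$P0mi)
  } else {
    wMut <- 1 + s * (1 - (1 - delta) * em$P0mi)
    wAnc <- 1 + s * (1 - em$P0mi - (1 - delta) * em$P1mi)
  }
  if (any(wMut <= 0) || any(wAnc <= 0))
    stop("non-positive Wrightian weight; selection coefficient too negative")
  list(wMut = wMut, wAnc = wAnc)
}

## Deterministic part of one generation: marginal-fitness selection then
## one-way mutation (no back mutation).  Drift is applied by the caller.
.wfUpdateDet <- function(p, mu, delta, s) {
  w <- marginalFitnesses(p, delta, s)
  q <- 1 - p
  num <- p * w$wMut
  pSel <- num / (num + q * w$wAnc)
  pSel + mu * (1 - pSel)
}

#' One Wright-Fisher generation
#'
#' Applies, per locus and independently (linkage equilibrium): the
#' deterministic selection update
#' \eqn{p^* = p\,w_{mut} / (p\,w_{mut} + (1-p)\,w_{anc})} with the
#' marginal Wrightian weights of [marginalFitnesses()], one-way mutation
#' \eqn{p^{**} = p^* + \mu_i (1 - p^*)}, and binomial drift
#' \eqn{p' \sim \mathrm{Binomial}(N_e, p^{**}) / N_e}.  `p = 1` is
#' absorbing (no back mutation); `p = 0` is absorbing iff \eqn{\mu = 0}.
#'
#' @param state a [PopulationState-class].
#' @param params a [ModelParams-class].
#' @param s current Malthusian selection coefficient.
#' @return the new [PopulationState-class], generation incremented.
#' @export
wfStep <- function(state, params, s) {
  stopifnot(is(state, "PopulationState"), is(params, "ModelParams"))
  pDet <- .wfUpdateDet(state@p, muVec(params), params@delta, s)
  ne <- params@ne
  populationState(stats::rbinom(params@L, ne, pDet) / ne,
                  state@generation + 1L)
}

#' Burn-in to mutation-selection-drift equilibrium
#'
#' Starting from a population monomorphic for the ancestral allele at all
#' loci, evolves for `burnInFactor * ne` generations under mutation and
#' deleterious selection (`sD`).  Runs in which the deleterious mutant
#' allele reaches fixation at any locus are discarded and the burn-in
#' restarts with fresh randomness (conditioning on adaptation from the
#' ancestral state); the number of discarded attempts is attached as
#' attribute `"discardedBurnIns"`.  If more than `maxDiscardFrac` of at
#' least ten attempts are discarded the function aborts with a diagnostic
#' (very high mutation combined with weak deleterious selection).
#'
#' Alternative starting conditions skip the simulation entirely:
#' `startMode = "monomorphic"` returns the all-zero state and
#' `"deterministic_msb"` the deterministic mutation-selection balance
#' frequencies \eqn{\mu_i / |s_d|}.
#'
#' @param params a [ModelParams-class].
#' @return a [PopulationState-class] at generation 0 (the environmental
#'   change), with attribute `discardedBurnIns`.
#' @export
burnIn <- function(params) {
  stopifnot(is(params, "ModelParams"))
  L <- params@L
  mu <- muVec(params)
  if (params@startMode == "monomorphic") {
    st <- populationState(numeric(L), 0L)
    attr(st, "discardedBurnIns") <- 0L
    return(st)
  }
  if (params@startMode == "deterministic_msb") {
    if (params@sD >= 0)
      stop("'deterministic_msb' start requires sD < 0")
    st <- populationState(pmin(mu / abs(params@sD), 1), 0L)
    attr(st, "discardedBurnIns") <- 0L
    return(st)
  }
  ne <- params@ne
  nGen <- as.integer(round(params@burnInFactor * ne))
  delta <- params@delta
  sD <- params@sD
  attempts <- 0L
  discards <- 0L
  repeat {
    attempts <- attempts + 1L
    p <- numeric(L)
    fixed <- FALSE
    for (g in seq_len(nGen)) {
      p <- stats::rbinom(L, ne, .wfUpdateDet(p, mu, delta, sD)) / ne
      if (any(p == 1)) {
        fixed <- TRUE
        break
      }
    }
    if (!fixed) {
      st <- populationState(p, 0L)
      attr(st, "discardedBurnIns") <- discards
      return(st)
    }
    discards <- discards + 1L
    if (discards >= 10L && discards / attempts > params@maxDiscardFrac)
      stop("burn-in discard rate exceeds ", params@maxDiscardFrac,
           " (", discards, "/", attempts, " attempts lost to fixation); ",
           "mutation too strong relative to deleterious selection")
  }
}

#' Run the adaptive phase until the stopping rule fires
#'
#' Iterates Wright-Fisher generations under beneficial selection (`sB`)
#' from the supplied starting state, evaluating the stopping metric once
#' per generation after the drift step, until it drops to or below `fW`.
#' Because the rule is checked in discrete time the recorded
#' `metricAtStop` may overshoot below `fW`; the metric one generation
#' earlier (`metricPrev`) is recorded alongside.  A generation cap of
#' `maxGenFactor * ne` guards against parameter sets for which adaptation
#' stalls (e.g. relaxed redundancy with a single locus, where the optimum
#' is unreachable).
#'
#' @param state0 starting [PopulationState-class] (typically from
#'   [burnIn()]).
#' @param params a [ModelParams-class].
#' @param record logical; record the trajectory of allele frequencies.
#' @param thin record every `thin`-th generation when `record = TRUE`.
#' @return a [ReplicateResult-class].
#' @export
runAdaptivePhase <- function(state0, params, record = FALSE, thin = 1L) {
  stopifnot(is(state0, "PopulationState"), is(params, "ModelParams"))
  L <- params@L
  ne <- params@ne
  mu <- muVec(params)
  delta <- params@delta
  sB <- params@sB
  fW <- params@fW
  maxGen <- as.integer(round(params@maxGenFactor * ne))
  disc <- attr(state0, "discardedBurnIns")
  if (is.null(disc)) disc <- 0L

  p <- state0@p
  metric <- stoppingMetric(p, delta)
  traj <- if (record) list(`0` = p) else NULL
  g <- 0L
  metricPrev <- NA_real_
  while (metric > fW) {
    if (g >= maxGen)
      stop("adaptive phase exceeded ", maxGen, " generations without ",
           "reaching the stopping condition (adaptation stalled)")
    g <- g + 1L
    p <- stats::rbinom(L, ne, .wfUpdateDet(p, mu, delta, sB)) / ne
    metricPrev <- metric
    metric <- stoppingMetric(p, delta)
    if (record && (g %% thin == 0L || metric <= fW))
      traj[[as.character(g)]] <- p
  }
  trajectory <- if (record) {
    m <- do.call(rbind, traj)
    rownames(m) <- names(traj)
    m
  } else matrix(numeric(0), nrow = 0, ncol = L)
  new("ReplicateResult",
      pStop = p,
      order = order(-p),
      generations = g,
      metricAtStop = metric,
      metricPrev = metricPrev,
      discardedBurnIns = as.integer(disc),
      trajectory = trajectory)
}

#' @rdname accessors
#' @export
setMethod("stoppedFreqs", "ReplicateResult", function(x) x@pStop)

#' @rdname accessors
#' @export
setMethod("locusOrder", "ReplicateResult", function(x) x@order)

#' @rdname accessors
#' @export
setMethod("generationsElapsed", "ReplicateResult",
          function(x) x@generations)

#' @rdname accessors
#' @export
setMethod("metricAtStop", "ReplicateResult", function(x) x@metricAtStop)

setMethod("show", "ReplicateResult", function(object) {
  cat("ReplicateResult:", length(object@pStop), "loci, stopped after",
      object@generations, "generations\n")
  cat("  p_stop =", paste(format(object@pStop, digits = 4), collapse = ", "),
      "\n")
  cat("  major locus:", object@order[1],
      " metric_at_stop:", format(object@metricAtStop, digits = 4), "\n")
  invisible(NULL)
})

#' Simulate an ensemble of Wright-Fisher replicates
#'
#' Runs `replicates` independent replicates (each a conditioned burn-in
#' followed by the adaptive phase) and collects the stopped frequencies
#' into an [ArchitectureEnsemble-class].  A master seed (`params@seed`)
#' deterministically derives one sub-seed per replicate, so ensembles are
#' bit-reproducible and replicates independent.
#'
#' @param params a [ModelParams-class].
#' @param replicates number of replicates (>= 1).
#' @param verbose emit a progress message every 1000 replicates.
#' @return an [ArchitectureEnsemble-class] with `source = "wf"`.
#' @examples
#' \donttest{
#' par <- modelParams(ne = 500, L = 2, theta = 1, seed = 7)
#' ens <- simulateEnsemble(par, 20)
#' ratioSummary(ens)
#' }
#' @export
simulateEnsemble <- function(params, replicates, verbose = FALSE) {
  validateParams(params)
  stopifnot(replicates >= 1)
  set.seed(params@seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, replicates)
  L <- params@L
  freqs <- matrix(NA_real_, replicates, L)
  locusF <- matrix(NA_real_, replicates, L)
  gens <- numeric(replicates)
  metrics <- numeric(replicates)
  disc <- integer(replicates)
  for (r in seq_len(replicates)) {
    set.seed(subSeeds[r])
    st <- burnIn(params)
    res <- runAdaptivePhase(st, params)
    locusF[r, ] <- res@pStop
    freqs[r, ] <- res@pStop[res@order]
    gens[r] <- res@generations
    metrics[r] <- res@metricAtStop
    disc[r] <- res@discardedBurnIns
    if (verbose && r %% 1000L == 0L)
      message("replicate ", r, "/", replicates)
  }
  colnames(freqs) <- c("major", if (L > 1) paste0("minor", seq_len(L - 1)))
  colnames(locusF) <- paste0("locus", seq_len(L))
  new("ArchitectureEnsemble",
      freqs = freqs, locusFreqs = locusF, generations = gens,
      metricAtStop = metrics, discards = disc, params = params,
      source = "wf", seed = params@seed)
}
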