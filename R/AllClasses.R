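#' @import methods
NULL

#' Full parameterization of one adaptation scenario
#'
#' `ModelParams` holds every quantity needed to simulate or analyse the
#' adaptation of a redundant binary trait: a haploid population of size
#' \eqn{N_e} carries \eqn{L} bi-allelic loci, each mutating one-way
#' (ancestral to derived) at population-scaled rate
#' \eqn{\Theta_i = 2 N_e \mu_i}.  The derived phenotype has Malthusian
#' fitness \eqn{s_d \le 0} before and \eqn{s_b > 0} after the
#' environmental change; a genotype carrying a single mutation expresses
#' phenotype \eqn{\delta} (\eqn{\delta = 1}: complete redundancy;
#' \eqn{1/2 \le \delta < 1}: relaxed redundancy, two or more mutations
#' needed for the full phenotype).  Simulations are stopped when the mean
#' fitness has covered all but a fraction `fW` of the maximal increase.
#'
#' The population-scaled rates \eqn{\Theta_i} are the canonical mutation
#' input; per-generation rates \eqn{\mu_i = \Theta_i / (2 N_e)} are always
#' derived from them (see [muVec()]), so the analytic machinery never needs
#' \eqn{N_e}.
#'
#' @slot ne effective population size (haploid individuals), integer >= 2.
#' @slot L number of loci, integer >= 1.
#' @slot theta numeric vector of per-locus population mutation rates
#'   \eqn{\Theta_i = 2 N_e \mu_i}, all > 0, length `L`.
#' @slot sB beneficial Malthusian selection coefficient, > 0.
#' @slot sD deleterious Malthusian selection coefficient, <= 0 with
#'   Wrightian weight `1 + sD > 0`.
#' @slot delta single-mutant phenotype value; 1 for complete redundancy,
#'   in `[0.5, 1)` for relaxed redundancy.
#' @slot fW stopping fraction in (0, 1): residual fraction of the maximal
#'   fitness increase at the time of observation.
#' @slot burnInFactor burn-in length multiplier; the burn-in runs for
#'   `burnInFactor * ne` generations (default 8).
#' @slot seed RNG seed (integer).
#' @slot startMode one of `"equilibrium_burn_in"`, `"monomorphic"`,
#'   `"deterministic_msb"`.
#' @slot maxGenFactor adaptive-phase generation cap as a multiple of `ne`
#'   (default 100); exceeding it signals stalled adaptation.
#' @slot maxDiscardFrac burn-in guard: abort when more than this fraction
#'   of burn-in attempts is discarded by the no-fixation conditioning
#'   (default 0.9).
#'
#' @seealso [modelParams()] for the validating constructor,
#'   [thetaBg()] for the compound background mutation rate.
#' @export
setClass("ModelParams",
  slots = c(
    ne = "integer",
    L = "integer",
    theta = "numeric",
    sB = "numeric",
    sD = "numeric",
    delta = "numeric",
    fW = "numeric",
    burnInFactor = "numeric",
    seed = "integer",
    startMode = "character",
    maxGenFactor = "numeric",
    maxDiscardFrac = "numeric"
  )
)

.validModelParams <- function(object) {
  msg <- character()
  if (length(object@ne) != 1L || is.na(object@ne) || object@ne < 2L)
    msg <- c(msg, "'ne' must be a single integer >= 2")
  if (length(object@L) != 1L || is.na(object@L) || object@L < 1L)
    msg <- c(msg, "'L' must be a single integer >= 1")
  if (length(object@theta) != object@L)
    msg <- c(msg, "'theta' must have length L")
  if (any(!is.finite(object@theta)) || any(object@theta <= 0))
    msg <- c(msg, "all entries of 'theta' must be positive and finite")
  mu <- object@theta / (2 * as.numeric(object@ne))
  if (any(mu >= 1))
    msg <- c(msg, "per-locus mutation rate mu_i = theta_i/(2*ne) must be < 1")
  if (length(object@sB) != 1L || !is.finite(object@sB) || object@sB <= 0)
    msg <- c(msg, "'sB' must be a single positive number")
  if (length(object@sD) != 1L || !is.finite(object@sD) || object@sD > 0)
    msg <- c(msg, "'sD' must be a single number <= 0")
  if (length(object@sD) == 1L && is.finite(object@sD) && 1 + object@sD <= 0)
    msg <- c(msg, "Wrightian weight 1 + sD must be positive")
  if (length(object@delta) != 1L || !is.finite(object@delta) ||
      object@delta < 0.5 || object@delta > 1)
    msg <- c(msg, "'delta' must lie in [0.5, 1]")
  if (length(object@fW) != 1L || !is.finite(object@fW) ||
      object@fW <= 0 || object@fW >= 1)
    msg <- c(msg, "'fW' must lie strictly between 0 and 1")
  if (length(object@burnInFactor) != 1L || !is.finite(object@burnInFactor) ||
      object@burnInFactor <= 0)
    msg <- c(msg, "'burnInFactor' must be a single positive number")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(object@startMode) != 1L ||
      !object@startMode %in% c("equilibrium_burn_in", "monomorphic",
                               "deterministic_msb"))
    msg <- c(msg, paste("'startMode' must be one of 'equilibrium_burn_in',",
                        "'monomorphic', 'deterministic_msb'"))
  if (length(object@maxGenFactor) != 1L || !is.finite(object@maxGenFactor) ||
      object@maxGenFactor <= 0)
    msg <- c(msg, "'maxGenFactor' must be a single positive number")
  if (length(object@maxDiscardFrac) != 1L ||
      !is.finite(object@maxDiscardFrac) ||
      object@maxDiscardFrac <= 0 || object@maxDiscardFrac > 1)
    msg <- c(msg, "'maxDiscardFrac' must lie in (0, 1]")
  if (length(msg)) msg else TRUE
}

setValidity("ModelParams", .validModelParams)

#' Allele-frequency state of the simulated population
#'
#' A vector of mutant allele frequencies (one per locus, each in
#' \eqn{[0, 1]}) together with a generation counter.  Under linkage
#' equilibrium this is the complete state of the Wright-Fisher model.
#'
#' @slot p numeric vector of mutant allele frequencies.
#' @slot generation non-negative integer generation counter.
#'
#' @seealso [populationState()], [wfStep()]
#' @export
setClass("PopulationState",
  slots = c(p = "numeric", generation = "integer")
)

setValidity("PopulationState", function(object) {
  msg <- character()
  if (length(object@p) < 1L)
    msg <- c(msg, "'p' must have at least one entry")
  if (any(!is.finite(object@p)) || any(object@p < 0) || any(object@p > 1))
    msg <- c(msg, "all allele frequencies must lie in [0, 1]")
  if (length(object@generation) != 1L || is.na(object@generation) ||
      object@generation < 0L)
    msg <- c(msg, "'generation' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Outcome of one Wright-Fisher replicate
#'
#' Stopped allele-frequency vector, rank ordering of loci (the locus with
#' the highest frequency at the stopping condition is the *major locus*,
#' all others are *minor loci*), the duration of the adaptive phase, and
#' the value of the stopping metric at (and one generation before) the
#' stopping generation.
#'
#' @slot pStop stopped frequency vector (original locus order).
#' @slot order integer permutation sorting loci by descending stopped
#'   frequency; ties broken by lowest locus index.
#' @slot generations adaptive-phase duration in generations.
#' @slot metricAtStop stopping metric at the stopping generation
#'   (<= `fW`; may overshoot below `fW` because the rule is checked once
#'   per generation after drift).
#' @slot metricPrev stopping metric one generation before stopping
#'   (> `fW`; `NA` when the initial state already satisfied the rule).
#' @slot discardedBurnIns number of burn-in attempts rejected by the
#'   no-fixation conditioning for this replicate.
#' @slot trajectory optional matrix of recorded states (rows = recorded
#'   generations, columns = loci); 0-row matrix when not recorded.
#'
#' @seealso [runAdaptivePhase()], [simulateEnsemble()]
#' @export
setClass("ReplicateResult",
  slots = c(
    pStop = "numeric",
    order = "integer",
    generations = "integer",
    metricAtStop = "numeric",
    metricPrev = "numeric",
    discardedBurnIns = "integer",
    trajectory = "matrix"
  )
)

setValidity("ReplicateResult", function(object) {
  msg <- character()
  L <- length(object@pStop)
  if (length(object@order) != L ||
      !identical(sort(object@order), seq_len(L)))
    msg <- c(msg, "'order' must be a permutation of 1..L")
  if (L >= 2L) {
    ord <- object@pStop[object@order]
    if (any(diff(ord) > 0))
      msg <- c(msg, "'order' must sort frequencies in descending order")
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble of adaptive architectures
#'
#' Replicate-by-rank matrix of stopped mutant allele frequencies: column 1
#' holds the major locus of each replicate, column `k` the `(k-1)`-th
#' minor.  The matrix in original locus order is kept alongside, so both
#' the trait-centered (rank-ordered) and gene-centered (fixed-locus) views
#' of the joint distribution are available.
#'
#' @slot freqs numeric matrix, replicates x ranks, each row non-increasing.
#' @slot locusFreqs numeric matrix, replicates x loci, original locus order.
#' @slot generations numeric vector of adaptive-phase durations (`NA` for
#'   analytic samplers, which are time-free).
#' @slot metricAtStop numeric vector of stopping-metric values.
#' @slot discards integer vector of discarded burn-in attempts per
#'   replicate (all zero for analytic samplers).
#' @slot params the [ModelParams-class] the ensemble was generated under.
#' @slot source `"wf"` for the Wright-Fisher simulator,
#'   `"two_phase_analytic"` for the stochastic-phase + projection sampler.
#' @slot seed integer seed used for the ensemble.
#'
#' @seealso [simulateEnsemble()], [sampleArchitectureAnalytic()],
#'   [ratioSummary()], [rankHistograms()], [compareEnsembles()]
#' @export
setClass("ArchitectureEnsemble",
  slots = c(
    freqs = "matrix",
    locusFreqs = "matrix",
    generations = "numeric",
    metricAtStop = "numeric",
    discards = "integer",
    params = "ModelParams",
    source = "character",
    seed = "integer"
  )
)

setValidity("ArchitectureEnsemble", function(object) {
  msg <- character()
  n <- nrow(object@freqs)
  if (!identical(dim(object@freqs), dim(object@locusFreqs)))
    msg <- c(msg, "'freqs' and 'locusFreqs' must have identical dimensions")
  if (ncol(object@freqs) >= 2L &&
      any(object@freqs[, -1L, drop = FALSE] -
          object@freqs[, -ncol(object@freqs), drop = FALSE] > 1e-12))
    msg <- c(msg, "each row of 'freqs' must be non-increasing across ranks")
  if (length(object@generations) != n || length(object@metricAtStop) != n ||
      length(object@discards) != n)
    msg <- c(msg, "per-replicate vectors must match nrow(freqs)")
  if (length(object@source) != 1L ||
      !object@source %in% c("wf", "two_phase_analytic"))
    msg <- c(msg, "'source' must be 'wf' or 'two_phase_analytic'")
  if (length(msg)) msg else TRUE
})
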