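#' @include AllClasses.R AllGenerics.R
NULL

#' Construct and validate a scenario parameterization
#'
#' Builds a [ModelParams-class] object and validates every invariant of the
#' model: positive population-scaled mutation rates \eqn{\Theta_i} with
#' derived per-generation rates \eqn{\mu_i = \Theta_i/(2 N_e) < 1}, a
#' stopping fraction strictly inside (0, 1), a single-mutant phenotype
#' \eqn{\delta \in [1/2, 1]}, \eqn{s_b > 0}, \eqn{s_d \le 0} and positive
#' Wrightian weight \eqn{1 + s_d}.
#'
#' Defaults mirror the canonical study conditions: \eqn{N_e = 10^4},
#' \eqn{s_b = 0.1}, \eqn{s_d = -0.1}, \eqn{f_w = 0.05}, complete
#' redundancy (\eqn{\delta = 1}) and an `8 Ne`-generation burn-in.
#'
#' @param ne effective population size (haploid individuals).
#' @param L number of loci.
#' @param theta population-scaled mutation rate(s) \eqn{\Theta_i}; a scalar
#'   is recycled to all `L` loci (the symmetric model), or a vector of
#'   length `L`.
#' @param sB beneficial Malthusian selection coefficient (> 0).
#' @param sD deleterious Malthusian selection coefficient (<= 0).
#' @param delta single-mutant phenotype value (1 = complete redundancy).
#' @param fW stopping fraction in (0, 1).
#' @param burnInFactor burn-in length in units of `ne` generations.
#' @param seed RNG seed.
#' @param startMode starting condition: `"equilibrium_burn_in"` (default;
#'   monomorphic start followed by a conditioned burn-in under `sD`),
#'   `"monomorphic"` (all-ancestral start, no standing variation), or
#'   `"deterministic_msb"` (deterministic mutation-selection balance
#'   frequencies `mu/|sD|`, no simulation).
#' @param maxGenFactor adaptive-phase generation cap in units of `ne`.
#' @param maxDiscardFrac burn-in discard-rate guard in (0, 1].
#'
#' @return a validated [ModelParams-class] object.
#' @examples
#' p <- modelParams(ne = 10000, L = 2, theta = 1)
#' muVec(p)          # 5e-05 per locus per generation
#' thetaBg(thetaVec(p))
#' @export
modelParams <- function(ne = 10000, L = 2, theta = 1, sB = 0.1, sD = -0.1,
                        delta = 1, fW = 0.05, burnInFactor = 8, seed = 1L,
                        startMode = c("equilibrium_burn_in", "monomorphic",
                                      "deterministic_msb"),
                        maxGenFactor = 100, maxDiscardFrac = 0.9) {
  startMode <- match.arg(startMode)
  if (length(theta) == 1L) theta <- rep(as.numeric(theta), L)
  new("ModelParams",
      ne = as.integer(ne), L = as.integer(L), theta = as.numeric(theta),
      sB = as.numeric(sB), sD = as.numeric(sD), delta = as.numeric(delta),
      fW = as.numeric(fW), burnInFactor = as.numeric(burnInFactor),
      seed = as.integer(seed), startMode = startMode,
      maxGenFactor = as.numeric(maxGenFactor),
      maxDiscardFrac = as.numeric(maxDiscardFrac))
}

#' Validate a parameter object
#'
#' Re-runs the full validity check on an existing [ModelParams-class]
#' object (useful after programmatic slot surgery or config-file parsing)
#' and returns it invisibly unchanged on success.
#'
#' @param params a [ModelParams-class] object.
#' @return `params`, invisibly; signals an error listing all violated
#'   invariants otherwise.
#' @export
validateParams <- function(params) {
  stopifnot(is(params, "ModelParams"))
  validObject(params)
  invisible(params)
}

#' @rdname accessors
#' @export
setMethod("popSize", "ModelParams", function(x) x@ne)

#' @rdname accessors
#' @export
setMethod("nLoci", "ModelParams", function(x) x@L)

#' @rdname accessors
#' @export
setMethod("thetaVec", "ModelParams", function(x) x@theta)

#' @rdname accessors
#' @export
setMethod("stopFraction", "ModelParams", function(x) x@fW)

#' @rdname accessors
#' @export
setMethod("muVec", "ModelParams", function(x) x@theta / (2 * as.numeric(x@ne)))

setMethod("show", "ModelParams", function(object) {
  eq <- length(unique(object@theta)) == 1L
  cat("ModelParams:", object@L, "loci, Ne =", object@ne, "\n")
  if (eq) {
    cat("  theta_l =", object@theta[1],
        " theta_bg =", format(thetaBg(object@theta)), "\n")
  } else {
    cat("  theta =", paste(format(object@theta), collapse = ", "),
        " theta_bg =", format(thetaBg(object@theta)), "\n")
  }
  cat("  sB =", object@sB, " sD =", object@sD, " delta =", object@delta,
      " fW =", object@fW, "\n")
  cat("  start:", object@startMode,
      sprintf("(burn-in %g*Ne generations), seed %d",
              object@burnInFactor, object@seed), "\n")
  invisible(NULL)
})

#' Construct a population state
#'
#' @param p numeric vector of mutant allele frequencies in `[0, 1]`.
#' @param generation non-negative generation counter.
#' @return a [PopulationState-class] object.
#' @examples
#' populationState(c(0.1, 0))
#' @export
populationState <- function(p, generation = 0L) {
  new("PopulationState", p = as.numeric(p), generation = as.integer(generation))
}

#' @rdname accessors
#' @param state a [PopulationState-class] object.
#' @export
alleleFreqs <- function(state) {
  stopifnot(is(state, "PopulationState"))
  state@p
}

setMethod("show", "PopulationState", function(object) {
  cat("PopulationState: generation", object@generation, "\n")
  cat("  p =", paste(format(object@p, digits = 4), collapse = ", "), "\n")
  invisible(NULL)
})

#' Background mutation rate
#'
#' The compound parameter that classifies the adaptive regime: for a focal
#' locus, the summed population-scaled mutation rate of all other
#' (redundant) loci in its background.  For unequal rates the relevant
#' focal locus is the one maximizing its background share, so
#' \deqn{\Theta_{bg} = \min_i \big[\sum_j \Theta_j - \Theta_i\big],}
#' which reduces to \eqn{(L-1)\Theta_l} for equal rates and to
#' \eqn{\Theta_l} for two loci.  A single locus has no background;
#' `thetaBg` returns 0 for `L = 1` by convention.
#'
#' @param theta numeric vector of positive per-locus rates \eqn{\Theta_i}.
#' @return scalar background mutation rate.
#' @examples
#' thetaBg(rep(0.1, 10))   # 0.9
#' thetaBg(c(1, 2, 3))     # 3
#' @seealso [thetaBgRelaxed()] for the relaxed-redundancy analogue,
#'   [classifyRegime()]
#' @export
thetaBg <- function(theta) {
  if (length(theta) == 0L) stop("'theta' must be non-empty")
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all entries of 'theta' must be positive and finite")
  if (length(theta) == 1L) return(0)
  min(sum(theta) - theta)
}

#' Background mutation rate under relaxed redundancy
#'
#' With relaxed redundancy (\eqn{\delta < 1}) at least two mutant loci are
#' needed to reach the full phenotype, so one background locus is
#' *essential* rather than redundant.  The effective background rate
#' counts only the loci that are not essential to accomplish adaptation:
#' \deqn{\Theta_{bg}^{relax} = (L - 2)\,\Theta_l} for equal locus rates,
#' i.e. `thetaBg(theta) - theta_l`.
#'
#' @param theta numeric vector of equal positive per-locus rates, length
#'   >= 2.
#' @param delta single-mutant phenotype value, < 1 (the relaxed model).
#' @return scalar relaxed background mutation rate (0 for `L = 2`).
#' @examples
#' thetaBgRelaxed(rep(0.1, 11), delta = 0.5)   # 0.9
#' @export
thetaBgRelaxed <- function(theta, delta) {
  if (length(theta) < 2L) stop("relaxed redundancy needs L >= 2 loci")
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all entries of 'theta' must be positive and finite")
  if (diff(range(theta)) > 1e-12 * max(theta))
    stop("'thetaBgRelaxed' is defined for equal locus rates")
  if (!missing(delta) && (delta >= 1 || delta < 0.5))
    stop("'delta' must lie in [0.5, 1) for the relaxed-redundancy model")
  (length(theta) - 2) * theta[1]
}

#' Read a flat key/value configuration file
#'
#' Parses a plain-text configuration with one `key = value` pair per line
#' (`#` starts a comment).  Recognized keys: `ne`, `num_loci`, `theta`
#' (scalar for equal rates or comma-separated vector), `s_b`, `s_d`,
#' `delta`, `f_w`, `burn_in_factor`, `seed`, `start_mode`, `replicates`.
#' Values in `overrides` (e.g. parsed CLI flags) take precedence over the
#' file, which takes precedence over the defaults of [modelParams()].
#'
#' @param path path to the config file.
#' @param overrides named list of values overriding the file.
#' @return a list with elements `params` (a validated
#'   [ModelParams-class]) and `replicates` (integer, default 1).
#' @export
readParamsConfig <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed config line: '", ln, "'")
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  known <- c("ne", "num_loci", "theta", "s_b", "s_d", "delta", "f_w",
             "burn_in_factor", "seed", "start_mode", "replicates")
  bad <- setdiff(names(kv), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) kv[[nm]] <- overrides[[nm]]

  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  theta <- if (is.null(kv[["theta"]])) 1 else
    as.numeric(strsplit(as.character(kv[["theta"]]), ",")[[1]])
  L <- as.integer(num("num_loci", if (length(theta) > 1L) length(theta) else 2))
  params <- modelParams(
    ne = num("ne", 10000), L = L, theta = theta,
    sB = num("s_b", 0.1), sD = num("s_d", -0.1),
    delta = num("delta", 1), fW = num("f_w", 0.05),
    burnInFactor = num("burn_in_factor", 8),
    seed = as.integer(num("seed", 1)),
    startMode = if (is.null(kv[["start_mode"]])) "equilibrium_burn_in"
                else as.character(kv[["start_mode"]]))
  list(params = params, replicates = as.integer(num("replicates", 1)))
}
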