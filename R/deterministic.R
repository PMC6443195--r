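#' @include AllClasses.R modelParams.R wrightFisher.R yule.R
NULL

#' Right-hand side of the deterministic selection dynamics
#'
#' Once mutant lineages are established, drift and mutation can be
#' ignored and allele frequencies follow the replicator dynamics under
#' linkage equilibrium.  For the completely redundant trait
#' \deqn{\dot p_i = s_b\, p_i\, (Z_1 - \bar Z) = s_b\, p_i \prod_j (1 - p_j),}
#' so the per-capita growth rate is identical across loci and all
#' frequency ratios \eqn{x_i = p_i / p_1} are invariants of the flow.
#' For relaxed redundancy (\eqn{\delta < 1}) the generalization is the
#' per-locus marginal-fitness form
#' \eqn{\dot p_i = p_i (1 - p_i)(m_{mut,i} - m_{anc,i})} with the
#' Malthusian marginal fitnesses of [marginalFitnesses()]; ratio
#' invariance is *not* claimed there.
#'
#' @param p numeric vector of frequencies in `(0, 1)^L` (boundaries
#'   allowed, they are fixed points).
#' @param sB beneficial Malthusian selection coefficient.
#' @param delta single-mutant phenotype value.
#' @return numeric vector of time derivatives.
#' @examples
#' odeRhs(c(0.3), sB = 0.1)             # logistic: 0.1 * 0.3 * 0.7
#' odeRhs(c(0.1, 0.2, 0.4), sB = 0.1)   # common factor s_b * P0
#' @export
odeRhs <- function(p, sB, delta = 1) {
  stopifnot(all(p >= 0), all(p <= 1), sB > 0)
  if (delta == 1) return(sB * p * prod(1 - p))
  w <- marginalFitnesses(p, delta, sB)
  p * (1 - p) * (w$wMut - w$wAnc)
}

#' Integrate the deterministic phase
#'
#' Numerically integrates the selection dynamics of [odeRhs()] with
#' `deSolve::lsodar`, optionally stopping by root detection exactly when
#' the stopping metric \eqn{1 - \bar Z} reaches `fW`.
#'
#' @param p0 starting frequency vector (strictly positive at loci intended
#'   to segregate).
#' @param sB beneficial selection coefficient.
#' @param delta single-mutant phenotype value.
#' @param fW stop when the metric reaches this value (`NULL`: integrate to
#'   `tEnd` only).
#' @param tEnd final time when `fW` is `NULL`; when stopping at `fW` it
#'   serves as a cap (default `500 / sB`).
#' @param nOut number of output time points.
#' @param rtol,atol integration tolerances.
#' @return a list of class `"detTrajectory"` with elements `time` (numeric
#'   vector), `p` (matrix, rows = times, columns = loci), `stopped`
#'   (logical: did the metric root fire), `tStop` (time of stopping or
#'   `NA`).
#' @examples
#' tr <- integrateDeterministic(c(0.01, 0.002, 0.005), sB = 0.1, fW = 0.05)
#' tr$p[nrow(tr$p), ] / tr$p[nrow(tr$p), 1]   # ratios preserved
#' @export
integrateDeterministic <- function(p0, sB, delta = 1, fW = NULL,
                                   tEnd = NULL, nOut = 400,
                                   rtol = 1e-12, atol = 1e-14) {
  stopifnot(all(p0 >= 0), all(p0 <= 1), sB > 0)
  if (is.null(tEnd)) {
    if (is.null(fW)) stop("one of 'fW' or 'tEnd' is required")
    tEnd <- 500 / sB
  }
  rhs <- function(t, y, parms) list(odeRhs(y, sB, delta))
  times <- seq(0, tEnd, length.out = nOut)
  if (!is.null(fW)) {
    root <- function(t, y, parms) stoppingMetric(y, delta) - fW
    out <- deSolve::lsodar(p0, times, rhs, parms = NULL, rootfunc = root,
                           rtol = rtol, atol = atol)
  } else {
    out <- deSolve::lsodar(p0, times, rhs, parms = NULL,
                           rtol = rtol, atol = atol)
  }
  tvec <- out[, 1]
  pm <- out[, -1, drop = FALSE]
  colnames(pm) <- paste0("locus", seq_along(p0))
  stopped <- !is.null(fW) &&
    abs(stoppingMetric(pm[nrow(pm), ], delta) - fW) < 1e-6
  if (!is.null(fW) && !stopped)
    stop("integration reached tEnd = ", tEnd,
         " without meeting the stopping condition")
  structure(list(time = tvec, p = pm, stopped = stopped,
                 tStop = if (stopped) tvec[length(tvec)] else NA_real_),
            class = "detTrajectory")
}

#' Project establishment-phase ratios onto the stopping manifold
#'
#' Under complete redundancy the deterministic phase preserves all
#' frequency ratios, so a stopped architecture is fully determined by the
#' ratio vector from the stochastic phase and the stopping condition
#' \eqn{\prod_i (1 - p_i) = f_w}.  Writing \eqn{p_i = c\,x_i} (with the
#' reference entry \eqn{x_1 = 1}), the product is strictly decreasing in
#' `c`, so the unique scale \eqn{c \in (0, 1/\max_i x_i)} is found by
#' bisection (vectorized over rows when `x` is a matrix), to a manifold
#' residual below 1e-12.  Ratios equal to 0 (loci that never established a
#' lineage) are carried through as exact zeros.
#'
#' @param x numeric vector of ratios including the reference entry (e.g.
#'   `c(1, x2, ..., xL)`), or a matrix with one such vector per row.
#' @param fW stopping fraction in (0, 1).
#' @return frequency vector (or matrix) on the stopping manifold.
#' @examples
#' projectToStop(c(1, 1), fW = 0.05)   # both 1 - sqrt(0.05)
#' projectToStop(c(1, 0), fW = 0.05)   # c(0.95, 0)
#' @export
projectToStop <- function(x, fW) {
  if (fW <= 0 || fW >= 1) stop("'fW' must lie strictly in (0, 1)")
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (any(xm < 0)) stop("ratios must be non-negative")
  mx <- apply(xm, 1, max)
  if (any(mx == 0)) stop("each ratio vector needs a positive entry")
  lo <- numeric(nrow(xm))
  hi <- (1 - 1e-16) / mx
  logfW <- log(fW)
  g <- function(cc) {
    z <- log1p(-cc * xm)   # log(1 - c x); x = 0 contributes 0
    rowSums(z) - logfW
  }
  for (it in seq_len(80L)) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  cc <- (lo + hi) / 2
  p <- xm * cc
  if (is.matrix(x)) p else drop(p)
}

#' Exact sampler of the joint stopped-frequency distribution
#'
#' Composes the inverted-Dirichlet ratio sampler ([sampleRatioLimit()])
#' with the projection onto the stopping manifold ([projectToStop()]).
#' Because the deterministic phase preserves ratios, this two-phase
#' construction draws exactly from the joint distribution of stopped
#' mutant frequencies of the completely redundant trait — with no
#' dependence on the selection strength, which never enters.
#'
#' @param theta positive numeric vector of locus rates \eqn{\Theta_i}
#'   (length >= 1; a single locus puts all mass at `1 - fW`).
#' @param fW stopping fraction in (0, 1).
#' @param replicates number of draws.
#' @param seed optional RNG seed recorded in the ensemble.
#' @return an [ArchitectureEnsemble-class] with
#'   `source = "two_phase_analytic"`; `generations` are `NA` (the sampler
#'   is time-free).
#' @examples
#' ens <- sampleArchitectureAnalytic(c(1, 1), fW = 0.05,
#'                                   replicates = 500, seed = 1)
#' ratioSummary(ens)
#' @export
sampleArchitectureAnalytic <- function(theta, fW, replicates, seed = 1L) {
  stopifnot(all(theta > 0), replicates >= 1)
  L <- length(theta)
  set.seed(seed)
  if (L == 1L) {
    locusF <- matrix(1 - fW, replicates, 1L)
  } else {
    xs <- sampleRatioLimit(theta, replicates)
    locusF <- projectToStop(cbind(1, xs), fW)
  }
  freqs <- matrix(NA_real_, replicates, L)
  for (r in seq_len(replicates))
    freqs[r, ] <- locusF[r, order(-locusF[r, ])]
  colnames(freqs) <- c("major", if (L > 1) paste0("minor", seq_len(L - 1)))
  colnames(locusF) <- paste0("locus", seq_len(L))
  params <- modelParams(ne = 10000, L = L, theta = theta, fW = fW,
                        seed = seed)
  new("ArchitectureEnsemble",
      freqs = freqs, locusFreqs = locusF,
      generations = rep(NA_real_, replicates),
      metricAtStop = rep(fW, replicates),
      discards = integer(replicates), params = params,
      source = "two_phase_analytic", seed = as.integer(seed))
}
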