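#' @include AllClasses.R modelParams.R
NULL

#' Transition probabilities of the establishment jump chain
#'
#' During the stochastic phase, new mutant lineages destined for
#' establishment arise at locus i at rate \eqn{\Theta_i s_b} and existing
#' established lineages split at rate \eqn{s_b} (a Yule pure-birth
#' process).  Given current lineage counts \eqn{k_1, \dots, k_L}, the
#' probability that the next event (mutation or split) occurs at locus i
#' is \deqn{\frac{k_i + \Theta_i}{\sum_j (k_j + \Theta_j)},}
#' in which the selection coefficient cancels: the embedded jump chain is
#' independent of the mutant fitness \eqn{s_b}.
#'
#' @param k non-negative integer vector of established-lineage counts.
#' @param theta positive numeric vector of locus rates \eqn{\Theta_i}.
#' @param i optional locus index; when omitted the full probability vector
#'   is returned.
#' @return probability (or vector of probabilities summing to 1).
#' @examples
#' eventProbability(c(1, 0), c(1, 1))       # c(2/3, 1/3)
#' eventProbability(c(1, 0), c(1, 1), i = 1)
#' @export
eventProbability <- function(k, theta, i = NULL) {
  stopifnot(length(k) == length(theta), all(k >= 0), all(theta > 0))
  w <- k + theta
  pr <- w / sum(w)
  if (is.null(i)) return(pr)
  if (i < 1 || i > length(k)) stop("locus index out of range")
  pr[i]
}

#' Sample the stochastic establishment phase (Yule jump chain)
#'
#' Iterates the embedded jump chain of the multi-locus Yule process —
#' each event adds one established lineage at a locus chosen with
#' probability \eqn{(k_i + \Theta_i) / \sum_j (k_j + \Theta_j)} — until
#' the total lineage count reaches `kTarget`.  All replicates are advanced
#' in lockstep (one event index per iteration), which is the identical
#' chain, merely vectorized.  As `kTarget` grows, the distribution of the
#' count ratios approaches the inverted-Dirichlet limit sampled exactly by
#' [sampleRatioLimit()].
#'
#' @param theta positive numeric vector of locus rates \eqn{\Theta_i}.
#' @param kTarget total-lineage stopping threshold (>= 1).
#' @param replicates number of independent chains.
#' @param seed optional RNG seed.
#' @return integer matrix `replicates x L` of final lineage counts (each
#'   row sums to `kTarget`).
#' @examples
#' k <- sampleStochasticPhase(c(1, 1), kTarget = 100, replicates = 5,
#'                            seed = 1)
#' rowSums(k)   # all 100
#' @export
sampleStochasticPhase <- function(theta, kTarget, replicates = 1L,
                                  seed = NULL) {
  stopifnot(all(theta > 0))
  if (kTarget < 1) stop("'kTarget' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- length(theta)
  n <- as.integer(replicates)
  K <- matrix(0L, n, L)
  thetaTot <- sum(theta)
  for (ev in seq_len(kTarget)) {
    u <- stats::runif(n) * (ev - 1 + thetaTot)
    idx <- integer(n)
    acc <- numeric(n)
    for (j in seq_len(L)) {
      acc <- acc + K[, j] + theta[j]
      hit <- idx == 0L & u <= acc
      idx[hit] <- j
    }
    idx[idx == 0L] <- L  # guard against floating-point spill
    K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + 1L
  }
  colnames(K) <- paste0("locus", seq_len(L))
  K
}

#' Exact draws from the inverted-Dirichlet ratio limit
#'
#' The limit law of the between-locus lineage-count ratios
#' \eqn{x_i = k_i / k_1} of the Yule jump chain is the inverted Dirichlet
#' distribution \deqn{P[x \mid \Theta] = \frac{1}{B[\Theta]}
#' \prod_{j=2}^{L} x_j^{\Theta_j - 1}
#' \Big(1 + \sum_{i=2}^{L} x_i\Big)^{-\sum_i \Theta_i}.}
#' It is sampled exactly via independent Gamma variables:
#' \eqn{G_j \sim \Gamma(\Theta_j, 1)} and \eqn{x_j = G_j / G_1}, with
#' locus 1 as the reference.
#'
#' @inheritParams sampleStochasticPhase
#' @return numeric matrix `replicates x (L - 1)` of ratios
#'   \eqn{(x_2, \dots, x_L)} relative to locus 1.
#' @examples
#' x <- sampleRatioLimit(c(1, 1), replicates = 1000, seed = 1)
#' mean(x <= 1)   # ~1/2 by exchangeability
#' @export
sampleRatioLimit <- function(theta, replicates = 1L, seed = NULL) {
  stopifnot(all(theta > 0), length(theta) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(replicates)
  L <- length(theta)
  G <- vapply(theta, function(a) stats::rgamma(n, shape = a),
              numeric(n))
  if (n == 1L) G <- matrix(G, nrow = 1L)
  x <- G[, -1L, drop = FALSE] / G[, 1L]
  colnames(x) <- paste0("x", 2:L)
  x
}

#' Expected minor/major allele-frequency ratio
#'
#' The expectation of the minor-over-major frequency ratio in the
#' symmetric two-locus reduction, computed by numerical integration of
#' \eqn{x \, P_{\beta'}[x \mid \Theta_l]} over `[0, 1]` (see
#' [betaprimeConditionalPdf()]).  A trait with L equal loci is mapped to
#' this two-locus form through the background mutation rate:
#' `theta_bg = (L - 1) * theta_l` plays the role of the single competing
#' locus rate.  Small `thetaBg` gives sweep-like, heterogeneous adaptation
#' (E[x] near 0); large `thetaBg` gives homogeneous shifts (E[x] near 1).
#'
#' @param thetaBg positive background mutation rate.
#' @return scalar expected ratio in (0, 1).
#' @examples
#' expectedMinorMajorRatio(1)   # 2*log(2) - 1 = 0.3863
#' @export
expectedMinorMajorRatio <- function(thetaBg) {
  if (!is.finite(thetaBg) || thetaBg <= 0)
    stop("'thetaBg' must be positive")
  stats::integrate(function(x) x * betaprimeConditionalPdf(x, thetaBg),
                   0, 1, rel.tol = 1e-10)$value
}
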