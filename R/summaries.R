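#' @include AllClasses.R AllGenerics.R modelParams.R wrightFisher.R
NULL

#' @rdname accessors
#' @export
setMethod("rankedFreqs", "ArchitectureEnsemble", function(x) x@freqs)

#' @rdname accessors
#' @export
setMethod("locusFreqs", "ArchitectureEnsemble", function(x) x@locusFreqs)

#' @rdname accessors
#' @export
setMethod("nReplicates", "ArchitectureEnsemble", function(x) nrow(x@freqs))

#' @rdname accessors
#' @export
setMethod("sourceTag", "ArchitectureEnsemble", function(x) x@source)

#' @rdname accessors
#' @export
setMethod("generationsElapsed", "ArchitectureEnsemble",
          function(x) x@generations)

#' @rdname accessors
#' @export
setMethod("metricAtStop", "ArchitectureEnsemble", function(x) x@metricAtStop)

#' @rdname accessors
#' @export
setMethod("modelParamsOf", "ArchitectureEnsemble", function(x) x@params)

setMethod("show", "ArchitectureEnsemble", function(object) {
  L <- ncol(object@freqs)
  cat("ArchitectureEnsemble:", nrow(object@freqs), "replicates,",
      L, "loci, source:", object@source, "\n")
  cat("  theta_bg =", format(thetaBg(object@params@theta)),
      " fW =", object@params@fW, " seed =", object@seed, "\n")
  mj <- object@freqs[, 1]
  cat("  major-locus frequency: mean", format(mean(mj), digits = 4),
      " range [", format(min(mj), digits = 4), ",",
      format(max(mj), digits = 4), "]\n")
  if (L >= 2L && nrow(object@freqs) >= 2L) {
    rs <- ratioSummary(object)
    cat("  minor/major ratio: mean", format(rs$mean, digits = 4),
        "(se", format(rs$se, digits = 3), ")\n")
  }
  invisible(NULL)
})

#' Rank loci by stopped allele frequency
#'
#' Returns the permutation sorting loci by descending frequency: the first
#' element is the major locus, the rest are the first, second, ... minor
#' loci.  Ties are broken by lowest locus index (relevant only at boundary
#' cases; interior frequencies are ties with probability zero).
#'
#' @param p numeric frequency vector.
#' @return integer permutation of `seq_along(p)`.
#' @examples
#' orderLoci(c(0.2, 0.9, 0.1))   # 2 1 3
#' @export
orderLoci <- function(p) {
  stopifnot(all(is.finite(p)))
  order(-p)
}

#' Mean and standard error of the minor/major frequency ratio
#'
#' For each replicate the ratio of the first-minor over the major stopped
#' frequency is computed (0 when the major frequency is positive but the
#' first minor is 0); replicates with a zero major frequency are dropped
#' with a warning (a degenerate stopped state the model does not
#' produce).  The standard error is the sample standard deviation divided
#' by the square root of the number of retained replicates.
#'
#' @param ens an [ArchitectureEnsemble-class] with at least two loci.
#' @return list with elements `mean`, `se`, `n`; `se` is `NA` (with a
#'   warning) for a single replicate.
#' @export
ratioSummary <- function(ens) {
  stopifnot(is(ens, "ArchitectureEnsemble"))
  f <- ens@freqs
  if (ncol(f) < 2L)
    stop("ratio summary requires at least two loci")
  major <- f[, 1]
  keep <- major > 0
  if (!all(keep)) {
    warning(sum(!keep), " replicate(s) with zero major frequency dropped")
    f <- f[keep, , drop = FALSE]
    major <- major[keep]
  }
  n <- nrow(f)
  if (n < 1L) stop("no replicates with positive major frequency")
  x <- f[, 2] / major
  if (n == 1L) {
    warning("standard error undefined for a single replicate")
    return(list(mean = mean(x), se = NA_real_, n = 1L))
  }
  list(mean = mean(x), se = stats::sd(x) / sqrt(n), n = n)
}

#' Per-rank histograms of stopped frequencies
#'
#' Normalized marginal histograms of the rank-ordered stopped frequencies
#' (major locus, first minor, ...), each rank normalized to unit mass
#' (density summed over bins times bin width equals 1 per locus).  Bins
#' span `[0, 1 - fW]`, the attainable range under complete redundancy
#' (extended to the observed maximum if frequencies exceed it, as can
#' happen with relaxed redundancy).
#'
#' @param ens an [ArchitectureEnsemble-class].
#' @param bins number of bins (>= 2).
#' @return a data.frame with columns `rank` (1 = major), `mid` (bin
#'   midpoint), `density`.
#' @export
rankHistograms <- function(ens, bins = 20L) {
  stopifnot(is(ens, "ArchitectureEnsemble"), bins >= 2L)
  f <- ens@freqs
  upper <- max(1 - ens@params@fW, max(f))
  breaks <- seq(0, upper, length.out = bins + 1L)
  width <- diff(breaks)[1]
  out <- lapply(seq_len(ncol(f)), function(r) {
    h <- graphics::hist(f[, r], breaks = breaks, plot = FALSE)
    data.frame(rank = r, mid = h$mids, density = h$density)
  })
  do.call(rbind, out)
}

#' Compare two ensembles rank by rank
#'
#' Two-sample Kolmogorov-Smirnov tests of the per-rank stopped-frequency
#' distributions of two ensembles (e.g. Wright-Fisher simulation against
#' the analytic two-phase sampler, or two selection strengths against
#' each other).  Ensembles must have matching locus counts and stopping
#' fractions.
#'
#' @param a,b [ArchitectureEnsemble-class] objects.
#' @param alpha significance level for the overall pass/fail verdict.
#' @return list with elements `table` (data.frame: `rank`, `statistic`,
#'   `p.value`) and `pass` (logical: no rank rejected at `alpha`).
#' @export
compareEnsembles <- function(a, b, alpha = 0.01) {
  stopifnot(is(a, "ArchitectureEnsemble"), is(b, "ArchitectureEnsemble"))
  if (ncol(a@freqs) != ncol(b@freqs))
    stop("ensembles have different numbers of loci")
  if (abs(a@params@fW - b@params@fW) > 1e-12)
    stop("ensembles have different stopping fractions")
  tab <- do.call(rbind, lapply(seq_len(ncol(a@freqs)), function(r) {
    kt <- suppressWarnings(stats::ks.test(a@freqs[, r], b@freqs[, r]))
    data.frame(rank = r, statistic = unname(kt$statistic),
               p.value = kt$p.value)
  }))
  list(table = tab, pass = all(tab$p.value > alpha))
}

#' Parameter grids for reproducing the study conditions
#'
#' `"paper_grid"` enumerates the full factorial of the published study
#' conditions: \eqn{N_e = 10^4}, \eqn{s_b \in \{0.1, 0.01\}},
#' \eqn{s_d \in \{-0.1, -0.001\}}, \eqn{L \in \{2, 10, 50, 100\}},
#' \eqn{\Theta_{bg} \in \{0.01, 0.1, 1, 10, 100\}} (equal locus rates
#' \eqn{\Theta_l = \Theta_{bg}/(L-1)}), \eqn{f_w = 0.05}, complete
#' redundancy, 10 000 replicates — excluding the combinations
#' \eqn{\Theta_{bg} \ge 10} with \eqn{s_d = -0.001}, where recurrent
#' mutation overwhelms weak deleterious selection and most burn-ins are
#' discarded.  `"desk_grid"` is the same design scaled to
#' \eqn{N_e = 10^3} and 2000 replicates for fast desk validation.
#'
#' @param preset `"paper_grid"` or `"desk_grid"`.
#' @return a list of validated [ModelParams-class] objects with attribute
#'   `"replicates"`.
#' @export
generateFixtureGrid <- function(preset = c("paper_grid", "desk_grid")) {
  preset <- match.arg(preset)
  ne <- if (preset == "paper_grid") 10000L else 1000L
  reps <- if (preset == "paper_grid") 10000L else 2000L
  design <- expand.grid(sB = c(0.1, 0.01), sD = c(-0.1, -0.001),
                        L = c(2L, 10L, 50L, 100L),
                        thetaBg = 10^(-2:2))
  design <- design[!(design$thetaBg >= 10 & design$sD == -0.001), ]
  grid <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    modelParams(ne = ne, L = d$L, theta = d$thetaBg / (d$L - 1),
                sB = d$sB, sD = d$sD, fW = 0.05, seed = i)
  })
  attr(grid, "replicates") <- reps
  grid
}
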