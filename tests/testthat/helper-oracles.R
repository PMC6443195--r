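# Brute-force oracles over the full genotype-class table (2^L classes under
# linkage equilibrium).  Independent of the package's exclusion-based
# implementation; used to freeze expected values.

bruteMoments <- function(p, delta) {
  L <- length(p)
  gen <- as.matrix(expand.grid(rep(list(0:1), L)))
  prob <- apply(gen, 1, function(g) prod(ifelse(g == 1, p, 1 - p)))
  nmut <- rowSums(gen)
  Z <- ifelse(nmut == 0, 0, ifelse(nmut == 1, delta, 1))
  list(P0 = sum(prob[nmut == 0]), P1 = sum(prob[nmut == 1]),
       meanZ = sum(prob * Z))
}

# Conditional mean trait given the allele at locus i, by enumerating the
# background genotypes of the other loci.
bruteConditionalZ <- function(p, delta, i, allele) {
  L <- length(p)
  if (L == 1L) {
    nm <- if (allele == 1) 1 else 0
    return(if (nm == 0) 0 else if (nm == 1) delta else 1)
  }
  bg <- as.matrix(expand.grid(rep(list(0:1), L - 1)))
  pb <- p[-i]
  prob <- apply(bg, 1, function(g) prod(ifelse(g == 1, pb, 1 - pb)))
  nmut <- rowSums(bg) + (allele == 1)
  Z <- ifelse(nmut == 0, 0, ifelse(nmut == 1, delta, 1))
  sum(prob * Z)
}

# Minimal ensemble construction around a given rank-ordered matrix.
makeEnsemble <- function(freqs, fW = 0.05, source = "two_phase_analytic") {
  n <- nrow(freqs)
  L <- ncol(freqs)
  locusF <- freqs
  colnames(freqs) <- c("major", if (L > 1) paste0("minor", seq_len(L - 1)))
  colnames(locusF) <- paste0("locus", seq_len(L))
  new("ArchitectureEnsemble",
      freqs = freqs, locusFreqs = locusF,
      generations = rep(NA_real_, n), metricAtStop = rep(fW, n),
      discards = integer(n),
      params = modelParams(L = L, theta = 1, fW = fW),
      source = source, seed = 1L)
}

# Observe an ensemble of stopped states on the common comparison surface:
# ratio-preserving projection onto the exact stopping manifold (removes
# the discrete-time overshoot of the once-per-generation stopping check),
# then rounding to the 1/Ne frequency grid shared with the reference.
matchedObservation <- function(locusF, fW, ne) {
  proj <- projectToStop(locusF / apply(locusF, 1, max), fW)
  g <- round(proj * ne) / ne
  t(apply(g, 1, sort, decreasing = TRUE))
}
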