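test_that("phenotype moments match full genotype-class enumeration", {
  # frozen examples
  pm <- phenotypeMoments(c(0.95, 0), delta = 1)
  expect_equal(pm$P0, 0.05)
  expect_equal(pm$meanZ, 0.95)
  pm <- phenotypeMoments(rep(0, 5), delta = 0.7)
  expect_equal(pm, list(P0 = 1, P1 = 0, meanZ = 0))
  pm <- phenotypeMoments(c(0.5, 0.5), delta = 0.5)
  expect_equal(pm, list(P0 = 0.25, P1 = 0.5, meanZ = 0.5))

  # property: agreement with the 2^L enumeration oracle, including exact
  # boundary frequencies 0 and 1
  set.seed(21)
  for (i in 1:40) {
    L <- sample(1:4, 1)
    p <- runif(L)
    p[runif(L) < 0.2] <- 1
    p[runif(L) < 0.2] <- 0
    delta <- sample(c(1, 0.5, 0.75), 1)
    got <- phenotypeMoments(p, delta)
    want <- bruteMoments(p, delta)
    expect_equal(got$P0, want$P0, tolerance = 1e-12)
    expect_equal(got$P1, want$P1, tolerance = 1e-12)
    expect_equal(got$meanZ, want$meanZ, tolerance = 1e-12)
  }
})

test_that("stopping metric is the residual fraction of the fitness gap", {
  expect_equal(stoppingMetric(c(0.95, 0), delta = 1), 0.05)
  expect_equal(stoppingMetric(rep(0, 4), delta = 1), 1)
  expect_equal(stoppingMetric(c(0.5, 0.5), delta = 0.5), 0.5)
  # the selection coefficient cancels; a zero coefficient is rejected
  expect_equal(stoppingMetric(c(0.3, 0.2), delta = 1, s = 0.1),
               stoppingMetric(c(0.3, 0.2), delta = 1, s = 5))
  expect_error(stoppingMetric(c(0.3, 0.2), delta = 1, s = 0), "non-zero")
})

test_that("marginal allele fitnesses match background enumeration", {
  # frozen relaxed-redundancy example
  w <- marginalFitnesses(c(0.5, 0.5), delta = 0.5, s = 0.1)
  expect_equal(w$wMut[1], 1.075)
  expect_equal(w$wAnc[1], 1.025)

  # complete redundancy: no background mutants -> classic single-locus
  # selection; fully redundant background -> no selection at the focal locus
  w <- marginalFitnesses(c(0.3, 0), delta = 1, s = 0.1)
  expect_equal(w$wMut[1], 1.1)
  expect_equal(w$wAnc[1], 1)
  w <- marginalFitnesses(c(0.3, 1), delta = 1, s = 0.1)
  expect_equal(w$wMut[1], 1.1)
  expect_equal(w$wAnc[1], 1.1)

  # property: conditional means agree with enumeration, and recombine to
  # the population mean trait
  set.seed(22)
  for (i in 1:30) {
    L <- sample(2:4, 1)
    p <- runif(L)
    if (runif(1) < 0.3) p[sample(L, 1)] <- 1
    delta <- sample(c(1, 0.5, 0.9), 1)
    s <- 0.1
    w <- marginalFitnesses(p, delta, s)
    zbar <- phenotypeMoments(p, delta)$meanZ
    for (j in seq_len(L)) {
      expect_equal((w$wMut[j] - 1) / s, bruteConditionalZ(p, delta, j, 1),
                   tolerance = 1e-12)
      expect_equal((w$wAnc[j] - 1) / s, bruteConditionalZ(p, delta, j, 0),
                   tolerance = 1e-12)
      ez <- p[j] * (w$wMut[j] - 1) / s + (1 - p[j]) * (w$wAnc[j] - 1) / s
      expect_equal(ez, zbar, tolerance = 1e-12)
    }
  }
})

test_that("within-generation update has the correct absorbing states and
           deterministic selection limit", {
  # deterministic selection part: single-locus logistic map
  for (p in c(0.01, 0.3, 0.9)) {
    s <- 0.1
    expect_equal(polysweep:::.wfUpdateDet(p, mu = 0, delta = 1, s = s),
                 p * (1 + s) / (1 + s * p), tolerance = 1e-14)
  }
  # absorbing states through the full stochastic step
  par <- modelParams(ne = 100, L = 2, theta = 1e-9)
  st <- populationState(c(0, 1))
  set.seed(1)
  for (i in 1:20) st <- wfStep(st, par, s = 0.1)
  expect_equal(alleleFreqs(st)[2], 1)   # no back mutation
  parNoMu <- modelParams(ne = 100, L = 1, theta = 1e-12)
  expect_lt(muVec(parNoMu), 1e-14)
  # frequencies stay in [0, 1] along a trajectory
  st <- populationState(c(0.5, 0.5))
  set.seed(2)
  for (i in 1:50) {
    st <- wfStep(st, par, s = -0.1)
    expect_true(all(alleleFreqs(st) >= 0 & alleleFreqs(st) <= 1))
  }
})

test_that("burn-in start modes and conditioning behave as specified", {
  par <- modelParams(ne = 200, L = 3, theta = 0.4, sD = -0.1,
                     startMode = "monomorphic")
  expect_equal(alleleFreqs(burnIn(par)), c(0, 0, 0))

  par <- modelParams(ne = 200, L = 3, theta = 0.4, sD = -0.1,
                     startMode = "deterministic_msb")
  expect_equal(alleleFreqs(burnIn(par)), muVec(par) / 0.1)

  # vanishing mutational input: equilibrium state is (near) monomorphic
  par <- modelParams(ne = 200, L = 2, theta = 1e-6, sD = -0.1,
                     burnInFactor = 2)
  set.seed(3)
  expect_lt(max(alleleFreqs(burnIn(par))), 0.05)

  # discard-rate guard: strong mutation with negligible deleterious
  # selection drives every burn-in to fixation
  par <- modelParams(ne = 50, L = 1, theta = 60, sD = -1e-9,
                     burnInFactor = 2)
  set.seed(4)
  expect_error(burnIn(par), "discard rate")
})

test_that("burn-in equilibrium matches deterministic mutation-selection
           balance in the mean", {
  # ensemble of locus-level equilibrium frequencies vs mu/|s_d|
  par <- modelParams(ne = 1000, L = 10, theta = 0.01, sB = 0.1, sD = -0.1,
                     seed = 9)
  set.seed(9)
  vals <- replicate(150, alleleFreqs(burnIn(par)))  # 1500 locus samples
  mu <- muVec(par)[1]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - mu / 0.1), 4 * se)
})

test_that("adaptive phase stops at the prescribed residual fraction", {
  # single locus, complete redundancy: stopping requires p >= 1 - fW
  par <- modelParams(ne = 300, L = 1, theta = 0.5, sB = 0.1, sD = -0.1,
                     fW = 0.05, startMode = "monomorphic")
  set.seed(5)
  res <- runAdaptivePhase(burnIn(par), par, record = TRUE)
  expect_gte(stoppedFreqs(res)[1], 0.95)
  expect_lte(metricAtStop(res), 0.05)
  expect_gt(res@metricPrev, 0.05)
  # recorded trajectory is consistent with the stopping rule
  traj <- res@trajectory
  expect_equal(unname(traj[nrow(traj), ]), stoppedFreqs(res))

  # relaxed redundancy at a single locus cannot reach the optimum
  par <- modelParams(ne = 200, L = 1, theta = 0.5, delta = 0.5,
                     fW = 0.05, startMode = "monomorphic",
                     maxGenFactor = 5)
  set.seed(6)
  expect_error(runAdaptivePhase(burnIn(par), par), "stalled")
})

test_that("ensembles are seed-reproducible and rank-ordered", {
  par <- modelParams(ne = 200, L = 2, theta = 1, sB = 0.1, sD = -0.1,
                     burnInFactor = 2, seed = 17)
  e1 <- simulateEnsemble(par, 10)
  e2 <- simulateEnsemble(par, 10)
  expect_identical(rankedFreqs(e1), rankedFreqs(e2))
  expect_identical(generationsElapsed(e1), generationsElapsed(e2))
  expect_true(all(rankedFreqs(e1)[, 1] >= rankedFreqs(e1)[, 2]))
  expect_true(all(metricAtStop(e1) <= 0.05))
  # single replicate: ratio SE is flagged as undefined
  e3 <- simulateEnsemble(par, 1)
  expect_warning(rs <- ratioSummary(e3), "single replicate")
  expect_true(is.na(rs$se))
})
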