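test_that("selection dynamics have the redundant-trait structure", {
  # fixed point at the ancestral state
  expect_equal(odeRhs(rep(0, 4), sB = 0.1), rep(0, 4))
  # single locus reduces to the logistic equation
  for (p in c(0.01, 0.4, 0.9))
    expect_equal(odeRhs(p, sB = 0.1), 0.1 * p * (1 - p))
  # per-capita growth rate is locus-independent under complete redundancy
  p <- c(0.1, 0.3, 0.6)
  rhs <- odeRhs(p, sB = 0.2)
  expect_equal(rhs / p, rep((rhs / p)[1], 3))
  # relaxed redundancy: marginal-fitness replicator form
  p <- c(0.2, 0.5)
  w <- marginalFitnesses(p, 0.5, 0.1)
  expect_equal(odeRhs(p, 0.1, delta = 0.5),
               p * (1 - p) * (w$wMut - w$wAnc))
})

test_that("integration preserves frequency ratios and matches the
           logistic closed form", {
  p0 <- c(0.01, 0.002, 0.005)
  tr <- integrateDeterministic(p0, sB = 0.1, fW = 0.05)
  expect_true(tr$stopped)
  x0 <- p0 / p0[1]
  dev <- max(abs(sweep(tr$p / tr$p[, 1], 2, x0)))
  expect_lt(dev, 1e-8)
  expect_equal(stoppingMetric(tr$p[nrow(tr$p), ]), 0.05, tolerance = 1e-6)

  # single-locus stopping time equals the logistic formula
  s <- 0.1; p0 <- 0.01; pEnd <- 0.95
  tr <- integrateDeterministic(p0, sB = s, fW = 0.05)
  tForm <- (1 / s) * log(pEnd * (1 - p0) / (p0 * (1 - pEnd)))
  expect_equal(tr$tStop, tForm, tolerance = 1e-6)

  # doubling selection rescales time but not the stopped state
  p0 <- c(0.02, 0.01)
  trA <- integrateDeterministic(p0, sB = 0.05, fW = 0.05)
  trB <- integrateDeterministic(p0, sB = 0.1, fW = 0.05)
  expect_equal(unname(trA$p[nrow(trA$p), ]), unname(trB$p[nrow(trB$p), ]),
               tolerance = 1e-7)
  expect_equal(trA$tStop / trB$tStop, 2, tolerance = 1e-6)
})

test_that("projection lands exactly on the stopping manifold", {
  expect_equal(projectToStop(c(1, 1), 0.05), rep(1 - sqrt(0.05), 2),
               tolerance = 1e-12)
  expect_equal(projectToStop(c(1, 0), 0.05), c(0.95, 0),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:25) {
    L <- sample(2:6, 1)
    x <- c(1, rexp(L - 1))
    x[runif(L) < 0.15] <- 0
    if (all(x == 0)) x[1] <- 1
    fW <- runif(1, 0.01, 0.5)
    p <- projectToStop(x, fW)
    expect_lt(abs(prod(1 - p) - fW), 1e-10)
    expect_equal(p[x == 0], rep(0, sum(x == 0)))
    # ratios preserved by construction
    ref <- which(x > 0)[1]
    expect_equal(p / p[ref], x / x[ref], tolerance = 1e-12)
  }
  # monotonicity: later observation (smaller fW) means higher frequencies
  x <- c(1, 0.4, 0.2)
  pA <- projectToStop(x, 0.2)
  pB <- projectToStop(x, 0.05)
  expect_true(all(pB > pA))
  expect_error(projectToStop(c(0, 0), 0.05), "positive entry")
  expect_error(projectToStop(c(1, 1), 1.2), "fW")
})

test_that("two-phase analytic sampler sits on the manifold and shows the
           boundary pile-up of low background rates", {
  ens <- sampleArchitectureAnalytic(c(1, 1), fW = 0.05, replicates = 400,
                                    seed = 42)
  f <- locusFreqs(ens)
  expect_lt(max(abs(apply(1 - f, 1, prod) - 0.05)), 1e-10)
  expect_true(all(rankedFreqs(ens)[, 1] >= rankedFreqs(ens)[, 2]))
  expect_identical(sourceTag(ens), "two_phase_analytic")
  expect_true(all(is.na(generationsElapsed(ens))))

  # single locus: all mass at 1 - fW
  e1 <- sampleArchitectureAnalytic(2, fW = 0.05, replicates = 10, seed = 1)
  expect_equal(unname(rankedFreqs(e1)[, 1]), rep(0.95, 10))

  # major-locus mass in the top band near 1 - fW grows as theta_bg drops
  top <- vapply(c(0.3, 1, 3), function(th) {
    e <- sampleArchitectureAnalytic(c(th, th), 0.05, 2000, seed = 7)
    mean(rankedFreqs(e)[, 1] > 0.90)
  }, 0)
  expect_true(all(diff(top) < 0))

  # reproducibility under a fixed seed
  e2 <- sampleArchitectureAnalytic(c(1, 1), 0.05, 400, seed = 42)
  expect_identical(rankedFreqs(ens), rankedFreqs(e2))
})
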