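test_that("generalized Beta function evaluates through log-Gamma", {
  expect_equal(logMultivariateBeta(c(1, 1)), 0)
  expect_equal(logMultivariateBeta(7), 0)        # single entry
  expect_equal(logMultivariateBeta(c(0.5, 0.5)), log(pi))
  expect_error(logMultivariateBeta(c(1, 0)), "positive")
})

test_that("inverted Dirichlet density: values, normalization, symmetry", {
  expect_equal(invertedDirichletPdf(1, c(1, 1)), 0.25)
  expect_error(invertedDirichletPdf(c(1, 1), c(1, 1)), "length")
  expect_error(invertedDirichletPdf(-0.1, c(1, 1)), "non-negative")

  # normalization, L = 2, several rate pairs (quadrature on [0, Inf))
  for (th in list(c(1, 1), c(0.5, 2), c(0.2, 0.2))) {
    total <- integrate(function(x)
      vapply(x, invertedDirichletPdf, 0, theta = th),
      0, Inf, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }

  # normalization, L = 3, via compactifying substitution x = u/(1-u)
  # (rates >= 1 keep the transformed integrand bounded; rates < 1 are
  # singularity-checked in the L = 2 quadrature above)
  skip_if_not_installed("pracma")
  th <- c(1.5, 1, 2)
  f <- function(u, v) {
    x <- u / (1 - u); y <- v / (1 - v)
    jac <- 1 / ((1 - u)^2 * (1 - v)^2)
    vapply(seq_along(x), function(i)
      invertedDirichletPdf(c(x[i], y[i]), th) * jac[i], 0)
  }
  total <- pracma::integral2(f, 0, 1 - 1e-9, 0, 1 - 1e-9,
                             reltol = 1e-8)$Q
  expect_equal(total, 1, tolerance = 1e-3)

  # exchangeability of non-reference loci
  expect_equal(invertedDirichletPdf(c(0.4, 1.7), c(1, 0.5, 2)),
               invertedDirichletPdf(c(1.7, 0.4), c(1, 2, 0.5)))

  # boundary singularity flagged explicitly
  expect_identical(invertedDirichletPdf(0, c(1, 0.5)), Inf)
  expect_equal(invertedDirichletPdf(0, c(1, 2)), 0)
})

test_that("conditioned beta-prime ratio density is normalized and singular
           below theta = 1", {
  expect_equal(betaprimeConditionalPdf(1, 1), 0.5)
  for (th in c(0.1, 1, 10)) {
    total <- integrate(function(x) betaprimeConditionalPdf(x, th), 0, 1,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # divergence toward x = 0 for theta < 1, decay for theta > 1
  expect_gt(betaprimeConditionalPdf(1e-8, 0.5),
            betaprimeConditionalPdf(1e-4, 0.5))
  expect_lt(betaprimeConditionalPdf(1e-8, 2),
            betaprimeConditionalPdf(1e-4, 2))
  expect_error(betaprimeConditionalPdf(1.5, 1), "\\[0, 1\\]")
  # CDF consistency with the density
  for (x in c(0.2, 0.7)) {
    num <- integrate(function(t) betaprimeConditionalPdf(t, 0.7), 0, x,
                     rel.tol = 1e-9)$value
    expect_equal(betaprimeConditionalCdf(x, 0.7), num, tolerance = 1e-6)
  }
})

test_that("two-locus fixed-locus marginal normalizes and carries the
           printed singularity structure", {
  for (th in list(c(1, 1), c(0.5, 2), c(2, 0.4), c(0.3, 0.4))) {
    total <- integrate(function(p) marginal2Pdf(p, th[1], th[2], 0.05),
                       0, 0.95, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-5)
  }
  # another stopping fraction
  total <- integrate(function(p) marginal2Pdf(p, 1.5, 0.8, 0.2),
                     0, 0.8, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-5)

  # singularity at p1 = 0 iff theta_1 < 1
  expect_gt(marginal2Pdf(1e-10, 0.5, 1, 0.05),
            marginal2Pdf(1e-5, 0.5, 1, 0.05))
  expect_lt(marginal2Pdf(1e-10, 2, 1, 0.05), 1e-3)
  # singularity at p1 = 1 - fW iff theta_2 (the background rate) < 1
  expect_gt(marginal2Pdf(0.95 - 1e-10, 1, 0.5, 0.05),
            marginal2Pdf(0.95 - 1e-5, 1, 0.5, 0.05))
  expect_lt(marginal2Pdf(0.95 - 1e-10, 1, 2, 0.05), 1e-3)
  expect_error(marginal2Pdf(0.96, 1, 1, 0.05), "1 - fW")
})

test_that("stopped joint density matches the eliminated-coordinate
           marginal and is exchangeable", {
  fW <- 0.05
  for (p1 in c(0.1, 0.4, 0.7, 0.93)) {
    p2 <- 1 - fW / (1 - p1)
    expect_equal(stoppedJointPdf(c(p1, p2), c(1.3, 0.6), fW),
                 marginal2Pdf(p1, 1.3, 0.6, fW), tolerance = 1e-12)
  }
  # symmetric rates: invariant under locus exchange at the symmetric point
  ps <- 1 - sqrt(fW)
  expect_equal(stoppedJointPdf(c(ps, ps), c(0.7, 0.7), fW, eliminate = 1),
               stoppedJointPdf(c(ps, ps), c(0.7, 0.7), fW, eliminate = 2))
  # permutation of loci together with rates
  p1 <- 0.3; p2 <- 1 - fW / (1 - p1)
  expect_equal(stoppedJointPdf(c(p1, p2), c(0.5, 2), fW, eliminate = 1),
               stoppedJointPdf(c(p2, p1), c(2, 0.5), fW, eliminate = 2))
  expect_error(stoppedJointPdf(c(0.5, 0.5), c(1, 1), fW), "off the")
})

test_that("stopped family recovers the inverted Dirichlet ratio law as
           fW -> 0", {
  # transform the fixed-locus marginal to ratio coordinates
  # x = p2/p1 through the manifold map and compare pointwise
  th <- c(1.2, 0.7)
  xs <- c(0.05, 0.3, 1, 2.5, 8)
  for (fW in c(1e-2, 1e-5)) {
    for (x in xs) {
      p <- projectToStop(c(1, x), fW)
      p1 <- p[1]
      # |dx/dp1| on the manifold, from x(p1) = (1-p1-fW)/(p1(1-p1))
      dxdp1 <- ((1 - p1)^2 - fW * (1 - 2 * p1)) / (p1^2 * (1 - p1)^2)
      got <- marginal2Pdf(p1, th[1], th[2], fW) / dxdp1
      expect_equal(got, invertedDirichletPdf(x, th), tolerance = 1e-6)
    }
  }
})

test_that("regime classification and singularity flags follow the
           background mutation rate", {
  expect_equal(classifyRegime(0.05)$label, "completed_sweeps")
  expect_equal(classifyRegime(10)$label, "partial_sweeps")
  expect_equal(classifyRegime(100)$label, "frequency_shifts")
  expect_false(classifyRegime(10)$majorSingularity)
  # flags flip exactly at 1
  expect_true(classifyRegime(0.99)$majorSingularity)
  expect_false(classifyRegime(1)$majorSingularity)
  expect_true(classifyRegime(5, thetaL = 0.99)$minorSingularity)
  expect_false(classifyRegime(5, thetaL = 1)$minorSingularity)
  expect_true(is.na(classifyRegime(5)$minorSingularity))
  expect_error(classifyRegime(-1), "non-negative")
})
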