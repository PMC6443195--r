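#' @include AllClasses.R modelParams.R
NULL

#' Log of the generalized (multivariate) Beta function
#'
#' \deqn{\log B[\Theta] = \sum_i \log\Gamma(\Theta_i) -
#'   \log\Gamma\Big(\sum_i \Theta_i\Big),} computed via `lgamma` for
#' numerical stability at small or large rates.
#'
#' @param theta positive numeric vector.
#' @return scalar log Beta value.
#' @examples
#' logMultivariateBeta(c(1, 1))       # 0
#' logMultivariateBeta(c(0.5, 0.5))   # log(pi)
#' @export
logMultivariateBeta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all entries of 'theta' must be positive and finite")
  sum(lgamma(theta)) - lgamma(sum(theta))
}

#' Inverted Dirichlet density of frequency ratios
#'
#' Density of the ratio vector \eqn{(x_2, \dots, x_L)} relative to the
#' reference locus 1, the limit law of the establishment jump chain:
#' \deqn{P[x \mid \Theta] = \frac{1}{B[\Theta]}
#' \prod_{j=2}^{L} x_j^{\Theta_j - 1}
#' \Big(1 + \sum_{i} x_i\Big)^{-\sum_i \Theta_i}.}
#' The density depends on the locus mutation rates only, never on the
#' selection strength.  Boundary evaluations with \eqn{x_j = 0} and
#' \eqn{\Theta_j < 1} return `Inf` explicitly.
#'
#' @param x numeric vector of ratios, length `length(theta) - 1`, all
#'   >= 0.
#' @param theta positive numeric vector of locus rates (length L >= 2).
#' @param log return the log density.
#' @return density value.
#' @examples
#' invertedDirichletPdf(1, c(1, 1))   # 0.25
#' @export
invertedDirichletPdf <- function(x, theta, log = FALSE) {
  if (length(theta) < 2L) stop("'theta' must have length >= 2")
  if (length(x) != length(theta) - 1L)
    stop("'x' must have length length(theta) - 1")
  if (any(x < 0)) stop("ratios must be non-negative")
  a <- theta[-1] - 1
  lx <- ifelse(x == 0 & a == 0, 0, a * log(x))  # 0*log(0) := 0
  logf <- -logMultivariateBeta(theta) + sum(lx) -
    sum(theta) * log1p(sum(x))
  if (log) logf else exp(logf)
}

#' Conditioned beta-prime density of the minor/major ratio
#'
#' In the symmetric two-locus model the ratio of the minor-locus over the
#' major-locus frequency has density
#' \deqn{P_{\beta'}[x \mid \Theta_l] =
#'   \frac{2\,\Gamma(2\Theta_l)}{\Gamma(\Theta_l)^2}\,
#'   x^{\Theta_l - 1} (1 + x)^{-2\Theta_l}, \qquad 0 \le x \le 1,}
#' a beta-prime density folded onto `[0, 1]` (the factor 2 conditions on
#' which locus is major).  For \eqn{\Theta_l < 1} the density diverges as
#' \eqn{x \to 0} (sweep-like heterogeneity); for large \eqn{\Theta_l} it
#' concentrates near 1 (homogeneous shifts).
#'
#' @param x ratio value(s) in `[0, 1]`.
#' @param thetaL positive locus (or background) mutation rate.
#' @param log return the log density.
#' @return density value(s).
#' @examples
#' betaprimeConditionalPdf(1, 1)   # 0.5
#' @export
betaprimeConditionalPdf <- function(x, thetaL, log = FALSE) {
  if (!is.finite(thetaL) || thetaL <= 0) stop("'thetaL' must be positive")
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  a <- thetaL - 1
  lx <- ifelse(x == 0 & a == 0, 0, a * log(x))
  logf <- log(2) + lgamma(2 * thetaL) - 2 * lgamma(thetaL) +
    lx - 2 * thetaL * log1p(x)
  if (log) logf else exp(logf)
}

#' @rdname betaprimeConditionalPdf
#' @details `betaprimeConditionalCdf` gives the corresponding distribution
#'   function, \eqn{2\,I_{x/(1+x)}(\Theta_l, \Theta_l)} with the
#'   regularized incomplete beta function \eqn{I}; it is convenient as a
#'   reference in one-sample Kolmogorov-Smirnov tests.
#' @export
betaprimeConditionalCdf <- function(x, thetaL) {
  if (!is.finite(thetaL) || thetaL <= 0) stop("'thetaL' must be positive")
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  2 * stats::pbeta(x / (1 + x), thetaL, thetaL)
}

#' Joint density of stopped allele frequencies on the manifold
#'
#' The joint distribution of mutant frequencies at the end of the rapid
#' adaptive phase lives on the `(L-1)`-dimensional manifold
#' \eqn{\prod_j (1 - p_j) = f_w}.  This function evaluates the proper
#' `(L-1)`-dimensional density obtained by resolving the delta constraint:
#' coordinate `eliminate` (default: the last) is expressed through the
#' others and the corresponding Jacobian factor
#' \eqn{(1 - p_{elim}) / f_w} is included, so that integrating over the
#' remaining coordinates gives total mass 1.  The density kernel is
#' \deqn{\frac{1}{B[\Theta]} \prod_j p_j^{\Theta_j - 1}
#'   \Big(\sum_i p_i\Big)^{-\sum_i \Theta_i}
#'   \Big(\sum_j \frac{f_w\, p_j}{1 - p_j}\Big).}
#' In the limit \eqn{f_w \to 0} the implied ratio density recovers the
#' inverted Dirichlet law of [invertedDirichletPdf()].
#'
#' @param p frequency vector on (or numerically near) the manifold.
#' @param theta positive numeric vector of locus rates.
#' @param fW stopping fraction in (0, 1).
#' @param eliminate index of the coordinate resolved by the constraint.
#' @param tol maximal tolerated off-manifold deviation
#'   `|prod(1 - p) - fW|`.
#' @param log return the log density.
#' @return density value with respect to the remaining `L - 1`
#'   coordinates.
#' @examples
#' fW <- 0.05; p1 <- 0.6; p2 <- 1 - fW / (1 - p1)
#' stoppedJointPdf(c(p1, p2), c(1, 1), fW)
#' marginal2Pdf(p1, 1, 1, fW)   # identical
#' @export
stoppedJointPdf <- function(p, theta, fW, eliminate = length(p),
                            tol = 1e-8, log = FALSE) {
  stopifnot(length(p) == length(theta), fW > 0, fW < 1)
  if (any(p < 0) || any(p >= 1)) stop("'p' must lie in [0, 1)")
  if (abs(prod(1 - p) - fW) > tol)
    stop("'p' is off the stopping manifold beyond tolerance")
  a <- theta - 1
  lp <- ifelse(p == 0 & a == 0, 0, a * log(p))
  logf <- -logMultivariateBeta(theta) + sum(lp) -
    sum(theta) * log(sum(p)) +
    log(sum(fW * p / (1 - p))) +
    log1p(-p[eliminate]) - log(fW)
  if (log) logf else exp(logf)
}

#' Marginal stopped-frequency density of a fixed locus (two-locus model)
#'
#' Gene-centered marginal of the stopped joint distribution for `L = 2`,
#' obtained by eliminating \eqn{p_2 = 1 - f_w/(1 - p_1)} on the manifold:
#' \deqn{P_{f_w}[p_1 \mid \Theta_1, \Theta_2] =
#'   \frac{p_1^{\Theta_1 - 1} (1 - p_1 - f_w)^{\Theta_2 - 1}
#'         (1 - p_1)^{\Theta_1 + 1}}
#'        {B[\Theta_1, \Theta_2]\,(1 - p_1^2 - f_w)^{\Theta_1 + \Theta_2}}
#'   \Big(1 - \frac{f_w (1 - 2 p_1)}{(1 - p_1)^2}\Big)}
#' on the support \eqn{0 \le p_1 \le 1 - f_w}.  It integrates to 1 and
#' has integrable singularities at \eqn{p_1 = 0} when \eqn{\Theta_1 < 1}
#' (the locus's own rate) and at \eqn{p_1 = 1 - f_w} when
#' \eqn{\Theta_2 < 1} (its background rate).
#'
#' @param p1 frequency value(s) in `[0, 1 - fW]`.
#' @param theta1,theta2 positive locus rates.
#' @param fW stopping fraction in (0, 1).
#' @param log return the log density.
#' @return density value(s); boundary singularities evaluate to `Inf`.
#' @export
marginal2Pdf <- function(p1, theta1, theta2, fW, log = FALSE) {
  stopifnot(theta1 > 0, theta2 > 0, fW > 0, fW < 1)
  if (any(p1 < 0 | p1 > 1 - fW))
    stop("'p1' must lie in [0, 1 - fW]")
  a1 <- theta1 - 1
  a2 <- theta2 - 1
  u <- 1 - p1 - fW
  l1 <- ifelse(p1 == 0 & a1 == 0, 0, a1 * log(p1))
  l2 <- ifelse(u <= 0 & a2 == 0, 0, a2 * log(u))
  logf <- l1 + l2 + (theta1 + 1) * log1p(-p1) -
    logMultivariateBeta(c(theta1, theta2)) -
    (theta1 + theta2) * log(1 - p1^2 - fW) +
    log1p(-fW * (1 - 2 * p1) / (1 - p1)^2)
  if (log) logf else exp(logf)
}

#' Major- and minor-locus marginal densities (two-locus model)
#'
#' Trait-centered marginals of the stopped two-locus model: the density of
#' the locus that ends up with the higher (major) or lower (minor)
#' frequency is the sum of the two ordered fixed-locus marginals,
#' \deqn{P^{\pm}_{f_w}[p] = P_{f_w}[p \mid \Theta_1, \Theta_2] +
#'   P_{f_w}[p \mid \Theta_2, \Theta_1],}
#' restricted to the branch support derived from the stopping constraint:
#' the symmetric point \eqn{p^*} with \eqn{(1 - p^*)^2 = f_w} splits the
#' range, giving major support \eqn{[1 - \sqrt{f_w},\, 1 - f_w]} and
#' minor support \eqn{[0,\, 1 - \sqrt{f_w}]}.  Each branch integrates to
#' 1, so the two together carry mass 2 (one marginal per locus).
#'
#' @param p frequency value(s) inside the requested branch support.
#' @param theta1,theta2 positive locus rates.
#' @param fW stopping fraction in (0, 1).
#' @param which `"major"` or `"minor"`.
#' @param log return the log density.
#' @return density value(s).
#' @examples
#' majorMinorPdf(0.9, 1, 1, 0.05, which = "major")
#' @export
majorMinorPdf <- function(p, theta1, theta2, fW,
                          which = c("major", "minor"), log = FALSE) {
  which <- match.arg(which)
  pStar <- 1 - sqrt(fW)
  if (which == "major") {
    if (any(p < pStar | p > 1 - fW))
      stop("major-locus support is [1 - sqrt(fW), 1 - fW]")
  } else {
    if (any(p < 0 | p > pStar))
      stop("minor-locus support is [0, 1 - sqrt(fW)]")
  }
  f <- marginal2Pdf(p, theta1, theta2, fW) +
    marginal2Pdf(p, theta2, theta1, fW)
  if (log) base::log(f) else f
}

#' Classify the adaptive regime from the background mutation rate
#'
#' The background mutation rate is the single compound parameter that
#' determines the qualitative architecture of adaptation:
#' *single completed sweeps* for \eqn{\Theta_{bg} \le 0.1},
#' *heterogeneous partial sweeps* for \eqn{0.1 < \Theta_{bg} < 100}, and
#' *polygenic frequency shifts* for \eqn{\Theta_{bg} \ge 100}.  Alongside
#' the label, singularity flags of the stopped marginals are reported:
#' the major-locus density is singular at its upper bound \eqn{1 - f_w}
#' iff \eqn{\Theta_{bg} < 1}, and the minor-locus density is singular at 0
#' iff the minimal locus rate \eqn{\Theta_l < 1}.
#'
#' @param thetaBg non-negative background mutation rate (see [thetaBg()]).
#' @param thetaL optional minimal locus mutation rate; when omitted the
#'   minor-locus flag is `NA`.
#' @return a list with elements `label` (one of `"completed_sweeps"`,
#'   `"partial_sweeps"`, `"frequency_shifts"`), `thetaBg`,
#'   `majorSingularity`, `minorSingularity`.
#' @examples
#' classifyRegime(0.05)$label   # "completed_sweeps"
#' classifyRegime(10)$majorSingularity   # FALSE
#' @export
classifyRegime <- function(thetaBg, thetaL = NULL) {
  if (!is.finite(thetaBg) || thetaBg < 0)
    stop("'thetaBg' must be non-negative")
  label <- if (thetaBg <= 0.1) "completed_sweeps"
           else if (thetaBg < 100) "partial_sweeps"
           else "frequency_shifts"
  list(label = label,
       thetaBg = thetaBg,
       majorSingularity = thetaBg < 1,
       minorSingularity = if (is.null(thetaL)) NA else thetaL < 1)
}
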