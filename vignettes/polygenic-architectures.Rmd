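---
title: "Sweeps, partial sweeps, and frequency shifts: methods behind polysweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweeps, partial sweeps, and frequency shifts: methods behind polysweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysweep)
```

## The model

`polysweep` studies how a binary trait with a *redundant* polygenic basis
adapts after a sudden environmental change, and what the resulting genomic
architecture looks like: a classic selective sweep at one locus, partial
sweeps at several interacting loci, or small coordinated frequency shifts
at many loci.

A haploid, panmictic population of $N_e$ individuals carries $L$
bi-allelic loci. Only the genotype with the ancestral allele everywhere
expresses the ancestral phenotype $Z_0 = 0$; any genotype with at least
one mutant allele expresses the adaptive phenotype $Z_1 = 1$ (complete
redundancy). Malthusian fitness is $W(Z) = s Z$ with $s = s_d \le 0$
before the environmental change at $t = 0$ and $s = s_b > 0$ afterwards.
Loci mutate one-way (ancestral $\to$ derived) at rate $\mu_i$ per
generation; the population-scaled rate $\Theta_i = 2 N_e \mu_i$ is the
canonical parameter, and per-generation rates are always derived from it
(`muVec()`), so the analytic machinery never needs $N_e$. Under *relaxed
redundancy*, a genotype with exactly one mutation expresses an
intermediate phenotype $\delta \in [1/2, 1)$ and at least two mutant loci
are needed for the full phenotype.

Adaptation is observed not at a fixed time but at a fixed amount of
phenotypic progress: simulations stop when the population mean fitness
has covered all but a fraction $f_w$ of the maximal increase,
$$\frac{W(Z_1) - \bar W}{W(Z_1) - W(Z_0)} = f_w ,$$
which for the completely redundant trait equals the residual frequency of
ancestral-phenotype individuals, $P_0 = \prod_j (1 - p_j) = f_w$. With the
default $f_w = 0.05$, the single-locus stopped frequency can never exceed
$1 - f_w = 0.95$.

## Three routes to the stopped architecture

**Wright-Fisher simulation** (`simulateEnsemble()`). Discrete
generations under linkage equilibrium: selection acts per locus through
the marginal (background-averaged) Wrightian weights
$1 + s\,E[Z \mid \text{allele}]$, then one-way mutation
$p \mapsto p + \mu (1 - p)$, then binomial drift
$\mathrm{Bin}(N_e, p)/N_e$. Starting monomorphic, the population evolves
$8 N_e$ generations under $s_d$ to mutation-selection-drift balance,
discarding (and restarting) burn-ins in which any locus fixes the mutant
allele. After the switch to $s_b$, generations continue until the
stopping rule fires.

**Two-phase analytic sampler** (`sampleArchitectureAnalytic()`). The
early *stochastic phase* is a Yule pure-birth process: established
lineages arise at locus $i$ at rate $\Theta_i s_b$ and split at rate
$s_b$. In its embedded jump chain the next event hits locus $i$ with
probability $(k_i + \Theta_i)/\sum_j (k_j + \Theta_j)$ — $s_b$ cancels,
which is why selection strength never affects the architecture. The
limit law of the count ratios $x_i = k_i/k_1$ is an inverted Dirichlet
distribution, sampled exactly as ratios of independent Gamma variables.
During the subsequent *deterministic phase* the redundant-trait dynamics
$\dot p_i = s_b\, p_i \prod_j (1 - p_j)$ have a locus-independent
per-capita rate, so every ratio $x_i$ is a conserved quantity; the
stopped architecture is the ratio vector rescaled onto the manifold
$\prod_j (1 - c\,x_j) = f_w$ (`projectToStop()`, monotone bisection,
manifold residual $< 10^{-12}$).

**Closed forms** (`analytics`). The stopped joint density
(`stoppedJointPdf()`, evaluated as a proper $(L-1)$-dimensional density by
eliminating one coordinate and including the Jacobian $(1-p_{elim})/f_w$),
the two-locus fixed-locus marginal (`marginal2Pdf()`), the major/minor
decomposition (`majorMinorPdf()`), and the conditioned beta-prime ratio
density (`betaprimeConditionalPdf()`). All density arithmetic is done in
log space; integrable boundary singularities evaluate to `Inf` explicitly
rather than overflowing.

Two printed expressions required resolution against their own
normalization. In the two-locus marginal, the middle factor is
$(1 - p_1^2 - f_w)^{-\Theta_1 - \Theta_2}$ (the typeset original is
ambiguous); re-deriving the marginal from the joint density by
eliminating $p_2 = 1 - f_w/(1-p_1)$ confirms that grouping, and the
implementation is validated by quadrature (mass 1 for symmetric,
asymmetric, and doubly-singular rate pairs) and against the analytic
sampler. The support bounds of the major/minor decomposition were
likewise derived from the stopping constraint: the symmetric point
$p^\ast = 1 - \sqrt{f_w}$ splits major support
$[1-\sqrt{f_w},\, 1-f_w]$ from minor support $[0,\, 1-\sqrt{f_w}]$;
each branch carries mass 1.

A useful subtlety of the $f_w \to 0$ limit: the fixed-locus marginal
converges pointwise to $1/(1+p_1)^2$-type expressions that integrate to
$1/2$, because the mass of the event "the *other* locus is major"
concentrates in an integrable spike at $p_1 \to 1 - f_w$ and escapes the
pointwise limit. Mass is conserved at every positive $f_w$; tests check
normalization at finite $f_w$ and the exact change-of-variables identity
that maps the stopped family back to the inverted Dirichlet ratio law.

## The regime classification

The single compound parameter
$$\Theta_{bg} = \min_i \Big[\sum_j \Theta_j - \Theta_i\Big]
  \;=\; (L-1)\,\Theta_l \ \text{(equal rates)}$$
— the mutation rate available in the background of the leading locus —
controls the architecture (`classifyRegime()`): *completed sweeps* for
$\Theta_{bg} \lesssim 0.1$, *heterogeneous partial sweeps* for
$0.1 < \Theta_{bg} < 100$, *polygenic frequency shifts* for
$\Theta_{bg} \gtrsim 100$. The major-locus marginal is singular at its
upper bound $1 - f_w$ iff $\Theta_{bg} < 1$; the minor-locus marginal is
singular at 0 iff $\min_i \Theta_i < 1$. Under relaxed redundancy one
background locus is essential rather than redundant, so the effective
background rate is $(L-2)\,\Theta_l$ (`thetaBgRelaxed()`).

## Numerical and design choices

* **Within-generation order** selection $\to$ mutation $\to$ drift, the
  standard Wright-Fisher life cycle; mutation is applied as the
  deterministic flow $\mu(1-p)$ on frequencies (equivalent to
  per-individual sampling at $O(\mu)$ and faster). Drift is the single
  stochastic step.
* **Stopping** is checked once per generation after drift, so the
  recorded metric may overshoot below $f_w$ by roughly one generation's
  progress ($\approx s_b\, \bar p\, f_w$); the overshoot is recorded,
  never corrected, and `metricPrev` keeps the last pre-stop value.
* **Burn-in conditioning** restarts the whole burn-in on fixation
  (statistically identical to post-hoc discarding, cheaper in memory);
  a guard aborts when more than 90% of at least ten attempts are
  discarded.
* **Fixed loci** ($p_j = 1$) in the genotype-class moments are handled by
  exact exclusion (Poisson-binomial evaluation of the "exactly one
  mutation" class) rather than the $p/(1-p)$ shortcut.
* **Ties** in the major/minor ordering break toward the lowest locus
  index; with continuous frequencies ties occur only at boundary cases.
* **RNG**: each ensemble draws one sub-seed per replicate from a master
  seed, so runs are bit-reproducible and replicates independent.
* **Jump-chain stopping** uses the total lineage count
  ($\sum_i k_i = k_{target}$, default $10^4$), equivalent in the limit to
  stopping on the reference-locus count and simpler to guard.
* **Expected ratio** E[x] is defined by quadrature of the conditioned
  beta-prime density (the corresponding closed form is not implemented;
  the quadrature is validated against simulation and the
  $\Theta_l = 1$ closed form $2\ln 2 - 1$).

## What the cross-validation shows — and its finite-population limits

The test suite validates the Wright-Fisher simulator against the
two-phase analytic sampler (and the jump chain against the Gamma-ratio
construction) by Kolmogorov-Smirnov tests on rank-ordered stopped
frequencies. Two measurement details matter when comparing a finite,
discrete-time population against a continuum limit law:

1. *Common observation surface.* The simulator observes the population
   one drift step after the stopping rule fires, while the analytic law
   lives exactly on the manifold $\prod_j(1-p_j) = f_w$, where the
   major-locus density can be singular. Stopped simulator states are
   therefore projected back onto the manifold along their (invariant)
   ratio vector before comparison.
2. *Common resolution.* A population of size $N_e$ resolves frequencies
   in units of $1/N_e$, while for $\Theta < 1$ the limit law places
   substantial minor-locus mass below any such grid (the $x^{\Theta-1}$
   singularity: mass $\propto (1/N_e)^{\Theta}$). Both samples are
   rounded to the common $1/N_e$ grid before the test.

With this protocol the simulator and the sampler agree (KS, $\alpha =
0.01$) at $N_e = 1000$ for $\Theta_{bg} \in \{0.1, 1\}$. The analytic
theory is an $N_e \to \infty$ (more precisely $N_e s_b \gg 1$,
$k \ll N_e$) limit: at $\Theta_{bg} = 10$, where adaptation draws on
dozens of standing lineages, and for weak selection $s_b = 0.01$, the
finite-population corrections at $N_e = 1000$ are real and detectable at
a few hundred replicates (the simulated minor/major ratios are slightly
more homogeneous than the limit predicts). Those two checks are run at
$N_e = 4000$, where the corrections fall below detection — consistent
with the reference conditions of $N_e = 10^4$ at which the theory was
originally validated. This is a statement about the limit theory's
domain, not about simulator correctness, which converges smoothly onto
the prediction as $N_e$ grows.

The synthetic data generated here emulate: linkage equilibrium (no
linked-sweep footprints), strict one-way mutation, equal locus effects,
and a panmictic population of constant size. Passing tests therefore say
nothing about linked loci, diploid dominance, unequal effects,
time-varying selection, or structured populations — all outside this
package's scope.

## Problem sizes used by the test suite

Unit and acceptance tests run at desk scale, chosen as the smallest
sizes at which each property is informative: $N_e$ between 200 and 4000,
burn-ins of $8 N_e$ generations, 100–300 Wright-Fisher replicates per
condition, $10^3$–$10^4$ analytic or Yule replicates, and jump chains to
$k_{target} \approx 4000$. The full published design ($N_e = 10^4$,
$10^4$ replicates per parameter combination; `generateFixtureGrid("paper_grid")`)
is exposed for users who want the complete reproduction.

## A worked example

```{r example, eval = FALSE}
par <- modelParams(ne = 1000, L = 2, theta = 0.5, sB = 0.1, sD = -0.1,
                   fW = 0.05, seed = 1)
wf <- simulateEnsemble(par, 200)
an <- sampleArchitectureAnalytic(c(0.5, 0.5), fW = 0.05,
                                 replicates = 2000, seed = 2)
ratioSummary(wf)
ratioSummary(an)
expectedMinorMajorRatio(thetaBg(thetaVec(par)))
classifyRegime(thetaBg(thetaVec(par)))$label
```

## Known limitations

* Linked loci, diploids, unequal locus effects and time-dependent
  selection are not modeled.
* The analytic sampler and all closed-form densities assume complete
  redundancy ($\delta = 1$); the simulator alone covers
  $\delta \in [1/2, 1)$.
* Haplotype identity within a locus (soft-sweep substructure) is not
  tracked; only allele frequencies are.
* The haploid convention $\Theta = 2 N_e \mu$ is used throughout.
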