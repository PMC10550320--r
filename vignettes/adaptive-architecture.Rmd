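---
title: "Adaptive architectures of an additive quantitative trait: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive architectures of an additive quantitative trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(adaptarch)
```

## The question and the model

When a quantitative trait adapts to a sudden environmental change, the same
phenotypic response can be produced by very different genotypic patterns: a
single selective sweep, a handful of partial sweeps, or subtle frequency
shifts at very many loci. `adaptarch` implements a haploid model in which
this "adaptive architecture" can be simulated exactly and predicted
analytically.

The trait is additive over $L$ biallelic loci of equal effect $\gamma$:
$Z = \gamma \sum_i \eta_i$ with $\eta_i \in \{0, 1\}$. Fitness is Gaussian
stabilizing selection, $W(Z) = \exp[-\tfrac{\sigma(t)}{2}(Z -
Z_{\mathrm{opt}}(t))^2]$, and at generation $t = 0$ the optimum jumps from
$Z_{\mathrm{opt}}^0$ to a higher value. Of the $L$ loci, $d$ start with the
trait-increasing allele $A_i$ rare ("beneficial variation"); the other
$L - d$ start with $A_i$ common. Mutation is bidirectional with
per-generation rates $\mu$ (and $\nu$, equal by default).

The central object is not a time series but the **joint distribution of
allele frequencies across evolutionary replicates at fixed phenotypic
progress** ("pheno-time"): frequencies are recorded the first generation the
population mean satisfies $\bar Z \ge Z_{\mathrm{opt}}^0 + c_Z \gamma$, so
replicates are compared at the same adaptive stage rather than the same
age. For visualization and testing, the joint distribution is projected onto
size-ordered marginals: within each replicate loci are ranked by frequency,
the $L - d$ ancestral-majority loci are discarded, and the remaining ranks
are pooled across replicates (major locus, first minor, second minor, ...).

A single composite parameter, the background mutation rate
$\Theta_{\mathrm{bg}} = 2 N_e \mu (d - 1)$, governs the type of
architecture: sweeps for $\Theta_{\mathrm{bg}} \lesssim 0.1$, partial sweeps
at intermediate values, collective shifts for $\Theta_{\mathrm{bg}} \gtrsim
10$ (`theta_bg()`, `classify_regime()`; the boundaries are advisory, the
transition is gradual).

## The two simulation engines

**Linkage-equilibrium Wright–Fisher (`wf_simulate()`).** Loci are updated
independently given the shared trait mean: per generation, deterministic
mutation $p' = p(1-\nu) + (1-p)\mu$, then binomial sampling of $N_e$ copies
with the $A$ allele weighted by
$w = \exp[\sigma\gamma((Z_{\mathrm{opt}} - \bar Z) - \tfrac{\gamma}{2}(1 -
2p))]$ relative to weight 1 for $a$. The second term in the exponent is
disruptive selection; `directional_only = TRUE` drops it, giving the pure
directional model whose odds ratios $u_i/u_j$ ($u = p/(1-p)$) are exactly
conserved in continuous time. Conventions fixed here: events are mutation
first, then selection + drift; $\bar Z$ enters the weight as the
pre-mutation parental mean (mutation perturbs $\bar Z$ by $O(L\mu)$, which
is negligible, but a fixed convention makes runs reproducible); crossing is
detected at integer generations, so a snapshot can overshoot the waypoint by
one generation's progress — the overshoot is reported, not corrected.
Burn-in to mutation–selection–drift balance defaults to $8 N_e$
generations; with `sgv = FALSE` the run starts monomorphic and skips
burn-in (adaptation from new mutation only), implemented as an
initialization flag rather than a $\sigma \to \infty$ limit for numerical
robustness.

All replicates advance together through vectorized binomial draws from one
RNG stream. Reproducibility is therefore at the run level (same seed and
replicate count give bit-identical output), not per replicate; we chose this
over per-replicate streams because it is orders of magnitude faster in R and
every analysis here uses replicate ensembles.

**Individual-based with linkage (`ib_simulate()`).** $N_e$ haploid genomes
on one linear chromosome with per-interval recombination probability $r$;
the compiled (C++) life cycle is: both parents of each of $N_e$ offspring
drawn by stochastic acceptance on Gaussian fitness (accept a uniform index
with probability $W/W_{\max}$, with $W_{\max}$ recomputed each generation),
a $\mathrm{Binomial}(L-1, r)$ number of crossovers placed on distinct
intervals uniformly at random with a fair-coin starting parent, then
population-level mutation with a $\mathrm{Poisson}(N_e L \mu)$ number of
allele toggles at uniform cells. Selfing is possible (probability $1/N_e$):
the model does not forbid it and excluding it would bias fitness sampling at
small $N_e$. The $d$ majority-$a$ loci are chosen uniformly at random per
replicate; burn-in defaults to $20 N_e$ generations. The recombination
probability between loci $\Delta\ell$ intervals apart is
$r_{\Delta\ell} = (1 - (1 - 2r)^{\Delta\ell})/2 \ge r$ (`recomb_prob()`,
with the odd-crossover binomial sum available as a cross-check).
`genic_and_genetic_variance()` returns the population variance of
individual trait values ($v_g$, units $\gamma^2$) against the
linkage-equilibrium expectation $v_g^{LE} = \sum_i p_i(1 - p_i)$; their gap
measures linkage disequilibrium.

## The analytical approximation

The theory splits adaptation into two phases.

*Establishment phase.* While beneficial copies are rare, the lineages that
escape drift loss form a multi-type Yule process: new immortal lineages are
seeded at locus $i$ at rate proportional to $\Theta_i = 2 N_e \mu_i$ and
every lineage splits at rate proportional to 1. The establishment
probability multiplies all rates equally (equal locus effects) and cancels
under time rescaling, so it is deliberately never computed.
`yule_simulate()` runs the embedded jump chain. In the many-lineage limit
the vector of lineage-count ratios converges to an inverted Dirichlet law —
equivalently, ratios of independent $\mathrm{Gamma}(\Theta_i)$ variables.

*Deterministic phase.* Under directional selection the odds ratios
$u_i/u_j$ are frozen, so the establishment-phase ratio law is transported
unchanged until the trait mean hits the sampling condition
$\sum_i p_i = c_Z$. `sample_joint()` implements this directly: draw
$G_i \sim \mathrm{Gamma}(\Theta_i)$, set $u_i = \lambda G_i$ with the scalar
$\lambda$ solving $\sum_i \lambda G_i / (1 + \lambda G_i) = c_Z$, and return
$p_i = u_i/(1 + u_i)$. The resulting joint density of $(p_2, \dots, p_d)$
(`joint_frequency_density()`) is the pushforward of the inverted Dirichlet
under this constraint; for $d = 2$ the marginal has a closed form
(`marginal_frequency_density()`). No selection parameter appears anywhere
in this module — the predicted architecture depends only on the
$\Theta_i$ — and that structural independence is itself one of the tested
claims.

## Numerical choices

* **$\lambda$ solver** (`solve_lambda()`): the constraint map is strictly
  increasing in $\lambda$; we bracket by doubling/halving from the
  equal-draw starting value $c_Z / ((d - c_Z)\,\overline G)$, run
  `uniroot`, and polish with safeguarded Newton steps until the constraint
  residual is at most $10^{-10}$. Every emitted sample satisfies
  $|\sum_i p_i - c_Z| \le 10^{-10}$.
* **Log-space densities**: both densities are evaluated in log space and
  exponentiated last, so rates up to order $10^3$ and near-boundary points
  are handled; outside the open support the value is exactly 0 (or
  $-\infty$ on the log scale).
* **Degenerate gamma draws**: for $\Theta_i$ far below 1,
  $\mathrm{Gamma}(\Theta_i)$ draws can underflow to exactly 0; they are
  clamped to the smallest positive normal. The mass near 0 is real, but the
  open-support contract of the transport map requires strictly positive
  ratios.
* **Rank ties**: sorting is stable, so ties (which are real events for
  simulated frequencies $k/N_e$, measure-zero for the theory sampler) break
  by locus index.
* **Endpoint singularities**: for $\Theta$ near 0 the conditioned densities
  diverge at the support endpoints with exponents approaching $-1$, and a
  non-negligible share of the probability mass sits within $10^{-13}$ of
  the boundary. Quadrature against these densities in the test suite
  therefore evaluates the integrand in distance-to-endpoint coordinates
  with tanh–sinh (double-exponential) quadrature; naive adaptive
  quadrature in $p$ cannot resolve this mass in double precision.

## What the generators emulate, and problem sizes

The simulators' default conditions are the study conditions of the model:
burn-in $8N_e$ (LE) and $20N_e$ (IB) generations, equal forward and back
mutation, a step change of the optimum, and pheno-time snapshots. Reference
scenarios used throughout the tests: a 3-locus trait adapting from a
monomorphic start to an optimum 3 mutational steps away, sampled at
$c_Z = 1$ ($\Theta_{\mathrm{bg}} = 4 N_e \mu$); and a 10-locus trait with
the ancestral optimum at $2\gamma$ ($d = 8$, so
$\Theta_{\mathrm{bg}} = 14 N_e \mu$) adapting to $8\gamma$ from standing
variation. The test suite and the acceptance script run these at reduced
size — $N_e$ of 300–1,000, $10^2$–$3\times10^3$ replicates, and theory
samples of $2\times10^3$–$10^5$ — chosen so the whole suite completes on a
single CPU in minutes while keeping Monte-Carlo error well below the effect
sizes being tested. Highly polygenic scenarios ($L$ of order $10^4$,
$10^5$ replicates) are supported by the same machinery but are not desk
scale; the oscillation and limit-shape diagnostics are exercised at reduced
size via `theory_cumulant_series()` and `periodicity_diagnostic()`.

What the generators deliberately do not emulate: unequal effect sizes,
dominance/diploidy, pleiotropy, population structure or gene flow, linked
neutral diversity, and the late equilibration phase at the new optimum
(disruptive-selection allele sorting). Passing tests therefore support the
model's claims within those boundaries and say nothing about, e.g.,
effect-size heterogeneity in real traits.

## Known limitations

* The analytical approximation assumes minority frequencies stay small
  during establishment ($\lesssim 10\%$ standing frequency). With weak
  selection and large mutation rates, disruptive selection and
  back-mutation reshape the standing variation and the prediction degrades.
* The theory is a continuous-time approximation. In discrete generations
  the per-generation selection differential is
  $\sigma\gamma(Z_{\mathrm{opt}} - \bar Z)$; once this is of order 0.1 or
  more (e.g. $\sigma\gamma^2 = 0.1$ with an initial gap of a few mutational
  steps, as arises when scaling $N_e \sigma \gamma^2 = 100$ down to
  $N_e = 10^3$), the one-generation crossing overshoot and the coarse
  establishment dynamics produce a small but statistically detectable
  dependence of the sampled architecture on the selection strength. At
  $N_e = 10^4$ and $\sigma\gamma^2 \le 0.01$ the selection-independence
  property holds to the power of thousands-of-replicate comparisons.
  `wf_simulate()` reports the overshoot rather than hiding it.
* The extension that scales deleterious standing variants into the joint
  distribution (relevant for $\Theta_{\mathrm{bg}} \gtrsim 1$ with weak
  selection at short sampling distances) is not implemented; the joint
  density here treats the $L - d$ ancestral-majority loci as fixed.
* `classify_regime()` labels are heuristics on a continuum; no formal
  convergence test for the quasi-stable limit shape is provided —
  `periodicity_diagnostic()` reports the series and leaves judgment to the
  user.

## A worked example

```{r example, eval = FALSE}
Ne <- 1000
m <- trait_model(L = 3, Ne = Ne, gamma = 1, mu = 1 / (4 * Ne),  # theta_bg = 1
                 sigma_before = 10 / Ne, d = 3, zopt_new = 3, sgv = FALSE)
sim <- wf_simulate(m, stop_schedule(1), replicates = 2000,
                   directional_only = TRUE, seed = 1)
ordered_marginals(sim)
theory <- ordered_marginal_theory(rep(0.5, 3), cz = 1, n = 2000)
theory
```

The two rank-wise mean vectors agree to Monte-Carlo error (about 0.61 /
0.30 / 0.10 for major / first minor / second minor), the partial-sweep
signature of $\Theta_{\mathrm{bg}} = 1$.
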