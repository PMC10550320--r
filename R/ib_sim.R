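#' Recombination probability between two loci on a linear chromosome
#'
#' For loci separated by `delta` intervals with per-interval crossover
#' probability `r`, the probability of an odd number of crossovers between
#' them is
#' `sum over odd k of choose(delta, k) r^k (1-r)^(delta-k)`,
#' which equals the closed form `(1 - (1 - 2 r)^delta) / 2`. The value is
#' always at least `r`, with equality at `delta = 1`, and caps at 0.5 for
#' free recombination.
#'
#' @param delta number of intervals between the loci (`>= 1`; vectorized).
#' @param r per-interval recombination probability in `[0, 0.5]`.
#' @param method `"closed"` for the closed form (default) or `"sum"` for
#'   the explicit odd-crossover binomial sum.
#' @return recombination probabilities.
#' @export
#' @examples
#' recomb_prob(9, 0.01)          # ~ 0.08
#' recomb_prob(1:9, 0.5)         # all 0.5
recomb_prob <- function(delta, r, method = c("closed", "sum")) {
  method <- match.arg(method)
  if (any(delta < 1)) stop("'delta' must be >= 1")
  if (any(delta != as.integer(delta))) stop("'delta' must be integer")
  if (r < 0 || r > 0.5) stop("'r' must be in [0, 0.5]")
  if (method == "closed") {
    (1 - (1 - 2 * r)^delta) / 2
  } else {
    vapply(as.integer(delta), function(dl) {
      k <- seq(1L, dl, by = 2L)
      sum(stats::dbinom(k, dl, r))
    }, numeric(1))
  }
}

#' Construct a haploid population of binary genomes
#'
#' `Ne` haploid genomes of `L` biallelic loci (1 = `A` allele). For the
#' standard initialization, `a_loci` gives the loci fixed for the `a`
#' allele (frequency 0); all others are fixed for `A`.
#'
#' @param Ne population size.
#' @param L number of loci.
#' @param a_loci integer indices of loci initialized monomorphic for `a`.
#' @return an `Ne x L` integer matrix of 0/1 allele states.
#' @export
haploid_population <- function(Ne, L, a_loci = integer(0)) {
  pop <- matrix(1L, Ne, L)
  if (length(a_loci)) {
    stopifnot(all(a_loci >= 1), all(a_loci <= L))
    pop[, a_loci] <- 0L
  }
  pop
}

#' Fitness-proportional parent choice by stochastic acceptance
#'
#' Repeatedly draws a uniform individual index and accepts it with
#' probability `W / max(W)`; the returned index is distributed
#' proportionally to fitness without building a cumulative table.
#'
#' @param fitness vector of nonnegative fitness values, at least one
#'   positive.
#' @return a 1-based individual index.
#' @export
stochastic_acceptance_choose <- function(fitness) {
  .ib_choose_cpp(as.numeric(fitness))
}

#' Recombine two parental genomes
#'
#' Draws the crossover count from `Binomial(L - 1, r)`, places the
#' crossovers on distinct intervals uniformly at random, and copies
#' alternating parental segments starting from a fair-coin choice of the
#' initial parent.
#'
#' @param parent_a,parent_b integer 0/1 genomes of equal length.
#' @param r per-interval recombination probability in `[0, 0.5]`.
#' @return the recombinant offspring genome.
#' @export
recombine <- function(parent_a, parent_b, r) {
  .ib_recombine_cpp(as.integer(parent_a), as.integer(parent_b), r)
}

#' Population-level bidirectional mutation
#'
#' The number of mutated sites in the whole population is Poisson with mean
#' `Ne * L * mu`; each mutation toggles the allele at a uniformly chosen
#' (individual, locus) cell.
#'
#' @param pop `Ne x L` integer 0/1 genome matrix.
#' @param mu per-locus mutation probability per generation.
#' @return the mutated population matrix.
#' @export
mutate_population <- function(pop, mu) {
  .ib_mutate_cpp(pop, mu)
}

#' One individual-based life cycle
#'
#' `Ne` offspring are produced; for each, both parents are chosen
#' independently by stochastic acceptance on their Gaussian fitness
#' (selfing is possible with probability `1/Ne`), a recombinant genome is
#' built, and population-level bidirectional mutation is applied.
#'
#' @param pop `Ne x L` integer 0/1 genome matrix.
#' @param model a [trait_model()].
#' @param r per-interval recombination probability.
#' @param t generation index (selects `sigma(t)` and `Zopt(t)` of the
#'   parental generation).
#' @return the offspring population matrix.
#' @export
ib_generation <- function(pop, model, r, t = 0L) {
  .ib_generation_cpp(pop, model$gamma, sigma_at(model, t),
                     zopt_at(model, t), r, model$mu)
}

#' Genetic and genic variance of a population
#'
#' `vg` is the variance of individual trait values across the population
#' (population moments, scaled by `gamma^2`); `vg_le` is the
#' linkage-equilibrium expectation `sum(p_i (1 - p_i))`. Their gap
#' diagnoses linkage disequilibrium: `vg < vg_le` indicates negative LD.
#'
#' @param pop `Ne x L` integer 0/1 genome matrix.
#' @return named vector `c(vg, vg_le)`.
#' @export
genic_and_genetic_variance <- function(pop) {
  z <- rowSums(pop)
  p <- colMeans(pop)
  c(vg = mean(z^2) - mean(z)^2, vg_le = sum(p * (1 - p)))
}

#' Individual-based simulation sampled at phenotypic waypoints
#'
#' Full forward simulation of `Ne` haploid genomes on a linear chromosome:
#' initialization with `d` randomly chosen majority-`a` loci, burn-in under
#' the ancestral optimum (default `20 * Ne` generations; skipped when
#' `model$sgv` is `FALSE`), environmental change at `t = 0`, and a snapshot
#' of all allele frequencies, plus genetic/genic variance, at the first
#' generation the trait mean reaches each waypoint. Replicates are run
#' sequentially through the compiled core; all randomness comes from R's
#' RNG, so a single [set.seed()] makes the whole run reproducible.
#'
#' @param model a [trait_model()].
#' @param stops a [stop_schedule()].
#' @param r per-interval recombination probability in `[0, 0.5]`.
#' @param replicates number of replicate populations.
#' @param equilibration burn-in generations (default `20 * Ne`).
#' @param seed optional integer seed.
#' @return an `"architecture_sample"` (see [wf_simulate()]) with additional
#'   `replicates x stops` matrices `vg` and `vg_le`.
#' @export
ib_simulate <- function(model, stops, r, replicates,
                        equilibration = 20L * model$Ne, seed = NULL) {
  stopifnot(inherits(model, "trait_model"), inherits(stops, "stop_schedule"))
  if (r < 0 || r > 0.5) stop("'r' must be in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  ncz <- length(stops$cz_values)
  L <- model$L
  freqs <- array(NA_real_, dim = c(replicates, ncz, L))
  generation <- matrix(NA_integer_, replicates, ncz)
  completed <- matrix(FALSE, replicates, ncz)
  vg <- matrix(NA_real_, replicates, ncz)
  vg_le <- matrix(NA_real_, replicates, ncz)
  sgv <- matrix(NA_real_, replicates, L)
  for (i in seq_len(replicates)) {
    a_loci <- sample.int(L, model$d) - 1L  # d randomly chosen loci per run
    res <- .ib_run_cpp(model$Ne, L, model$gamma, model$mu, a_loci,
                       model$sigma_before, model$sigma_after,
                       model$zopt0, model$zopt_new, r,
                       as.integer(equilibration), stops$cz_values,
                       stops$max_generations, model$sgv)
    freqs[i, , ] <- res$freqs
    generation[i, ] <- res$generation
    completed[i, ] <- res$completed
    vg[i, ] <- res$vg
    vg_le[i, ] <- res$vg_le
    sgv[i, ] <- res$sgv[1, ]
  }
  structure(list(freqs = freqs, generation = generation,
                 completed = completed, sgv = sgv,
                 vg = vg, vg_le = vg_le,
                 model = model, stops = stops,
                 directional_only = FALSE, engine = "ib", seed = seed,
                 r = r),
            class = "architecture_sample")
}
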