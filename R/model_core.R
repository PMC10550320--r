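#' Trait and selection model for an additive quantitative trait
#'
#' Defines a haploid, biallelic, additive trait with `L` loci of equal effect
#' `gamma`. Individual trait values are `Z = gamma * (number of A alleles)`.
#' Fitness is Gaussian stabilizing selection towards a trait optimum that
#' jumps at generation 0 from the ancestral optimum `zopt0` to `zopt_new`
#' (sudden environmental change). `d` of the `L` loci start with the `a`
#' allele in the majority ("beneficial variation", frequency of `A` near 0);
#' the remaining `L - d` loci start near fixation for `A` ("deleterious
#' variation"). With the ancestral optimum at `zopt0 = (L - d) * gamma`
#' (the default) the starting population mean matches the old optimum.
#'
#' @param L positive integer, number of loci.
#' @param Ne positive integer, haploid population size.
#' @param gamma positive effect size per locus, in trait units.
#' @param mu forward mutation probability per locus per generation
#'   (`a -> A`), in `[0, 1]`.
#' @param nu back mutation probability (`A -> a`); defaults to `mu`
#'   (symmetric mutation, the case for which `theta_i = 2 * Ne * mu`).
#' @param sigma_before,sigma_after selection strength `sigma(t)` (inverse
#'   squared trait units) before (`t < 0`) and after (`t >= 0`) the
#'   environmental change. `sigma_after` defaults to `sigma_before`.
#' @param d integer, number of loci initialized with the `a` majority allele,
#'   `0 <= d <= L`.
#' @param zopt0 ancestral trait optimum; default `(L - d) * gamma`.
#' @param zopt_new new trait optimum after the change; must be `>= zopt0`.
#' @param sgv logical; if `FALSE` the population is started exactly at the
#'   majority-allele configuration and burn-in is skipped (adaptation from
#'   recurrent new mutation only).
#'
#' @return an object of class `"trait_model"`.
#' @seealso [gaussian_fitness()], [trait_mean()], [wf_simulate()],
#'   [ib_simulate()]
#' @export
#' @examples
#' m <- trait_model(L = 3, Ne = 1000, gamma = 1, mu = 2.5e-4,
#'                  sigma_before = 0.01, d = 3, zopt_new = 3, sgv = FALSE)
#' gaussian_fitness(1, t = 0, m)
trait_model <- function(L, Ne, gamma = 1, mu, nu = mu,
                        sigma_before, sigma_after = sigma_before,
                        d = L, zopt0 = (L - d) * gamma, zopt_new,
                        sgv = TRUE) {
  stopifnot(length(L) == 1L, L >= 1, L == as.integer(L))
  stopifnot(length(Ne) == 1L, Ne >= 1, Ne == as.integer(Ne))
  if (!(gamma > 0)) stop("'gamma' must be positive")
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]")
  if (nu < 0 || nu > 1) stop("'nu' must be in [0, 1]")
  if (!(sigma_before > 0) || !(sigma_after > 0))
    stop("selection strengths 'sigma_before'/'sigma_after' must be positive")
  if (d < 0 || d > L) stop("'d' must satisfy 0 <= d <= L")
  if (zopt_new < zopt0)
    stop("'zopt_new' must be >= 'zopt0' (optimum shifts upwards)")
  structure(
    list(L = as.integer(L), Ne = as.integer(Ne), gamma = gamma,
         mu = mu, nu = nu,
         sigma_before = sigma_before, sigma_after = sigma_after,
         d = as.integer(d), zopt0 = zopt0, zopt_new = zopt_new,
         sgv = isTRUE(sgv)),
    class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Additive trait model (haploid)\n")
  cat(sprintf("  L = %d loci, effect gamma = %g, Ne = %d\n",
              x$L, x$gamma, x$Ne))
  cat(sprintf("  mutation: mu = %g, nu = %g  (theta_locus = %g)\n",
              x$mu, x$nu, 2 * x$Ne * x$mu))
  cat(sprintf("  selection: sigma = %g (t < 0), %g (t >= 0); Ne*sigma*gamma^2 = %g / %g\n",
              x$sigma_before, x$sigma_after,
              x$Ne * x$sigma_before * x$gamma^2,
              x$Ne * x$sigma_after * x$gamma^2))
  cat(sprintf("  optimum: %g -> %g at t = 0; d = %d beneficial loci; SGV: %s\n",
              x$zopt0, x$zopt_new, x$d, if (x$sgv) "yes" else "no"))
  invisible(x)
}

#' Selection strength and trait optimum at a generation
#'
#' Both schedules are step functions: the environmental change happens
#' between generations -1 and 0, so `t < 0` returns the ancestral value and
#' `t >= 0` the post-change value.
#'
#' @param model a [trait_model()].
#' @param t integer generation (vectorized).
#' @return numeric vector.
#' @export
sigma_at <- function(model, t) {
  if (any(!is.finite(t))) stop("generation 't' must be finite")
  ifelse(t < 0, model$sigma_before, model$sigma_after)
}

#' @rdname sigma_at
#' @export
zopt_at <- function(model, t) {
  if (any(!is.finite(t))) stop("generation 't' must be finite")
  ifelse(t < 0, model$zopt0, model$zopt_new)
}

#' Gaussian stabilizing fitness
#'
#' `W(Z) = exp(-sigma(t)/2 * (Z - Zopt(t))^2)`: equals 1 at the optimum and
#' decays symmetrically with the squared distance from it.
#'
#' @param Z trait value(s).
#' @inheritParams sigma_at
#' @return positive numeric vector of Wrightian fitnesses.
#' @export
gaussian_fitness <- function(Z, t, model) {
  s <- sigma_at(model, t)
  exp(-s / 2 * (Z - zopt_at(model, t))^2)
}

#' Population state under linkage equilibrium
#'
#' A vector of `A`-allele frequencies, one per locus, plus the generation
#' index. Under linkage equilibrium this fully determines the population.
#'
#' @param p numeric vector of frequencies in `[0, 1]`.
#' @param t integer generation index.
#' @return an object of class `"frequency_state"`.
#' @export
frequency_state <- function(p, t = 0L) {
  if (any(p < 0 | p > 1)) stop("all frequencies must lie in [0, 1]")
  structure(list(p = as.numeric(p), t = as.integer(t)),
            class = "frequency_state")
}

#' Population mean trait value
#'
#' `Zbar = gamma * sum(p_i)`, linear in the frequencies and bounded by
#' `[0, L * gamma]`.
#'
#' @param state a [frequency_state()] or a bare numeric frequency vector.
#' @param model a [trait_model()].
#' @return scalar trait mean.
#' @export
trait_mean <- function(state, model) {
  p <- if (inherits(state, "frequency_state")) state$p else state
  model$gamma * sum(p)
}

#' Phenotypic stopping schedule ("pheno-time" waypoints)
#'
#' Snapshots of the full frequency vector are taken the first generation the
#' trait mean reaches `zopt0 + cz * gamma` for each waypoint `cz`, i.e.
#' adaptation is sampled at fixed phenotypic progress measured in mutational
#' steps, not at fixed times.
#'
#' @param cz_values strictly ascending positive waypoint values (units of
#'   `gamma` above the ancestral optimum).
#' @param max_generations cap on post-change generations; replicates that
#'   never reach a waypoint within the cap are flagged incomplete.
#' @return an object of class `"stop_schedule"`.
#' @export
stop_schedule <- function(cz_values, max_generations = 100000L) {
  cz <- as.numeric(cz_values)
  if (length(cz) < 1L) stop("need at least one waypoint")
  if (any(cz <= 0)) stop("all waypoints must be positive")
  if (is.unsorted(cz, strictly = TRUE)) stop("waypoints must be strictly ascending")
  stopifnot(max_generations >= 1)
  structure(list(cz_values = cz,
                 max_generations = as.integer(max_generations)),
            class = "stop_schedule")
}
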