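#' Wrightian sampling weight of the A allele
#'
#' Relative sampling weight of the `A_i` allele (the `a_i` weight is
#' normalized to 1) in the per-locus binomial update of the
#' linkage-equilibrium Wright-Fisher model,
#' `w = exp(sigma * gamma * ((Zopt - Zbar) - gamma/2 * (1 - 2 p)))`.
#' The first term is directional selection towards the optimum, the second
#' (dropped when `directional_only = TRUE`) is the disruptive-selection
#' component that pushes frequencies towards the boundaries once the mean is
#' close to the optimum.
#'
#' @param p frequency of `A` at the locus (vectorized; matrices allowed).
#' @param zbar current population trait mean (recycled against `p`; for a
#'   replicate-by-locus matrix `p`, pass one value per replicate/row).
#' @param t generation (selects `sigma(t)` and `Zopt(t)`).
#' @param model a [trait_model()].
#' @param directional_only drop the disruptive term (pure directional
#'   selection model).
#' @return positive weights, same shape as `p`.
#' @export
selection_weight <- function(p, zbar, t, model, directional_only = FALSE) {
  s <- sigma_at(model, t)
  g <- model$gamma
  term <- (zopt_at(model, t) - zbar)
  if (!directional_only) term <- term - g / 2 * (1 - 2 * p)
  exp(s * g * term)
}

#' Deterministic mutation update of an allele frequency
#'
#' `p' = p (1 - nu) + (1 - p) mu`; the fixed point is `mu / (mu + nu)`
#' (0.5 for symmetric rates).
#'
#' @param p frequency (vectorized).
#' @param mu forward mutation rate `a -> A`.
#' @param nu back mutation rate `A -> a`.
#' @return updated frequencies.
#' @export
mutation_update <- function(p, mu, nu) {
  p * (1 - nu) + (1 - p) * mu
}

#' One Wright-Fisher generation under linkage equilibrium
#'
#' Loci are updated independently given the shared trait mean: the mean is
#' computed once from the current (pre-mutation) state, then each locus
#' undergoes deterministic mutation followed by weighted binomial sampling of
#' `Ne` allele copies (selection + drift).
#'
#' @param state a [frequency_state()].
#' @param model a [trait_model()].
#' @param directional_only see [selection_weight()].
#' @return the [frequency_state()] of the next generation (`t + 1`).
#' @export
wf_generation <- function(state, model, directional_only = FALSE) {
  zbar <- trait_mean(state, model)
  p <- mutation_update(state$p, model$mu, model$nu)
  w <- selection_weight(p, zbar, state$t, model, directional_only)
  psel <- p * w / (p * w + (1 - p))
  k <- stats::rbinom(model$L, model$Ne, psel)
  frequency_state(k / model$Ne, state$t + 1L)
}

# Vectorized engine: P is a replicates x L matrix of frequencies, zbar a
# per-replicate vector (recycles correctly down the columns of P).
wf_step_matrix <- function(P, model, t, directional_only) {
  zbar <- model$gamma * rowSums(P)
  P <- mutation_update(P, model$mu, model$nu)
  w <- selection_weight(P, zbar, t, model, directional_only)
  psel <- P * w / (P * w + (1 - P))
  matrix(stats::rbinom(length(P), model$Ne, psel),
         nrow = nrow(P)) / model$Ne
}

wf_init_matrix <- function(model, replicates) {
  P <- matrix(1, replicates, model$L)
  if (model$d > 0L) P[, seq_len(model$d)] <- 0
  P
}

#' Equilibrate a linkage-equilibrium population to mutation-selection-drift
#' balance
#'
#' Starts from the majority-allele configuration (`d` loci at `p = 0`,
#' `L - d` at `p = 1`) and runs the Wright-Fisher update for `generations`
#' burn-in generations under the ancestral optimum. Returns the standing
#' genetic variation (SGV) state at `t = 0`.
#'
#' @param model a [trait_model()].
#' @param generations burn-in length; the default is `8 * Ne`.
#' @param replicates number of independent replicate populations.
#' @param directional_only see [selection_weight()].
#' @return a `replicates x L` matrix of frequencies at `t = 0`.
#' @export
wf_equilibrate <- function(model, generations = 8L * model$Ne,
                           replicates = 1L, directional_only = FALSE) {
  stopifnot(generations >= 0)
  P <- wf_init_matrix(model, replicates)
  if (!model$sgv) return(P)
  if (model$mu == 0 && model$nu == 0) return(P)  # boundaries are absorbing
  for (t in seq_len(generations)) {
    P <- wf_step_matrix(P, model, t - generations - 1L, directional_only)
  }
  P
}

#' Wright-Fisher simulation sampled at phenotypic waypoints
#'
#' Full linkage-equilibrium forward simulation: burn-in to
#' mutation-selection-drift balance under the ancestral optimum (skipped when
#' `model$sgv` is `FALSE`), environmental change at `t = 0`, then evolution
#' towards the new optimum with a snapshot of all allele frequencies at the
#' first generation the trait mean reaches each waypoint of `stops`.
#' Replicates that fail to reach a waypoint within
#' `stops$max_generations` are flagged incomplete (never silently dropped).
#'
#' All replicates are advanced together through vectorized binomial updates
#' drawing from the current R random number stream; set a seed (or pass
#' `seed`) for reproducible runs.
#'
#' @param model a [trait_model()].
#' @param stops a [stop_schedule()].
#' @param replicates number of replicate populations.
#' @param directional_only simulate the pure directional selection model.
#' @param equilibration burn-in generations (default `8 * Ne`).
#' @param seed optional integer seed applied with [set.seed()].
#' @param init optional initial `replicates x L` frequency matrix (or single
#'   frequency vector) at `t = 0`, bypassing initialization and burn-in.
#' @return an object of class `"architecture_sample"`: a list with
#'   \describe{
#'   \item{freqs}{`replicates x stops x L` array of snapshot frequencies}
#'   \item{generation}{`replicates x stops` matrix of crossing generations}
#'   \item{completed}{`replicates x stops` logical matrix}
#'   \item{sgv}{`replicates x L` matrix of frequencies at `t = 0`}
#'   \item{model, stops, directional_only, seed}{run provenance}
#'   }
#' @export
wf_simulate <- function(model, stops, replicates,
                        directional_only = FALSE,
                        equilibration = 8L * model$Ne,
                        seed = NULL, init = NULL) {
  stopifnot(inherits(model, "trait_model"), inherits(stops, "stop_schedule"))
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (any(stops$cz_values > model$L))
    stop("waypoints beyond L mutational steps can never be reached")

  if (is.null(init)) {
    P <- wf_equilibrate(model, equilibration, replicates, directional_only)
  } else {
    P <- if (is.matrix(init)) init else
      matrix(init, replicates, model$L, byrow = TRUE)
    stopifnot(nrow(P) == replicates, ncol(P) == model$L)
  }
  sgv <- P

  ncz <- length(stops$cz_values)
  thresholds <- model$zopt0 + stops$cz_values * model$gamma
  freqs <- array(NA_real_, dim = c(replicates, ncz, model$L))
  generation <- matrix(NA_integer_, replicates, ncz)
  completed <- matrix(FALSE, replicates, ncz)
  # next waypoint index per replicate
  nxt <- rep(1L, replicates)

  t <- 0L
  repeat {
    zbar <- model$gamma * rowSums(P)
    # record any waypoint crossings at the current generation
    repeat {
      active <- which(nxt <= ncz)
      hit <- active[zbar[active] >= thresholds[nxt[active]]]
      if (length(hit) == 0L) break
      for (i in hit) {
        freqs[i, nxt[i], ] <- P[i, ]
        generation[i, nxt[i]] <- t
        completed[i, nxt[i]] <- TRUE
        nxt[i] <- nxt[i] + 1L
      }
    }
    running <- nxt <= ncz
    if (!any(running) || t >= stops$max_generations) break
    # advance only unfinished replicates
    idx <- which(running)
    P[idx, ] <- wf_step_matrix(P[idx, , drop = FALSE], model, t,
                               directional_only)
    t <- t + 1L
  }

  structure(list(freqs = freqs, generation = generation,
                 completed = completed, sgv = sgv,
                 model = model, stops = stops,
                 directional_only = directional_only,
                 engine = "wf_le", seed = seed),
            class = "architecture_sample")
}

#' @export
print.architecture_sample <- function(x, ...) {
  cat(sprintf("Architecture sample (%s engine)\n", x$engine))
  cat(sprintf("  %d replicates, L = %d loci, waypoints cz = %s\n",
              nrow(x$completed), x$model$L,
              paste(x$stops$cz_values, collapse = ", ")))
  cat(sprintf("  completion rate per waypoint: %s\n",
              paste(sprintf("%.3f", colMeans(x$completed)), collapse = ", ")))
  invisible(x)
}

#' Completion rate of an architecture sample
#'
#' Fraction of replicates that reached each phenotypic waypoint within the
#' generation cap.
#'
#' @param sample an `architecture_sample`.
#' @return named numeric vector, one entry per waypoint.
#' @export
completion_rate <- function(sample) {
  r <- colMeans(sample$completed)
  names(r) <- paste0("cz=", sample$stops$cz_values)
  r
}
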