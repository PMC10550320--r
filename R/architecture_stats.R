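#' Background mutation rate
#'
#' `theta_bg = 2 * Ne * mu * (d - 1)`: the population-scaled input of
#' beneficial mutations at loci redundant to a focal adaptive allele. This
#' single composite parameter governs the type of adaptive architecture,
#' from single sweeps (small values) to collective frequency shifts (large
#' values).
#'
#' @param Ne haploid population size.
#' @param mu per-locus forward mutation rate per generation.
#' @param d number of loci carrying the `a` majority allele before the
#'   environmental change (`>= 1`).
#' @return nonnegative scalar.
#' @export
theta_bg <- function(Ne, mu, d) {
  if (d < 1) stop("'d' must be >= 1")
  2 * Ne * mu * (d - 1)
}

#' Effective background mutation rate after partial adaptation
#'
#' When a trait with finitely many loci adapts over several mutational
#' steps, the supply of loci still able to compete shrinks; the background
#' rate relevant for the next step is rescaled by the ratio of remaining to
#' initial competitor loci, `theta_bg * remaining / initial_competitors`
#' (for a 10-locus trait sampled at step `k` with 7 initial competitors this
#' is `theta_bg * (10 - k) / 7`).
#'
#' @param theta_bg initial background mutation rate.
#' @param remaining number of loci still available to compete (`>= 0`).
#' @param initial_competitors number of competitor loci at the first step
#'   (`>= 1`).
#' @return rescaled rate.
#' @export
theta_bg_eff <- function(theta_bg, remaining, initial_competitors) {
  stopifnot(remaining >= 0, initial_competitors >= 1)
  theta_bg * remaining / initial_competitors
}

#' Classify the adaptive regime from the background mutation rate
#'
#' Advisory labels for the architecture type: `"sweep"` below the lower
#' threshold, `"shift"` at or above the upper one, `"partial"` in between.
#' The transition is gradual with no sharp demarcation; the default
#' thresholds (0.1 and 10) encode the conventional boundaries as half-open
#' intervals.
#'
#' @param theta_bg nonnegative background mutation rate(s); vectorized.
#' @param thresholds length-2 ascending numeric vector of regime boundaries.
#' @return character vector with values `"sweep"`, `"partial"`, `"shift"`.
#' @export
classify_regime <- function(theta_bg, thresholds = c(0.1, 10)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  if (any(theta_bg < 0)) stop("'theta_bg' must be nonnegative")
  ifelse(theta_bg < thresholds[1], "sweep",
         ifelse(theta_bg < thresholds[2], "partial", "shift"))
}

# row-wise descending sort; ties broken by column (locus) index because
# sort() is stable on the reversed columns
sort_rows_desc <- function(M) {
  t(apply(M, 1L, function(x) sort(x, decreasing = TRUE, method = "radix")))
}

rank_labels <- function(k) {
  if (k == 1L) return("major")
  c("major", paste0("minor", seq_len(k - 1L)))
}

new_ordered_marginals <- function(values, source, cz, bins = 50L) {
  colnames(values) <- rank_labels(ncol(values))
  structure(list(values = values, bins = as.integer(bins),
                 breaks = seq(0, 1, length.out = bins + 1L),
                 source = source, cz = cz),
            class = "ordered_marginals")
}

#' Size-ordered marginal distributions of an architecture sample
#'
#' Within each replicate the loci are sorted by the frequency of their `A`
#' allele (descending). The `L - keep` top-ranked loci -- the ancestral
#' majority-`A` loci, assumed (nearly) fixed -- are discarded, and the
#' remaining ranks are labelled major, minor1, minor2, ... The rank-wise
#' collections of frequencies across replicates are the size-ordered
#' marginals used to visualize the joint distribution. Only replicates that
#' completed the requested waypoint enter.
#'
#' @param sample an `architecture_sample` (from [wf_simulate()] or
#'   [ib_simulate()]).
#' @param stop index of the phenotypic waypoint to use (default first).
#' @param keep number of lowest ranks to keep; defaults to `model$d`
#'   (discard the `L - d` ancestral-majority loci).
#' @param bins number of shared equal-width histogram bins on `[0, 1]`.
#' @return an object of class `"ordered_marginals"`: list with a
#'   `replicates x keep` matrix `values` (columns major, minor1, ...) and
#'   shared binning metadata.
#' @export
ordered_marginals <- function(sample, stop = 1L, keep = NULL, bins = 50L) {
  stopifnot(inherits(sample, "architecture_sample"))
  L <- sample$model$L
  if (is.null(keep)) keep <- sample$model$d
  if (keep < 1L || keep > L) stop("'keep' must be in 1..L")
  ok <- sample$completed[, stop]
  M <- sample$freqs[ok, stop, , drop = FALSE]
  dim(M) <- c(sum(ok), L)
  S <- sort_rows_desc(M)
  kept <- S[, (L - keep + 1L):L, drop = FALSE]
  # reorder so column 1 is the largest *kept* rank (the major locus)
  new_ordered_marginals(kept[, seq_len(keep), drop = FALSE],
                        source = sample$engine,
                        cz = sample$stops$cz_values[stop], bins = bins)
}

#' @export
print.ordered_marginals <- function(x, ...) {
  cat(sprintf("Ordered marginals (%s), %d replicates, %d ranks, cz = %g\n",
              x$source, nrow(x$values), ncol(x$values), x$cz))
  m <- colMeans(x$values)
  cat("  mean frequency per rank:\n")
  print(round(m, 4))
  invisible(x)
}

#' Per-rank histogram of ordered marginals
#'
#' Bin counts on the shared equal-width binning, one column per rank.
#'
#' @param om an [ordered_marginals()] object.
#' @return matrix `bins x ranks` of counts.
#' @export
marginal_histogram <- function(om) {
  stopifnot(inherits(om, "ordered_marginals"))
  apply(om$values, 2L, function(v)
    tabulate(findInterval(v, om$breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = om$bins))
}

#' @export
as.data.frame.ordered_marginals <- function(x, ...) {
  k <- ncol(x$values)
  data.frame(replicate = rep(seq_len(nrow(x$values)), times = k),
             rank = rep(colnames(x$values), each = nrow(x$values)),
             p = as.vector(x$values))
}

#' Trait-distribution cumulants from allele frequencies
#'
#' Under linkage equilibrium the scaled genetic variance of the trait is
#' `vg = sum(p_i (1 - p_i))` (units `gamma^2`) and the scaled third cumulant
#' (skew) is `kappa3 = sum(p_i (1 - p_i) (1 - 2 p_i))` (units `gamma^3`).
#'
#' @param p numeric frequency vector.
#' @return named vector `c(vg, kappa3)`.
#' @export
trait_cumulants <- function(p) {
  q <- p * (1 - p)
  c(vg = sum(q), kappa3 = sum(q * (1 - 2 * p)))
}

#' Cumulant series over phenotypic waypoints (oscillation diagnostic)
#'
#' Mean trait variance and skew across replicates at each waypoint of an
#' architecture sample. With waypoints at half-integer mutational steps the
#' series exposes the period-`gamma` oscillation of the joint distribution:
#' in the sweep regime a lone allele crossing `p = 0.5` maximizes the
#' variance mid-step, so `vg` peaks at half steps; the oscillation
#' amplitude shrinks as the background mutation rate grows and the response
#' becomes collective.
#'
#' @param sample an `architecture_sample`.
#' @return data frame with columns `cz`, `n` (completed replicates),
#'   `mean_vg`, `mean_kappa3`.
#' @export
periodicity_diagnostic <- function(sample) {
  stopifnot(inherits(sample, "architecture_sample"))
  cz <- sample$stops$cz_values
  out <- data.frame(cz = cz, n = NA_integer_,
                    mean_vg = NA_real_, mean_kappa3 = NA_real_)
  for (s in seq_along(cz)) {
    ok <- sample$completed[, s]
    out$n[s] <- sum(ok)
    if (any(ok)) {
      M <- sample$freqs[ok, s, , drop = FALSE]
      dim(M) <- c(sum(ok), sample$model$L)
      cum <- t(apply(M, 1L, trait_cumulants))
      out$mean_vg[s] <- mean(cum[, "vg"])
      out$mean_kappa3[s] <- mean(cum[, "kappa3"])
    }
  }
  out
}

#' Theory cumulant series over waypoints
#'
#' Same diagnostic as [periodicity_diagnostic()] but computed from the
#' analytical conditioned distribution via [sample_joint()] at each
#' waypoint, for a trait whose polymorphic basis at every step is `d` loci
#' with equal rates `theta`.
#'
#' @param theta positive scaled mutation rates (length `d`).
#' @param cz_values waypoints, each in `(0, d)`.
#' @param n samples per waypoint.
#' @return data frame with columns `cz`, `mean_vg`, `mean_kappa3`.
#' @export
theory_cumulant_series <- function(theta, cz_values, n = 2000L) {
  res <- lapply(cz_values, function(cz) {
    S <- sample_joint(theta, cz, n)
    cum <- t(apply(unclass(S), 1L, trait_cumulants))
    c(mean(cum[, "vg"]), mean(cum[, "kappa3"]))
  })
  res <- do.call(rbind, res)
  data.frame(cz = cz_values, mean_vg = res[, 1], mean_kappa3 = res[, 2])
}
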