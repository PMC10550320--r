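#' Multi-type Yule process of the establishment phase
#'
#' During the early, stochastic phase of adaptation the copies of beneficial
#' alleles that escape drift loss ("immortal lineages") are described by a
#' multi-type Yule process: new lineages are seeded at locus `i` at rate
#' `theta_i` (population-scaled mutation rate `2 Ne mu_i`) and every existing
#' lineage splits at rate 1. The common establishment-probability factor
#' cancels from all rates under the time rescaling and is never computed.
#' This function simulates the embedded jump chain until `n_lines` lineages
#' exist: at each event a new lineage arises at locus `i` with probability
#' `theta_i / (sum(theta) + K)` and an existing lineage at locus `i` splits
#' with probability `k_i / (sum(theta) + K)`, where `k_i` is the current
#' lineage count at locus `i` and `K` their total.
#'
#' @param theta vector of positive per-locus scaled mutation rates
#'   (length `d >= 2`).
#' @param n_lines target total number of immortal lineages (`>= 1`).
#' @return an object of class `"yule_state"`: list with integer `counts`
#'   (per-locus lineage numbers) and `total`.
#' @export
yule_simulate <- function(theta, n_lines) {
  stopifnot(length(theta) >= 2L, all(theta > 0), n_lines >= 1)
  d <- length(theta)
  counts <- integer(d)
  total <- 0L
  while (total < n_lines) {
    i <- sample.int(2L * d, 1L, prob = c(theta, counts))
    if (i > d) i <- i - d
    counts[i] <- counts[i] + 1L
    total <- total + 1L
  }
  structure(list(counts = counts, total = total), class = "yule_state")
}

#' Solve for the scale of the odds vector under the trait-mean constraint
#'
#' Given positive ratios `G` (proportional to the allelic odds
#' `u_i = p_i / (1 - p_i)`), finds the unique `lambda > 0` with
#' `sum(lambda * G / (1 + lambda * G)) == cz`. The map is strictly
#' increasing in `lambda`, so the root is bracketed by doubling/halving from
#' the equal-odds starting value and polished with safeguarded Newton steps
#' until the constraint holds to `1e-10`.
#'
#' @param G positive numeric vector.
#' @param cz constraint value, `0 < cz < length(G)`.
#' @return scalar `lambda`.
#' @export
solve_lambda <- function(G, cz) {
  d <- length(G)
  if (any(!is.finite(G)) || any(G <= 0)) stop("'G' must be finite and positive")
  if (!is.finite(cz) || cz <= 0 || cz >= d)
    stop("'cz' must lie strictly between 0 and length(G)")
  f <- function(l) sum(l * G / (1 + l * G)) - cz
  lam <- cz / ((d - cz) * mean(G))
  if (abs(f(lam)) > 1e-12) {
    lo <- lam / 2; hi <- lam * 2
    while (f(lo) > 0) lo <- lo / 2
    while (f(hi) < 0) hi <- hi * 2
    lam <- stats::uniroot(f, c(lo, hi), tol = 1e-15)$root
  }
  # Newton polish on the constraint residual
  for (k in 1:50) {
    r <- f(lam)
    if (abs(r) <= 1e-10) break
    fp <- sum(G / (1 + lam * G)^2)
    step <- r / fp
    lam2 <- lam - step
    if (!is.finite(lam2) || lam2 <= 0) lam2 <- lam / 2
    lam <- lam2
  }
  lam
}

#' Sample joint allele frequencies conditioned on the trait mean
#'
#' Draws from the joint distribution of the frequencies of `d` beneficial
#' alleles at the moment the population trait mean has advanced by `cz`
#' mutational steps. Uses the gamma representation of the inverted Dirichlet
#' ratio law: `G_i ~ Gamma(theta_i, 1)` independently, the odds are
#' `u_i = lambda * G_i` with `lambda` solving
#' `sum(p_i) = sum(u_i / (1 + u_i)) = cz`, and `p_i = u_i / (1 + u_i)`.
#' The result depends only on the scaled mutation rates `theta`, not on any
#' selection parameter.
#'
#' @param theta vector of positive scaled mutation rates (length `d >= 2`).
#' @param cz phenotypic constraint, `0 < cz < d` (in mutational steps).
#' @param n number of samples.
#' @return an `n x d` matrix of frequencies, each row summing to `cz` to
#'   within `1e-10`; class `"conditioned_sample"` with attributes `theta`
#'   and `cz`.
#' @export
sample_joint <- function(theta, cz, n) {
  d <- length(theta)
  stopifnot(d >= 2L, all(theta > 0), n >= 1)
  if (cz <= 0 || cz >= d)
    stop("'cz' must lie strictly in (0, d): constraint unsatisfiable otherwise")
  G <- matrix(stats::rgamma(n * d, shape = rep(theta, each = n)), n, d)
  # Gamma(theta -> 0) draws can underflow to exactly 0; clamp to the
  # smallest positive normal to preserve the open-support contract.
  G[G < .Machine$double.xmin] <- .Machine$double.xmin
  P <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    lam <- solve_lambda(G[i, ], cz)
    P[i, ] <- lam * G[i, ] / (1 + lam * G[i, ])
  }
  structure(P, theta = theta, cz = cz, class = c("conditioned_sample", "matrix"))
}

#' Joint density of minor-coordinate frequencies given the trait mean
#'
#' Density of `(p_2, ..., p_d)` under the conditioned joint distribution;
#' the first coordinate is implied by the constraint,
#' `p_1 = cz - sum(p_2..p_d)`. The density is the pushforward of the
#' inverted-Dirichlet law of the odds ratios under the trait-mean
#' constraint. In terms of odds `u_i = p_i/(1-p_i)`,
#' \deqn{P[\{p_i\} | c_Z] = \frac{1}{B(\Theta)}
#'   \prod_{i=2}^{d} \frac{p_i^{\Theta_i - 1}}{(1-p_i)^{\Theta_i + 1}}
#'   \; u_1^{\Theta_1} \Big(u_1 + \sum_{i\ge 2} u_i\Big)^{-\sum_i \Theta_i}
#'   \Big(1 + \frac{\sum_{i \ge 2} p_i (1-p_i)}{p_1 (1-p_1)}\Big),}
#' with `B` the multivariate beta function
#' `prod(gamma(theta)) / gamma(sum(theta))`. Evaluation is in log space so
#' large `theta` (up to order 1000) and near-boundary points are handled.
#' Returns 0 outside the support (any coordinate, including the implied
#' `p_1`, outside `(0, 1)`).
#'
#' @param p_minor numeric vector `(p_2, ..., p_d)` (length `d - 1`).
#' @param cz constraint value in `(0, d)`.
#' @param theta positive scaled mutation rates, length `d`.
#' @param log return the log density (`-Inf` outside the support).
#' @return scalar density (or log density).
#' @seealso [marginal_frequency_density()] for the closed-form `d = 2`
#'   marginal.
#' @export
joint_frequency_density <- function(p_minor, cz, theta, log = FALSE) {
  d <- length(theta)
  stopifnot(length(p_minor) == d - 1L, all(theta > 0))
  if (cz <= 0 || cz >= d) stop("'cz' must lie strictly in (0, d)")
  s <- sum(p_minor)
  p1 <- cz - s
  if (p1 <= 0 || p1 >= 1 || any(p_minor <= 0) || any(p_minor >= 1)) {
    return(if (log) -Inf else 0)
  }
  th1 <- theta[1]; thm <- theta[-1]
  u1 <- p1 / (1 - p1)
  su <- sum(p_minor / (1 - p_minor))
  lB <- sum(lgamma(theta)) - lgamma(sum(theta))
  ll <- -lB +
    sum((thm - 1) * log(p_minor) - (thm + 1) * log1p(-p_minor)) +
    th1 * log(u1) - sum(theta) * log(u1 + su) +
    log1p(sum(p_minor * (1 - p_minor)) / (p1 * (1 - p1)))
  if (log) ll else exp(ll)
}

#' Closed-form two-locus marginal density given the trait mean
#'
#' For `d = 2` loci the marginal distribution of the second frequency
#' (`p_2 = p`) conditioned on `p_1 + p_2 = cz` has the closed form
#' \deqn{P[p | c_Z] = \frac{\Gamma(\Theta_1+\Theta_2)}
#'   {\Gamma(\Theta_1)\Gamma(\Theta_2)}
#'   \frac{p(1-p) + (c_Z-p)(1+p-c_Z)}{(c_Z - 2p(c_Z-p))^{\Theta_1+\Theta_2}}
#'   ((c_Z-p)(1-p))^{\Theta_1-1} ((1+p-c_Z)p)^{\Theta_2-1},}
#' supported on `p` in `(max(0, cz - 1), min(1, cz))`. Vectorized in `p`;
#' 0 outside the support.
#'
#' @param p frequency value(s).
#' @param cz constraint value in `(0, 2)`.
#' @param theta1,theta2 positive scaled mutation rates of the two loci.
#' @param log return log density.
#' @return numeric vector of densities.
#' @export
marginal_frequency_density <- function(p, cz, theta1, theta2, log = FALSE) {
  if (!(theta1 > 0) || !(theta2 > 0)) stop("'theta1'/'theta2' must be positive")
  if (cz <= 0 || cz >= 2) stop("'cz' must lie strictly in (0, 2)")
  lo <- max(0, cz - 1); hi <- min(1, cz)
  out <- rep(if (log) -Inf else 0, length(p))
  ok <- is.finite(p) & p > lo & p < hi
  if (any(ok)) {
    pp <- p[ok]
    ll <- lgamma(theta1 + theta2) - lgamma(theta1) - lgamma(theta2) +
      log(pp * (1 - pp) + (cz - pp) * (1 + pp - cz)) -
      (theta1 + theta2) * log(cz - 2 * pp * (cz - pp)) +
      (theta1 - 1) * (log(cz - pp) + log1p(-pp)) +
      (theta2 - 1) * (log1p(pp - cz) + log(pp))
    out[ok] <- if (log) ll else exp(ll)
  }
  out
}

#' Size-ordered marginal samples from the analytical theory
#'
#' Draws `n` joint architectures from [sample_joint()] and returns the
#' rank-ordered frequencies (major locus = largest, then first minor,
#' second minor, ...) as an [ordered_marginals()] object, directly
#' comparable with ordered marginals computed from simulation output.
#'
#' @inheritParams sample_joint
#' @return an object of class `"ordered_marginals"`.
#' @export
ordered_marginal_theory <- function(theta, cz, n) {
  S <- sample_joint(theta, cz, n)
  new_ordered_marginals(sort_rows_desc(unclass(S)), source = "theory",
                        cz = cz)
}
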