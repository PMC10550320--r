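test_that("selection weight reduces to 1 without selection pressure and matches the formula", {
  m <- trait_model(L = 3, Ne = 1000, gamma = 1, mu = 0,
                   sigma_before = 0.01, d = 3, zopt0 = 0, zopt_new = 2)
  # both selection terms vanish: mean at optimum, p = 1/2
  expect_equal(selection_weight(0.5, zbar = 2, t = 0, m), 1)
  # directional-only model: weight 1 at the optimum for every frequency
  for (p in c(0, 0.1, 0.5, 0.9, 1)) {
    expect_equal(selection_weight(p, zbar = 2, t = 0, m,
                                  directional_only = TRUE), 1)
  }
  # independent scalar evaluation: sigma*gamma^2 = 0.01, gap 2*gamma, p = 0
  expect_equal(selection_weight(0, zbar = 0, t = 0, m),
               exp(0.01 * (2 - 0.5)))
  # directional-only drops the disruptive term
  expect_equal(selection_weight(0, zbar = 0, t = 0, m,
                                directional_only = TRUE), exp(0.01 * 2))
})

test_that("mutation update has the mutation-balance fixed point", {
  expect_equal(mutation_update(0.37, 0, 0), 0.37)
  expect_equal(mutation_update(0.5, 1e-4, 1e-4), 0.5)
  expect_equal(mutation_update(0, 1e-5, 1e-5), 1e-5)
  mu <- 3e-4; nu <- 1e-4
  expect_equal(mutation_update(mu / (mu + nu), mu, nu), mu / (mu + nu))
})

test_that("Wright-Fisher generation respects absorbing boundaries and the neutral martingale", {
  m0 <- trait_model(L = 4, Ne = 200, gamma = 1, mu = 0, nu = 0,
                    sigma_before = 0.01, d = 2, zopt_new = 4)
  st <- frequency_state(c(0, 0, 1, 1), t = 0)
  set.seed(10)
  for (i in 1:10) {
    st2 <- wf_generation(st, m0)
    expect_equal(st2$p, c(0, 0, 1, 1))
  }
  # no selection pressure at the optimum (directional-only), no mutation:
  # E[p'] = p
  mneu <- trait_model(L = 1, Ne = 100, gamma = 1, mu = 0, nu = 0,
                      sigma_before = 0.05, d = 1, zopt0 = 0.3,
                      zopt_new = 0.3)
  set.seed(11)
  p1 <- replicate(4000, wf_generation(frequency_state(0.3), mneu,
                                      directional_only = TRUE)$p)
  se <- sqrt(0.3 * 0.7 / 100 / 4000)
  expect_lt(abs(mean(p1) - 0.3), 4 * se)
})

test_that("one-generation mean change matches the integrated deterministic dynamics", {
  # oracle: RK4 integration of the single-locus equation
  #   dp/dt = p(1-p) sigma gamma ((Zopt - Zbar) - gamma/2 (1-2p)) + mu(1-p) - nu p
  # over one generation, with the loci coupled through Zbar
  sg <- 0.01; mu <- 1e-4
  ode_step <- function(p, zopt, h = 1e-3) {
    rhs <- function(p) {
      zbar <- sum(p)
      p * (1 - p) * sg * ((zopt - zbar) - 0.5 * (1 - 2 * p)) +
        mu * (1 - p) - mu * p
    }
    for (i in seq_len(round(1 / h))) {
      k1 <- rhs(p); k2 <- rhs(p + h / 2 * k1)
      k3 <- rhs(p + h / 2 * k2); k4 <- rhs(p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    p
  }
  p0 <- c(0.05, 0.1, 0.2)
  expected <- ode_step(p0, zopt = 3)
  Ne <- 1e6
  m <- trait_model(L = 3, Ne = Ne, gamma = 1, mu = mu, sigma_before = sg,
                   d = 3, zopt_new = 3, sgv = FALSE)
  set.seed(12)
  sims <- replicate(200, wf_generation(frequency_state(p0), m)$p)
  mc_se <- sqrt(max(p0 * (1 - p0)) / Ne / 200)
  # agreement to the one-generation discretization error O(sigma^2) plus
  # Monte Carlo noise
  expect_lt(max(abs(rowMeans(sims) - expected)), 1e-3 + 4 * mc_se)
})

test_that("odds ratios are invariant under pure directional selection", {
  # oracle: RK4 on dp/dt = sigma gamma p (1-p) (Zopt - Zbar), 3 coupled loci
  sg <- 0.05; zopt <- 3
  rhs <- function(p) p * (1 - p) * sg * (zopt - sum(p))
  p <- c(0.01, 0.03, 0.07)
  u0 <- p / (1 - p)
  h <- 1e-3
  ratios <- c()
  for (i in seq_len(30000)) {
    k1 <- rhs(p); k2 <- rhs(p + h / 2 * k1)
    k3 <- rhs(p + h / 2 * k2); k4 <- rhs(p + h * k3)
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% 5000 == 0) {
      u <- p / (1 - p)
      ratios <- rbind(ratios, c(u[1] / u[2], u[1] / u[3], u[2] / u[3]))
    }
  }
  expect_gt(sum(p), 1.2)  # trajectory actually adapted
  r0 <- c(u0[1] / u0[2], u0[1] / u0[3], u0[2] / u0[3])
  for (k in 1:3) {
    expect_lt(max(abs(ratios[, k] / r0[k] - 1)), 1e-6)
  }
})

test_that("equilibration builds a U-shaped standing variation and mirrors under label symmetry", {
  # no mutation: the initial configuration is absorbing
  m0 <- trait_model(L = 6, Ne = 200, gamma = 1, mu = 0, nu = 0,
                    sigma_before = 0.05, d = 3, zopt_new = 5)
  P <- wf_equilibrate(m0, generations = 50, replicates = 5)
  expect_true(all(P[, 1:3] == 0) && all(P[, 4:6] == 1))
  # strong selection, small mutation: frequencies hug the boundaries
  Ne <- 500
  m <- trait_model(L = 10, Ne = Ne, gamma = 1, mu = 2e-5,
                   sigma_before = 100 / Ne, d = 5, zopt_new = 8)
  set.seed(13)
  P <- wf_equilibrate(m, generations = 8 * Ne, replicates = 200)
  minor <- cbind(P[, 1:5], 1 - P[, 6:10])  # minor-allele frequencies
  expect_lt(mean(minor), 0.05)
  # label symmetry at the mid-range optimum: p at a-majority loci mirrors
  # 1-p at A-majority loci
  expect_lt(abs(mean(P[, 1:5]) - mean(1 - P[, 6:10])), 0.01)
})

test_that("pheno-time snapshots record first passage, overshoot, and incompleteness", {
  m <- model_3locus_new_mutation(Ne = 1000, theta_bg = 1)
  st <- stop_schedule(1, max_generations = 500000)
  # immediate crossing: initial state already beyond the waypoint
  s0 <- wf_simulate(m, st, replicates = 3, seed = 20,
                    init = c(0.5, 0.4, 0.3))
  expect_true(all(s0$completed))
  expect_true(all(s0$generation == 0L))
  expect_equal(s0$freqs[2, 1, ], c(0.5, 0.4, 0.3))
  # crossing overshoot audit: sum of frequencies at the snapshot is >= cz
  # and close to it (one-generation discretization)
  set.seed(21)
  s <- wf_simulate(m, st, replicates = 400, directional_only = TRUE)
  expect_equal(unname(completion_rate(s)), 1)
  sums <- rowSums(s$freqs[, 1, ])
  expect_true(all(sums >= 1))
  expect_lt(max(sums), 1.25)
  expect_lt(abs(mean(sums) - 1), 0.05)
  # replicates that cannot reach the waypoint are flagged, not dropped
  mslow <- trait_model(L = 3, Ne = 200, gamma = 1, mu = 1e-7,
                       sigma_before = 0.01, d = 3, zopt_new = 3, sgv = FALSE)
  sinc <- wf_simulate(mslow, stop_schedule(1, max_generations = 10),
                      replicates = 5, seed = 22)
  expect_equal(unname(completion_rate(sinc)), 0)
  expect_true(all(is.na(sinc$generation)))
  expect_equal(dim(sinc$freqs), c(5, 1, 3))
})

test_that("sweep regime yields single sweeps; runs are reproducible from the seed", {
  m <- model_3locus_new_mutation(Ne = 1000, theta_bg = 0.01)
  st <- stop_schedule(1, max_generations = 2000000)
  s <- wf_simulate(m, st, replicates = 60, directional_only = TRUE, seed = 23)
  om <- ordered_marginals(s)$values
  # low background rate: the major locus sweeps, minors stay near 0
  expect_gt(mean(om[, "major"]), 0.9)
  expect_lt(mean(om[, "minor1"]), 0.1)
  s2 <- wf_simulate(m, st, replicates = 60, directional_only = TRUE, seed = 23)
  expect_identical(s$freqs, s2$freqs)
  expect_identical(s$generation, s2$generation)
})
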