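# Shared model constructors for the test suite.

# Three-locus trait adapting from a monomorphic start (no SGV) by recurrent
# new mutation: ancestral optimum 0, new optimum 3*gamma, sampled at cz = 1.
# theta_bg = 4*Ne*mu.
model_3locus_new_mutation <- function(Ne = 1000, theta_bg = 1,
                                      Ne_sigma_gamma2 = 10) {
  trait_model(L = 3, Ne = Ne, gamma = 1, mu = theta_bg / (4 * Ne),
              sigma_before = Ne_sigma_gamma2 / Ne,
              d = 3, zopt_new = 3, sgv = FALSE)
}

# Ten-locus trait adapting from standing variation: ancestral optimum
# 2*gamma (d = 8 beneficial loci, 7 competitors), new optimum 8*gamma.
# theta_bg = 14*Ne*mu.
model_10locus_sgv <- function(Ne = 500, theta_bg = 1,
                              Ne_sigma_gamma2 = 10) {
  trait_model(L = 10, Ne = Ne, gamma = 1, mu = theta_bg / (14 * Ne),
              sigma_before = Ne_sigma_gamma2 / Ne,
              d = 8, zopt_new = 8, sgv = TRUE)
}

# Build an architecture_sample object directly from a replicate x locus
# frequency matrix observed at a single waypoint (for descriptor tests).
manual_sample <- function(freqs, cz = 1, model = NULL) {
  R <- nrow(freqs); L <- ncol(freqs)
  if (is.null(model))
    model <- trait_model(L = L, Ne = 100, gamma = 1, mu = 1e-4,
                         sigma_before = 0.01, d = L, zopt_new = L,
                         sgv = FALSE)
  arr <- array(freqs, dim = c(R, 1, L))
  structure(list(freqs = arr,
                 generation = matrix(0L, R, 1),
                 completed = matrix(TRUE, R, 1),
                 sgv = freqs, model = model,
                 stops = stop_schedule(cz),
                 directional_only = FALSE, engine = "manual", seed = NULL),
            class = "architecture_sample")
}
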