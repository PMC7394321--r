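# Shared fixtures: everything is generated in code at test time.

default_seq <- function() seq_params(10000, 100, 35)

# Noiseless model-expected spectrum for a known truth.
noiseless_obs <- function(M = 300, L = 12500, T = "exp", d = 0.03,
                          q_max = 60, seq = default_seq()) {
  expected_contig_spectrum(model_params(M, L, T, d), seq, q_max = q_max)
}

# A small random Monte-Carlo spectrum, cheap enough for optimizer tests.
small_mc_obs <- function(seed, M0 = 4, R = 500) {
  sq <- seq_params(R, 100, 35)
  pop <- simulate_population(M0, "pl", 0.5, 50000, v = 0, seed = seed)
  montecarlo_contig_spectrum(pop, sq, seed = seed + 1L)
}

# A tight search specification that keeps optimizer tests fast.
tiny_spec <- function(..., seed = 1) {
  search_spec(M_bounds = c(200, 400), L_bounds = c(10000, 15000),
              d_bounds = c(0.01, 0.1), distributions = "exp", N_L = 1,
              ga = list(pop_size = 20, generations = 40, patience = 10),
              seed = seed, ...)
}
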