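# Shared fixtures: tiny, fast configurations and independent oracles.

# GA configuration small enough for unit tests of fitter mechanics
quick_config <- function(seed = 1L, ...) {
  fit_config(population_size = 24L, generations = 40L, seed = seed, ...)
}

# independent root oracle for beta*cot(beta) + L - 1 = 0: plain uniroot
# bisection on the stated bracket, no shared code with solve_eigenvalues()
oracle_root <- function(biot, n) {
  f <- function(b) b / tan(b) + biot - 1
  stats::uniroot(f, c((n - 1) * pi + 1e-9, n * pi - 1e-9),
                 tol = 1e-14)$root
}

# independent series oracle in the diffusion-controlled limit: literal
# partial sum with a fixed large term count
oracle_large_l_fraction <- function(tau, n_terms = 1e4) {
  n <- seq_len(n_terms)
  vapply(tau, function(tt)
    1 - 6 / pi^2 * sum(exp(-n^2 * pi^2 * tt) / n^2), numeric(1))
}

# noiseless single curve from given truth, default informative design
make_truth_curve <- function(d_eff, h, radius = default_radius(),
                             n = 12L, f_lo = 0.05, f_hi = 0.99) {
  sc <- release_scenario("truth", model_params(d_eff, h, radius),
                         noise_sd = 0, n_replicates = 1L,
                         time_design = list(n = n, f_lo = f_lo, f_hi = f_hi))
  simulate_release_curves(sc)[[1]]
}
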