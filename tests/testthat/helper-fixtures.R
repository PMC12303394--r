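# Shared fixtures for the test suite. Everything is generated in code with
# fixed seeds; no files are read.

# A small random symmetric connectome with heterogeneous volumes.
toy_connectome <- function(R = 6, seed = 11, density = 0.5) {
  generate_connectome(R, density = density, seed = seed)
}

# Regional parameters with distinct spans per region.
toy_regional <- function(R = 6, seed = 11) {
  generate_regional_params(R, seed = seed)
}

toy_laplacian <- function(conn) volume_weight(build_laplacian(conn), conn)

# A midpoint-seeded initial state (first two regions elevated).
seeded_state <- function(rp, idx = 1:2) {
  y0 <- rp$baselines
  y0[idx] <- (rp$baselines[idx] + rp$capacities[idx]) / 2
  y0
}

# A small synthetic cohort plus its fitting context, for inference tests.
toy_study <- function(R = 8, N = 8, scans = 3, seed = 21,
                      rho_mu = 0.02, rho_sigma = 0.008,
                      alpha_mu = 0.15, alpha_sigma = 0.08,
                      noise_sd = 0.05, family = "local_fkpp",
                      onset_years = c(10, 25)) {
  conn <- generate_connectome(R, density = 0.5, seed = seed)
  rp <- generate_regional_params(R, seed = seed)
  gt <- ground_truth(conn, rp, rho_mu = rho_mu, rho_sigma = rho_sigma,
                     alpha_mu = alpha_mu, alpha_sigma = alpha_sigma,
                     noise_sd = noise_sd)
  gen <- generate_cohort(gt, n_subjects = N, scans_per_subject = scans,
                         family = family, onset_years = onset_years,
                         seed = seed)
  lap <- toy_laplacian(conn)
  list(conn = conn, rp = rp, lap = lap, cohort = gen$cohort,
       truth = gen$truth,
       ctx = model_context(lap, rp, family))
}

# Short sampler runs for structural tests (not convergence tests).
quick_config <- function(seed = 1, chains = 2, draws = 200, warmup = 200) {
  sampler_config(chains = chains, draws = draws, warmup = warmup, seed = seed)
}

quiet_fit <- function(...) suppressWarnings(fit_hierarchical(...))

# Build a hierarchical_posterior shell with prescribed draws, for testing
# scoring functions whose contract depends only on the draws and context.
fake_posterior <- function(draws, context, cohort, loglik = numeric(0),
                           family = context$family) {
  structure(
    list(draws = draws, chain = rep(1L, nrow(draws)), loglik = loglik,
         diagnostics = list(rhat = NULL, accept_rates = NULL, ode_failures = 0),
         config = quick_config(), priors = default_priors(),
         family = family, subject_ids = names(cohort$subjects),
         context = context, cohort = cohort),
    class = "hierarchical_posterior"
  )
}
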