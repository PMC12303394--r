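test_that("log-likelihood matches closed-form Gaussian sums", {
  # zero-rate trajectories are constant, so the likelihood is a plain
  # Gaussian density sum around each subject's initial state
  conn <- toy_connectome(2, seed = 5)
  rp <- toy_regional(2, seed = 5)
  ctx <- model_context(toy_laplacian(conn), rp, "local_fkpp")
  mk <- function(id, shift) {
    suvr <- rbind(rp$baselines + 0.2,
                  rp$baselines + 0.2 + shift,
                  rp$baselines + 0.2 + 2 * shift)
    colnames(suvr) <- conn$region_labels
    subject_series(id, c(0, 1, 2.5), suvr)
  }
  coh <- cohort(list(mk("a", 0.05), mk("b", -0.03)))
  theta <- data.frame(rho = c(0, 0), alpha = c(0, 0))
  sigma <- 0.07
  got <- log_likelihood(coh, theta, sigma, ctx)
  manual <- 0
  for (s in coh$subjects) {
    pred <- matrix(s$suvr[1, ], 3, 2, byrow = TRUE)
    manual <- manual + sum(dnorm(s$suvr, pred, sigma, log = TRUE))
  }
  expect_equal(got, manual, tolerance = 1e-10)

  # with nonzero rates, compare against an independent R-side integration
  theta2 <- data.frame(rho = c(0.03, 0.01), alpha = c(0.2, 0.1))
  got2 <- log_likelihood(coh, theta2, sigma, ctx)
  manual2 <- 0
  for (i in 1:2) {
    s <- coh$subjects[[i]]
    rhs <- function(t, y, p) {
      d <- y - rp$baselines
      list(as.numeric(-theta2$rho[i] * (ctx$laplacian$matrix %*% d) +
                        theta2$alpha[i] * d * (rp$qinf - d)))
    }
    sol <- deSolve::ode(s$initial_state, c(0, 1, 2.5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    manual2 <- manual2 + sum(dnorm(s$suvr, sol[, -1], sigma, log = TRUE))
  }
  expect_equal(got2, manual2, tolerance = 1e-6)

  # permuting the region ordering consistently leaves the likelihood alone
  perm <- c(2, 1)
  conn_p <- connectome(conn$adjacency[perm, perm],
                       volumes = conn$volumes[perm],
                       region_labels = conn$region_labels[perm],
                       reference_volume = conn$reference_volume)
  rp_p <- regional_params(rp$baselines[perm], rp$capacities[perm],
                          conn$region_labels[perm])
  ctx_p <- model_context(toy_laplacian(conn_p), rp_p, "local_fkpp")
  coh_p <- cohort(lapply(coh$subjects, function(s) {
    subject_series(s$subject_id, s$scan_times, s$suvr[, perm, drop = FALSE])
  }))
  expect_equal(log_likelihood(coh_p, theta2, sigma, ctx_p), got2,
               tolerance = 1e-8)
})

test_that("perturbing one observation by +sigma costs exactly half a nat", {
  st <- toy_study(R = 4, N = 2, noise_sd = 0, seed = 33)
  truth <- st$truth$subject_params
  theta <- truth[, c("rho", "alpha")]
  sigma <- 0.05
  base <- log_likelihood(st$cohort, theta, sigma, st$ctx)
  pert <- st$cohort
  pert$subjects[[1]]$suvr[2, 3] <- pert$subjects[[1]]$suvr[2, 3] + sigma
  expect_equal(log_likelihood(pert, theta, sigma, st$ctx) - base, -0.5,
               tolerance = 1e-4)
})

test_that("the sampler is seed-deterministic and respects the truncation", {
  st <- toy_study(R = 6, N = 5, seed = 44)
  cfg <- quick_config(seed = 9)
  f1 <- quiet_fit(st$cohort, st$ctx, config = cfg)
  f2 <- quiet_fit(st$cohort, st$ctx, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  # different seed gives different draws
  f3 <- quiet_fit(st$cohort, st$ctx, config = quick_config(seed = 10))
  expect_false(identical(f1$draws, f3$draws))
  # no negative transport draws anywhere
  rho_cols <- grep("^rho", colnames(f1$draws))
  expect_true(all(f1$draws[, rho_cols] >= 0))
  # every parameter has a recorded convergence diagnostic
  expect_named(f1$diagnostics$rhat, colnames(f1$draws))
})

test_that("population parameters are recovered on synthetic data", {
  st <- toy_study(R = 8, N = 16, seed = 55, rho_mu = 0.02, rho_sigma = 0.008,
                  alpha_mu = 0.15, alpha_sigma = 0.08, noise_sd = 0.05)
  fit <- quiet_fit(st$cohort, st$ctx,
                   config = quick_config(seed = 2, draws = 500, warmup = 500))
  qr <- quantile(fit$draws[, "rho_mu"], c(0.02, 0.98))
  qa <- quantile(fit$draws[, "alpha_mu"], c(0.02, 0.98))
  expect_gt(0.02, qr[1]); expect_lt(0.02, qr[2])
  expect_gt(0.15, qa[1]); expect_lt(0.15, qa[2])
  # subject-level estimates correlate with the generating rates
  ids <- st$truth$subject_params$subject_id
  alpha_hat <- colMeans(fit$draws[, paste0("alpha[", ids, "]")])
  expect_gt(cor(alpha_hat, st$truth$subject_params$alpha), 0.7)
})

test_that("a production-free cohort yields a production posterior near zero", {
  st <- toy_study(R = 6, N = 10, seed = 66, rho_mu = 0.03, rho_sigma = 0.01,
                  alpha_mu = 0, alpha_sigma = 1e-4, noise_sd = 0.05,
                  onset_years = c(2, 8))
  fit <- quiet_fit(st$cohort, st$ctx,
                   config = quick_config(seed = 3, draws = 400, warmup = 400))
  a <- fit$draws[, "alpha_mu"]
  expect_lt(abs(mean(a)), 2 * sd(a))
})

test_that("posterior noise grows with generator noise", {
  sig_hat <- vapply(c(0.05, 0.1), function(ns) {
    st <- toy_study(R = 6, N = 8, seed = 77, noise_sd = ns)
    fit <- quiet_fit(st$cohort, st$ctx, config = quick_config(seed = 4))
    mean(fit$draws[, "sigma"])
  }, numeric(1))
  expect_gt(sig_hat[2], sig_hat[1])
})

test_that("posterior predictions start at the initial state and fan out", {
  st <- toy_study(R = 6, N = 6, seed = 88)
  fit <- quiet_fit(st$cohort, st$ctx, config = quick_config(seed = 5))
  id <- st$truth$subject_params$subject_id[1]
  pp <- posterior_predict(fit, id, times = c(0, 1, 2, 4, 8),
                          include_noise = FALSE, ndraws = 100)
  y0 <- st$cohort$subjects[[id]]$initial_state
  # all draws equal the initial state exactly at t = 0
  expect_equal(max(abs(sweep(pp$draws[, 1, ], 2, y0))), 0)
  # 90% band width is non-decreasing with horizon (averaged over regions)
  width <- apply(pp$quantiles[, , "95%"] - pp$quantiles[, , "5%"], 1, mean)
  expect_true(all(diff(width) > -1e-6))

  # unknown subjects fall back to population draws with a warning
  y_new <- st$rp$baselines * 1.1
  names(y_new) <- st$conn$region_labels
  suvr <- matrix(y_new, 1, 6, dimnames = list(NULL, st$conn$region_labels))
  newcomer <- subject_series("newcomer", 0, suvr)
  expect_warning(
    pp2 <- posterior_predict(fit, newcomer, times = c(0, 2), ndraws = 50),
    "population")
  expect_true(pp2$population_fallback)
})

test_that("growing training series tighten iterative forecasts", {
  st <- toy_study(R = 6, N = 10, scans = 6, seed = 99, noise_sd = 0.05)
  split_ids <- names(st$cohort$subjects)
  train <- cohort(st$cohort$subjects[split_ids[1:7]])
  test <- cohort(st$cohort$subjects[split_ids[8:10]])
  out <- suppressWarnings(iterative_forecast_experiment(
    train, test, st$ctx, scans_per_iteration = c(1, 3),
    config = quick_config(seed = 6, draws = 300, warmup = 300)))
  expect_equal(out$n_train_scans, c(1, 3))
  expect_equal(out$n_test, c(3, 3))
  # more training scans should not widen the predictive interval
  expect_lte(out$mean_interval_width[2], out$mean_interval_width[1])

  # an empty test cohort gives an empty summary without error
  empty <- iterative_forecast_experiment(train, NULL, st$ctx)
  expect_equal(nrow(empty), 0)
  # asking for more training scans than test subjects have is an error
  expect_error(
    iterative_forecast_experiment(train, test, st$ctx,
                                  scans_per_iteration = c(1, 6)),
    "too few")
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(1)
  good <- cbind(p = rnorm(2000))
  expect_lt(abs(split_rhat(good, rep(1:2, each = 1000))["p"] - 1), 0.02)
  bad <- cbind(p = c(rnorm(1000, 0), rnorm(1000, 5)))
  expect_gt(split_rhat(bad, rep(1:2, each = 1000))["p"], 1.5)
})

test_that("in-sampler ODE tolerances do not distort trajectories", {
  st <- toy_study(R = 6, N = 4, seed = 111)
  y0 <- st$cohort$subjects[[1]]$initial_state
  dev <- check_ode_sensitivity(st$ctx, y0, c(0, 2, 5), rho = 0.02,
                               alpha = 0.15)
  expect_lt(dev, 1e-5)
})
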