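test_that("parameter counts match the family structure", {
  expect_identical(count_parameters("local_fkpp", 57), 119L)
  expect_identical(count_parameters("global_fkpp", 57), 119L)
  expect_identical(count_parameters("diffusion", 57), 60L)
  expect_identical(count_parameters("logistic", 57), 60L)
  expect_error(count_parameters("heterodimer", 57), "unknown")
})

test_that("BIC reduces to k log(n) - 2 log L on hand-checkable fixtures", {
  st <- toy_study(R = 4, N = 2, seed = 7)
  ctx <- st$ctx
  draws <- matrix(0.1, 1, 1, dimnames = list(NULL, "sigma"))
  post <- fake_posterior(draws, ctx, st$cohort, loglik = 0)  # L = 1
  sc <- compute_bic(post, k = 1, n_obs = 1)
  expect_equal(sc$bic, 0)

  # on a real fit the identity holds with derived counts
  fit <- quiet_fit(st$cohort, ctx, config = quick_config(seed = 2,
                                                         draws = 100,
                                                         warmup = 100))
  sc2 <- compute_bic(fit)
  expect_equal(sc2$k, count_parameters("local_fkpp", 2))
  expect_equal(sc2$n_obs, n_observations(st$cohort))
  expect_equal(sc2$bic, sc2$k * log(sc2$n_obs) - 2 * max(fit$loglik))
  expect_error(compute_bic(fake_posterior(draws, ctx, st$cohort)), "no draws")
})

test_that("ELPD equals hand-computed log-mean-exp over posterior draws", {
  # zero-rate context: predictions equal the conditioning initial state,
  # so per-draw likelihoods have a closed form
  conn <- toy_connectome(2, seed = 15)
  rp <- toy_regional(2, seed = 15)
  ctx <- model_context(toy_laplacian(conn), rp, "local_fkpp")
  y0 <- rp$baselines + 0.1
  mk_train <- function(id) {
    suvr <- rbind(y0, y0 + 0.02)
    colnames(suvr) <- conn$region_labels
    subject_series(id, c(0, 1), suvr)
  }
  mk_held <- function(id, obs) {
    suvr <- matrix(obs, 1, 2, dimnames = list(NULL, conn$region_labels))
    subject_series(id, 2, suvr, initial_state = y0)
  }
  train <- cohort(list(mk_train("a"), mk_train("b")))
  held <- cohort(list(mk_held("a", y0 + 0.05), mk_held("b", y0 - 0.04)))

  sigmas <- c(0.05, 0.12)
  draws <- cbind("rho[a]" = c(0, 0), "rho[b]" = c(0, 0),
                 "alpha[a]" = c(0, 0), "alpha[b]" = c(0, 0),
                 sigma = sigmas)
  post <- fake_posterior(draws, ctx, train)
  got <- compute_elpd(post, held)
  manual <- 0
  for (id in c("a", "b")) {
    per_draw <- vapply(sigmas, function(sg) {
      sum(dnorm(held$subjects[[id]]$suvr, matrix(y0, 1, 2), sg, log = TRUE))
    }, numeric(1))
    m <- max(per_draw)
    manual <- manual + m + log(mean(exp(per_draw - m)))
  }
  expect_equal(got, manual, tolerance = 1e-10)

  # a single draw degenerates to the plain held-out log-likelihood
  post1 <- fake_posterior(draws[1, , drop = FALSE], ctx, train)
  exp1 <- sum(vapply(c("a", "b"), function(id) {
    sum(dnorm(held$subjects[[id]]$suvr, matrix(y0, 1, 2), sigmas[1],
              log = TRUE))
  }, numeric(1)))
  expect_equal(compute_elpd(post1, held), exp1, tolerance = 1e-10)

  # invariant to the ordering of held-out subjects
  held_rev <- cohort(rev(held$subjects))
  expect_equal(compute_elpd(post, held_rev), got, tolerance = 1e-12)

  # unknown held-out subjects are an error
  held_bad <- cohort(list(mk_held("zz", y0)))
  expect_error(compute_elpd(post, held_bad), "zz")
})

test_that("log-mean-exp is stable for extreme log-likelihoods", {
  expect_equal(tauspread:::log_mean_exp(c(-1e4, -1e4)), -1e4)
  expect_equal(tauspread:::log_mean_exp(c(1e4, 1e4 - log(2))),
               1e4 + log(0.75))
  expect_equal(tauspread:::log_mean_exp(c(-Inf, 0)), log(0.5))
})

test_that("residual summaries report signed final-scan errors", {
  st <- toy_study(R = 5, N = 4, seed = 19, noise_sd = 0)
  truth <- st$truth$subject_params
  cols <- c(paste0("rho[", truth$subject_id, "]"),
            paste0("alpha[", truth$subject_id, "]"), "sigma")
  draws <- matrix(rep(c(truth$rho, truth$alpha, 0.05), 2), 2,
                  byrow = TRUE, dimnames = list(NULL, cols))
  post <- fake_posterior(draws, st$ctx, st$cohort)

  # noise-free data at the generating rates: zero residuals
  rs <- residual_summary(post)
  expect_lt(max(abs(rs$per_region)), 1e-5)

  # a constant observation shift appears as the mean signed error
  shifted <- st$cohort
  for (i in seq_along(shifted$subjects)) {
    n <- shifted$subjects[[i]]$n_scans
    shifted$subjects[[i]]$suvr[n, ] <- shifted$subjects[[i]]$suvr[n, ] - 0.04
  }
  rs2 <- residual_summary(post, shifted)
  expect_equal(rs2$mean_error, 0.04, tolerance = 1e-5)
})

test_that("a logistic fit on transport-dominated data underestimates cold regions", {
  st <- toy_study(R = 8, N = 8, seed = 23, rho_mu = 0.06, rho_sigma = 0.015,
                  alpha_mu = 0.02, alpha_sigma = 0.02, noise_sd = 0.03,
                  onset_years = c(1, 4))
  ctx_log <- model_context(st$lap, st$rp, "logistic")
  fit <- quiet_fit(st$cohort, ctx_log,
                   config = quick_config(seed = 8, draws = 300, warmup = 300))
  rs <- residual_summary(fit)
  # regions still near baseline at the first scan grow by transport in
  # truth, which a production-only model cannot reproduce
  first_scan <- sapply(st$cohort$subjects, function(s) s$suvr[1, ])
  cold <- rowMeans(first_scan) < quantile(rowMeans(first_scan), 0.5)
  expect_lt(mean(rs$per_region[cold]), 0)
})

test_that("spatial shuffling permutes values jointly and preserves multisets", {
  st <- toy_study(R = 6, N = 4, seed = 29)
  sh <- spatial_shuffle(st$cohort, st$rp, seed = 1,
                        permutation = seq_len(6))
  expect_equal(sh$cohort$subjects[[1]]$suvr, st$cohort$subjects[[1]]$suvr)
  expect_equal(sh$regional_params$baselines, st$rp$baselines)

  sh2 <- spatial_shuffle(st$cohort, st$rp, seed = 42)
  perm <- sh2$permutation
  expect_false(all(perm == seq_len(6)))
  for (i in seq_along(st$cohort$subjects)) {
    a <- st$cohort$subjects[[i]]$suvr
    b <- sh2$cohort$subjects[[i]]$suvr
    # per-scan multisets of SUVR values are preserved
    for (r in seq_len(nrow(a))) expect_equal(sort(a[r, ]), sort(b[r, ]),
                                             ignore_attr = TRUE)
    expect_equal(unname(b), unname(a[, perm, drop = FALSE]))
  }
  # the same permutation is applied to baselines and capacities
  expect_equal(unname(sh2$regional_params$baselines),
               unname(st$rp$baselines[perm]))
  expect_equal(unname(sh2$regional_params$capacities),
               unname(st$rp$capacities[perm]))
  # region labels keep their original order (the graph is untouched)
  expect_identical(colnames(sh2$cohort$subjects[[1]]$suvr),
                   st$cohort$region_labels)
  # identical seed, identical shuffle
  sh3 <- spatial_shuffle(st$cohort, st$rp, seed = 42)
  expect_identical(sh3$permutation, sh2$permutation)
})

test_that("scores are invariant to subject ordering", {
  st <- toy_study(R = 5, N = 5, seed = 37)
  fit <- quiet_fit(st$cohort, st$ctx, config = quick_config(seed = 11,
                                                            draws = 150,
                                                            warmup = 150))
  sc <- compute_bic(fit)
  rev_cohort <- cohort(rev(st$cohort$subjects))
  expect_equal(compute_bic(fit, rev_cohort)$bic, sc$bic)
})
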