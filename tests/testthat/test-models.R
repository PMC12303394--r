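test_that("the healthy baseline is a fixed point of every family", {
  conn <- toy_connectome(6)
  rp <- toy_regional(6)
  lap <- toy_laplacian(conn)
  expect_equal(rhs_local_fkpp(rp$baselines, lap, rp, rho = 0.1, alpha = 0.4),
               rep(0, 6), tolerance = 1e-12)
  # integrated: s stays at s0 for each family
  for (fam in c("local_fkpp", "global_fkpp", "diffusion", "logistic")) {
    spec <- model_spec(fam, transport_rate = 0.05, production_rate = 0.3)
    # the healthy state of the global variant is its scalar baseline
    s_star <- if (fam == "global_fkpp") rep(min(rp$baselines), 6) else rp$baselines
    tr <- simulate_model(spec, lap, rp, s_star, times = c(0, 5, 10))
    expect_equal(max(abs(sweep(tr$values, 2, s_star))), 0,
                 tolerance = 1e-7)
  }
  # heterodimer healthy equilibrium p = k0/k1, ptilde = 0
  rates <- list(k0 = 2, k1 = 0.5, k12 = 1, k1t = 0.4)
  d <- rhs_heterodimer(rep(4, 6), rep(0, 6), lap, rates, rho = 0.1)
  expect_equal(d$healthy, rep(0, 6), tolerance = 1e-12)
  expect_equal(d$toxic, rep(0, 6), tolerance = 1e-12)
})

test_that("local FKPP right-hand side matches its closed form", {
  conn <- toy_connectome(5, seed = 7)
  rp <- toy_regional(5, seed = 7)
  lap <- toy_laplacian(conn)
  set.seed(1)
  s <- rp$baselines + runif(5, 0, 1) * rp$qinf
  d <- s - rp$baselines
  expect_equal(
    rhs_local_fkpp(s, lap, rp, rho = 0.03, alpha = 0.2),
    as.numeric(-0.03 * lap$matrix %*% d + 0.2 * d * (rp$qinf - d)))
  expect_error(rhs_local_fkpp(s[1:3], lap, rp, 0.03, 0.2), "mismatch")

  # at carrying capacity the production term vanishes; transport does not
  # unless the capacity span is constant across regions
  d_at_cap <- rhs_local_fkpp(rp$capacities, lap, rp, rho = 0.03, alpha = 0.2)
  expect_equal(d_at_cap,
               as.numeric(-0.03 * lap$matrix %*% rp$qinf))
  expect_gt(max(abs(d_at_cap)), 0)
  rp_const <- regional_params(rp$baselines, rp$baselines + 0.8)
  expect_equal(rhs_local_fkpp(rp_const$capacities, lap, rp_const, 0.03, 0.2),
               rep(0, 5), tolerance = 1e-12)

  # single region, rho = 0: logistic growth peaks at the midpoint with
  # rate alpha * span^2 / 4
  lap1 <- build_laplacian(connectome(matrix(0, 1, 1)))
  rp1 <- regional_params(1.1, 2.1)
  expect_equal(rhs_local_fkpp(1.6, lap1, rp1, rho = 0, alpha = 0.4),
               0.4 * 1^2 / 4)
})

test_that("pure diffusion conserves the volume-weighted total signal", {
  for (seed in c(2, 5)) {
    conn <- toy_connectome(8, seed = seed)
    rp <- toy_regional(8, seed = seed)
    lap <- toy_laplacian(conn)
    spec <- model_spec("diffusion", transport_rate = 0.05)
    tr <- simulate_model(spec, lap, rp, seeded_state(rp),
                         times = seq(0, 50, 5))
    tot <- as.numeric(tr$values %*% conn$volumes)
    expect_lt(max(abs(tot - tot[1])) / abs(tot[1]), 1e-8)
  }
})

test_that("local FKPP trajectories respect the invariant bounds", {
  conn <- toy_connectome(8, seed = 9)
  rp <- toy_regional(8, seed = 9)
  lap <- toy_laplacian(conn)
  spec <- model_spec("local_fkpp", transport_rate = 0.03,
                     production_rate = 0.25)
  set.seed(3)
  y0 <- rp$baselines + runif(8) * rp$qinf
  tr <- simulate_model(spec, lap, rp, y0, times = seq(0, 40, 2))
  eps <- 1e-6 * rp$qinf
  # the baseline is a lower barrier regardless of capacity heterogeneity
  expect_true(all(t(tr$values) >= rp$baselines - eps))
  expect_true(all(is.finite(tr$values)))
  # with heterogeneous spans, transport inflow pushes low-capacity regions
  # transiently (and even asymptotically) above their own capacity
  expect_gt(max(t(tr$values) - rp$capacities), 0)

  # with a constant capacity span the full box [s0, sinf] is invariant
  rp_const <- regional_params(rp$baselines, rp$baselines + 0.9)
  set.seed(4)
  y0c <- rp_const$baselines + runif(8) * 0.9
  trc <- simulate_model(model_spec("local_fkpp", 0.05, 0.25), lap, rp_const,
                        y0c, times = seq(0, 50, 2))
  epsc <- 1e-6 * rp_const$qinf
  expect_true(all(t(trc$values) >= rp_const$baselines - epsc))
  expect_true(all(t(trc$values) <= rp_const$capacities + epsc))
})

test_that("SUVR and concentration forms agree under rescaling", {
  conn <- toy_connectome(10, seed = 13)
  rp <- toy_regional(10, seed = 13)
  lap <- toy_laplacian(conn)
  rho <- 0.025; alpha <- 0.25
  y0 <- seeded_state(rp)
  times <- seq(0, 30, 2)
  spec <- model_spec("local_fkpp", rho, alpha)
  q_from_s <- rescale_to_concentration(
    simulate_model(spec, lap, rp, y0, times), rp)

  # independent oracle: integrate the rescaled network FKPP equation
  # directly (alpha_hat = alpha * qinf, Lhat = Qinf^-1 L Qinf)
  qinf <- rp$qinf
  Lhat <- sweep(sweep(lap$matrix, 2, qinf, `*`), 1, qinf, `/`)
  alpha_hat <- alpha * qinf
  rhs_q <- function(t, q, p) {
    list(as.numeric(-rho * (Lhat %*% q) + alpha_hat * q * (1 - q)))
  }
  q0 <- (y0 - rp$baselines) / qinf
  oracle <- deSolve::ode(q0, times, rhs_q, NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(q_from_s$values - oracle[, -1])), 1e-6)

  # trivial endpoints of the rescaling map
  tr0 <- trajectory(c(0, 1), rbind(rp$baselines, rp$capacities))
  q <- rescale_to_concentration(tr0, rp)
  expect_equal(unname(q$values), rbind(rep(0, 10), rep(1, 10)))
  expect_error(rescale_to_concentration(q, rp), "already")
})

test_that("reduced families are nested in the local FKPP model", {
  conn <- toy_connectome(7, seed = 17)
  rp <- toy_regional(7, seed = 17)
  lap <- toy_laplacian(conn)
  y0 <- seeded_state(rp)
  times <- seq(0, 20, 2)
  sim <- function(fam, rho, alpha) {
    simulate_model(model_spec(fam, rho, alpha), lap, rp, y0, times)$values
  }
  expect_equal(sim("local_fkpp", 0, 0.25), sim("logistic", 0.9, 0.25),
               tolerance = 1e-7)
  expect_equal(sim("local_fkpp", 0.04, 0), sim("diffusion", 0.04, 0.7),
               tolerance = 1e-7)
})

test_that("logistic trajectories approach the carrying capacity monotonically", {
  lap1 <- build_laplacian(connectome(matrix(0, 1, 1)))
  rp1 <- regional_params(1.1, 2.3)
  tr <- simulate_model(model_spec("logistic", 0, 0.6), lap1, rp1, 1.3,
                       times = seq(0, 60, 2))
  expect_true(all(diff(tr$values[, 1]) > -1e-8))  # monotone up to solver noise
  expect_lt(abs(tr$values[nrow(tr$values), 1] - 2.3), 1e-3)
})

test_that("heterodimer kinetics reduce to FKPP near the healthy state", {
  # k12 = 0 is a linear decay of toxic load at rate k1t
  lap1 <- build_laplacian(connectome(matrix(0, 1, 1)))
  rates0 <- list(k0 = 1, k1 = 0.5, k12 = 1e-12, k1t = 0.4)
  spec0 <- model_spec("heterodimer", 0, 0, heterodimer_rates = rates0)
  tr <- simulate_model(spec0, lap1, NULL, c(2, 0.3), times = seq(0, 10, 1))
  expect_equal(tr$values[, 2], 0.3 * exp(-0.4 * (0:10)), tolerance = 1e-5)

  # with conversion, the early toxic growth follows the linearised
  # alpha * pt - beta * pt^2 reduction while pt << p
  k0 <- 1; k1 <- 0.5; k12 <- 0.35; k1t <- 0.4
  alpha_red <- k0 * k12 / k1          # net linear growth: k0 k12 / k1 - k1t
  beta_red <- k0 * k12^2 / k1^2
  rates <- list(k0 = k0, k1 = k1, k12 = k12, k1t = k1t)
  spec <- model_spec("heterodimer", 0, 0, heterodimer_rates = rates)
  pt0 <- 1e-3
  times <- seq(0, 8, 0.5)
  full <- simulate_model(spec, lap1, NULL, c(k0 / k1, pt0), times)$values[, 2]
  rhs_red <- function(t, y, p) list((alpha_red - k1t) * y - beta_red * y^2)
  red <- deSolve::ode(pt0, times, rhs_red, NULL, rtol = 1e-10)[, 2]
  expect_equal(full, red, tolerance = 0.05)
})

test_that("stage means track the invasion of Braak regions in order", {
  # all-zero concentrations give zero stage means; a single stage
  # reproduces the global mean
  tr <- trajectory(c(0, 1), matrix(0, 2, 4,
                                   dimnames = list(NULL, letters[1:4])),
                   scale = "concentration")
  stages <- setNames(c(1L, 1L, 2L, 2L), letters[1:4])
  expect_equal(unname(braak_region_means(tr, stages)),
               matrix(0, 2, 2))
  tr2 <- trajectory(c(0, 1), matrix(c(0.1, 0.2, 0.3, 0.4,
                                      0.5, 0.6, 0.7, 0.8),
                                    2, 4, byrow = FALSE,
                                    dimnames = list(NULL, letters[1:4])),
                    scale = "concentration")
  one <- setNames(rep(1L, 4), letters[1:4])
  expect_equal(unname(braak_region_means(tr2, one)[1, ]),
               unname(rowMeans(tr2$values)))
  expect_error(braak_region_means(tr2, stages[1:2]), "missing")

  # a seeded whole-brain simulation reaches half-saturation in the
  # entorhinal stage before the association-cortex stage
  conn <- generate_connectome(72, density = 0.3, seed = 31)
  rp <- generate_regional_params(72, seed = 31)
  lap <- toy_laplacian(conn)
  idx <- grep("entorhinal", conn$region_labels)
  y0 <- rp$baselines
  y0[idx] <- (rp$baselines[idx] + rp$capacities[idx]) / 2
  tr <- simulate_model(model_spec("local_fkpp", 0.025, 0.25), lap, rp, y0,
                       times = seq(0, 45, 1))
  q <- rescale_to_concentration(tr, rp)
  sm <- braak_region_means(q)
  crossing <- apply(sm, 1, function(x) {
    i <- which(x >= 0.5)[1]
    if (is.na(i)) Inf else q$times[i]
  })
  expect_lt(crossing["stage_1"], crossing["stage_5"])
})

test_that("simulate_model validates inputs", {
  conn <- toy_connectome(4)
  rp <- toy_regional(4)
  lap <- toy_laplacian(conn)
  spec <- model_spec("local_fkpp", 0.02, 0.2)
  expect_error(simulate_model(spec, lap, rp, rp$baselines[1:2], 0:3),
               "mismatch")
  expect_error(simulate_model(spec, lap, rp, rp$baselines, c(0, 0)),
               "increasing")
  expect_error(model_spec("local_fkpp", transport_rate = -1), "nonnegative")
  expect_error(model_spec("heterodimer"), "requires")
})
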